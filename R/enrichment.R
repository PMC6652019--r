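# Hypergeometric subgroup enrichment with a BLAST-similarity background.
#
# The upper-tail probability is computed from first principles in log
# space (log-gamma binomial coefficients, log-sum-exp accumulation with
# early termination) rather than delegated to a distribution routine, so
# the tail convention and numerical behaviour are explicit and testable
# against brute-force enumeration.

#' Exact upper-tail hypergeometric probability P(X >= k)
#'
#' For a population of `N` genes of which `K` are "successes" (the
#' background), and a sample of `n` genes (the induced set) containing `k`
#' successes, returns the one-sided enrichment p value
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`,
#' evaluated via log-gamma with log-sum-exp accumulation; the sum
#' terminates early once a term falls below 1e-16 of the running total.
#'
#' @param N population size.
#' @param K background successes (K <= N).
#' @param n sample size (n <= N).
#' @param k observed successes (0 <= k <= min(K, n)).
#' @return p value in (0, 1].
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop("N, K, n, k must be single non-negative integers", call. = FALSE)
  if (K > N || n > N || k > min(K, n))
    stop("invalid contingency: need k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(K, n)
  log_denom <- lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1)
  log_terms <- (lgamma(K + 1) - lgamma(i + 1) - lgamma(K - i + 1)) +
    (lgamma(N - K + 1) - lgamma(n - i + 1) - lgamma(N - K - n + i + 1)) -
    log_denom
  # log-sum-exp with early termination at 1e-16 relative tolerance; terms
  # are unimodal in i, so only terminate once they are decreasing
  m <- max(log_terms)
  acc <- 0
  prev <- Inf
  for (lt in log_terms) {
    term <- exp(lt - m)
    acc <- acc + term
    if (lt < prev && term < 1e-16 * acc) break
    prev <- lt
  }
  min(1, exp(m) * acc)
}

#' Enrichment factor (k/n) / (K/N)
#'
#' @inheritParams hypergeom_pvalue
#' @return over-representation of the subgroup among selected genes
#'   relative to its background frequency.
#' @export
enrichment_factor <- function(N, K, n, k) {
  if (K <= 0 || n <= 0) stop("K and n must be > 0", call. = FALSE)
  (k / n) / (K / N)
}

#' BLAST-similarity background for a subgroup
#'
#' The background against which a functional subgroup is tested is the set
#' of genome genes similar to the subgroup: the subgroup itself plus every
#' gene hit by any subgroup member below the e-value threshold in a
#' genome-wide search.
#'
#' @param subgroup character vector of subgroup gene ids (non-empty).
#' @param hits hit table with columns `query`, `subject`, `evalue`.
#' @param e_threshold e-value threshold (default 1e-5, strict `<`).
#' @return character vector: the background gene set.
#' @export
blast_background <- function(subgroup, hits, e_threshold = 1e-5) {
  if (length(subgroup) == 0) stop("empty subgroup", call. = FALSE)
  stopifnot(all(c("query", "subject", "evalue") %in% names(hits)))
  hit_genes <- hits$subject[hits$query %in% subgroup &
                              hits$evalue < e_threshold]
  sort(unique(c(subgroup, hit_genes)))
}

#' Hypergeometric enrichment of subgroups within the induced set
#'
#' For each subgroup (a subset of the induced genes), k is the subgroup
#' size, n the induced-set size, K the size of its BLAST-similarity
#' background, and N the genome size.  Rows are sorted by p value.
#'
#' @param induced character vector of induced gene ids.
#' @param subgroups named list of gene-id vectors, each a subset of
#'   `induced`.
#' @param hits genome-wide hit table (see [blast_background()]).
#' @param genome_size N.
#' @param e_threshold background e-value threshold.
#' @param adjust add a Benjamini-Hochberg adjusted-p column.
#' @return data frame: subgroup, N, K, n, k, enrichment_factor, p_value
#'   (and `p_adjusted` when `adjust`).
#' @export
enrich_subgroups <- function(induced, subgroups, hits, genome_size,
                             e_threshold = 1e-5, adjust = FALSE) {
  stopifnot(is.list(subgroups), !is.null(names(subgroups)))
  n <- length(unique(induced))
  rows <- lapply(names(subgroups), function(nm) {
    sg <- unique(subgroups[[nm]])
    if (!all(sg %in% induced))
      stop("subgroup '", nm, "' is not a subset of the induced set",
           call. = FALSE)
    bg <- blast_background(sg, hits, e_threshold)
    K <- length(bg)
    if (K == 0) stop("empty background for subgroup '", nm, "'",
                     call. = FALSE)
    k <- length(sg)
    data.frame(subgroup = nm, N = genome_size, K = K, n = n, k = k,
               enrichment_factor = enrichment_factor(genome_size, K, n, k),
               p_value = hypergeom_pvalue(genome_size, K, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), , drop = FALSE]
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
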