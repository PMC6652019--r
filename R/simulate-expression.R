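# Negative-binomial count simulator with planted coculture induction.
#
# RPKM normalization downstream uses the *configured* library sizes as the
# mapped totals, not the realized count sums: with fixed normalization
# constants the expected Co/Mo of a planted gene equals its fold exactly,
# whereas realized-total normalization would deflate every ratio by the
# compositional shift the induced genes introduce.

#' Simulate per-condition read counts with planted differential genes
#'
#' Per-gene expected counts are proportional to gene length (kb) times a
#' log-normal baseline; coculture means are additionally multiplied by the
#' planted fold for induced/repressed genes.  Counts are negative binomial
#' (mean/dispersion parameterization).  The configured library sizes are
#' returned as the mapped totals for RPKM normalization, so a planted
#' gene's expected Co/Mo ratio equals its fold.
#'
#' @param genes gene table (needs `gene_id`, `start`, `end`).
#' @param spec an [expression_spec()].
#' @param seed integer seed for this simulator's RNG stream.
#' @return list with `counts` (data frame gene_id, count_mono, count_co),
#'   `lib_sizes` (named numeric `c(mono=, co=)`, the configured mapped
#'   totals), and `truth` (induced/repressed gene-id sets).
#' @export
simulate_expression <- function(genes, spec, seed = 1L) {
  stopifnot(inherits(spec, "expression_spec"))
  if (spec$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  n <- nrow(genes)
  if (spec$n_induced + spec$n_repressed > n)
    stop("more planted differential genes than genes", call. = FALSE)
  with_rng(stream_seed(seed, "expression"), {
    len_kb <- (genes$end - genes$start + 1) / 1000
    baseline <- exp(rnorm(n, mean = 0, sd = 1))
    planted <- sample.int(n, spec$n_induced + spec$n_repressed)
    induced <- planted[seq_len(spec$n_induced)]
    repressed <- setdiff(planted, induced)
    fold <- rep(1, n)
    fold[induced] <- spec$fold_induced
    fold[repressed] <- spec$fold_repressed

    w_mono <- len_kb * baseline
    mu_mono <- w_mono / sum(w_mono) * spec$lib_mono
    w_co <- w_mono * fold
    mu_co <- w_co / sum(w_mono) * spec$lib_co
    size <- 1 / spec$dispersion
    count_mono <- rnbinom(n, mu = mu_mono, size = size)
    count_co <- rnbinom(n, mu = mu_co, size = size)

    list(
      counts = data.frame(gene_id = genes$gene_id,
                          count_mono = count_mono, count_co = count_co,
                          stringsAsFactors = FALSE),
      lib_sizes = c(mono = spec$lib_mono, co = spec$lib_co),
      truth = list(induced = genes$gene_id[induced],
                   repressed = genes$gene_id[repressed])
    )
  })
}
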