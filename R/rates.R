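# Triplet relative-rate tests with consensus calling and a multi-method
# intersection rule for slow/fast evolver candidates.

split_aln <- function(alignment, names3) {
  if (inherits(alignment, "AAStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  missing <- setdiff(names3, names(alignment))
  if (length(missing))
    stop("sequence missing from alignment: ", missing[1], call. = FALSE)
  seqs <- lapply(alignment[names3], function(s)
    strsplit(toupper(s), "")[[1]])
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences differ in length", call. = FALSE)
  seqs
}

VALID_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

ungapped_columns <- function(f, r, o) {
  f %in% VALID_AA & r %in% VALID_AA & o %in% VALID_AA
}

#' Triplet relative-rate test (chi-square on private substitution counts)
#'
#' Over alignment columns with a valid residue in all three sequences,
#' counts the sites where only the focal sequence differs from the
#' agreeing reference and outgroup (`n_focal`) and the sites where only
#' the reference differs (`n_ref`).  Under equal rates the two counts have
#' equal expectation, giving the chi-square statistic
#' `(n_focal - n_ref)^2 / (n_focal + n_ref)` on 1 degree of freedom.  A
#' significant excess of focal-private substitutions calls the focal
#' lineage fast; a deficit calls it slow.
#'
#' @param alignment named character vector (or `AAStringSet`) of aligned
#'   sequences.
#' @param triplet character vector or list with `focal`, `reference`,
#'   `outgroup` sequence names.
#' @param alpha significance level (default 0.05, boundary inclusive).
#' @return list: `n_focal`, `n_ref`, `statistic`, `p`, `direction` in
#'   `c("focal_slow", "focal_fast", "none")`.  `n_focal + n_ref == 0`
#'   yields statistic 0 and p = 1.
#' @export
triplet_rate_test <- function(alignment, triplet, alpha = 0.05) {
  tr <- as.list(triplet)
  seqs <- split_aln(alignment,
                    c(tr$focal, tr$reference, tr$outgroup))
  f <- seqs[[1]]; r <- seqs[[2]]; o <- seqs[[3]]
  ok <- ungapped_columns(f, r, o)
  f <- f[ok]; r <- r[ok]; o <- o[ok]
  n_focal <- sum(f != r & r == o)
  n_ref <- sum(r != f & f == o)
  tot <- n_focal + n_ref
  if (tot == 0) {
    return(list(n_focal = 0L, n_ref = 0L, statistic = 0, p = 1,
                direction = "none"))
  }
  stat <- (n_focal - n_ref)^2 / tot
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  direction <- "none"
  if (p <= alpha)
    direction <- if (n_focal > n_ref) "focal_fast" else "focal_slow"
  list(n_focal = as.integer(n_focal), n_ref = as.integer(n_ref),
       statistic = stat, p = p, direction = direction)
}

#' Consensus slow/fast call over the triplets of one orthogroup
#'
#' The orthogroup is called slow (fast) when at least
#' `consensus_fraction` of its triplets are significant with that
#' direction and no triplet is significant in the opposite direction;
#' otherwise none.  With `mode = "significant-only"` the fraction is taken
#' over significant triplets only (the alternative reading of a
#' "predictions matched in >= 90% of triplets" rule).
#'
#' @param results list of [triplet_rate_test()] results (or a data frame
#'   with a `direction` column) for one orthogroup.
#' @param consensus_fraction required agreeing fraction (default 0.9).
#' @param mode `"all"` (fraction over all triplets) or
#'   `"significant-only"`.
#' @return `"slow"`, `"fast"`, or `"none"`.
#' @export
consensus_rate_call <- function(results, consensus_fraction = 0.9,
                                mode = c("all", "significant-only")) {
  mode <- match.arg(mode)
  dirs <- if (is.data.frame(results)) results$direction
          else vapply(results, `[[`, character(1), "direction")
  if (!length(dirs)) stop("no triplet results", call. = FALSE)
  n_slow <- sum(dirs == "focal_slow")
  n_fast <- sum(dirs == "focal_fast")
  if (n_slow > 0 && n_fast > 0) return("none")
  denom <- if (mode == "all") length(dirs) else n_slow + n_fast
  if (denom == 0) return("none")
  if (n_slow / denom >= consensus_fraction) return("slow")
  if (n_fast / denom >= consensus_fraction) return("fast")
  "none"
}

#' Intersect slow/fast calls across independent methods
#'
#' An orthogroup becomes a final slow (fast) candidate when at least
#' `min_methods` methods call it slow (fast); calls in conflicting
#' directions never combine.
#'
#' @param calls data frame with columns `orthogroup`, `method`, `call`
#'   (values in `slow`, `fast`, `none`).
#' @param min_methods minimal number of agreeing methods (default 2).
#' @return list with character vectors `slow` and `fast`.
#' @export
multi_method_intersection <- function(calls, min_methods = 2) {
  stopifnot(all(c("orthogroup", "method", "call") %in% names(calls)))
  if (length(unique(calls$method)) < min_methods)
    stop("fewer methods supplied than min_methods", call. = FALSE)
  pick <- function(dir) {
    cnt <- tapply(calls$call == dir, calls$orthogroup, sum)
    sort(names(cnt)[cnt >= min_methods])
  }
  list(slow = pick("slow"), fast = pick("fast"))
}

#' Distance-based rate call (Poisson-corrected, bootstrap support)
#'
#' Computes Poisson-corrected distances `d = -ln(1 - p)` (p the fraction
#' of differing ungapped sites) from focal and reference to the outgroup,
#' then bootstraps alignment columns `B` times; the focal lineage is
#' called fast (slow) when the central `1 - alpha` percentile interval of
#' the bootstrapped distance difference excludes zero from above (below).
#' Saturated distances (p >= 1) and degenerate resamples give `none`.
#'
#' @inheritParams triplet_rate_test
#' @param B bootstrap column resamples (default 200; B = 1 is degenerate
#'   and always returns `none`).
#' @param seed integer seed for the bootstrap.
#' @return `"slow"`, `"fast"`, or `"none"`.
#' @export
distance_rate_method <- function(alignment, triplet, alpha = 0.05,
                                 B = 200, seed = 1L) {
  tr <- as.list(triplet)
  seqs <- split_aln(alignment, c(tr$focal, tr$reference, tr$outgroup))
  f <- seqs[[1]]; r <- seqs[[2]]; o <- seqs[[3]]
  ok <- ungapped_columns(f, r, o)
  f <- f[ok]; r <- r[ok]; o <- o[ok]
  n <- length(f)
  if (n == 0 || B < 2) return("none")
  pdist <- function(x, y) mean(x != y)
  dcorr <- function(p) if (p >= 1) NA_real_ else -log(1 - p)
  d_f <- dcorr(pdist(f, o))
  d_r <- dcorr(pdist(r, o))
  if (is.na(d_f) || is.na(d_r)) {
    warning("saturated distance; no call")
    return("none")
  }
  with_rng(seed, {
    diffs <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      db_f <- dcorr(pdist(f[idx], o[idx]))
      db_r <- dcorr(pdist(r[idx], o[idx]))
      if (is.na(db_f) || is.na(db_r)) NA_real_ else db_f - db_r
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 2) {
      "none"
    } else {
      ci <- quantile(diffs, probs = c(alpha / 2, 1 - alpha / 2),
                     names = FALSE)
      if (ci[1] > 0) "fast" else if (ci[2] < 0) "slow" else "none"
    }
  })
}

#' Run the full rate screen over simulated or loaded orthogroups
#'
#' Applies the chi-square triplet test with consensus calling (method
#' `"relrate"`) and the distance bootstrap method (method `"distance"`,
#' consensus over the same triplets), then intersects the per-method calls.
#'
#' @param alignments named list of orthogroup alignments.
#' @param triplets data frame `orthogroup`, `focal`, `reference`,
#'   `outgroup`.
#' @param alpha significance level.
#' @param consensus_fraction triplet-consensus fraction (default 0.9).
#' @param min_methods methods that must agree (default 2).
#' @param B bootstrap resamples for the distance method.
#' @param seed integer seed.
#' @return list with `per_method` (call data frame) and `final`
#'   (slow/fast candidate id vectors).
#' @export
rate_screen <- function(alignments, triplets, alpha = 0.05,
                        consensus_fraction = 0.9, min_methods = 2,
                        B = 200, seed = 1L) {
  ogs <- unique(triplets$orthogroup)
  rows <- lapply(seq_along(ogs), function(i) {
    og <- ogs[i]
    tt <- triplets[triplets$orthogroup == og, , drop = FALSE]
    aln <- alignments[[og]]
    if (is.null(aln)) stop("no alignment for orthogroup ", og, call. = FALSE)
    rr <- lapply(seq_len(nrow(tt)), function(j)
      triplet_rate_test(aln, tt[j, ], alpha))
    call_rr <- consensus_rate_call(rr, consensus_fraction)
    dd <- vapply(seq_len(nrow(tt)), function(j)
      distance_rate_method(aln, tt[j, ], alpha, B = B,
                           seed = stream_seed(seed + i, "alignments") + j),
      character(1))
    dd_dir <- ifelse(dd == "slow", "focal_slow",
                     ifelse(dd == "fast", "focal_fast", "none"))
    call_dd <- consensus_rate_call(
      data.frame(direction = dd_dir, stringsAsFactors = FALSE),
      consensus_fraction)
    data.frame(orthogroup = og,
               method = c("relrate", "distance"),
               call = c(call_rr, call_dd),
               stringsAsFactors = FALSE)
  })
  per_method <- do.call(rbind, rows)
  list(per_method = per_method,
       final = multi_method_intersection(per_method, min_methods))
}
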