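# Differential-expression screen on coculture/monoculture RPKM ratios.

#' Threshold sets for coculture induction/repression calling
#'
#' The mycobiont (fungus) and photobiont (alga) display different Co/Mo
#' ranges, so different ratio thresholds are used: induction at a Co/Mo
#' ratio >= 2 (fungus) or >= 1.3 (alga), repression at <= 0.5 or <= 0.77.
#' Boundary values are inclusive.
#'
#' @param induce induction ratio threshold (> 1).
#' @param repress repression ratio threshold (< 1).
#' @param log2_cut cut used by the log2-based classifier (> 0).
#' @param detection_floor RPKM below which, in both conditions, a gene is
#'   reported as not detected.
#' @return list of class `threshold_set`.
#' @export
threshold_set <- function(induce, repress, log2_cut = 0.6,
                          detection_floor = 0.5) {
  if (!(repress < 1 && 1 < induce))
    stop("thresholds must satisfy repress < 1 < induce", call. = FALSE)
  if (log2_cut <= 0) stop("log2_cut must be > 0", call. = FALSE)
  structure(list(induce = induce, repress = repress, log2_cut = log2_cut,
                 detection_floor = detection_floor),
            class = "threshold_set")
}

#' @rdname threshold_set
#' @param organism `"fungus"` or `"alga"`.
#' @export
default_thresholds <- function(organism = c("fungus", "alga")) {
  organism <- match.arg(organism)
  if (organism == "fungus") threshold_set(induce = 2,   repress = 0.5)
  else                      threshold_set(induce = 1.3, repress = 0.77)
}

#' Reads per kilobase of gene model per million aligned reads
#'
#' `rpkm = count / (length_bp / 1000) / (mapped_total / 1e6)`.
#'
#' @param counts non-negative read counts.
#' @param gene_lengths gene lengths in bp (> 0); recycled against `counts`
#'   only if scalar.
#' @param mapped_total total aligned reads in the library (> 0).
#' @param gene_ids optional ids used in error messages.
#' @return numeric RPKM vector.
#' @export
compute_rpkm <- function(counts, gene_lengths, mapped_total,
                         gene_ids = NULL) {
  stop_if_not_scalar_number(mapped_total, "mapped_total")
  if (mapped_total <= 0) stop("mapped_total must be > 0", call. = FALSE)
  if (length(gene_lengths) == 1L)
    gene_lengths <- rep(gene_lengths, length(counts))
  if (length(gene_lengths) != length(counts))
    stop("counts and gene_lengths differ in length", call. = FALSE)
  bad <- which(gene_lengths <= 0)
  if (length(bad)) {
    id <- if (!is.null(gene_ids)) gene_ids[bad[1]] else paste0("#", bad[1])
    stop("gene with non-positive length: ", id, call. = FALSE)
  }
  counts / (gene_lengths / 1000) / (mapped_total / 1e6)
}

#' Bootstrap (resampled) RPKM with percentile intervals
#'
#' The count vector is resampled `B` times as a multinomial draw at the
#' fixed library total, RPKM is computed per resample, and the per-gene
#' mean and 2.5/97.5 percentiles are reported.  This emulates a
#' resampled-RPKM expression estimate when the read-level data are not
#' available.
#'
#' @param counts integer counts, one per gene.
#' @param gene_lengths gene lengths in bp.
#' @param mapped_total library total used for normalization (defaults to
#'   `sum(counts)`).
#' @param B number of resamples (>= 1).
#' @param seed integer seed.
#' @return data frame with columns `mean`, `lower`, `upper` (one row per
#'   gene).
#' @export
bootstrap_rpkm <- function(counts, gene_lengths, mapped_total = sum(counts),
                           B = 1000, seed = 1L) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("no counts to resample", call. = FALSE)
  with_rng(seed, {
    res <- rmultinom(B, size = total, prob = counts / total)
    rp <- apply(res, 2, compute_rpkm, gene_lengths = gene_lengths,
                mapped_total = mapped_total)
    if (is.null(dim(rp))) rp <- matrix(rp, nrow = length(counts))
    data.frame(mean = rowMeans(rp),
               lower = apply(rp, 1, quantile, probs = 0.025),
               upper = apply(rp, 1, quantile, probs = 0.975))
  })
}

#' Build the per-gene expression table (RPKM, ratio, class)
#'
#' @param counts data frame with `gene_id`, `count_mono`, `count_co`.
#' @param gene_lengths lengths in bp, aligned with `counts` rows.
#' @param lib_sizes named numeric `c(mono=, co=)` of aligned-read totals.
#' @param thresholds a [threshold_set()].
#' @return data frame of per-gene records: counts, RPKM per condition,
#'   `ratio` (coculture/monoculture RPKM; `Inf` when the monoculture RPKM
#'   is 0 but the coculture RPKM is above the detection floor, `NA` when
#'   not detected), `log2_ratio`, and `class`.
#' @export
expression_table <- function(counts, gene_lengths, lib_sizes, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("mono", "co") %in% names(lib_sizes)))
  rpkm_mono <- compute_rpkm(counts$count_mono, gene_lengths,
                            lib_sizes[["mono"]], counts$gene_id)
  rpkm_co <- compute_rpkm(counts$count_co, gene_lengths,
                          lib_sizes[["co"]], counts$gene_id)
  tab <- data.frame(gene_id = counts$gene_id,
                    length_bp = gene_lengths,
                    count_mono = counts$count_mono,
                    count_co = counts$count_co,
                    rpkm_mono = rpkm_mono, rpkm_co = rpkm_co,
                    stringsAsFactors = FALSE)
  floor <- thresholds$detection_floor
  not_detected <- rpkm_mono < floor & rpkm_co < floor
  ratio <- ifelse(rpkm_mono > 0, rpkm_co / rpkm_mono,
                  ifelse(rpkm_co >= floor, Inf, NA_real_))
  ratio[not_detected] <- NA_real_
  tab$ratio <- ratio
  tab$log2_ratio <- log2(ratio)
  tab$class <- classify_differential(tab, thresholds)
  tab
}

#' Classify genes as induced / repressed / unchanged / not detected
#'
#' A gene whose monoculture and coculture RPKM both sit below the
#' detection floor is `not_detected`.  Otherwise the Co/Mo ratio is
#' compared with the thresholds, boundaries inclusive; a zero-monoculture
#' gene whose coculture RPKM clears the floor has ratio `Inf` and is
#' induced.
#'
#' @param table expression table with `rpkm_mono`, `rpkm_co` and `ratio`.
#' @param thresholds a [threshold_set()].
#' @return character vector over
#'   `c("induced", "repressed", "unchanged", "not_detected")`.
#' @export
classify_differential <- function(table, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  floor <- thresholds$detection_floor
  nd <- table$rpkm_mono < floor & table$rpkm_co < floor
  cls <- rep("unchanged", nrow(table))
  r <- table$ratio
  cls[!is.na(r) & r >= thresholds$induce] <- "induced"
  cls[!is.na(r) & r <= thresholds$repress] <- "repressed"
  cls[nd | is.na(r)] <- "not_detected"
  cls[nd] <- "not_detected"
  cls
}

#' Log2-fold-change classifier (GO-style screen)
#'
#' `log2(Co/Mo) > log2_cut` is up-regulated, `< -log2_cut` down-regulated,
#' anything between (inclusive) neither.
#'
#' @param table expression table with a `ratio` column (> 0 where
#'   classified; `NA` ratios are `neither`).
#' @param log2_cut positive cut, default 0.6.
#' @return character vector over `c("up", "down", "neither")`.
#' @export
classify_log2 <- function(table, log2_cut = 0.6) {
  if (log2_cut <= 0) stop("log2_cut must be > 0", call. = FALSE)
  lr <- log2(table$ratio)
  out <- rep("neither", nrow(table))
  out[!is.na(lr) & lr > log2_cut] <- "up"
  out[!is.na(lr) & lr < -log2_cut] <- "down"
  out
}
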