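# Consensus secretome calling and induced-secretome summaries.

#' Three-predictor consensus secretion call
#'
#' A protein is called secreted only if the signal-peptide predictor and
#' the localization predictor both score it secretory AND its
#' transmembrane annotation is compatible with secretion: no predicted TM
#' domain, or exactly one that starts within the N-terminal window (a
#' signal anchor).
#'
#' @param calls data frame with `signal_positive`, `target_secretory`,
#'   `tm_count`, `tm_first_start` (NA when `tm_count` is 0).
#' @param n_terminal_window residues from the N terminus within which a
#'   single TM domain is tolerated (default 60).
#' @return logical vector, one call per row.
#' @export
consensus_secreted <- function(calls, n_terminal_window = 60) {
  stopifnot(all(c("signal_positive", "target_secretory", "tm_count") %in%
                  names(calls)))
  tm_ok <- calls$tm_count == 0 |
    (calls$tm_count == 1 &
       !is.na(calls$tm_first_start) &
       calls$tm_first_start <= n_terminal_window)
  as.logical(calls$signal_positive & calls$target_secretory & tm_ok)
}

#' Mean protein length per gene subset
#'
#' @param protein_lengths named numeric vector (names = gene ids).
#' @param subsets named list of gene-id character vectors.
#' @return data frame `subset`, `n`, `mean_length` (NA for empty subsets).
#' @export
size_summary <- function(protein_lengths, subsets) {
  stopifnot(!is.null(names(protein_lengths)), is.list(subsets))
  rows <- lapply(names(subsets), function(nm) {
    ids <- intersect(subsets[[nm]], names(protein_lengths))
    data.frame(subset = nm, n = length(ids),
               mean_length = if (length(ids))
                 mean(protein_lengths[ids]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Contingency of the secretome among induced genes
#'
#' Returns the counts used for the enrichment of secreted proteins among
#' coculture-induced proteins: N = genome size, K = secretome size,
#' n = induced set size, k = induced-and-secreted, plus the two fractions
#' K/N and k/n as percentages rounded to one decimal.
#'
#' @param induced character vector of induced gene ids.
#' @param secreted character vector of secreted gene ids.
#' @param genome_size total number of genes N.
#' @return list with `N`, `K`, `n`, `k`, `genome_pct`, `induced_pct`.
#' @export
secretome_overlap <- function(induced, secreted, genome_size) {
  stop_if_not_scalar_number(genome_size, "genome_size", 1)
  K <- length(unique(secreted))
  n <- length(unique(induced))
  k <- length(intersect(unique(induced), unique(secreted)))
  list(N = as.integer(genome_size), K = K, n = n, k = k,
       genome_pct = round(100 * K / genome_size, 1),
       induced_pct = if (n > 0) round(100 * k / n, 1) else NA_real_)
}
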