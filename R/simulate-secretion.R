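# Secretion-predictor call simulator (signal peptide, secretory
# localization, transmembrane topology).

#' Simulate three-predictor secretion calls with planted true secretome
#'
#' True secreted genes receive a positive signal-peptide call, a
#' secretory-pathway localization call, and a secretion-compatible
#' transmembrane annotation (no TM domain, or a single N-terminal one),
#' each independently with probability `concordance`; a predictor "flip"
#' yields a negative call (for TM compatibility: two mid-protein domains).
#' Non-secreted genes draw independent false positives at `fp_rate` and a
#' Poisson number of TM domains at random positions.
#'
#' @param genes gene table (needs `gene_id`, `protein_length`).
#' @param spec a [secretome_spec()].
#' @param seed integer seed.
#' @return list with `calls` (data frame gene_id, signal_positive,
#'   target_secretory, tm_count, tm_first_start, protein_length) and
#'   `truth$secreted` (planted gene ids).
#' @export
simulate_secretion_calls <- function(genes, spec, seed = 1L) {
  stopifnot(inherits(spec, "secretome_spec"))
  if (spec$concordance < 0 || spec$concordance > 1)
    stop("concordance must be in [0, 1]", call. = FALSE)
  n <- nrow(genes)
  if (spec$n_true_secreted > n)
    stop("more planted secreted genes than genes", call. = FALSE)
  with_rng(stream_seed(seed, "secretion"), {
    plen <- genes$protein_length
    sec_idx <- sample.int(n, spec$n_true_secreted)
    is_sec <- seq_len(n) %in% sec_idx

    signal <- ifelse(is_sec, runif(n) < spec$concordance,
                     runif(n) < spec$fp_rate)
    target <- ifelse(is_sec, runif(n) < spec$concordance,
                     runif(n) < spec$fp_rate)

    tm_count <- integer(n)
    tm_first <- rep(NA_integer_, n)
    # true secretome: TM-compatible unless the TM predictor flips
    tm_ok <- runif(n) < spec$concordance
    for (i in seq_len(n)) {
      if (is_sec[i]) {
        if (tm_ok[i]) {
          if (runif(1) < 0.3) {           # signal anchor: one N-terminal TM
            tm_count[i] <- 1L
            tm_first[i] <- sample.int(30L, 1L)
          }
        } else {
          tm_count[i] <- 2L
          tm_first[i] <- sample(seq(80L, max(81L, plen[i] - 40L)), 1L)
        }
      } else {
        k <- rpois(1, 0.8)
        tm_count[i] <- k
        if (k >= 1L)
          tm_first[i] <- sample.int(max(2L, plen[i] - 20L), 1L)
      }
    }
    list(
      calls = data.frame(gene_id = genes$gene_id,
                         signal_positive = as.logical(signal),
                         target_secretory = as.logical(target),
                         tm_count = tm_count, tm_first_start = tm_first,
                         protein_length = plen,
                         stringsAsFactors = FALSE),
      truth = list(secreted = genes$gene_id[sec_idx])
    )
  })
}
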