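# Orthogroup alignment simulator: star triplets with rate-shifted focal
# branches under a Poisson replacement process.

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

mutate_seq <- function(anc, p_sub) {
  n <- length(anc)
  hit <- runif(n) < p_sub
  if (any(hit)) {
    repl <- sample(AA_ALPHABET20, sum(hit), replace = TRUE)
    # uniform replacement by a *different* residue
    same <- repl == anc[hit]
    while (any(same)) {
      repl[same] <- sample(AA_ALPHABET20, sum(same), replace = TRUE)
      same <- repl == anc[hit]
    }
    anc[hit] <- repl
  }
  anc
}

#' Simulate orthogroup protein alignments with rate-shifted focal branches
#'
#' Each orthogroup is a star: an ancestral sequence of uniform random
#' residues, a single focal sequence, and `n_triplets` independent
#' reference/outgroup sequence pairs.  Each branch replaces each site with
#' probability `base_subs` (outgroup: `out_subs`) by a uniformly chosen
#' different residue; the focal branch probability is multiplied by the
#' planted rate factor for slow/fast orthogroups (capped at 0.95).
#'
#' @param spec a [rate_spec()].
#' @param seed integer seed.
#' @return list with `alignments` (per-orthogroup named character-vector
#'   alignments: `focal`, `ref_i`, `out_i`), `triplets` (data frame
#'   orthogroup, focal, reference, outgroup) and `truth` (slow/fast
#'   orthogroup ids).
#' @export
simulate_alignments <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "rate_spec"))
  if (spec$length < 50) stop("alignment length must be >= 50", call. = FALSE)
  with_rng(stream_seed(seed, "alignments"), {
    og_ids <- sprintf("OG%04d", seq_len(spec$n_orthogroups))
    mult <- rep(1, spec$n_orthogroups)
    idx <- sample.int(spec$n_orthogroups, spec$n_slow + spec$n_fast)
    slow_idx <- idx[seq_len(spec$n_slow)]
    fast_idx <- setdiff(idx, slow_idx)
    mult[slow_idx] <- spec$mult_slow
    mult[fast_idx] <- spec$mult_fast

    alignments <- vector("list", spec$n_orthogroups)
    names(alignments) <- og_ids
    trip_rows <- vector("list", spec$n_orthogroups)
    for (i in seq_len(spec$n_orthogroups)) {
      anc <- sample(AA_ALPHABET20, spec$length, replace = TRUE)
      p_focal <- min(0.95, spec$base_subs * mult[i])
      focal <- mutate_seq(anc, p_focal)
      aln <- list(focal = focal)
      for (t in seq_len(spec$n_triplets)) {
        aln[[paste0("ref_", t)]] <- mutate_seq(anc, spec$base_subs)
        aln[[paste0("out_", t)]] <- mutate_seq(anc, spec$out_subs)
      }
      alignments[[i]] <- vapply(aln, paste, character(1), collapse = "")
      trip_rows[[i]] <- data.frame(
        orthogroup = og_ids[i], focal = "focal",
        reference = paste0("ref_", seq_len(spec$n_triplets)),
        outgroup = paste0("out_", seq_len(spec$n_triplets)),
        stringsAsFactors = FALSE)
    }
    list(alignments = alignments,
         triplets = do.call(rbind, trip_rows),
         truth = list(slow = og_ids[slow_idx], fast = og_ids[fast_idx]))
  })
}

#' Write orthogroup alignments as FASTA files
#'
#' @param alignments alignment list from [simulate_alignments()].
#' @param dir output directory (created if missing); one
#'   `<orthogroup>.fasta` per orthogroup.
#' @return character vector of written paths, invisibly.
#' @export
write_alignments_fasta <- function(alignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(alignments), function(og) {
    p <- file.path(dir, paste0(og, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(alignments[[og]]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read one orthogroup alignment from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
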