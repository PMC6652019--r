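# Reciprocal-best-hit orthology, presence/absence matrices, and
# CiliaCut-style motile-only set selection.

best_hit_per_query <- function(hits, e_threshold, strict_ties) {
  h <- hits[hits$evalue < e_threshold, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(query = character(0), subject = character(0),
                      stringsAsFactors = FALSE))
  sim <- if ("similarity" %in% names(h)) h$similarity else rep(0, nrow(h))
  ord <- order(h$query, h$evalue, -sim, h$subject)
  h <- h[ord, , drop = FALSE]
  sim <- sim[ord]
  first <- !duplicated(h$query)
  if (strict_ties) {
    # a query whose top two hits tie on (evalue, similarity) has no best
    key <- paste(h$evalue, sim)
    best_key <- setNames(key[first], h$query[first])
    n_at_best <- tapply(key == best_key[h$query], h$query, sum)
    tied <- names(n_at_best)[n_at_best > 1]
    keep <- first & !(h$query %in% tied)
  } else {
    keep <- first
  }
  data.frame(query = h$query[keep], subject = h$subject[keep],
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits between two genomes
#'
#' A pair `(a, b)` is emitted when `b` is `a`'s best hit in the A-to-B
#' table and `a` is `b`'s best hit in the B-to-A table, both below the
#' e-value threshold (strict `<`).  "Best" is the lowest e-value; ties are
#' broken by higher similarity, then lexicographic subject id.  With
#' `strict_ties = TRUE` an unresolved tie for best hit disqualifies the
#' query instead.
#'
#' @param hits_ab,hits_ba hit tables (`query`, `subject`, `evalue`,
#'   optional `similarity`).
#' @param e_threshold e-value threshold, default 1e-5.
#' @param strict_ties disqualify queries with tied best hits.
#' @return data frame of ortholog pairs `a`, `b` (sorted by `a`).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, e_threshold = 1e-5,
                                 strict_ties = FALSE) {
  ba <- best_hit_per_query(hits_ab, e_threshold, strict_ties)
  bb <- best_hit_per_query(hits_ba, e_threshold, strict_ties)
  if (!nrow(ba) || !nrow(bb))
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  back <- setNames(bb$subject, bb$query)
  keep <- !is.na(back[ba$subject]) & back[ba$subject] == ba$query
  out <- data.frame(a = ba$query[keep], b = ba$subject[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Presence/absence matrix of reference proteins across a taxon panel
#'
#' @param reference_ids reference protein/family ids (matrix rows).
#' @param panel data frame `taxon`, `motile`; every taxon must have an
#'   entry in `rbh_by_taxon`.
#' @param rbh_by_taxon named list (by taxon) of RBH pair data frames whose
#'   `a` column holds reference ids.
#' @return logical matrix (rows = reference ids, columns = taxa) with the
#'   panel's motility flags attached as attribute `motile`.
#' @export
build_presence_matrix <- function(reference_ids, panel, rbh_by_taxon) {
  missing <- setdiff(panel$taxon, names(rbh_by_taxon))
  if (length(missing))
    stop("no RBH results for taxon: ", missing[1], call. = FALSE)
  m <- vapply(panel$taxon, function(tx)
    reference_ids %in% rbh_by_taxon[[tx]]$a, logical(length(reference_ids)))
  m <- matrix(m, nrow = length(reference_ids),
              dimnames = list(reference_ids, panel$taxon))
  attr(m, "motile") <- setNames(panel$motile, panel$taxon)
  m
}

#' CiliaCut-style selection: present in all motile, absent in all non-motile
#'
#' @param matrix presence matrix from [build_presence_matrix()] (or any
#'   logical matrix with a named logical `motile` attribute or with
#'   `motile` supplied).
#' @param motile optional named logical vector over the matrix columns.
#' @return character vector of selected row ids.
#' @export
ciliacut_select <- function(matrix, motile = attr(matrix, "motile")) {
  if (is.null(motile)) stop("motility flags missing", call. = FALSE)
  motile <- motile[colnames(matrix)]
  if (!any(motile) || !any(!motile))
    stop("both motility classes must be non-empty", call. = FALSE)
  in_motile <- rowSums(!matrix[, motile, drop = FALSE]) == 0
  in_nonmot <- rowSums(matrix[, !motile, drop = FALSE]) == 0
  rownames(matrix)[in_motile & in_nonmot]
}

#' Overlap of two gene sets with percentage of the first
#'
#' @param a,b character vectors.
#' @return list with `n_a`, `n_b`, `n_overlap`, `pct_of_a`
#'   (`100 * |A n B| / |A|`, one decimal; `NA` when A is empty).
#' @export
set_overlap_report <- function(a, b) {
  a <- unique(a); b <- unique(b)
  k <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = k,
       pct_of_a = if (length(a)) round(100 * k / length(a), 1) else NA_real_)
}
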