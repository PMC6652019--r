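# Homolog retention filtering and gene-cluster detection (the nitrate
# assimilation cluster, HANT-AC, style analysis).

#' Filter homology hits on similarity and query coverage
#'
#' Retains hits with at least `min_similarity` percent similarity whose
#' alignment covers between `cov_low` and `cov_high` of the query length;
#' all boundaries are inclusive (a hit at exactly 45% similarity and 100%
#' coverage is retained).
#'
#' @param hits data frame with `similarity` (percent) and `coverage`
#'   (fraction of query length).
#' @param min_similarity percent similarity floor (default 45).
#' @param cov_low,cov_high coverage window (defaults 0.5 and 1.5).
#' @return the retained subset of `hits`.
#' @export
filter_homologs <- function(hits, min_similarity = 45,
                            cov_low = 0.5, cov_high = 1.5) {
  if (!(cov_low > 0 && cov_low < cov_high))
    stop("need 0 < cov_low < cov_high", call. = FALSE)
  keep <- hits$similarity >= min_similarity &
    hits$coverage >= cov_low & hits$coverage <= cov_high
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect gene clusters by intervening-gene-model chaining
#'
#' Two homolog genes on the same scaffold are linked when at most
#' `max_intervening` gene models lie between them (annotation ordinals:
#' `|ordinal difference| - 1 <= max_intervening`); connected components of
#' this relation are the clusters.  Chaining is transitive, so members at
#' the two ends of a cluster may be farther apart than the bound.
#' Singletons are reported as clusters of size 1 unless filtered with
#' `min_size`.
#'
#' @param genes gene table with `gene_id`, `scaffold`, `ordinal`, `start`,
#'   `end`.
#' @param homolog_ids gene ids retained as homologs of the query set.
#' @param max_intervening maximal intervening gene models (default 6).
#' @param min_size drop clusters smaller than this (default 1 = keep all).
#' @return data frame: cluster_id, scaffold, n_members, members
#'   (comma-joined ids in genomic order), span_start, span_end,
#'   max_intervening_observed.
#' @export
detect_clusters <- function(genes, homolog_ids, max_intervening = 6,
                            min_size = 1) {
  missing <- setdiff(homolog_ids, genes$gene_id)
  if (length(missing))
    stop("homolog id absent from gene table: ", missing[1], call. = FALSE)
  g <- genes[genes$gene_id %in% homolog_ids, , drop = FALSE]
  g <- g[order(g$scaffold, g$ordinal), , drop = FALSE]
  out <- list()
  cid <- 0L
  for (sc in unique(g$scaffold)) {
    gs <- g[g$scaffold == sc, , drop = FALSE]
    gap <- diff(gs$ordinal) - 1L
    comp <- cumsum(c(TRUE, gap > max_intervening))
    for (cc in split(seq_len(nrow(gs)), comp)) {
      cid <- cid + 1L
      m <- gs[cc, , drop = FALSE]
      out[[cid]] <- data.frame(
        cluster_id = sprintf("cluster_%03d", cid),
        scaffold = sc,
        n_members = nrow(m),
        members = paste(m$gene_id, collapse = ","),
        span_start = min(m$start), span_end = max(m$end),
        max_intervening_observed =
          if (nrow(m) > 1) max(diff(m$ordinal) - 1L) else 0L,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(0), scaffold = character(0),
               n_members = integer(0), members = character(0),
               span_start = integer(0), span_end = integer(0),
               max_intervening_observed = integer(0),
               stringsAsFactors = FALSE)
  res <- res[res$n_members >= min_size, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flanking and intra-cluster intervals for inspection
#'
#' Emits the upstream and downstream intervals of up to `flank_bp` bp
#' around a cluster span (clipped to the scaffold) plus the gaps between
#' consecutive cluster members, for downstream scans of unannotated genes.
#'
#' @param cluster one row of [detect_clusters()] output (or a list with
#'   `members`, `span_start`, `span_end`).
#' @param genes gene table (for member coordinates).
#' @param flank_bp flank length (>= 0; 0 emits only intra-cluster gaps).
#' @param scaffold_length scaffold length in bp for clipping.
#' @return data frame: kind (upstream/downstream/gap), start, end
#'   (1-based inclusive); empty intervals are omitted.
#' @export
flank_intervals <- function(cluster, genes, flank_bp = 10000,
                            scaffold_length) {
  if (flank_bp < 0) stop("flank_bp must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(scaffold_length, "scaffold_length", 1)
  s <- cluster$span_start
  e <- cluster$span_end
  rows <- list()
  if (flank_bp > 0 && s > 1)
    rows <- c(rows, list(data.frame(kind = "upstream",
                                    start = max(1, s - flank_bp),
                                    end = s - 1)))
  if (flank_bp > 0 && e < scaffold_length)
    rows <- c(rows, list(data.frame(kind = "downstream",
                                    start = e + 1,
                                    end = min(scaffold_length, e + flank_bp))))
  ids <- strsplit(cluster$members, ",", fixed = TRUE)[[1]]
  m <- genes[match(ids, genes$gene_id), , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in seq_len(nrow(m) - 1)) {
      gs <- m$end[i] + 1
      ge <- m$start[i + 1] - 1
      if (ge >= gs)
        rows <- c(rows, list(data.frame(kind = "gap", start = gs, end = ge)))
    }
  }
  if (!length(rows))
    return(data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
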