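# Genome + annotation simulator with a planted low-GC island.

#' Simulate a scaffold with a planted low-GC island and gene models
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2, switching from the
#' background GC to the island GC inside the planted interval.  When an
#' island is present, a tandem array of `repeat_copies` copies of a fixed
#' random `repeat_unit_length`-bp unit is placed at the scaffold end,
#' mirroring a horizontally acquired region that runs to a scaffold
#' extremity bounded by a repeat array.  Gene models are planted without
#' overlap; genes inside the island draw their best-hit affinity class from
#' the island distribution (viral-heavy) and are mostly intronless, genes
#' outside from a chlorophyte-heavy background distribution with many
#' introns.
#'
#' @param config a [sim_config()].
#' @param repeat_unit optional explicit repeat unit (character DNA string);
#'   by default a random unit is drawn.  Supplying the same unit to two
#'   simulated scaffolds creates a joinable fixture for
#'   [terminal_repeat_join()].
#' @param scaffold_name name of the emitted scaffold.
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `genes` (data
#'   frame: gene_id, scaffold, ordinal, start, end, strand, introns,
#'   protein_length, affinity), and `truth` (island interval, repeat unit,
#'   island gene ids).
#' @export
simulate_genome <- function(config, repeat_unit = NULL,
                            scaffold_name = "scaffold_1") {
  stopifnot(inherits(config, "sim_config"))
  isl <- config$island
  L <- config$genome_length
  with_rng(stream_seed(config$seed, "genome"), {
    has_island <- isl$length > 0
    arr_len <- if (has_island) isl$repeat_unit_length * isl$repeat_copies else 0L
    base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                 G = gc / 2, T = (1 - gc) / 2)
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                        prob = base_probs(config$background_gc))
    if (has_island) {
      idx <- isl$start:(isl$start + isl$length - 1L)
      seq_chars[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                               replace = TRUE, prob = base_probs(isl$gc))
      unit <- repeat_unit %||% paste(
        sample(c("A", "C", "G", "T"), isl$repeat_unit_length, replace = TRUE,
               prob = base_probs(isl$gc)),
        collapse = "")
      if (nchar(unit) != isl$repeat_unit_length)
        stop("repeat_unit length does not match island_spec", call. = FALSE)
      arr <- strsplit(strrep(unit, isl$repeat_copies), "")[[1]]
      seq_chars[(L - arr_len + 1L):L] <- arr
    } else {
      unit <- NULL
    }

    # genes: one per equal-width slot, random offset, length 300-2400 bp
    # (multiple of 3); slots too narrow are skipped rather than overlapped.
    gene_space <- L - arr_len
    slot <- floor(gene_space / config$n_genes)
    lens <- 3L * sample(100:800, config$n_genes, replace = TRUE)
    starts <- integer(0); ends <- integer(0); keep <- logical(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      lo <- (i - 1L) * slot + 1L
      hi <- i * slot
      if (hi - lo + 1L <= lens[i]) { keep[i] <- FALSE; next }
      s <- lo + sample.int(hi - lo + 1L - lens[i], 1L) - 1L
      starts <- c(starts, s); ends <- c(ends, s + lens[i] - 1L)
      keep[i] <- TRUE
    }
    n <- length(starts)
    mid <- (starts + ends) / 2
    in_island <- if (has_island)
      mid >= isl$start & mid <= isl$start + isl$length - 1L else rep(FALSE, n)

    background_affinity <- c(viral = 0.01, prokaryote = 0.04,
                             chlorophyte = 0.69, other_eukaryote = 0.12,
                             no_hit = 0.14)
    affinity <- character(n)
    affinity[!in_island] <- sample(AFFINITY_CLASSES, sum(!in_island),
                                   replace = TRUE, prob = background_affinity)
    if (any(in_island))
      affinity[in_island] <- sample(AFFINITY_CLASSES, sum(in_island),
                                    replace = TRUE, prob = isl$affinity)
    # ~8% of island genes carry introns vs ~90% outside
    introns <- integer(n)
    has_intr <- runif(n) < ifelse(in_island, 0.08, 0.9)
    introns[has_intr] <- 1L + rpois(sum(has_intr), 3)

    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      scaffold = scaffold_name,
      ordinal = seq_len(n),
      start = starts, end = ends,
      strand = sample(c("+", "-"), n, replace = TRUE),
      introns = introns,
      protein_length = as.integer((ends - starts + 1L) / 3L),
      affinity = affinity,
      stringsAsFactors = FALSE
    )

    genome <- Biostrings::DNAStringSet(
      setNames(paste(seq_chars, collapse = ""), scaffold_name))

    truth <- list(
      island = if (has_island)
        list(scaffold = scaffold_name, start = isl$start,
             end = isl$start + isl$length - 1L) else NULL,
      repeat_unit = unit,
      island_gene_ids = genes$gene_id[in_island]
    )
    list(genome = genome, genes = genes, truth = truth)
  })
}

#' Write simulated gene models as GFF3
#'
#' @param genes gene table from [simulate_genome()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lichenscreen",
    type = "gene",
    ID = genes$gene_id,
    introns = genes$introns,
    protein_length = genes$protein_length,
    affinity = genes$affinity
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 into the package gene-table layout
#'
#' Ordinal indices (rank of start per scaffold) are recomputed from the
#' coordinates.
#'
#' @param path GFF3 path.
#' @return gene table data frame.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  df <- data.frame(
    gene_id = as.character(gr$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  for (col in c("introns", "protein_length")) {
    if (col %in% names(S4Vectors::mcols(gr)))
      df[[col]] <- as.integer(S4Vectors::mcols(gr)[[col]])
  }
  if ("affinity" %in% names(S4Vectors::mcols(gr)))
    df$affinity <- as.character(gr$affinity)
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  df$ordinal <- stats::ave(df$start, df$scaffold,
                           FUN = function(x) rank(x, ties.method = "first"))
  rownames(df) <- NULL
  df[, c("gene_id", "scaffold", "ordinal", "start", "end", "strand",
         intersect(c("introns", "protein_length", "affinity"), names(df)))]
}
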