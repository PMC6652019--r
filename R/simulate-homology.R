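# Pairwise homology-hit simulator: planted reciprocal best hits across a
# taxon panel, motile-only families, and a planted within-genome homolog
# cluster (emulating tabular BLASTP output).

#' Simulate pairwise homology hit tables with planted structure
#'
#' Families are planted as present/absent per taxon: `n_ubiquitous`
#' families occur in every taxon, `n_motile_only_families` only in motile
#' taxa, and `n_random` with random presence.  For every ordered taxon pair
#' the table contains one strong hit (e-value < 1e-20) between the two
#' family members plus weak decoy hits (e-value > 1e-4) between unrelated
#' members, so reciprocal-best-hit pairing recovers exactly the planted
#' orthologs at the canonical 1e-5 threshold.  In addition, a homolog
#' cluster is planted on the supplied gene table: consecutive members are
#' separated by at most `clusters$max_gap` intervening gene models, and
#' `n_scattered` homologs are placed far from the cluster; the emitted
#' within-genome hit table gives planted homologs similarity/coverage
#' inside the retention window (>= 45% similarity, 50-150% coverage) and
#' decoys outside it.
#'
#' @param genes gene table from [simulate_genome()].
#' @param clusters a [cluster_spec()].
#' @param ciliacut a [ciliacut_spec()].
#' @param seed integer seed.
#' @return list with `pair_hits` (named list `"A__B"` of hit data frames
#'   query, subject, evalue, similarity, coverage), `genome_hits` (query
#'   set vs genome hit table), `panel`, `presence` (planted family x taxon
#'   logical matrix) and `truth` (motile_only_families, cluster_members,
#'   scattered_members, rbh pairs for the reference taxon).
#' @export
simulate_homology <- function(genes, clusters, ciliacut, seed = 1L) {
  stopifnot(inherits(clusters, "cluster_spec"),
            inherits(ciliacut, "ciliacut_spec"))
  panel <- ciliacut$panel
  if (nrow(panel) < 2) stop("need at least 2 taxa", call. = FALSE)
  with_rng(stream_seed(seed, "homology"), {
    n_fam <- ciliacut$n_ubiquitous + ciliacut$n_motile_only_families +
      ciliacut$n_random
    fam_ids <- sprintf("fam%03d", seq_len(n_fam))
    kind <- rep(c("ubiquitous", "motile_only", "random"),
                c(ciliacut$n_ubiquitous, ciliacut$n_motile_only_families,
                  ciliacut$n_random))
    taxa <- panel$taxon
    presence <- matrix(FALSE, n_fam, length(taxa),
                       dimnames = list(fam_ids, taxa))
    presence[kind == "ubiquitous", ] <- TRUE
    presence[kind == "motile_only", ] <- matrix(
      rep(panel$motile, each = sum(kind == "motile_only")),
      nrow = sum(kind == "motile_only"))
    if (any(kind == "random"))
      presence[kind == "random", ] <- matrix(
        runif(sum(kind == "random") * length(taxa)) < 0.6,
        ncol = length(taxa))

    prot <- function(taxon, fam) paste0(taxon, "|", fam)
    pair_hits <- list()
    for (a in taxa) for (b in taxa) {
      if (a == b) next
      shared <- fam_ids[presence[, a] & presence[, b]]
      hits <- data.frame(query = character(0), subject = character(0),
                         evalue = numeric(0), similarity = numeric(0),
                         coverage = numeric(0), stringsAsFactors = FALSE)
      if (length(shared)) {
        hits <- data.frame(
          query = prot(a, shared), subject = prot(b, shared),
          evalue = 10^-runif(length(shared), 20, 60),
          similarity = runif(length(shared), 60, 95),
          coverage = runif(length(shared), 0.7, 1.1),
          stringsAsFactors = FALSE)
      }
      # weak decoys between unrelated family members, above 1e-5
      fa <- fam_ids[presence[, a]]; fb <- fam_ids[presence[, b]]
      n_decoy <- min(20L, length(fa) * length(fb))
      if (n_decoy > 0) {
        qa <- sample(fa, n_decoy, replace = TRUE)
        sb <- sample(fb, n_decoy, replace = TRUE)
        keep <- qa != sb
        if (any(keep)) {
          hits <- rbind(hits, data.frame(
            query = prot(a, qa[keep]), subject = prot(b, sb[keep]),
            evalue = 10^-runif(sum(keep), 0, 4),
            similarity = runif(sum(keep), 20, 45),
            coverage = runif(sum(keep), 0.2, 0.6),
            stringsAsFactors = FALSE))
        }
      }
      pair_hits[[paste0(a, "__", b)]] <- hits
    }

    # ---- planted within-genome homolog cluster --------------------------
    n_genes <- nrow(genes)
    need <- clusters$n_members
    member_ord <- integer(0)
    if (need > 0) {
      gaps <- if (need > 1)
        sample.int(clusters$max_gap + 1L, need - 1L, replace = TRUE) - 1L
      else integer(0)
      span <- need + sum(gaps)
      start_ord <- sample.int(max(1L, n_genes %/% 4L), 1L)
      member_ord <- start_ord + cumsum(c(0L, gaps + 1L))
      if (max(member_ord) > n_genes)
        stop("gene table too small to plant the cluster", call. = FALSE)
    }
    scatter_ord <- integer(0)
    if (clusters$n_scattered > 0) {
      lo <- if (length(member_ord)) max(member_ord) + clusters$max_gap + 10L
            else 1L
      cand <- seq(lo, n_genes, by = clusters$max_gap + 10L)
      scatter_ord <- head(cand, clusters$n_scattered)
    }
    queries <- c("nitrate_reductase", "nitrite_reductase", "NRT2",
                 "formate_nitrite_transporter", "molybdopterin_synthase")
    plant_ord <- c(member_ord, scatter_ord)
    genome_hits <- data.frame(query = character(0), subject = character(0),
                              evalue = numeric(0), similarity = numeric(0),
                              coverage = numeric(0), stringsAsFactors = FALSE)
    if (length(plant_ord)) {
      genome_hits <- data.frame(
        query = sample(queries, length(plant_ord), replace = TRUE),
        subject = genes$gene_id[match(plant_ord, genes$ordinal)],
        evalue = 10^-runif(length(plant_ord), 10, 60),
        similarity = runif(length(plant_ord), 50, 90),
        coverage = runif(length(plant_ord), 0.6, 1.4),
        stringsAsFactors = FALSE)
    }
    # decoys failing the retention filter (low similarity or excess coverage)
    decoy_ord <- setdiff(sample.int(n_genes, min(30L, n_genes)), plant_ord)
    if (length(decoy_ord)) {
      low_sim <- runif(length(decoy_ord)) < 0.5
      genome_hits <- rbind(genome_hits, data.frame(
        query = sample(queries, length(decoy_ord), replace = TRUE),
        subject = genes$gene_id[match(decoy_ord, genes$ordinal)],
        evalue = 10^-runif(length(decoy_ord), 2, 20),
        similarity = ifelse(low_sim, runif(length(decoy_ord), 10, 44),
                            runif(length(decoy_ord), 50, 90)),
        coverage = ifelse(low_sim, runif(length(decoy_ord), 0.6, 1.4),
                          runif(length(decoy_ord), 1.6, 3.0)),
        stringsAsFactors = FALSE))
    }

    ref <- taxa[1L]
    truth <- list(
      motile_only_families = fam_ids[kind == "motile_only"],
      cluster_members = genes$gene_id[match(member_ord, genes$ordinal)],
      scattered_members = genes$gene_id[match(scatter_ord, genes$ordinal)],
      rbh = lapply(setNames(taxa[-1L], taxa[-1L]), function(b) {
        shared <- fam_ids[presence[, ref] & presence[, b]]
        data.frame(a = prot(ref, shared), b = prot(b, shared),
                   stringsAsFactors = FALSE)
      })
    )
    list(pair_hits = pair_hits, genome_hits = genome_hits,
         panel = panel, presence = presence, truth = truth)
  })
}
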