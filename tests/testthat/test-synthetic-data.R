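small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, genome_length = 2e5, n_genes = 80,
             island = island_spec(length = 50000), ...)
}

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(genome_length = 1e5,
                          island = island_spec(length = 99000)),
               "does not fit")
  expect_error(sim_config(island = island_spec(length = 1e5, start = 1e6)),
               "does not fit")
  expect_error(expression_spec(dispersion = 0), "dispersion")
  expect_error(expression_spec(fold_induced = 0.8), "fold_induced")
  expect_error(expression_spec(fold_repressed = 1.2), "fold_repressed")
  expect_error(secretome_spec(concordance = 1.2), "concordance")
  expect_error(rate_spec(length = 40), ">= 50")
  expect_error(rate_spec(mult_fast = 0), "multipliers")
  expect_error(island_spec(gc = 1.4), "gc")
  expect_error(ciliacut_spec(panel = data.frame(taxon = "t",
                                                motile = TRUE)),
               "at least 2")
})

test_that("simulators are byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 33)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  simulate_fixture_set(cfg, d1)
  simulate_fixture_set(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted island GC and background GC are respected", {
  cfg <- sim_config(seed = 5, genome_length = 1e6, n_genes = 300,
                    island = island_spec(length = 100000, gc = 0.49))
  gen <- simulate_genome(cfg)
  s <- gen$genome[[1]]
  isl <- gen$truth$island
  island_gc <- Biostrings::letterFrequency(
    Biostrings::subseq(s, isl$start, isl$end), "GC", as.prob = TRUE)
  expect_lt(abs(island_gc - 0.49), 0.01)
  outside <- Biostrings::subseq(s, 1, isl$start - 1)
  bg_gc <- Biostrings::letterFrequency(outside, "GC", as.prob = TRUE)
  expect_lt(abs(bg_gc - 0.58), 0.01)
  # repeat array occupies the scaffold end
  arr_len <- 141 * 10
  arr <- as.character(Biostrings::subseq(s, length(s) - arr_len + 1))
  expect_equal(arr, strrep(gen$truth$repeat_unit, 10))
})

test_that("island length 0 yields no island and no repeat array", {
  cfg <- sim_config(seed = 2, genome_length = 1e5, n_genes = 40,
                    island = island_spec(length = 0))
  gen <- simulate_genome(cfg)
  expect_null(gen$truth$island)
  expect_null(gen$truth$repeat_unit)
  tr <- gc_windows(gen$genome[[1]], 5000, 1000)
  expect_equal(nrow(detect_low_gc_regions(tr)), 0)
})

test_that("GFF3 round-trips through the reader without loss", {
  cfg <- small_cfg(seed = 12)
  gen <- simulate_genome(cfg)
  path <- tempfile(fileext = ".gff3")
  write_genes_gff3(gen$genes, path)
  back <- read_genes_gff3(path)
  for (col in c("gene_id", "scaffold", "ordinal", "start", "end",
                "strand", "introns", "protein_length", "affinity")) {
    expect_equal(back[[col]], gen$genes[[col]], info = col,
                 ignore_attr = TRUE)
  }
  unlink(path)
})

test_that("ground-truth sets are subsets of emitted ids, and disjoint", {
  cfg <- small_cfg(seed = 9)
  gen <- simulate_genome(cfg)
  expr <- simulate_expression(gen$genes, cfg$expression, cfg$seed)
  sec <- simulate_secretion_calls(gen$genes, cfg$secretome, cfg$seed)
  hom <- simulate_homology(gen$genes, cfg$clusters, cfg$ciliacut, cfg$seed)
  ids <- gen$genes$gene_id
  expect_true(all(expr$truth$induced %in% ids))
  expect_true(all(expr$truth$repressed %in% ids))
  expect_length(intersect(expr$truth$induced, expr$truth$repressed), 0)
  expect_true(all(sec$truth$secreted %in% ids))
  expect_true(all(hom$truth$cluster_members %in% ids))
  expect_true(all(gen$truth$island_gene_ids %in% ids))
})

test_that("planted fold is recovered in expectation (Monte Carlo)", {
  genes <- toy_genes(50, gene_len = 1200)
  spec <- expression_spec(n_induced = 5, n_repressed = 0, fold_induced = 3,
                          lib_mono = 1e6, lib_co = 1e6)
  ratios <- numeric(0)
  for (s in 1:200) {
    sim <- simulate_expression(genes, spec, seed = s)
    tab <- expression_table(sim$counts, genes$end - genes$start + 1,
                            sim$lib_sizes, default_thresholds("fungus"))
    ratios <- c(ratios, tab$ratio[tab$gene_id %in% sim$truth$induced])
  }
  expect_gt(mean(ratios), 2.7)
  expect_lt(mean(ratios), 3.3)
})

test_that("null simulation has a negligible induced fraction", {
  # with dispersion 0.01 and mean counts in the thousands, the ratio's
  # log-sd is ~sqrt(2 * (1/mu + 0.01)) ~ 0.15, so P(ratio >= 2) under the
  # null corresponds to |z| > 4; measure it rather than assume it
  genes <- toy_genes(400, gene_len = 1200)
  spec <- expression_spec(n_induced = 0, n_repressed = 0,
                          lib_mono = 2e6, lib_co = 2e6)
  sim <- simulate_expression(genes, spec, seed = 77)
  tab <- expression_table(sim$counts, genes$end - genes$start + 1,
                          sim$lib_sizes, default_thresholds("fungus"))
  expect_lte(mean(tab$class == "induced"), 0.01)
})

test_that("zero-depth libraries are flagged not_detected throughout", {
  genes <- toy_genes(20)
  counts <- data.frame(gene_id = genes$gene_id, count_mono = 0,
                       count_co = 0)
  tab <- expression_table(counts, genes$end - genes$start + 1,
                          c(mono = 1e6, co = 1e6),
                          default_thresholds("fungus"))
  expect_true(all(tab$class == "not_detected"))
})

test_that("homology simulator plants recoverable signals", {
  cfg <- small_cfg(seed = 14)
  gen <- simulate_genome(cfg)
  hom <- simulate_homology(gen$genes, cfg$clusters, cfg$ciliacut, cfg$seed)

  # planted reciprocal pairs appear in RBH output
  pairs <- reciprocal_best_hits(hom$pair_hits[["ref_motile__motA"]],
                                hom$pair_hits[["motA__ref_motile"]])
  planted <- hom$truth$rbh[["motA"]]
  expect_true(all(paste(planted$a, planted$b) %in%
                    paste(pairs$a, pairs$b)))

  # motile-only families are selected; ubiquitous families are not
  panel <- hom$panel
  m <- hom$presence
  got <- ciliacut_select(m, setNames(panel$motile, panel$taxon))
  expect_setequal(got, hom$truth$motile_only_families)

  # planted cluster members form one cluster after retention filtering
  retained <- filter_homologs(hom$genome_hits)
  cl <- detect_clusters(gen$genes, unique(retained$subject),
                        max_intervening = cfg$clusters$max_gap)
  members <- strsplit(cl$members, ",")
  containing <- members[vapply(members, function(mm)
    hom$truth$cluster_members[1] %in% mm, logical(1))][[1]]
  expect_setequal(containing, hom$truth$cluster_members)
  expect_error(simulate_homology(gen$genes, cfg$clusters,
                                 ciliacut_spec(panel = data.frame(
                                   taxon = "x", motile = TRUE))),
               "at least 2")
})

test_that("alignment simulator: zero substitutions give a null statistic", {
  sim <- simulate_alignments(rate_spec(n_orthogroups = 2, n_slow = 0,
                                       n_fast = 0, base_subs = 0,
                                       out_subs = 0, n_triplets = 2),
                             seed = 6)
  tt <- sim$triplets[1, ]
  r <- triplet_rate_test(sim$alignments[[tt$orthogroup]], tt)
  expect_equal(c(r$statistic, r$p), c(0, 1))
})
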