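test_that("gc_windows closed forms and counting oracle", {
  expect_equal(gc_windows("ATGC", window = 4, step = 4)$gc, 0.5)
  expect_equal(gc_windows("GGGG", window = 4, step = 4)$gc, 1.0)
  # ambiguous bases excluded; all-ambiguous window is NA
  expect_equal(gc_windows("GNNC", window = 4, step = 4)$gc, 1.0)
  expect_true(is.na(gc_windows("NNNN", window = 4, step = 4)$gc))
  expect_error(gc_windows("ACGT", window = 2, step = 3), "window >= step")

  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
             collapse = "")
  tr <- gc_windows(s, window = 1000, step = 400)
  for (i in sample(nrow(tr), 10)) {
    chars <- strsplit(substr(s, tr$start[i], tr$end[i]), "")[[1]]
    gc <- sum(chars %in% c("G", "C")) /
      sum(chars %in% c("A", "C", "G", "T"))
    expect_equal(tr$gc[i], gc)
  }
})

test_that("detect_low_gc_regions: degenerate tracks", {
  set.seed(4)
  uniform <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
                   collapse = "")
  tr <- gc_windows(uniform, 5000, 1000)
  expect_equal(nrow(detect_low_gc_regions(tr)), 0)

  # whole scaffold below an externally supplied baseline: one region
  low <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  tr <- gc_windows(low, 5000, 1000)
  reg <- detect_low_gc_regions(tr, baseline = c(0.58, 0.005),
                               min_length = 10000)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 1)
  expect_equal(reg$end, max(tr$end))

  # short track: empty result, not an error
  expect_equal(nrow(detect_low_gc_regions(gc_windows("ACGT", 4, 4))), 0)
})

test_that("planted island is recovered within one window", {
  cfg <- sim_config(seed = 202, genome_length = 6e5, n_genes = 200,
                    island = island_spec(length = 100000))
  gen <- simulate_genome(cfg)
  isl <- gen$truth$island
  tr <- gc_windows(gen$genome[[1]], 5000, 1000)
  reg <- detect_low_gc_regions(tr)
  expect_equal(nrow(reg), 1)
  expect_lte(abs(reg$start - isl$start), 5000)
  expect_lte(abs(reg$end - isl$end), 5000)
})

test_that("detection is invariant under reverse complement", {
  cfg <- sim_config(seed = 77, genome_length = 4e5, n_genes = 100,
                    island = island_spec(length = 80000))
  gen <- simulate_genome(cfg)
  L <- length(gen$genome[[1]])
  w <- 5000L
  fwd <- detect_low_gc_regions(gc_windows(gen$genome[[1]], w, w))
  rc <- Biostrings::reverseComplement(gen$genome[[1]])
  rev <- detect_low_gc_regions(gc_windows(rc, w, w))
  expect_equal(nrow(fwd), nrow(rev))
  # mirrored coordinates, window-snapped
  expect_lte(abs((L - rev$end + 1) - fwd$start), w)
  expect_lte(abs((L - rev$start + 1) - fwd$end), w)
})

test_that("terminal_repeat_join joins scaffolds sharing a terminal array", {
  set.seed(9)
  unit <- paste(sample(c("A", "C", "G", "T"), 141, replace = TRUE),
                collapse = "")
  body_a <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                  collapse = "")
  body_b <- paste(sample(c("A", "C", "G", "T"), 15000, replace = TRUE),
                  collapse = "")
  a <- paste0(body_a, strrep(unit, 5))
  b <- paste0(body_b, strrep(unit, 5))
  j <- terminal_repeat_join(a, b)
  expect_false(is.null(j))
  expect_equal(j$unit_length, 141)
  expect_equal(j$copies_a, 5)
  expect_equal(j$joined_length,
               nchar(a) + nchar(b) - (5 + 5 - 1) * 141)
  expect_equal(j$map$joined_end[2], j$joined_length)

  # different copy numbers still join (primitive unit is canonical)
  j2 <- terminal_repeat_join(paste0(body_a, strrep(unit, 10)),
                             paste0(body_b, strrep(unit, 4)))
  expect_false(is.null(j2))
  expect_equal(j2$unit_length, 141)

  # reverse-complemented array on the second scaffold also joins
  b_rc <- paste0(body_b, strrep(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unit))), 5))
  expect_false(is.null(terminal_repeat_join(a, b_rc)))

  # unrelated termini, or an array on only one scaffold: no join
  expect_null(terminal_repeat_join(body_a, body_b))
  expect_null(terminal_repeat_join(a, body_b))
})

test_that("region_gene_report tallies affinity and intron composition", {
  # the printed instance: 24 chlorophyte-matching of 462 island genes = 5.2%
  n <- 462
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:n), scaffold = "sc", ordinal = 1:n,
    start = seq(1, by = 1000, length.out = n),
    end = seq(900, by = 1000, length.out = n),
    strand = "+", introns = rep(c(1L, 0L), c(36, n - 36)),
    protein_length = 300L,
    affinity = rep(c("chlorophyte", "viral", "no_hit"), c(24, 212, 226)),
    stringsAsFactors = FALSE)
  rep_ <- region_gene_report(
    list(scaffold = "sc", start = 1, end = 462000), genes)
  expect_equal(rep_$region$n_genes, 462)
  expect_equal(round(100 * rep_$region$affinity_fractions[["chlorophyte"]], 1),
               5.2)
  expect_equal(rep_$region$intron_fraction, 36 / 462)
  expect_equal(sum(rep_$region$affinity_fractions), 1, tolerance = 1e-12)

  # toy region: 2 viral of 4 genes -> 50%
  toy <- toy_genes(8)
  toy$affinity <- rep(c("viral", "no_hit"), 4)
  rp <- region_gene_report(list(scaffold = "sc1", start = 1,
                                end = toy$end[4]), toy)
  expect_equal(rp$region$n_genes, 4)
  expect_equal(rp$region$affinity_fractions[["viral"]], 0.5)
  expect_equal(rp$rest$n_genes, 4)

  # random labels equal a direct tally; empty region gives NA fractions
  set.seed(15)
  toy$affinity <- sample(c("viral", "prokaryote", "chlorophyte",
                           "other_eukaryote", "no_hit"), 8, replace = TRUE)
  rp <- region_gene_report(list(scaffold = "sc1", start = 1,
                                end = toy$end[8]), toy)
  tab <- table(factor(toy$affinity, levels = names(
    rp$region$affinity_fractions)))
  expect_equal(unname(rp$region$affinity_fractions),
               unname(as.numeric(tab) / 8))
  rp0 <- region_gene_report(list(scaffold = "other", start = 1, end = 10),
                            toy)
  expect_equal(rp0$region$n_genes, 0)
  expect_true(all(is.na(rp0$region$affinity_fractions)))
})
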