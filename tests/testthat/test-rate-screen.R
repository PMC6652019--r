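test_that("triplet_rate_test statistic, p and direction", {
  # n_focal = n_ref = 10: statistic 0, p 1, no call
  aln <- toy_triplet_alignment(10, 10)
  r <- triplet_rate_test(aln, toy_triplet)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$direction, "none")

  # n_focal = 20, n_ref = 5: chi-square 225/25 = 9, p ~ 0.0027, fast
  r <- triplet_rate_test(toy_triplet_alignment(20, 5), toy_triplet)
  expect_equal(r$n_focal, 20L)
  expect_equal(r$n_ref, 5L)
  expect_equal(r$statistic, 9)
  expect_equal(r$p, 2 * pnorm(-3), tolerance = 1e-12)
  expect_equal(r$direction, "focal_fast")

  # no informative sites at all: statistic 0, p 1 (not an error)
  r0 <- triplet_rate_test(toy_triplet_alignment(0, 0), toy_triplet)
  expect_equal(c(r0$statistic, r0$p), c(0, 1))
})

test_that("swapping focal and reference flips direction only", {
  aln <- toy_triplet_alignment(20, 5)
  fwd <- triplet_rate_test(aln, toy_triplet)
  swapped <- triplet_rate_test(aln, list(focal = "ref", reference = "focal",
                                         outgroup = "out"))
  expect_equal(swapped$statistic, fwd$statistic)
  expect_equal(swapped$p, fwd$p)
  expect_equal(swapped$direction, "focal_slow")
  expect_equal(swapped$n_focal, fwd$n_ref)
})

test_that("gapped columns are excluded and column order is irrelevant", {
  with_gaps <- toy_triplet_alignment(20, 5, n_gap = 30)
  r <- triplet_rate_test(with_gaps, toy_triplet)
  expect_equal(c(r$n_focal, r$n_ref), c(20L, 5L))

  # permute columns
  set.seed(2)
  chars <- lapply(with_gaps, function(s) strsplit(s, "")[[1]])
  perm <- sample(length(chars[[1]]))
  permuted <- vapply(chars, function(x) paste(x[perm], collapse = ""),
                     character(1))
  names(permuted) <- names(with_gaps)
  r2 <- triplet_rate_test(permuted, toy_triplet)
  expect_equal(r2$statistic, r$statistic)
  expect_equal(r2$p, r$p)
})

test_that("consensus_rate_call applies the 90% same-direction rule", {
  res <- function(dirs) data.frame(direction = dirs,
                                   stringsAsFactors = FALSE)
  expect_equal(consensus_rate_call(res(rep("focal_slow", 10))), "slow")
  expect_equal(consensus_rate_call(
    res(c(rep("focal_slow", 9), "none"))), "slow")
  expect_equal(consensus_rate_call(
    res(c(rep("focal_slow", 8), "none", "none"))), "none")
  expect_equal(consensus_rate_call(
    res(c(rep("focal_slow", 9), "focal_fast"))), "none")
  expect_equal(consensus_rate_call(res(rep("focal_fast", 10))), "fast")
  # alternative reading: fraction over significant triplets only
  expect_equal(consensus_rate_call(
    res(c(rep("focal_slow", 8), "none", "none")),
    mode = "significant-only"), "slow")
  expect_error(consensus_rate_call(res(character(0))), "no triplet")
})

test_that("multi_method_intersection requires same-direction agreement", {
  calls <- data.frame(
    orthogroup = c("o1", "o1", "o2", "o2", "o3", "o3"),
    method = rep(c("m1", "m2"), 3),
    call = c("slow", "slow", "slow", "none", "slow", "fast"),
    stringsAsFactors = FALSE)
  out <- multi_method_intersection(calls, min_methods = 2)
  expect_equal(out$slow, "o1")
  expect_equal(out$fast, character(0))
  expect_error(multi_method_intersection(calls[calls$method == "m1", ]),
               "fewer methods")
})

test_that("distance_rate_method degenerate cases give no call", {
  aln <- toy_triplet_alignment(0, 0)
  expect_equal(distance_rate_method(aln, toy_triplet), "none")
  expect_equal(distance_rate_method(toy_triplet_alignment(20, 5),
                                    toy_triplet, B = 1), "none")
})

test_that("distance_rate_method detects a strong planted rate shift", {
  # 3x focal rate, length 500: the bootstrap interval should exclude zero
  # for the overwhelming majority of orthogroups (scaled-down power check;
  # the full 100-orthogroup run lives in the acceptance suite)
  sim <- simulate_alignments(rate_spec(n_orthogroups = 20, n_slow = 0,
                                       n_fast = 20, length = 500,
                                       n_triplets = 1), seed = 5)
  calls <- vapply(names(sim$alignments), function(og) {
    tt <- sim$triplets[sim$triplets$orthogroup == og, ][1, ]
    distance_rate_method(sim$alignments[[og]], tt, B = 200,
                         seed = match(og, names(sim$alignments)))
  }, character(1))
  expect_gte(mean(calls == "fast"), 0.9)
})

test_that("null rejection rate is near alpha (scaled-down type-I check)", {
  sim <- simulate_alignments(rate_spec(n_orthogroups = 300, n_slow = 0,
                                       n_fast = 0, length = 500,
                                       n_triplets = 1), seed = 11)
  rej <- vapply(names(sim$alignments), function(og) {
    tt <- sim$triplets[sim$triplets$orthogroup == og, ][1, ]
    triplet_rate_test(sim$alignments[[og]], tt)$p <= 0.05
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), 300, 0.05) / 300
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("rate_screen recovers planted slow and fast orthogroups", {
  sim <- simulate_alignments(rate_spec(n_orthogroups = 12, n_slow = 3,
                                       n_fast = 3, length = 500,
                                       n_triplets = 10), seed = 8)
  rs <- rate_screen(sim$alignments, sim$triplets, B = 100, seed = 2)
  expect_setequal(rs$final$slow, sim$truth$slow)
  expect_setequal(rs$final$fast, sim$truth$fast)
  # per-orthogroup calls exist for both methods
  expect_equal(sort(unique(rs$per_method$method)),
               c("distance", "relrate"))
})
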