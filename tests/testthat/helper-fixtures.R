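# Shared fixture builders (everything generated in code; no stored data).

# minimal gene table with one gene per ordinal on one scaffold
toy_genes <- function(n = 20, scaffold = "sc1", gene_len = 900, gap = 100) {
  starts <- (seq_len(n) - 1L) * (gene_len + gap) + 1L
  data.frame(
    gene_id = sprintf("t%03d", seq_len(n)),
    scaffold = scaffold,
    ordinal = seq_len(n),
    start = starts, end = starts + gene_len - 1L,
    strand = rep(c("+", "-"), length.out = n),
    introns = rep(c(0L, 3L), length.out = n),
    protein_length = as.integer(gene_len / 3),
    affinity = rep("chlorophyte", n),
    stringsAsFactors = FALSE
  )
}

# build an alignment with exact private-substitution counts: the focal
# sequence differs alone at n_focal sites, the reference alone at n_ref,
# on a backbone of identical residues
toy_triplet_alignment <- function(n_focal, n_ref, n_same = 100,
                                  n_gap = 0) {
  L <- n_focal + n_ref + n_same + n_gap
  focal <- ref <- out <- rep("A", L)
  if (n_focal > 0) focal[seq_len(n_focal)] <- "R"
  if (n_ref > 0) ref[n_focal + seq_len(n_ref)] <- "K"
  if (n_gap > 0) {
    idx <- n_focal + n_ref + n_same + seq_len(n_gap)
    focal[idx] <- "-"
    ref[idx] <- "W"   # would be counted if gaps were not excluded
  }
  c(focal = paste(focal, collapse = ""),
    ref = paste(ref, collapse = ""),
    out = paste(out, collapse = ""))
}

toy_triplet <- list(focal = "focal", reference = "ref", outgroup = "out")

# brute-force upper-tail hypergeometric by direct enumeration with choose()
hyper_tail_oracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force union-find connected components for the cluster oracle
union_find_clusters <- function(ordinals, max_intervening) {
  n <- length(ordinals)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(ordinals[i] - ordinals[j]) - 1 <= max_intervening) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}
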