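# Simulation configuration constructors with validation.
#
# Defaults describe the stated world the generator emulates: a compact
# algal-like scaffold whose background GC sits at 0.58 with one planted
# low-GC (0.49) island terminating in an array of 141-bp repeat units, an
# RNA-seq experiment with a few percent of genes induced or repressed in
# coculture, a small true secretome with highly (but not perfectly)
# concordant predictor calls, a planted homolog cluster, a chlorophyte-like
# taxon panel with motile-only families, and orthogroup alignments with
# 3-fold rate-shifted focal branches.

#' Island specification for the genome simulator
#'
#' @param length island length in bp (0 disables the island).
#' @param gc island GC fraction.
#' @param start 1-based island start; `NULL` places the island immediately
#'   upstream of the terminal repeat array (the default mirrors an island
#'   that runs to the scaffold extremity).
#' @param repeat_unit_length tandem repeat unit length in bp (default 141).
#' @param repeat_copies number of tandem copies placed at the scaffold end.
#' @param affinity named probability vector over best-hit affinity classes
#'   `viral, prokaryote, chlorophyte, other_eukaryote, no_hit` used for
#'   genes inside the island.
#' @return a validated list of class `island_spec`.
#' @export
island_spec <- function(length = 100000, gc = 0.49, start = NULL,
                        repeat_unit_length = 141, repeat_copies = 10,
                        affinity = c(viral = 0.23, prokaryote = 0.13,
                                     chlorophyte = 0.052,
                                     other_eukaryote = 0.098, no_hit = 0.49)) {
  stop_if_not_scalar_number(length, "length", 0)
  stop_if_not_scalar_number(gc, "gc", 0, 1)
  stop_if_not_scalar_number(repeat_unit_length, "repeat_unit_length", 1)
  stop_if_not_scalar_number(repeat_copies, "repeat_copies", 0)
  affinity <- check_affinity(affinity)
  structure(list(length = as.integer(length), gc = gc, start = start,
                 repeat_unit_length = as.integer(repeat_unit_length),
                 repeat_copies = as.integer(repeat_copies),
                 affinity = affinity),
            class = "island_spec")
}

AFFINITY_CLASSES <- c("viral", "prokaryote", "chlorophyte",
                      "other_eukaryote", "no_hit")

check_affinity <- function(p) {
  if (is.null(names(p)) || !all(names(p) %in% AFFINITY_CLASSES))
    stop("affinity distribution must be named with classes: ",
         paste(AFFINITY_CLASSES, collapse = ", "), call. = FALSE)
  full <- setNames(numeric(length(AFFINITY_CLASSES)), AFFINITY_CLASSES)
  full[names(p)] <- p
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    stop("affinity distribution must be non-negative and sum to 1",
         call. = FALSE)
  full / sum(full)
}

#' Expression experiment specification
#'
#' @param n_induced,n_repressed numbers of planted differential genes.
#' @param fold_induced coculture/monoculture fold for induced genes (> 1).
#' @param fold_repressed fold for repressed genes (< 1).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.  The default 0.01 reflects a
#'   design in which replicate cultures are pooled into one library per
#'   condition, leaving mostly technical (near-Poisson) count noise.
#' @param lib_mono,lib_co target library sizes (aligned reads) per condition.
#' @return list of class `expression_spec`.
#' @export
expression_spec <- function(n_induced = 30, n_repressed = 20,
                            fold_induced = 3, fold_repressed = 1 / 3,
                            dispersion = 0.01,
                            lib_mono = 5e6, lib_co = 5e6) {
  stop_if_not_scalar_number(n_induced, "n_induced", 0)
  stop_if_not_scalar_number(n_repressed, "n_repressed", 0)
  if (fold_induced <= 1) stop("fold_induced must be > 1", call. = FALSE)
  if (fold_repressed >= 1 || fold_repressed <= 0)
    stop("fold_repressed must be in (0, 1)", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  stop_if_not_scalar_number(lib_mono, "lib_mono", 0)
  stop_if_not_scalar_number(lib_co, "lib_co", 0)
  structure(list(n_induced = as.integer(n_induced),
                 n_repressed = as.integer(n_repressed),
                 fold_induced = fold_induced, fold_repressed = fold_repressed,
                 dispersion = dispersion, lib_mono = lib_mono, lib_co = lib_co),
            class = "expression_spec")
}

#' Secretion-predictor call specification
#'
#' @param n_true_secreted number of genes planted as truly secreted.
#' @param concordance per-predictor probability that a true secreted gene is
#'   called positive (the three predictors flip independently).
#' @param fp_rate per-predictor false-positive probability on non-secreted
#'   genes.
#' @return list of class `secretome_spec`.
#' @export
secretome_spec <- function(n_true_secreted = 40, concordance = 0.95,
                           fp_rate = 0.03) {
  stop_if_not_scalar_number(n_true_secreted, "n_true_secreted", 0)
  stop_if_not_scalar_number(concordance, "concordance", 0, 1)
  stop_if_not_scalar_number(fp_rate, "fp_rate", 0, 1)
  structure(list(n_true_secreted = as.integer(n_true_secreted),
                 concordance = concordance, fp_rate = fp_rate),
            class = "secretome_spec")
}

#' Homolog-cluster planting specification
#'
#' @param n_members genes planted as clustered homologs of the query set.
#' @param max_gap maximal number of intervening gene models used when
#'   planting consecutive members (default 6, the retention rule's bound).
#' @param n_scattered additional homolog genes planted far from the cluster
#'   (unclustered paralogs).
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(n_members = 4, max_gap = 6, n_scattered = 2) {
  stop_if_not_scalar_number(n_members, "n_members", 0)
  stop_if_not_scalar_number(max_gap, "max_gap", 0)
  stop_if_not_scalar_number(n_scattered, "n_scattered", 0)
  structure(list(n_members = as.integer(n_members),
                 max_gap = as.integer(max_gap),
                 n_scattered = as.integer(n_scattered)),
            class = "cluster_spec")
}

#' Taxon panel / motile-only family specification
#'
#' @param panel data frame with columns `taxon` (character) and `motile`
#'   (logical); the first row is the reference taxon.
#' @param n_motile_only_families families planted present in every motile
#'   taxon and absent from every non-motile taxon.
#' @param n_ubiquitous families planted in all taxa.
#' @param n_random families with random presence/absence.
#' @return list of class `ciliacut_spec`.
#' @export
ciliacut_spec <- function(panel = default_panel(),
                          n_motile_only_families = 20,
                          n_ubiquitous = 30, n_random = 30) {
  if (!is.data.frame(panel) || !all(c("taxon", "motile") %in% names(panel)))
    stop("panel must be a data frame with columns taxon, motile", call. = FALSE)
  if (nrow(panel) < 2) stop("panel needs at least 2 taxa", call. = FALSE)
  structure(list(panel = panel,
                 n_motile_only_families = as.integer(n_motile_only_families),
                 n_ubiquitous = as.integer(n_ubiquitous),
                 n_random = as.integer(n_random)),
            class = "ciliacut_spec")
}

#' Default chlorophyte-like taxon panel (4 motile, 4 non-motile)
#' @return data frame with columns `taxon`, `motile`.
#' @export
default_panel <- function() {
  data.frame(
    taxon = c("ref_motile", "motA", "motB", "motC",
              "nonA", "nonB", "nonC", "nonD"),
    motile = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Orthogroup alignment / rate-shift specification
#'
#' @param n_orthogroups total orthogroups simulated.
#' @param length alignment length in amino-acid columns (minimum 50; below
#'   that the relative-rate test has essentially no power).
#' @param n_slow,n_fast numbers of orthogroups with rate-shifted focal
#'   branches.
#' @param mult_slow,mult_fast focal-branch rate multipliers (> 0).
#' @param base_subs expected substitutions per site on each ingroup branch.
#' @param out_subs expected substitutions per site on the outgroup branch.
#' @param n_triplets triplets (reference/outgroup pairs) per orthogroup.
#' @return list of class `rate_spec`.
#' @export
rate_spec <- function(n_orthogroups = 50, length = 500,
                      n_slow = 5, n_fast = 5,
                      mult_slow = 1 / 3, mult_fast = 3,
                      base_subs = 0.06, out_subs = 0.15, n_triplets = 10) {
  stop_if_not_scalar_number(n_orthogroups, "n_orthogroups", 1)
  if (length < 50) stop("alignment length must be >= 50", call. = FALSE)
  if (mult_slow <= 0 || mult_fast <= 0)
    stop("rate multipliers must be > 0", call. = FALSE)
  if (n_slow + n_fast > n_orthogroups)
    stop("n_slow + n_fast exceeds n_orthogroups", call. = FALSE)
  stop_if_not_scalar_number(base_subs, "base_subs", 0, 1)
  stop_if_not_scalar_number(out_subs, "out_subs", 0, 1)
  stop_if_not_scalar_number(n_triplets, "n_triplets", 1)
  structure(list(n_orthogroups = as.integer(n_orthogroups),
                 length = as.integer(length),
                 n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
                 mult_slow = mult_slow, mult_fast = mult_fast,
                 base_subs = base_subs, out_subs = out_subs,
                 n_triplets = as.integer(n_triplets)),
            class = "rate_spec")
}

#' Bundle all simulator specifications with a master seed
#'
#' One RNG stream per simulator is derived from `seed` by fixed offsets, so
#' any fixture can be regenerated independently of the others.
#'
#' @param seed master integer seed.
#' @param genome_length scaffold length in bp.
#' @param n_genes number of gene models to plant.
#' @param background_gc GC fraction outside the island, in (0, 1).
#' @param island an [island_spec()].
#' @param expression an [expression_spec()].
#' @param secretome a [secretome_spec()].
#' @param clusters a [cluster_spec()].
#' @param ciliacut a [ciliacut_spec()].
#' @param rates a [rate_spec()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 1e6, n_genes = 400,
                       background_gc = 0.58,
                       island = island_spec(),
                       expression = expression_spec(),
                       secretome = secretome_spec(),
                       clusters = cluster_spec(),
                       ciliacut = ciliacut_spec(),
                       rates = rate_spec()) {
  stop_if_not_scalar_number(seed, "seed", 0, .Machine$integer.max)
  stop_if_not_scalar_number(genome_length, "genome_length", 1000)
  stop_if_not_scalar_number(n_genes, "n_genes", 1)
  stop_if_not_scalar_number(background_gc, "background_gc", 1e-6, 1 - 1e-6)
  stopifnot(inherits(island, "island_spec"),
            inherits(expression, "expression_spec"),
            inherits(secretome, "secretome_spec"),
            inherits(clusters, "cluster_spec"),
            inherits(ciliacut, "ciliacut_spec"),
            inherits(rates, "rate_spec"))
  arr <- island$repeat_unit_length * island$repeat_copies
  if (island$length > 0) {
    start <- island$start %||% (genome_length - arr - island$length + 1)
    if (start < 1 || start + island$length - 1 > genome_length - arr)
      stop("island (with its terminal repeat array) does not fit in the scaffold",
           call. = FALSE)
    island$start <- as.integer(start)
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 background_gc = background_gc,
                 island = island, expression = expression,
                 secretome = secretome, clusters = clusters,
                 ciliacut = ciliacut, rates = rates),
            class = "sim_config")
}
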