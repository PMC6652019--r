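---
title: "Methods: the lichenscreen symbiosis-gene screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lichenscreen symbiosis-gene screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichenscreen)
```

# Overview

`lichenscreen` implements the computational screens used to nominate
candidate symbiosis genes from a two-partner lichen system — a fungal
mycobiont and a green-algal photobiont grown in coculture versus
monoculture. The screens are deliberately simple, threshold-based rules
(ratio cuts, set logic, exact tail probabilities, count-based rate tests)
rather than model-fitting machinery, because that is what the original
analyses were: each stage consumes tabular inputs that stand in for the
outputs of external tools (read aligners, secretion predictors, BLASTP),
and the package's job is to make the downstream decision rules explicit,
reusable and testable.

A first-class synthetic-data module generates all of those inputs with
planted ground truth, so every stage can be exercised end to end with no
external downloads.

# Differential expression on Co/Mo RPKM ratios

Expression is quantified as RPKM (reads per kilobase of gene model per
million aligned reads):

$$\mathrm{RPKM} = \frac{c}{(L/1000)\,(M/10^6)}$$

with count $c$, gene length $L$ bp, and mapped total $M$. The induction
metric is the coculture/monoculture RPKM ratio (Co/Mo). Because the two
symbionts display different Co/Mo ranges, different thresholds are used:
induced at Co/Mo $\ge 2$ (fungus) or $\ge 1.3$ (alga), repressed at
$\le 0.5$ or $\le 0.77$. Boundaries are inclusive — a fungal gene at
exactly 2.0 is induced. Choices made where the original rules were
underspecified:

* **Detection floor.** A gene below 0.5 RPKM in *both* conditions is
  `not_detected` (the source tables mark such genes "n.d." without a
  stated floor). 0.5 RPKM is a conventional low-expression floor for
  single-library RNA-seq.
* **Zero denominators.** A gene with monoculture RPKM 0 but coculture
  RPKM above the floor gets ratio `Inf` and is classified induced:
  strong induction should not be discarded because of an empty
  denominator.
* **Log2 variant.** A second, GO-style classifier calls up/down at
  $|\log_2(\mathrm{Co/Mo})| > 0.6$. (The source text's "< 0.6 for
  downregulation" is read as $-0.6$, consistent with its own summary
  "0.6 > log2 > −0.6".)
* **Bootstrap RPKM.** The upstream pipeline used a resampling
  quantifier whose internals are unpublished; `bootstrap_rpkm()`
  resamples the count vector as a multinomial at fixed library total
  (B = 1000 default) and reports the mean and 2.5/97.5 percentiles.
  This reproduces sampling noise of counts at fixed depth, not
  read-level alignment uncertainty.

# Consensus secretome

A protein is called secreted only when three independent predictions
agree: a positive signal-peptide call, a secretory-pathway localization
call, and a transmembrane annotation compatible with secretion — no TM
domain, or exactly one starting within the N-terminal window (a signal
anchor). The window defaults to 60 residues; "at the N terminus" is not
quantified in the source, and 60 residues comfortably covers signal
anchors while excluding genuine single-pass membrane proteins. The TM
rule is applied once, on the provided TM annotations.

# Hypergeometric enrichment with a BLAST background

Subgroups of induced genes are tested for over-representation with the
exact upper tail

$$P(X \ge k) = \sum_{i=k}^{\min(K,n)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

where the background $K$ is not a GO category but the BLAST-similarity
set: the subgroup plus every genome gene hit by a subgroup member at
e-value $< 10^{-5}$. The tail is evaluated from first principles in log
space (log-gamma coefficients, log-sum-exp accumulation, early
termination at $10^{-16}$ relative tolerance) so the convention is
explicit; tests verify agreement with brute-force enumeration to
$10^{-12}$ relative error. The observed $k$ is included in the tail
(one-sided). Raw p values are reported by default, matching the original
analysis; a Benjamini–Hochberg column is available behind a flag. The
enrichment factor is $(k/n)/(K/N)$.

For the printed secretome contingencies the exact tails computed here are
$3.5\times10^{-28}$ (fungus) and $4.8\times10^{-4}$ (alga); the source
printed $2.8\times10^{-28}$ and $3\times10^{-5}$. The original tool and
tail convention are unstated, so both are reported side by side and
neither is forced to match.

# Low-GC island detection and scaffold joining

GC is computed over sliding windows (default 5 kb window, 1 kb step;
the source states no window) with ambiguous bases excluded from both
numerator and denominator. Anomalous regions are maximal runs of windows
with GC below

$$\mathrm{median} - 4 \times \mathrm{MAD}\ (\times 1.4826),$$

merged across single-window gaps and discarded below a minimum length
(default 20 kb). The robust-z rule is a declared substitute for the
source's unquantified "significantly lower": its island (49% GC against
a 56–62% genome) is a $\ge 5$-SD excursion, so a $z < -4$ rule detects
it without tuning to the fixture. Genes belong to a region by midpoint
containment, which avoids double-counting at boundaries.

Terminal repeat arrays are discovered by exact tandem decomposition of
the terminal 5 kb of each scaffold. The unit reported is the *primitive*
(shortest $\ge$ 20 bp) period with at least 3 copies — not the longest:
the longest-unit rule would make the discovered unit depend on the copy
number (an array of 10 copies admits a 3-unit multiple as "longest"
while an array of 5 copies does not), so two arrays of the same unit
could fail to match. Units are compared up to cyclic rotation and
reverse complement, and a join retains a single array copy:
$L_{joined} = L_A + L_B - (c_A + c_B - 1)\,u$.

# Homolog clusters

Homology hits are retained at $\ge 45\%$ similarity with query coverage
in $[50\%, 150\%]$, boundaries inclusive. Retained homologs on one
scaffold are chained whenever at most 6 gene models intervene
(annotation ordinals over all models, both strands; nested models count
once), and connected components become clusters — so chaining is
transitive and end-to-end spans may exceed the pairwise bound.
Singletons are reported (unclustered paralogs are informative) and can
be filtered with `min_size`. Flanking intervals (default 10 kb, clipped
to the scaffold) and intra-cluster gaps are emitted for downstream
inspection.

# Orthology sets

Reciprocal best hits use the lowest e-value below $10^{-5}$ (strict
inequality); ties are broken by higher similarity, then lexicographic
subject id, because an unbroken tie makes "best" undefined. A
`strict_ties` mode disqualifies tied queries instead. The
presence/absence matrix marks a reference protein present in a taxon iff
an RBH pair exists there, and the CiliaCut-style selection takes rows
present in *every* motile taxon and absent from *every* non-motile
taxon. The same machinery serves presence checks for small query lists
(e.g. a meiosis gene toolkit); no separate operation is needed.

# Relative-rate screen

For each orthogroup and triplet (focal, reference, outgroup), over
columns with a valid residue in all three sequences, the test counts
sites where only the focal sequence differs ($n_f$) and where only the
reference differs ($n_r$), and uses the classical relative-rate
chi-square

$$\chi^2 = \frac{(n_f - n_r)^2}{n_f + n_r}, \quad df = 1,$$

with direction fast/slow by the sign of $n_f - n_r$ at $p \le 0.05$
(boundary inclusive). The original analysis delegated rate estimation to
an external likelihood package without printing a formula; this
standard, printable statistic is the declared substitute. Zero
informative sites give statistic 0 and $p = 1$ rather than an error.

An orthogroup-level call requires $\ge 90\%$ of its triplets significant
in the same direction with none significant in the opposite direction;
an alternative reading (90% of *significant* triplets agree) is
available as `mode = "significant-only"`. Final candidates must be
called in the same direction by at least two methods. The second method
is distance-based: Poisson-corrected distances $d = -\ln(1 - p)$ from
focal and reference to the outgroup, with a 200-resample column
bootstrap; a call is made only when the percentile interval of the
distance difference excludes zero. The triplet-definition table is a
required input — which reference/outgroup combinations constitute "all
triplets" cannot be reconstructed from the source text.

**Known power asymmetry.** With the default simulated world (0.06
substitutions/site on ingroup branches, alignment length 500, 10
triplets), 3×-fast orthogroups are recovered essentially always, while
⅓-slow ones are recovered in only ~60–80% of cases: a slowed focal
branch *removes* private substitutions, so the counts carry less signal
and the strict $\ge 9/10$-triplet consensus fails more often. The
acceptance bound (sensitivity $\ge 0.9$) therefore applies to the fast
direction, matching the stated power scenario; slow orthogroups remain
in the simulated world and their calls are checked for correctness, not
completeness.

# The synthetic world

The generator's defaults describe one fixed stated world:

* **Genome.** One scaffold, i.i.d. bases at background GC 0.58 with a
  planted 100-kb island at GC 0.49 (the contrast the source reports),
  terminating in an array of 10 copies of a random 141-bp unit at the
  scaffold end. No codon structure or repeat landscape — windowed GC is
  all the detector consumes.
* **Genes.** Non-overlapping models, 300–2400 bp, one per genome slot;
  island genes are mostly intronless (~8%, matching the reported 36/462)
  and viral-heavy in best-hit affinity; background genes are
  chlorophyte-heavy (~69%) with introns.
* **Counts.** Negative binomial with mean ∝ length × log-normal
  baseline × fold. Dispersion defaults to 0.01: the emulated design
  pools replicate cultures into a single library per condition, leaving
  mostly technical, near-Poisson noise; across-replicate biological
  dispersion does not apply. RPKM normalization downstream uses the
  configured library sizes as mapped totals, so a planted gene's
  expected Co/Mo equals its fold exactly (realized-total normalization
  would deflate every ratio by the compositional shift the induced set
  introduces).
* **Secretion calls.** Three predictors flip independently at
  concordance 0.95 on planted secreted genes (recovery follows
  concordance³), with 3% independent false positives elsewhere.
* **Homology.** Planted orthologs get mutual best hits at e <
  10⁻²⁰; decoys sit above 10⁻⁴, so RBH at 10⁻⁵ recovers exactly the
  planted pairs. A homolog cluster is planted with inter-member gaps
  drawn within the chaining bound, plus scattered unclustered paralogs
  and filter-failing decoy hits.
* **Alignments.** Star triplets under a Poisson replacement process with
  uniform target residues (the tests consume only difference counts);
  ingroup branches at 0.06, outgroup at 0.15 substitutions/site,
  multipliers 3 and ⅓ on rate-shifted focal branches.
* **Seeds.** One RNG stream per simulator, derived from the master seed
  by fixed offsets, so each fixture regenerates independently and
  byte-identically.

What a green test does *not* establish: realism of codon usage, intron
structure, read-level alignment artifacts, genuinely correlated
predictor errors, paralog-confounded homology, or heterotachy. The
generator plants clean signals at the stated effect sizes; the tests
establish that the decision rules recover exactly those signals and
agree with independent oracles (enumeration, union-find, brute-force set
logic) on random inputs.

# Numerical and interface choices

* Exact tails in log space; enumeration agreement to $10^{-12}$
  ($N \le 60$ verified).
* Ratio/threshold comparisons are plain floating-point comparisons on
  inclusive boundaries; printed percentages round to one decimal.
* Degenerate inputs are values, not errors, wherever absence is
  meaningful: empty GC tracks, regions without genes, saturated
  distances, zero informative sites, absent joins.
* The CLI `simulate` subcommand reads a JSON configuration (the
  deployment environment ships no YAML reader; the structure is the
  same nested list).

# Limitations

The study's headline counts (795 induced fungal genes, 462 island
genes, 38/11 and 3/7 slow/fast candidates, …) depend on the real genome
assemblies and RNA-seq libraries and are not reproducible here; the
package reproduces the *rules* and verifies every printed ratio those
rules compute from printed counts. The likelihood-based heterotachy
protocol of the original three-method screen is unavailable in the
source text and is explicitly out of scope; the two implemented methods
exercise the intersection rule in its place.
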