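---
title: "Classifying gene duplicates and measuring WGD retention in pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene duplicates and measuring WGD retention in pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodup)
```

# The question

Flowering-plant genomes carry layers of ancient whole-genome duplications
(WGDs, paleopolyploidies). After each WGD most duplicate copies are lost
again, but loss is not uniform: some functional modules — dosage-sensitive
complexes, whole metabolic pathways — keep both copies far more often than
the genome-wide average. `paleodup` implements the analysis chain needed
to ask, for any annotated genome and any gene set of interest: *what
fraction of these genes are WGD-derived duplicates, from which WGD epoch
does each pair date, and is the pathway's retention significantly above
the genome background?*

The chain has five stages, each usable on its own:

1. **Collinearity** (`detect_syntenic_blocks`): chain homologous gene
   pairs into syntenic blocks on gene-rank coordinates.
2. **Mode classification** (`classify_pair_modes`,
   `assign_gene_modes`): WGD / tandem (TD) / proximal (PD) / transposed
   (TRD) / dispersed (DSD) / singleton, with a fixed priority hierarchy.
3. **Ka/Ks** (`ng86_ka_ks`): Nei–Gojobori (1986) counting with
   Jukes–Cantor correction.
4. **Ks mixture and epochs** (`fit_ks_mixture`, `assign_wgd_epochs`):
   Gaussian mixture on log10(Ks), one component per paleopolyploidy.
5. **Retention statistics** (`wgd_pathway_enrichment`,
   `compute_retention_profile`, `profile_permutation_test`,
   `term_overrepresentation`, `group_mean_comparison`).

A genome-evolution simulator (`simulate_genome`) with fully recorded
truth closes the loop: every stage is validated by parameter recovery.

# Coordinates and ranks

Gene models come from GFF3 (1-based inclusive coordinates). Internally
every gene gets a 0-based *rank* along its chromosome, ordered by
ascending start, ties broken by end then gene id. All neighborhood and
window arithmetic — tandem adjacency, proximal distance, the ±20-gene
retention profile — is done on ranks, never on base pairs: "the 20 genes
to the left" is a gene-count statement, and rank arithmetic makes it
independent of intergenic distances. Strand is stored but ignored for
ranking.

# Collinearity detection

Anchor matches between two chromosomes are chained by dynamic
programming: match *j* can extend match *i* iff both rank gaps are
positive and at most `max_gap` (default 25 genes), with rank_b increasing
(parallel) or decreasing (antiparallel). The chain score is the anchor
count — deliberately the simplest score that satisfies an exhaustive
search oracle; there is no gap penalty or bitscore weighting. The best
chain is extracted, its anchors removed, and the search repeats, so no
anchor belongs to two blocks; chains shorter than `min_anchors` (default
5) are discarded. Ties between equal-score chains are resolved toward the
smallest starting `(rank_a, rank_b)`, which makes results independent of
input order and, where a tandem copy sits next to its parent inside a
block, deterministically keeps the parent as the anchor.

Defaults follow the MCScanX-family convention (`max_gap = 25`,
`min_anchors = 5`).

Two deliberate design choices:

* **Tandem arrays are not collapsed before chaining.** The documented
  consequence is that runs of unrelated tandem/proximal pairs near the
  self-diagonal of a chromosome can chain into spurious "blocks". Those
  are removed by a span test: an intra-genomic, same-chromosome block
  whose two rank spans overlap pairs a region with itself and is
  discarded as a tandem-array artifact. Genuine intra-chromosomal
  segmental duplications (disjoint spans) survive the filter.
* **Multiplicity.** For every gene the number of distinct blocks covering
  its rank is reported; after *n* rounds of full duplication a region has
  2^n − 1 homologous partners, so coverage depth is the natural check of
  nested-WGD structure.

# Duplication-mode classification

Pairs are classified by the first matching rule, in the priority order
WGD > TD > PD > TRD > DSD:

| mode | rule |
|------|------|
| WGD | pair is an anchor of an intra-genomic syntenic block |
| TD | same chromosome, rank distance exactly 1 |
| PD | same chromosome, rank distance in (1, `proximal_max`] (default 10) |
| TRD | exactly one gene of the pair lies at an ancestral locus (syntenic with the outgroup) |
| DSD | everything else |

Genes inherit the highest-priority mode among their pairs; genes in no
pair are singletons, so mode counts always partition the catalog.

Transposed duplications are only called when an outgroup anchor set is
supplied: the definition ("one copy at the ancestral locus, one at a
novel locus") is meaningless without an outgroup, so in its absence the
category degrades — loudly — into DSD rather than being guessed. A pair
whose two genes are both at ancestral loci but not collinear with each
other is DSD, not TRD.

# Ka/Ks by NG86

The NG86 method was chosen over maximum-likelihood counting because it is
fully specifiable and oracle-checkable: the test suite contains an
independent brute-force implementation (recursive pathway enumeration, no
lookup tables) and requires agreement to 1e-9 on hundreds of random
pairs. Conventions:

* Per codon position, the synonymous site fraction counts synonymous
  changes among the changes that do not create a stop codon
  (stop-producing changes are excluded from the denominator), so
  s + n = 3 exactly for every codon; sites are averaged over the two
  sequences.
* Codons differing at k > 1 positions average their difference counts
  over all k! substitution orders, skipping orders that pass through a
  stop; if every order hits a stop, the codon pair is dropped from the
  difference counts only.
* Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)·p) is applied to both
  proportions; where the argument is non-positive the rate is undefined
  and the estimate is flagged saturated.

Sequences of unequal length are aligned through their translations
(global protein alignment, BLOSUM62) and gapped codon columns removed;
equal-length pairs are compared ungapped.

# Ks mixture and epoch assignment

Ks values are windowed to (0.005, 5.0) — the lower bound removes
near-identical allelic artifacts, the upper the saturated tail — and
log10-transformed. Univariate Gaussian mixtures with unequal variances
are fitted for K = 1..`k_max` (default 4) via \pkg{mclust}'s EM
(deterministic hierarchical initialisation), and the K minimising
BIC = −2 log L + p log n is kept. Two admissibility guards protect the
model selection:

* a component sd below 1e-4 marks an ill-conditioned fit (degenerate
  spike) — that K is skipped;
* a component weight below 1% marks outlier capture — a "peak" carried
  by a handful of stray pairs is not a duplication epoch. Without this
  guard, a few mis-anchored low-Ks pairs among thousands can flip the
  selected K.

Components are ordered by ascending mean, so **epoch 1 is the youngest
peak**. Greek-letter naming (α/β/γ) is left to the user: the mapping of
letters to ages differs between communities, so the package reports
ordinal epochs only. Each WGD pair is assigned to the component with the
highest posterior membership (ties toward the younger epoch — the
documented, reproducible convention); saturated pairs stay unassigned. A
gene's epoch is that of its highest-posterior WGD pair.

# Retention statistics

**Pathway enrichment.** The 2×2 table (pathway vs rest-of-genome) ×
(WGD vs not) is tested with Pearson's chi-square *without* continuity
correction: intended use is genome-scale tables with expected counts far
above 5, where the correction only biases. The reported genome background
proportion is computed over *all* genes (pathway included), matching how
genome-wide WGD percentages are usually quoted, while the test itself
uses disjoint rows.

**Retention profile.** For focal genes and offsets −W..+W (default
W = 20), the gene at rank+offset contributes to that offset's
denominator, and to the numerator iff its mode is WGD. Offsets falling
off a chromosome shrink the denominator — windows never wrap or cross
chromosomes. Focal genes may appear in each other's windows; no exclusion
is applied. The permutation null redraws focal-sized gene sets uniformly
without replacement and recomputes the offset-0 ratio; the one-sided
empirical p uses add-one smoothing, so p ≥ 1/(n_perm + 1).

**ORA and group tests.** Term over-representation is the upper-tail
hypergeometric with Benjamini–Hochberg adjustment (terms with fewer than
3 genes in the universe are skipped). Cross-species group comparison is
Student's pooled-variance t-test; the degenerate zero-variance,
equal-mean case returns the defined limit t = 0, p = 1.

# The simulator: what it emulates and what it does not

`simulate_genome` produces an ancestral genome (default 5 chromosomes ×
400 genes, CDS lengths Poisson around 300 codons), then applies WGD
events oldest first. Each event copies every gene onto a new homeologous
chromosome in order; new copies survive with the pathway retention
probability (default 0.7) for genes in the designated pathway (default
120 ancestral genes) and the background probability (default 0.3)
otherwise. Between events, all lineages accumulate synonymous and
nonsynonymous substitutions so that pairs separated at an event reach
that event's present-day target Ks (defaults 0.6 and 0.2); per-family
rate factors (lognormal, sd 0.08 on log10) widen the peaks realistically.
Substitution targets are drawn Poisson and placed on uniformly random
synonymous (resp. nonsynonymous) single-nucleotide opportunities, never
creating stops; `omega` (default 0.2) sets Ka/Ks.

Small-scale duplications are applied after the WGDs, with divergence
drawn below the youngest WGD age (events that postdate the WGDs cannot be
older than them): tandem copies inserted rank-adjacent, proximal copies
within `proximal_max` ranks, transposed copies at random loci with the
parent kept at its ancestral locus, and — a deliberate modelling choice —
dispersed duplications acting on single-copy families with *both* members
relocated. A dispersed pair whose parent stayed at an ancestral locus
would be structurally indistinguishable from a transposed pair; modelling
DSD on single-copy families gives the category the defining property the
classifier tests for (no positional conservation on either side, no
ancestral-locus relative).

The frozen pre-WGD ancestor is emitted as the outgroup catalog and anchor
pairs, and homolog pairs are derived directly from recorded parentage
(with pseudo-bitscores decreasing in sequence divergence) rather than by
running a similarity search — tests stay hermetic while exercising the
exact input formats.

What the simulator does **not** emulate: intergenic sequence, introns,
transposable elements, chromosomal rearrangement beyond duplicate
placement, gene loss of pre-WGD parents, lineage-specific rate shifts,
codon-usage bias, and indel evolution inside CDS. Passing recovery tests
therefore demonstrates correctness of the inference machinery under a
clean duplication history, not robustness to assembly artifacts or
annotation noise in real genomes.

# Numerical and degenerate-input conventions

* Rank ties broken by (start, end, gene_id); all orderings deterministic,
  so identical inputs give byte-identical outputs.
* Homology input filtering defaults: e-value ≤ 1e-10, bitscore ≥ 0
  (typical paralog-search stringency); reciprocal rows collapse to one
  canonical (lexicographic) pair keeping the best bitscore; self-hits
  dropped.
* Saturated Ks (p ≥ 3/4) never enters the mixture; pairs with missing
  sequences get NA estimates and are carried, flagged, through the
  output tables.
* Mixture fitting needs ≥ 50 windowed Ks values; fewer is an error, not
  a silent fit.
* Chi-square with a zero row or column margin is an error (test
  undefined), not a 0-statistic.
* The master seed fans out to fixed per-stage offsets (mixture,
  permutation), so stages are individually reproducible.

# Problem sizes used in the tests

The bundled validation runs at desk scale, chosen so the full suite and
the acceptance script complete comfortably on one core: the default
5 × 400-gene genome (~4000 genes after two WGDs, ~3100 paralog pairs),
200 random 100-codon pairs against the NG86 oracle, 500 random instances
against the chaining oracle, 1000 null replicates for chi-square
calibration, and 999 permutations for the profile null. Recovery under
these conditions: gene-mode accuracy ≈ 0.97, WGD recall > 0.99, mixture
K = 2 with peak means within ±0.01 on log10(Ks), epoch agreement ≈ 0.99.

# Known limitations

* NG86 without transition/transversion or codon-usage corrections
  underestimates Ks slightly at high divergence; peaks beyond Ks ≈ 2 are
  better dated with ML methods.
* Chain scoring by anchor count (no gap penalty) can absorb occasional
  stray matches into large blocks; downstream this shows up as a
  percent-level contamination of WGD calls, handled by the mixture's
  admissibility guards.
* TRD calls depend entirely on the quality of the outgroup synteny; with
  a distant or fragmented outgroup the TRD/DSD boundary blurs.
* The enrichment test treats genes as independent; tandem arrays inside
  a pathway mildly violate that.
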