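# paleodup

Duplicate genes, paleopolyploidy, and pathway-biased retention.

Plant genomes are layered with ancient whole-genome duplications (WGDs).
Most duplicated genes are subsequently lost, but loss is biased: certain
pathways keep their WGD-derived copies far more often than the genome
average, and that retention bias is itself a biological signal — for
example, oilseed crops retain duplicated fatty-acid and triacylglycerol
biosynthesis genes at strikingly high rates. `paleodup` is an R toolkit
for making that kind of argument quantitative on any annotated genome:

* **Duplication-mode classification** in the DupGen_finder tradition.
  Paralog pairs become WGD / tandem (TD) / proximal (PD) / transposed
  (TRD) / dispersed (DSD) calls under the fixed priority
  WGD > TD > PD > TRD > DSD; genes inherit their best pair's mode or are
  singletons. WGD evidence is membership in an intra-genomic syntenic
  block, found by MCScanX-style anchor chaining on gene-rank coordinates
  (dynamic programming, greedy extraction, score = anchor count).
* **Ka/Ks estimation** by Nei–Gojobori (1986) counting with Jukes–Cantor
  correction: per-codon site fractions with stop-excluded denominators,
  all k! substitution pathways averaged for multi-hit codons,
  d = −¾·ln(1 − 4p/3).
* **Ks-based epoch dating**: Gaussian mixture on log10(Ks) fitted by EM
  for K = 1..k_max, BIC model selection; each WGD pair is assigned to a
  peak by posterior membership, so nested paleopolyploidies (α, β, ...)
  separate into ordinal epochs, youngest first.
* **Retention statistics**: pathway-vs-genome 2×2 chi-square (no
  continuity correction), duplication-mode composition tables,
  hypergeometric term over-representation with BH adjustment, Student's
  t-test for cross-species group contrasts, and a ±20-gene
  rank-neighborhood retention profile with a permutation null.
* **A genome-evolution simulator** with recorded ground truth — nested
  WGDs with biased pathway retention, small-scale duplications, sequence
  divergence tuned to target Ks — so the entire pipeline is validated by
  parameter recovery, no downloads required.

## Worked example

Simulate a small genome with two nested WGDs (present-day Ks peaks 0.6
and 0.2), a 40-gene pathway retained at 0.7 versus 0.3 background, then
run the analysis stages:

```r
library(paleodup)

params <- sim_params(n_chromosomes = 2, genes_per_chromosome = 150,
                     pathway_size = 40, seed = 2)
sim <- simulate_genome(params)
sim
#> synthetic_genome: 618 genes on 8 chromosomes (2 WGDs)
#>   true modes: DSD=44, PD=20, singleton=108, TD=29, TRD=19, WGD=398
#>   pathway: 136 genes; homolog pairs: 513

blocks <- detect_syntenic_blocks(sim$catalog, NULL, sim$pairs)
blocks
#> synteny_blocks: 14 block(s), 363 anchor pair(s) (intra-genomic)
#>   anchors per block: median 20.5, range 5-54
#>   gene coverage depth: 0x8, 1x4, 2x43, 3x430, 4x133
```

Most genes are covered by 3 blocks — exactly the 2² − 1 homologous
partners two rounds of duplication leave behind. Classify modes (the
outgroup synteny enables transposed calls), estimate Ks on the paralog
pairs, and date the WGD pairs:

```r
outg <- detect_syntenic_blocks(sim$outgroup_catalog, sim$catalog,
                               sim$outgroup_pairs)
anchors <- unique(unlist(lapply(outg$blocks, function(b) b$anchors$gene_b)))
pair_modes <- classify_pair_modes(sim$pairs, blocks, sim$catalog, anchors)
gene_modes <- assign_gene_modes(pair_modes, sim$catalog)

ks <- ks_for_pairs(pair_modes, sim$cds)
wgd <- ks[pair_modes$mode == "WGD" & !is.na(ks$saturated) & !ks$saturated, ]
fit_ks_mixture(wgd$ks, seed = 7)
#> ks_mixture: 2 component(s) on log10(Ks), n = 363, BIC = -126.3
#>   epoch 1: weight 0.379, mean log10(Ks) -0.700 (Ks ~ 0.199), sd 0.110
#>   epoch 2: weight 0.621, mean log10(Ks) -0.209 (Ks ~ 0.618), sd 0.098
```

Both simulated peaks (0.2 and 0.6) are recovered. Is the pathway's WGD
retention above the genome background?

```r
wgd_pathway_enrichment(gene_modes, sim$pathway_ids)
#> WGD retention: pathway 120/136 (88.2%) vs genome 415/618 (67.2%)
#> chi-square (df = 1, no continuity correction) = 35.1387, P = 3.07e-09

prof <- compute_retention_profile(sim$catalog, gene_modes, sim$pathway_ids)
prof
#> retention_profile: 136 focal genes, window +/-20
#>   ratio at offset 0: 0.882; mean ratio at |offset| >= 10: 0.715

profile_permutation_test(sim$catalog, gene_modes, sim$pathway_ids, seed = 99)
#> permutation test: observed retention 0.882 vs null 0.672 +/- 0.036; p = 0.001 (999 permutations)
```

The pathway sits at 88% WGD retention against a 67% genome background
(chi-square P ≈ 3e-09); the retention profile peaks exactly at the focal
genes and falls to background within the ±20-gene neighborhood, and no
random gene set among 999 permutations matches the observed peak.

`run_pipeline(pipeline_config(...))` performs the same chain from
standard files (GFF3 + CDS FASTA + 12-column similarity table + pathway
id list) and writes TSV/JSON result tables plus a run manifest;
`inst/cli/paleodup.R` exposes it as `simulate` / `blocks` / `classify` /
`ks` / `enrich` / `profile` / `run-all` subcommands.

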