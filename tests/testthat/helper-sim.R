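# Shared simulated-genome fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# classification stages on an in-memory synthetic genome
analyze_sim <- function(sim, max_gap = 25L, min_anchors = 5L,
                        proximal_max = 10L) {
  blocks <- detect_syntenic_blocks(sim$catalog, NULL, sim$pairs,
                                   max_gap = max_gap,
                                   min_anchors = min_anchors)
  ob <- detect_syntenic_blocks(sim$outgroup_catalog, sim$catalog,
                               sim$outgroup_pairs, max_gap = max_gap,
                               min_anchors = min_anchors)
  anchors <- unique(unlist(lapply(ob$blocks, function(b) b$anchors$gene_b)))
  pm <- classify_pair_modes(sim$pairs, blocks, sim$catalog, anchors,
                            proximal_max)
  gm <- assign_gene_modes(pm, sim$catalog)
  list(blocks = blocks, outgroup_anchors = anchors,
       pair_modes = pm, gene_modes = gm)
}

# default study conditions: 5 x 400 genes, two WGDs (Ks 0.6 then 0.2),
# retention 0.3 background / 0.7 pathway, pathway of 120 ancestral genes
default_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_genome(sim_params(seed = 1L))
  .fixture_cache$sim
}

default_analysis <- function() {
  if (is.null(.fixture_cache$analysis)) {
    sim <- default_sim()
    an <- suppressMessages(analyze_sim(sim))
    kp <- ks_for_pairs(an$pair_modes, sim$cds)
    kp$mode <- an$pair_modes$mode
    wgd <- kp[kp$mode == "WGD" & !is.na(kp$saturated) & !kp$saturated, ]
    mix <- suppressWarnings(fit_ks_mixture(wgd$ks, k_max = 4, seed = 7))
    ep <- suppressMessages(assign_wgd_epochs(mix, wgd))
    .fixture_cache$analysis <- c(an, list(
      ks_pairs = kp, wgd_estimates = wgd, mixture = mix, epochs = ep,
      wgd_truth = truth_pair_modes(sim, wgd)))
  }
  .fixture_cache$analysis
}

# small, fast genome for structural tests
small_sim <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- simulate_genome(sim_params(
      n_chromosomes = 2L, genes_per_chromosome = 120L, cds_codons = 120L,
      pathway_size = 30L, seed = 4L))
  .fixture_cache$small
}
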