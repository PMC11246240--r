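test_that("ancestral genomes have contiguous ranks and clean CDS", {
  p <- sim_params(n_chromosomes = 2L, genes_per_chromosome = 50L,
                  cds_codons = 80L, pathway_size = 10L, seed = 2L)
  g <- simulate_ancestral_genome(p)
  expect_equal(nrow(g$catalog), 100L)
  for (ch in attr(g$catalog, "chromosomes"))
    expect_setequal(g$catalog$rank[g$catalog$chromosome == ch], 0:49)
  expect_true(all(nchar(g$cds) %% 3 == 0))
  stops <- c("TAA", "TAG", "TGA")
  internal <- vapply(g$cds, function(s) {
    cod <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    any(cod %in% stops)
  }, logical(1))
  expect_false(any(internal))
  expect_true(all(substr(g$cds, 1, 3) == "ATG"))
  # determinism
  g2 <- simulate_ancestral_genome(p)
  expect_identical(g$cds, g2$cds)
  expect_identical(as.data.frame(g$catalog), as.data.frame(g2$catalog))
})

test_that("full retention with no small-scale events pairs every gene once", {
  p <- sim_params(n_chromosomes = 1L, genes_per_chromosome = 40L,
                  cds_codons = 60L,
                  wgd_events = list(list(ks = 0.3, log10_sd = 0.05,
                                         retention_bg = 1,
                                         retention_pathway = 1)),
                  pathway_size = 5L, rate_td = 0, rate_pd = 0,
                  rate_trd = 0, rate_dsd = 0, seed = 5L)
  sim <- simulate_genome(p)
  expect_equal(nrow(sim$catalog), 80L)
  expect_true(all(sim$truth$true_mode == "WGD"))
  expect_equal(nrow(sim$pairs), 40L)   # exactly one partner each
})

test_that("zero retention leaves the genome unchanged and all singletons", {
  p <- sim_params(n_chromosomes = 1L, genes_per_chromosome = 40L,
                  cds_codons = 60L,
                  wgd_events = list(list(ks = 0.3, log10_sd = 0.05,
                                         retention_bg = 0,
                                         retention_pathway = 0)),
                  pathway_size = 5L, rate_td = 0, rate_pd = 0,
                  rate_trd = 0, rate_dsd = 0, seed = 5L)
  sim <- simulate_genome(p)
  expect_equal(nrow(sim$catalog), 40L)
  expect_true(all(sim$truth$true_mode == "singleton"))
  expect_equal(nrow(sim$pairs), 0L)
})

test_that("retained-copy counts follow the binomial expectation", {
  p <- sim_params(n_chromosomes = 5L, genes_per_chromosome = 200L,
                  cds_codons = 60L,
                  wgd_events = list(list(ks = 0.3, log10_sd = 0.05,
                                         retention_bg = 0.3,
                                         retention_pathway = 0.3)),
                  pathway_size = 10L, rate_td = 0, rate_pd = 0,
                  rate_trd = 0, rate_dsd = 0, seed = 6L)
  sim <- simulate_genome(p)
  n_copies <- nrow(sim$catalog) - 1000L
  expect_lt(abs(n_copies - 300), 3 * sqrt(1000 * 0.3 * 0.7))
})

test_that("every catalog gene appears exactly once in the truth table", {
  sim <- small_sim()
  expect_setequal(sim$truth$gene_id, sim$catalog$gene_id)
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  # every non-ancestral gene has a parent
  created <- sim$truth$gene_id[!is.na(sim$truth$parent)]
  expect_setequal(created, sim$records$child)
})

test_that("sequence divergence hits its Ks and Ka targets", {
  set.seed(701)
  cds <- random_cds(300)
  same <- evolve_duplicate_sequences(cds, 0)
  expect_identical(same$a, same$b)
  expect_identical(same$a, cds)
  ks <- vapply(1:25, function(i) {
    pr <- evolve_duplicate_sequences(cds, 0.3)
    ng86_ka_ks(pr$a, pr$b)$ks
  }, numeric(1))
  expect_gt(mean(ks), 0.27)
  expect_lt(mean(ks), 0.33)
  # with omega = 0 only pathway-averaging artifacts remain in Ka
  ka <- vapply(1:10, function(i) {
    pr <- evolve_duplicate_sequences(cds, 0.3, omega = 0)
    ng86_ka_ks(pr$a, pr$b)$ka
  }, numeric(1))
  expect_lt(max(ka), 0.005)
  expect_error(evolve_duplicate_sequences(cds, -1), ">= 0")
})

test_that("excessive growth and invalid parameters are rejected", {
  expect_error(sim_params(n_chromosomes = 0), "sizes")
  expect_error(sim_params(wgd_events = list(
    list(ks = 0.2, log10_sd = 0.1, retention_bg = 0.3,
         retention_pathway = 0.3),
    list(ks = 0.6, log10_sd = 0.1, retention_bg = 0.3,
         retention_pathway = 0.3))), "oldest first")
  expect_error(sim_params(wgd_events = list(
    list(ks = 0.3, log10_sd = 0.1, retention_bg = 2,
         retention_pathway = 0.3))), "retention")
  p <- sim_params(n_chromosomes = 1L, genes_per_chromosome = 30L,
                  cds_codons = 60L, pathway_size = 5L,
                  wgd_events = rep(list(list(ks = 0.9, log10_sd = 0.05,
                                             retention_bg = 1,
                                             retention_pathway = 1)), 0),
                  seed = 2L)
  # growth guard: four full duplications exceed the 10x cap
  p$wgd_events <- lapply(4:1 / 4, function(k)
    list(ks = k, log10_sd = 0.05, retention_bg = 1, retention_pathway = 1))
  g <- simulate_ancestral_genome(p)
  expect_error(apply_duplication_history(g, p), "10x")
})

test_that("identical parameters emit byte-identical files", {
  p <- sim_params(n_chromosomes = 1L, genes_per_chromosome = 60L,
                  cds_codons = 60L, pathway_size = 10L, seed = 8L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_simulation(simulate_genome(p), d1)
  f2 <- write_simulation(simulate_genome(p), d2)
  for (k in names(f1))
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])), label = k)
})

test_that("pair-level truth resolves split events through the parentage chains", {
  sim <- small_sim()
  rec <- sim$records
  wgd_children <- rec$child[rec$type == "WGD"]
  pr <- data.frame(gene_a = rec$parent[rec$type == "WGD"][1:5],
                   gene_b = wgd_children[1:5])
  tp <- truth_pair_modes(sim, pr)
  expect_true(all(tp$true_mode == "WGD"))
  expect_true(all(!is.na(tp$true_epoch)))
  td <- rec[rec$type == "TD", ][1, ]
  tp2 <- truth_pair_modes(sim, data.frame(gene_a = td$parent,
                                          gene_b = td$child))
  expect_equal(tp2$true_mode, "TD")
})
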