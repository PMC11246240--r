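test_that("perfect diagonals chain into single blocks in either orientation", {
  m <- data.frame(rank_a = 1:5, rank_b = 1:5)
  bl <- chain_anchors_dp(m, max_gap = 25, min_anchors = 5,
                         orientation = "parallel")
  expect_length(bl, 1L)
  expect_equal(bl[[1]]$n_anchors, 5L)
  expect_equal(bl[[1]]$orientation, "parallel")

  m2 <- data.frame(rank_a = 1:5, rank_b = 5:1)
  bl2 <- chain_anchors_dp(m2, max_gap = 25, min_anchors = 5,
                          orientation = "antiparallel")
  expect_length(bl2, 1L)
  expect_equal(bl2[[1]]$n_anchors, 5L)
  expect_equal(bl2[[1]]$orientation, "antiparallel")
})

test_that("gaps beyond max_gap break chains below min_anchors", {
  m <- data.frame(rank_a = c(1, 2, 30), rank_b = c(1, 2, 30))
  bl <- chain_anchors_dp(m, max_gap = 25, min_anchors = 3)
  expect_length(bl, 0L)
  # exhaustive confirmation: no valid chain of length 3 exists
  expect_equal(oracle_max_chain(m$rank_a, m$rank_b, 25, "parallel"), 2L)
})

test_that("first-chain score matches exhaustive search on random small instances", {
  set.seed(301)
  for (case in 1:80) {
    n <- sample(3:12, 1)
    m <- data.frame(rank_a = sample(0:18, n, replace = TRUE),
                    rank_b = sample(0:18, n, replace = TRUE))
    gap <- sample(c(2, 5, 25), 1)
    for (ori in c("parallel", "antiparallel")) {
      got <- paleodup:::.best_chain(m$rank_a, m$rank_b, gap, ori)$score
      want <- oracle_max_chain(m$rank_a, m$rank_b, gap, ori)
      expect_equal(got, want,
                   info = sprintf("case %d ori %s gap %d", case, ori, gap))
    }
  }
})

test_that("increasing max_gap never decreases the best chain score", {
  set.seed(302)
  for (case in 1:25) {
    n <- sample(5:14, 1)
    m <- data.frame(rank_a = sample(0:30, n, replace = TRUE),
                    rank_b = sample(0:30, n, replace = TRUE))
    scores <- vapply(c(1, 3, 8, 20),
                     function(g) paleodup:::.best_chain(m$rank_a, m$rank_b,
                                                       g, "parallel")$score,
                     numeric(1))
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("anchors are disjoint across blocks and intra-genomic detection is symmetric", {
  sim <- small_sim()
  bl <- detect_syntenic_blocks(sim$catalog, NULL, sim$pairs)
  keys <- unlist(lapply(bl$blocks, function(b)
    paste(b$anchors$gene_a, b$anchors$gene_b)))
  expect_equal(anyDuplicated(keys), 0L)
  # swapping pair roles leaves the anchor-pair set unchanged
  swapped <- data.frame(gene_a = sim$pairs$gene_b, gene_b = sim$pairs$gene_a)
  bl2 <- detect_syntenic_blocks(sim$catalog, NULL, swapped)
  expect_setequal(bl$anchor_pairs, bl2$anchor_pairs)
})

test_that("unknown gene ids in pairs are reported", {
  cat_ <- make_catalog(10)
  bad <- data.frame(gene_a = "chr1_g1", gene_b = "nope")
  expect_error(detect_syntenic_blocks(cat_, NULL, bad), "nope")
})

test_that("an exact 2-copy genome gives one block per homeolog and depth 1", {
  p <- sim_params(n_chromosomes = 1L, genes_per_chromosome = 50L,
                  cds_codons = 60L,
                  wgd_events = list(list(ks = 0.3, log10_sd = 0.05,
                                         retention_bg = 1, retention_pathway = 1)),
                  pathway_size = 5L, rate_td = 0, rate_pd = 0,
                  rate_trd = 0, rate_dsd = 0, seed = 9L)
  sim <- simulate_genome(p)
  bl <- detect_syntenic_blocks(sim$catalog, NULL, sim$pairs)
  expect_length(bl$blocks, 1L)
  expect_true(all(bl$multiplicity$depth == 1L))
})

test_that("two nested full duplications give coverage depth 3", {
  p <- sim_params(n_chromosomes = 1L, genes_per_chromosome = 50L,
                  cds_codons = 60L,
                  wgd_events = list(
                    list(ks = 0.6, log10_sd = 0.05,
                         retention_bg = 1, retention_pathway = 1),
                    list(ks = 0.2, log10_sd = 0.05,
                         retention_bg = 1, retention_pathway = 1)),
                  pathway_size = 5L, rate_td = 0, rate_pd = 0,
                  rate_trd = 0, rate_dsd = 0, seed = 9L)
  sim <- simulate_genome(p)
  bl <- detect_syntenic_blocks(sim$catalog, NULL, sim$pairs)
  # 2^2 - 1 homologous partners per region
  expect_true(mean(bl$multiplicity$depth == 3L) > 0.95)
})

test_that("empty pair sets yield empty block lists", {
  cat_ <- make_catalog(10)
  empty <- data.frame(gene_a = character(0), gene_b = character(0))
  bl <- detect_syntenic_blocks(cat_, NULL, empty)
  expect_length(bl$blocks, 0L)
  expect_equal(nrow(as.data.frame(bl)), 0L)
})
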