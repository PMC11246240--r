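test_that("NG86 reproduces the hand-computed single-difference example", {
  a <- strrep("TTT", 10)
  b <- paste0(strrep("TTT", 9), "TTC")
  e <- ng86_ka_ks(a, b)
  expect_equal(e$s_sites, 10 / 3)
  expect_equal(e$ps, 0.3)
  expect_equal(e$ks, -0.75 * log(0.6))
  expect_equal(e$ka, 0)
  expect_false(e$saturated)
})

test_that("identical sequences give zero rates; saturation flags undefined Ks", {
  a <- strrep("ATGGCT", 15)
  e <- ng86_ka_ks(a, a)
  expect_equal(e$ks, 0)
  expect_equal(e$ka, 0)
  # every codon synonymously different: ps = 3 >> 3/4, JC undefined
  sat <- ng86_ka_ks(strrep("TTT", 10), strrep("TTC", 10))
  expect_true(sat$saturated)
  expect_true(is.na(sat$ks))
})

test_that("length violations are rejected", {
  expect_error(ng86_ka_ks("ATGAAA", "ATG"), "equal length")
  expect_error(ng86_ka_ks("ATGA", "ATGA"), "multiple of 3")
  expect_error(ng86_ka_ks("", ""), "empty")
})

test_that("sites are conserved and estimates symmetric on random pairs", {
  set.seed(401)
  for (i in 1:12) {
    n <- sample(20:60, 1)
    a <- random_cds(n)
    b <- mutate_random(a, sample(0:25, 1))
    ea <- ng86_ka_ks(a, b)
    eb <- ng86_ka_ks(b, a)
    expect_equal(ea$s_sites + ea$n_sites, 3 * ea$n_codons, tolerance = 1e-9)
    expect_identical(ea$ks, eb$ks)
    expect_identical(ea$ka, eb$ka)
  }
})

test_that("NG86 agrees with the brute-force pathway-enumeration oracle", {
  set.seed(402)
  for (i in 1:25) {
    a <- random_cds(40)
    b <- mutate_random(a, sample(1:30, 1))
    got <- ng86_ka_ks(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$s_sites, want$s_sites, tolerance = 1e-9)
    expect_equal(got$ks, want$ks, tolerance = 1e-9)
    expect_equal(got$ka, want$ka, tolerance = 1e-9)
  }
})

test_that("adding synonymous-only differences never decreases Ks or changes Ka", {
  base <- strrep("GCTAAATTTCCG", 20)   # Ala Lys Phe Pro repeats
  seqs <- base
  cur <- base
  # successive third-position synonymous edits (GCT -> GCC)
  pos <- seq(3, nchar(base), by = 12)
  for (p in pos[1:10]) {
    substr(cur, p, p) <- "C"
    seqs <- c(seqs, cur)
  }
  ks <- vapply(seqs, function(s) ng86_ka_ks(base, s)$ks, numeric(1))
  ka <- vapply(seqs, function(s) ng86_ka_ks(base, s)$ka, numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_true(all(ka == 0))
})

test_that("codon-aware alignment recovers in-frame columns around an indel", {
  a <- "ATGGCTAAATTTCCGGAA"
  b <- "ATGGCTTTTCCGGAA"      # AAA codon deleted
  al <- align_codon_pair(a, b)
  expect_equal(nchar(al$a), nchar(al$b))
  expect_equal(nchar(al$a) %% 3, 0)
  e <- ng86_ka_ks(al$a, al$b)
  expect_equal(e$ks, 0)
  expect_equal(e$ka, 0)
})

test_that("the mixture recovers a single log-normal component", {
  set.seed(403)
  ks <- 10^rnorm(1000, -0.6, 0.1)
  m <- fit_ks_mixture(ks, k_max = 4, seed = 403)
  expect_equal(m$n_components, 1L)
  expect_equal(m$mean, -0.6, tolerance = 0.03)
})

test_that("the mixture recovers two well-separated components", {
  set.seed(404)
  ks <- c(10^rnorm(500, -0.70, 0.08), 10^rnorm(500, -0.22, 0.08))
  m <- suppressWarnings(fit_ks_mixture(ks, k_max = 4, seed = 404))
  expect_equal(m$n_components, 2L)
  expect_equal(m$mean[1], -0.70, tolerance = 0.05)
  expect_equal(m$mean[2], -0.22, tolerance = 0.05)
  expect_equal(sum(m$weight), 1, tolerance = 1e-9)
})

test_that("too few Ks values is an error advising more pairs", {
  expect_error(fit_ks_mixture(rep(0.2, 10)), "at least 50")
})

test_that("epoch assignment picks the maximum-posterior component, younger on ties", {
  model <- structure(list(n_components = 2L, weight = c(0.5, 0.5),
                          mean = c(-0.7, -0.2), sd = c(0.08, 0.08),
                          bic = 0, bic_table = c(NA, 0), loglik = 0,
                          n = 100, ks_window = c(0.005, 5)),
                     class = "ks_mixture")
  est <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                    ks = c(10^-0.7, 10^-0.45, NA))
  ep <- suppressMessages(assign_wgd_epochs(model, est))
  expect_equal(ep$pairs$epoch, c(1L, 1L, NA))   # midpoint tie -> younger
  expect_gt(ep$pairs$posterior[1], 0.5)
  expect_false("e" %in% ep$genes$gene_id)       # saturated pair unassigned
  expect_equal(ep$genes$epoch[ep$genes$gene_id == "a"], 1L)
})

test_that("gene-level epoch follows the gene's highest-posterior pair", {
  model <- structure(list(n_components = 2L, weight = c(0.5, 0.5),
                          mean = c(-0.7, -0.2), sd = c(0.08, 0.08),
                          bic = 0, bic_table = c(NA, 0), loglik = 0,
                          n = 100, ks_window = c(0.005, 5)),
                     class = "ks_mixture")
  est <- data.frame(gene_a = c("g", "g"), gene_b = c("x", "y"),
                    ks = c(10^-0.7, 10^-0.35))
  ep <- assign_wgd_epochs(model, est)
  # the Ks at -0.7 sits exactly on component 1's mean: highest posterior
  expect_equal(ep$genes$epoch[ep$genes$gene_id == "g"], 1L)
})
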