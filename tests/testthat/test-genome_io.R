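test_that("GFF3 genes are read with per-chromosome ranks and 1-based coordinates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\t.\tgene\t50\t80\t.\t-\t.\tID=g0",
               "chr2\t.\tgene\t10\t40\t.\t+\t.\tID=h1"), f)
  cat_ <- read_gene_models(f)
  expect_s3_class(cat_, "gene_catalog")
  expect_equal(nrow(cat_), 3L)
  expect_equal(cat_$rank[cat_$gene_id == "g0"], 0L)
  expect_equal(cat_$rank[cat_$gene_id == "g1"], 1L)
  expect_equal(cat_$rank[cat_$gene_id == "h1"], 0L)
  expect_equal(cat_$start[cat_$gene_id == "g1"], 100L)
})

test_that("rank ordering is forced by start position and ranks are gap-free", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("chr1\t.\tgene\t500\t900\t.\t+\t.\tID=a",
               "chr1\t.\tgene\t100\t200\t.\t+\t.\tID=b"), f)
  cat_ <- read_gene_models(f)
  expect_equal(cat_$rank[match(c("a", "b"), cat_$gene_id)], c(1L, 0L))
  for (ch in attr(cat_, "chromosomes"))
    expect_setequal(cat_$rank[cat_$chromosome == ch],
                    seq_len(sum(cat_$chromosome == ch)) - 1L)
})

test_that("malformed GFF3 lines and duplicate ids are rejected with context", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\t.\tgene\t100\t500\t.\t+\t.", f)   # 8 fields
  expect_error(read_gene_models(f), "line 1")
  writeLines(c("chr1\t.\tgene\t1\t5\t.\t+\t.\tID=g1",
               "chr1\t.\tgene\t9\t12\t.\t+\t.\tID=g1"), f)
  expect_error(read_gene_models(f), "duplicate")
})

test_that("GFF3 round-trip preserves ranks and coordinates, and agrees with rtracklayer", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$catalog, f)
  back <- read_gene_models(f)
  expect_equal(back$gene_id, sim$catalog$gene_id)
  expect_equal(back$rank, sim$catalog$rank)
  expect_equal(back$start, sim$catalog$start)
  expect_equal(back$end, sim$catalog$end)
  gr <- rtracklayer::import(f)
  gr <- gr[gr$type == "gene"]
  idx <- match(back$gene_id, gr$ID)
  expect_equal(back$start, GenomicRanges::start(gr)[idx])
  expect_equal(back$end, GenomicRanges::end(gr)[idx])
})

test_that("CDS reader uppercases, flags frame and internal-stop problems, keeps records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "atgaaataa",
               ">g2", "ATGAAAA",
               ">g3", "ATGTAAAAATAA"), f)
  expect_message(cds <- read_cds_sequences(f), "flagged")
  expect_equal(unname(cds["g1"]), "ATGAAATAA")
  expect_length(cds, 3L)
  expect_equal(attr(cds, "frame_invalid"), "g2")
  expect_equal(attr(cds, "internal_stop"), "g3")
})

test_that("CDS reader rejects empty streams and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_cds_sequences(f))
  writeLines(c(">g1", "ATG", ">g1", "AAA"), f)
  expect_error(read_cds_sequences(f), "duplicate")
})

test_that("homolog pairs are canonicalised, self-hits removed, thresholds applied", {
  f <- withr::local_tempfile(fileext = ".tsv")
  row <- function(q, s, ev, bs)
    paste(q, s, 99, 300, 3, 0, 1, 300, 1, 300, ev, bs, sep = "\t")
  writeLines(c(row("a", "b", "1e-50", 100),
               row("b", "a", "1e-60", 120),
               row("a", "a", "0", 500),
               row("c", "d", "1e-3", 80)), f)
  expect_message(pr <- read_homolog_pairs(f, max_evalue = 1e-5), "dropped")
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$gene_a, "a")
  expect_equal(pr$gene_b, "b")
  expect_equal(pr$bitscore, 120)
  expect_equal(attr(pr, "n_dropped"), 1L)
})

test_that("non-numeric similarity fields raise a parse error with the line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("a", "b", 99, 300, 3, 0, 1, 300, 1, 300, "1e-50", 100,
                     sep = "\t"),
               paste("c", "d", 99, 300, 3, 0, 1, 300, 1, 300, "oops", 100,
                     sep = "\t")), f)
  expect_error(read_homolog_pairs(f), "line 2")
})

test_that("pair canonicalisation is idempotent across write/read cycles", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  paleodup:::.write_similarity_tsv(sim$pairs, f)
  p1 <- read_homolog_pairs(f, max_evalue = 1)
  p1$pident <- 99; p1$length <- 300L; p1$mismatches <- 3L
  paleodup:::.write_similarity_tsv(p1, f)
  expect_error(p2 <- read_homolog_pairs(f, max_evalue = 1), NA)
  expect_equal(p1[, c("gene_a", "gene_b")], p2[, c("gene_a", "gene_b")])
})

test_that("result tables are deterministic and complete", {
  d <- withr::local_tempdir()
  gm <- data.frame(gene_id = c("a", "b", "c"),
                   mode = c("WGD", "TD", "singleton"),
                   epoch = c(1L, NA, NA), is_pathway = c(TRUE, FALSE, FALSE))
  write_results_tables(list(gene_modes = gm), d)
  out <- file.path(d, "gene_modes.tsv")
  expect_equal(nrow(utils::read.delim(out)), 3L)
  sum1 <- unname(tools::md5sum(out))
  write_results_tables(list(gene_modes = gm), d)
  expect_identical(unname(tools::md5sum(out)), sum1)
  write_results_tables(list(gene_modes = gm[0, ]), d)
  expect_equal(nrow(utils::read.delim(out)), 0L)
  expect_equal(names(utils::read.delim(out)),
               c("gene_id", "mode", "epoch", "is_pathway"))
})
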