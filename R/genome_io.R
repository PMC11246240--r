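# Readers and writers for the formats the pipeline touches, and the
# rank-coordinate convention shared by every downstream module.
# Coordinates are GFF3-style 1-based inclusive externally; gene order is
# expressed as a 0-based rank per chromosome (ascending start, ties broken
# by end then gene_id). All window/offset arithmetic downstream uses ranks.

#' Build a gene catalog from a gene table
#'
#' Assigns per-chromosome 0-based ranks by ascending start, ties broken by
#' ascending end then gene id, and validates uniqueness of gene ids.
#'
#' @param genes data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`.
#' @return A `gene_catalog`: the gene data frame (sorted by chromosome then
#'   rank) with a `rank` column, plus a `chromosomes` attribute.
#' @export
gene_catalog <- function(genes) {
  req <- c("gene_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$start > genes$end)) stop("start > end for some genes")
  genes$chromosome <- as.character(genes$chromosome)
  genes$gene_id <- as.character(genes$gene_id)
  ord <- order(genes$chromosome, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chromosome,
                           FUN = function(x) seq_along(x) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL
  structure(genes[, c(req, "rank")],
            chromosomes = unique(genes$chromosome),
            class = c("gene_catalog", "data.frame"))
}

#' @export
print.gene_catalog <- function(x, ...) {
  chroms <- attr(x, "chromosomes")
  cat("gene_catalog: ", nrow(x), " genes on ", length(chroms),
      " chromosome(s)\n", sep = "")
  tab <- table(x$chromosome)
  cat("  genes per chromosome: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Extracts features of one type from a GFF3 stream and returns a ranked
#' [gene_catalog()]. Coordinates are kept 1-based inclusive. The gene id is
#' taken from the `ID` attribute (falling back to `Name`, then
#' `gene_id`).
#'
#' @param path path to a GFF3 file (transparently gzipped is fine).
#' @param feature_type feature to extract from column 3 (default
#'   `"gene"`).
#' @return A `gene_catalog`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no feature lines in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GFF3 line ", lineno[which(nf < 9L)[1L]],
         ": fewer than 9 tab-separated fields")
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  sel <- mat[, 3L] == feature_type
  if (!any(sel)) stop("no '", feature_type, "' features found")
  mat <- mat[sel, , drop = FALSE]
  attrs <- mat[, 9L]
  get_attr <- function(key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(paste0(key, "="), attrs)
    vals <- sub(paste0(".*", key, "="), "", m)
    out[hit] <- vals
    out
  }
  ids <- get_attr("ID")
  for (fb in c("Name", "gene_id")) {
    if (!anyNA(ids)) break
    alt <- get_attr(fb)
    ids[is.na(ids)] <- alt[is.na(ids)]
  }
  if (anyNA(ids)) stop("features without ID/Name/gene_id attribute")
  start <- suppressWarnings(as.integer(mat[, 4L]))
  end <- suppressWarnings(as.integer(mat[, 5L]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in GFF3")
  gene_catalog(data.frame(
    gene_id = ids, chromosome = mat[, 1L], start = start, end = end,
    strand = mat[, 7L], stringsAsFactors = FALSE))
}

#' Read CDS sequences from FASTA
#'
#' Reads a FASTA of in-frame coding sequences and reports (but keeps)
#' records whose length is not a multiple of 3 or that contain an internal
#' stop codon.
#'
#' @param path FASTA path.
#' @return named character vector of uppercased sequences with attributes
#'   `frame_invalid` and `internal_stop` (character vectors of flagged
#'   ids).
#' @export
read_cds_sequences <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids

  frame_invalid <- ids[nchar(seqs) %% 3L != 0L]
  has_internal_stop <- function(s) {
    if (nchar(s) %% 3L != 0L) return(FALSE)
    cod <- .split_codons(s)
    if (length(cod) > 1L) cod <- cod[-length(cod)]  # terminal stop allowed
    any(cod %in% c("TAA", "TAG", "TGA"))
  }
  internal_stop <- ids[vapply(seqs, has_internal_stop, logical(1))]
  if (length(frame_invalid) || length(internal_stop))
    message(length(frame_invalid), " sequence(s) with frame-invalid length, ",
            length(internal_stop), " with internal stop codons (kept, flagged)")
  attr(seqs, "frame_invalid") <- frame_invalid
  attr(seqs, "internal_stop") <- internal_stop
  seqs
}

#' Read homolog pairs from 12-column tabular similarity output
#'
#' Reads the standard 12-column tab-separated similarity format (query,
#' subject, identity, length, mismatches, gapopens, qstart, qend, sstart,
#' send, evalue, bitscore), removes self-hits, applies e-value/bitscore
#' thresholds, and collapses reciprocal rows to one canonical pair
#' (lexicographic gene order) keeping the best bitscore.
#'
#' @param path path to the tabular file.
#' @param max_evalue keep rows with evalue <= this (default 1e-10).
#' @param min_bitscore keep rows with bitscore >= this (default 0).
#' @return data frame `gene_a`, `gene_b`, `bitscore`, `evalue` with
#'   `gene_a < gene_b`; attribute `n_dropped` counts rows removed by the
#'   thresholds.
#' @export
read_homolog_pairs <- function(path, max_evalue = 1e-10, min_bitscore = 0) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(raw) < 12L) stop("expected 12 tab-separated columns, got ", ncol(raw))
  evalue <- suppressWarnings(as.numeric(raw[[11L]]))
  bitscore <- suppressWarnings(as.numeric(raw[[12L]]))
  bad <- which(is.na(evalue) | is.na(bitscore))
  if (length(bad))
    stop("non-numeric evalue/bitscore at line ", bad[1L])
  q <- raw[[1L]]; s <- raw[[2L]]
  self <- q == s
  pass <- !self & evalue <= max_evalue & bitscore >= min_bitscore
  n_dropped <- sum(!pass & !self)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped by evalue/bitscore thresholds")
  q <- q[pass]; s <- s[pass]; evalue <- evalue[pass]; bitscore <- bitscore[pass]
  a <- pmin(q, s); b <- pmax(q, s)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -bitscore, evalue)
  first <- !duplicated(key[ord])
  out <- data.frame(gene_a = a[ord][first], gene_b = b[ord][first],
                    bitscore = bitscore[ord][first],
                    evalue = evalue[ord][first], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

#' Write the pipeline's result tables
#'
#' Writes whichever result objects are supplied as deterministic TSV files
#' with fixed column orders: `gene_modes.tsv` (gene_id, mode, epoch,
#' is_pathway), `pair_modes.tsv`, `ks_pairs.tsv`, `blocks.tsv`,
#' `enrichment.tsv`, `profile.tsv`. Re-running on identical inputs yields
#' byte-identical files.
#'
#' @param results named list; recognised names: `gene_modes`,
#'   `pair_modes`, `ks_pairs`, `blocks`, `enrichment`, `profile`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_results_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  written <- character(0)
  emit <- function(df, cols, name) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df <- df[, cols, drop = FALSE]
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$gene_modes))
    emit(results$gene_modes, c("gene_id", "mode", "epoch", "is_pathway"),
         "gene_modes.tsv")
  if (!is.null(results$pair_modes))
    emit(results$pair_modes, c("gene_a", "gene_b", "mode"), "pair_modes.tsv")
  if (!is.null(results$ks_pairs))
    emit(results$ks_pairs,
         c("gene_a", "gene_b", "ka", "ks", "s_sites", "n_sites",
           "saturated", "mode", "epoch"), "ks_pairs.tsv")
  if (!is.null(results$blocks))
    emit(as.data.frame(results$blocks),
         c("block_id", "chrom_a", "chrom_b", "orientation", "n_anchors",
           "anchors"), "blocks.tsv")
  if (!is.null(results$enrichment))
    emit(results$enrichment,
         c("pathway_wgd", "pathway_total", "genome_wgd", "genome_total",
           "pathway_prop", "genome_prop", "chi2", "p_value"),
         "enrichment.tsv")
  if (!is.null(results$profile))
    emit(as.data.frame(results$profile),
         c("offset", "retained", "total", "ratio"), "profile.tsv")
  invisible(written)
}

#' Write a gene catalog as GFF3 (simulator output helper)
#' @param catalog a `gene_catalog`.
#' @param path output path.
#' @keywords internal
#' @export
write_gff3 <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tpaleodup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     catalog$chromosome, catalog$start, catalog$end,
                     catalog$strand, catalog$gene_id), con)
  invisible(path)
}
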