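# End-to-end orchestration: collinearity -> mode classification -> Ka/Ks
# -> Ks mixture / epochs -> enrichment -> retention profile, with
# deterministic seeding and a run manifest.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters with their documented
#' defaults. Unknown keys are rejected.
#'
#' @param gff3,cds,pairs,pathway required input paths (gene models, CDS
#'   FASTA, 12-column homolog table, pathway id list).
#' @param out_dir output directory.
#' @param outgroup_gff3,outgroup_pairs optional outgroup gene models and
#'   genome-vs-outgroup homolog table (enables transposed-duplication
#'   calls).
#' @param gene_terms optional two-column TSV (gene_id, term_id) enabling
#'   term over-representation of the WGD gene set.
#' @param feature_type GFF3 feature to read, default "gene".
#' @param max_evalue,min_bitscore homolog filtering thresholds.
#' @param max_gap,min_anchors collinearity chaining parameters.
#' @param proximal_max proximal-duplication rank bound.
#' @param ks_min,ks_max,k_max Ks mixture window and maximum components.
#' @param window retention-profile half-width (genes).
#' @param n_perm permutations for the profile null.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gff3, cds, pairs, pathway, out_dir,
                            outgroup_gff3 = NULL, outgroup_pairs = NULL,
                            gene_terms = NULL, feature_type = "gene",
                            max_evalue = 1e-10, min_bitscore = 0,
                            max_gap = 25L, min_anchors = 5L,
                            proximal_max = 10L,
                            ks_min = 0.005, ks_max = 5.0, k_max = 4L,
                            window = 20L, n_perm = 999L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Keys must be valid [pipeline_config()] arguments;
#' unknown keys are an error. Numeric-looking values are converted.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: syntenic block detection (intra-genomic, and
#' genome-vs-outgroup when an outgroup is configured), duplication-mode
#' classification (pair and gene level), NG86 Ka/Ks on all classified
#' pairs, Ks mixture fitting on the unsaturated WGD pairs, epoch
#' assignment, pathway WGD-retention enrichment, duplication-mode
#' composition of the pathway, term over-representation (when a gene-term
#' table is configured), the retention profile and its permutation test.
#' All result tables, `mixture.json`, `permutation.json` and a run
#' manifest are written to `config$out_dir`; outputs are byte-identical
#' across reruns with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all intermediate objects (`catalog`,
#'   `blocks`, `pair_modes`, `gene_modes`, `ks_pairs`, `mixture`,
#'   `epochs`, `enrichment`, `composition`, `profile`, `permutation`,
#'   `ora`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (key in c("gff3", "cds", "pairs", "pathway",
                "outgroup_gff3", "outgroup_pairs", "gene_terms")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("input file for '", key, "' not found: ", p)
  }
  seed <- as.integer(config$seed)

  catalog <- .stage("read_gene_models",
                    read_gene_models(config$gff3, config$feature_type))
  cds <- .stage("read_cds_sequences", read_cds_sequences(config$cds))
  pairs <- .stage("read_homolog_pairs",
                  read_homolog_pairs(config$pairs, config$max_evalue,
                                     config$min_bitscore))
  pathway_ids <- .stage("read_pathway",
                        readLines(config$pathway, warn = FALSE))
  pathway_ids <- trimws(pathway_ids)
  pathway_ids <- pathway_ids[nzchar(pathway_ids)]

  blocks <- .stage("detect_syntenic_blocks",
                   detect_syntenic_blocks(catalog, NULL, pairs,
                                          max_gap = config$max_gap,
                                          min_anchors = config$min_anchors))

  outgroup_anchors <- NULL
  if (!is.null(config$outgroup_gff3) && !is.null(config$outgroup_pairs)) {
    out_catalog <- .stage("read_outgroup",
                          read_gene_models(config$outgroup_gff3,
                                           config$feature_type))
    out_pairs <- .stage("read_outgroup_pairs",
                        read_homolog_pairs(config$outgroup_pairs,
                                           config$max_evalue,
                                           config$min_bitscore))
    # orient pairs as (outgroup, genome)
    flip <- out_pairs$gene_a %in% catalog$gene_id
    out_pairs[flip, c("gene_a", "gene_b")] <-
      out_pairs[flip, c("gene_b", "gene_a")]
    out_blocks <- .stage("outgroup_synteny",
                         detect_syntenic_blocks(out_catalog, catalog,
                                                out_pairs,
                                                max_gap = config$max_gap,
                                                min_anchors = config$min_anchors))
    outgroup_anchors <- unique(unlist(lapply(out_blocks$blocks, function(b)
      b$anchors$gene_b)))
  }

  pair_modes <- .stage("classify_pair_modes",
                       classify_pair_modes(pairs, blocks, catalog,
                                           outgroup_anchors,
                                           config$proximal_max))
  gene_modes <- .stage("assign_gene_modes",
                       assign_gene_modes(pair_modes, catalog))

  ks_pairs <- .stage("ng86_ka_ks", ks_for_pairs(pair_modes, cds))
  ks_pairs$mode <- pair_modes$mode

  wgd_est <- ks_pairs[ks_pairs$mode == "WGD", , drop = FALSE]
  mixture <- .stage("fit_ks_mixture",
                    fit_ks_mixture(wgd_est$ks[!is.na(wgd_est$saturated) &
                                                !wgd_est$saturated],
                                   k_max = config$k_max, seed = seed + 101L,
                                   ks_min = config$ks_min,
                                   ks_max = config$ks_max))
  epochs <- .stage("assign_wgd_epochs", assign_wgd_epochs(mixture, wgd_est))
  ks_pairs$epoch <- NA_integer_
  ks_pairs$epoch[ks_pairs$mode == "WGD"] <- epochs$pairs$epoch
  ge <- match(gene_modes$gene_id, epochs$genes$gene_id)
  gene_modes$epoch <- ifelse(gene_modes$mode == "WGD" & !is.na(ge),
                             epochs$genes$epoch[ge], NA_integer_)
  gene_modes$is_pathway <- gene_modes$gene_id %in% pathway_ids

  enr <- .stage("wgd_pathway_enrichment",
                wgd_pathway_enrichment(gene_modes, pathway_ids))
  comp <- .stage("duplication_mode_composition",
                 duplication_mode_composition(gene_modes, pathway_ids,
                                              label = "pathway"))
  ora <- NULL
  if (!is.null(config$gene_terms)) {
    gt <- utils::read.table(config$gene_terms, sep = "\t", header = FALSE,
                            col.names = c("gene_id", "term_id"),
                            stringsAsFactors = FALSE)
    ora <- .stage("term_overrepresentation",
                  term_overrepresentation(
                    gt, gene_modes$gene_id[gene_modes$mode == "WGD"],
                    gene_modes$gene_id))
  }

  profile <- .stage("compute_retention_profile",
                    compute_retention_profile(catalog, gene_modes,
                                              pathway_ids, config$window))
  perm <- .stage("profile_permutation_test",
                 profile_permutation_test(catalog, gene_modes, pathway_ids,
                                          config$window, config$n_perm,
                                          seed = seed + 202L))

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_results_tables(list(gene_modes = gene_modes, pair_modes = pair_modes,
                            ks_pairs = ks_pairs, blocks = blocks,
                            enrichment = as.data.frame(enr),
                            profile = profile), out_dir)
  .write_tsv(comp, file.path(out_dir, "composition.tsv"))
  if (!is.null(ora)) .write_tsv(ora, file.path(out_dir, "ora.tsv"))
  jsonlite::write_json(
    list(n_components = mixture$n_components, weight = mixture$weight,
         mean_log10_ks = mixture$mean, sd_log10_ks = mixture$sd,
         ks_peaks = 10^mixture$mean, bic = mixture$bic,
         bic_table = mixture$bic_table, n = mixture$n),
    file.path(out_dir, "mixture.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(observed = perm$observed, null_mean = perm$null_mean,
         null_sd = perm$null_sd, p_value = perm$p_value,
         n_perm = perm$n_perm),
    file.path(out_dir, "permutation.json"), auto_unbox = TRUE, digits = NA)

  mode_counts <- table(factor(gene_modes$mode, levels = .MODES))
  manifest <- list(
    package_version = as.character(utils::packageVersion("paleodup")),
    seed = seed,
    config = lapply(unclass(config), function(x) if (is.null(x)) NA else x),
    counts = list(genes = nrow(catalog), homolog_pairs = nrow(pairs),
                  blocks = length(blocks$blocks),
                  anchor_pairs = length(blocks$anchor_pairs),
                  outgroup_anchors = length(outgroup_anchors),
                  pathway_genes = sum(gene_modes$is_pathway),
                  mode_counts = as.list(mode_counts),
                  ks_estimates = sum(!is.na(ks_pairs$ks)),
                  mixture_components = mixture$n_components))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(catalog = catalog, blocks = blocks,
                 outgroup_anchors = outgroup_anchors,
                 pair_modes = pair_modes, gene_modes = gene_modes,
                 ks_pairs = ks_pairs, mixture = mixture, epochs = epochs,
                 enrichment = enr, composition = comp, ora = ora,
                 profile = profile, permutation = perm,
                 manifest = manifest))
}
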