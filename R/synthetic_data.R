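# Genome-evolution simulator with known truth: an ancestral diploid genome
# experiences nested whole-genome duplications (oldest first) with biased
# duplicate retention in a designated pathway, followed by tandem /
# proximal / transposed / dispersed duplications. Sequences diverge by
# synonymous and nonsynonymous substitutions tuned to target Ks, so the
# Ks-based stages of the pipeline can be validated against the simulated
# history. A frozen pre-WGD ancestor is emitted as the outgroup that
# anchors transposed-duplication calls.

#' Simulation parameters
#'
#' Constructs and validates the parameter set for [simulate_genome()].
#' Defaults describe a desk-scale genome with two nested WGDs whose
#' present-day Ks peaks sit at 0.6 (older) and 0.2 (younger), background
#' duplicate retention 0.3 and pathway retention 0.7 at each event.
#'
#' @param n_chromosomes number of ancestral chromosomes (default 5).
#' @param genes_per_chromosome genes per ancestral chromosome (default
#'   400).
#' @param cds_codons mean CDS length in codons (default 300; per-gene
#'   lengths are Poisson-distributed with a floor of 60).
#' @param wgd_events list of WGD events, oldest first; each a list with
#'   `ks` (target present-day Ks of pairs separated at the event; must be
#'   strictly decreasing across events), `log10_sd` (between-gene rate
#'   heterogeneity, sd of log10 Ks), `retention_bg` and
#'   `retention_pathway` (per-copy survival probabilities).
#' @param pathway_size number of ancestral genes designated as the focal
#'   pathway (default 120).
#' @param rate_td,rate_pd,rate_trd,rate_dsd small-scale duplication rates
#'   (events per present gene after the WGDs).
#' @param proximal_max rank distance bound used when placing proximal
#'   copies (default 10, matching the classifier default).
#' @param omega Ka/Ks ratio of the divergence process (default 0.2).
#' @param seed master seed (default 1).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 5L, genes_per_chromosome = 400L,
                       cds_codons = 300L,
                       wgd_events = list(
                         list(ks = 0.6, log10_sd = 0.08,
                              retention_bg = 0.3, retention_pathway = 0.7),
                         list(ks = 0.2, log10_sd = 0.08,
                              retention_bg = 0.3, retention_pathway = 0.7)),
                       pathway_size = 120L,
                       rate_td = 0.04, rate_pd = 0.03,
                       rate_trd = 0.03, rate_dsd = 0.04,
                       proximal_max = 10L, omega = 0.2, seed = 1L) {
  if (n_chromosomes < 1L || genes_per_chromosome < 1L || cds_codons < 10L)
    stop("non-positive genome sizes")
  kss <- vapply(wgd_events, `[[`, numeric(1), "ks")
  if (any(kss <= 0) || anyDuplicated(kss))
    stop("WGD target Ks values must be positive and distinct")
  if (length(kss) > 1L && any(diff(kss) >= 0))
    stop("wgd_events must be ordered oldest first (decreasing Ks)")
  probs <- unlist(lapply(wgd_events, function(e)
    c(e$retention_bg, e$retention_pathway)))
  if (any(probs < 0 | probs > 1)) stop("retention probabilities must be in [0,1]")
  if (pathway_size > n_chromosomes * genes_per_chromosome)
    stop("pathway_size exceeds the gene count")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 cds_codons = as.integer(cds_codons),
                 wgd_events = wgd_events,
                 pathway_size = as.integer(pathway_size),
                 rate_td = rate_td, rate_pd = rate_pd,
                 rate_trd = rate_trd, rate_dsd = rate_dsd,
                 proximal_max = as.integer(proximal_max),
                 omega = omega, seed = as.integer(seed)),
            class = "sim_params")
}

# -- codon-level machinery ---------------------------------------------------

# per-codon single-nucleotide substitution options (synonymous and
# nonsynonymous, stop codons never produced), cached alongside the NG86
# tables
.sim_tables <- function() {
  tb <- .ng86_tables()
  if (!is.null(.ng86$syn_opts)) return(tb)
  nuc <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(tb$codons, ""))
  syn_opts <- vector("list", 64); nonsyn_opts <- vector("list", 64)
  for (i in seq_len(64)) {
    so <- integer(0); no <- integer(0)
    if (tb$aa[i] != "*") {
      for (pos in 1:3) for (b in nuc) {
        if (b == cmat[i, pos]) next
        mut <- cmat[i, ]; mut[pos] <- b
        j <- match(paste(mut, collapse = ""), tb$codons)
        if (tb$aa[j] == "*") next
        if (tb$aa[j] == tb$aa[i]) so <- c(so, j) else no <- c(no, j)
      }
    }
    syn_opts[[i]] <- so; nonsyn_opts[[i]] <- no
  }
  .ng86$syn_opts <- syn_opts
  .ng86$nonsyn_opts <- nonsyn_opts
  .ng86$n_syn_opts <- lengths(syn_opts)
  .ng86$n_nonsyn_opts <- lengths(nonsyn_opts)
  .ng86$sense <- which(tb$aa != "*")
  .ng86$non_atg_sense <- which(tb$aa != "*" & tb$codons != "ATG")
  .ng86$stop_idx <- which(tb$aa == "*")
  tb
}

.codon_index <- function(seq) {
  tb <- .ng86_tables()
  match(.split_codons(seq), tb$codons)
}

.codon_string <- function(ci) paste(.ng86_tables()$codons[ci], collapse = "")

# apply n_syn synonymous and n_nonsyn nonsynonymous substitutions to a
# codon-index vector, each hitting a uniformly random remaining opportunity
.mutate_codons <- function(ci, n_syn, n_nonsyn) {
  tb <- .sim_tables()
  w_s <- .ng86$n_syn_opts[ci]
  w_n <- .ng86$n_nonsyn_opts[ci]
  types <- sample(c(rep(TRUE, n_syn), rep(FALSE, n_nonsyn)))
  for (syn in types) {
    w <- if (syn) w_s else w_n
    tot <- sum(w)
    if (tot == 0) next
    j <- sample.int(length(ci), 1L, prob = w)
    opts <- if (syn) .ng86$syn_opts[[ci[j]]] else .ng86$nonsyn_opts[[ci[j]]]
    ci[j] <- opts[sample.int(length(opts), 1L)]
    w_s[j] <- .ng86$n_syn_opts[ci[j]]
    w_n[j] <- .ng86$n_nonsyn_opts[ci[j]]
  }
  ci
}

# expected syn / nonsyn substitution counts for a branch of ks units
.branch_counts <- function(ci, ks_branch, omega) {
  tb <- .sim_tables()
  sense <- !is.na(tb$syn_sites[ci])
  S <- sum(tb$syn_sites[ci][sense])
  N <- 3 * sum(sense) - S
  c(stats::rpois(1L, ks_branch * S), stats::rpois(1L, omega * ks_branch * N))
}

.evolve_branch <- function(ci, ks_branch, omega) {
  cnt <- .branch_counts(ci, ks_branch, omega)
  .mutate_codons(ci, cnt[1L], cnt[2L])
}

#' Diverge a duplicate pair of sequences to a target Ks
#'
#' Creates two copies of a CDS and applies synonymous and nonsynonymous
#' substitutions (Poisson-distributed counts, split evenly between the two
#' copies) so that the expected NG86 Ks of the pair is about `target_ks`
#' and the expected Ka about `omega * target_ks`. Substitutions hit a
#' uniformly random remaining synonymous (resp. nonsynonymous,
#' stop-avoiding) single-nucleotide opportunity; stop codons are never
#' introduced.
#'
#' @param cds in-frame coding sequence (character).
#' @param target_ks target synonymous divergence of the pair (>= 0; a
#'   warning is issued beyond the saturation regime `target_ks > 3`).
#' @param omega Ka/Ks ratio, default 0.2.
#' @param seed optional integer seed.
#' @return list with diverged copies `a` and `b` (character strings).
#' @export
evolve_duplicate_sequences <- function(cds, target_ks, omega = 0.2,
                                       seed = NULL) {
  if (target_ks < 0) stop("target_ks must be >= 0")
  if (target_ks > 3) warning("target_ks > 3 is beyond Ks saturation; ",
                             "estimates will be unreliable")
  if (!is.null(seed)) set.seed(seed)
  ci <- .codon_index(toupper(as.character(cds)))
  if (anyNA(ci)) stop("CDS contains non-ACGT characters or partial codons")
  list(a = .codon_string(.evolve_branch(ci, target_ks / 2, omega)),
       b = .codon_string(.evolve_branch(ci, target_ks / 2, omega)))
}

# -- ancestral genome --------------------------------------------------------

#' Simulate an ancestral genome
#'
#' Lays out genes with non-overlapping coordinates and contiguous ranks on
#' each chromosome, and draws random in-frame CDS (ATG start, single
#' terminal stop, no internal stops).
#'
#' @param params a [sim_params()] object.
#' @return list with `catalog` (a [gene_catalog()]) and `cds` (named
#'   character vector).
#' @export
simulate_ancestral_genome <- function(params = sim_params()) {
  set.seed(params$seed)
  tb <- .sim_tables()
  n_chr <- params$n_chromosomes; n_g <- params$genes_per_chromosome
  ids <- character(0); chroms <- character(0)
  cds <- list()
  for (c_i in seq_len(n_chr)) {
    chrom <- paste0("chr", c_i)
    gid <- sprintf("g%d.%04d", c_i, seq_len(n_g))
    len <- pmax(60L, stats::rpois(n_g, params$cds_codons))
    for (k in seq_len(n_g)) {
      body <- sample(.ng86$non_atg_sense, len[k] - 2L, replace = TRUE)
      ci <- c(match("ATG", tb$codons), body,
              .ng86$stop_idx[sample.int(3L, 1L)])
      cds[[gid[k]]] <- .codon_string(ci)
    }
    ids <- c(ids, gid); chroms <- c(chroms, rep(chrom, n_g))
  }
  starts <- unlist(lapply(split(ids, chroms)[unique(chroms)], function(g)
    (seq_along(g) - 1L) * 3000L + 1L), use.names = FALSE)
  lens <- nchar(unlist(cds[ids]))
  catalog <- gene_catalog(data.frame(
    gene_id = ids, chromosome = chroms,
    start = starts, end = starts + lens - 1L,
    strand = sample(c("+", "-"), length(ids), replace = TRUE),
    stringsAsFactors = FALSE))
  list(catalog = catalog, cds = unlist(cds[catalog$gene_id]))
}

# -- duplication history -----------------------------------------------------

.random_slot <- function(chrom_order, avoid_chrom = NULL, avoid_pos = NULL,
                         min_dist = 0L) {
  repeat {
    chrom <- sample(names(chrom_order), 1L)
    pos <- sample.int(length(chrom_order[[chrom]]) + 1L, 1L) - 1L
    if (is.null(avoid_chrom) || chrom != avoid_chrom ||
        abs(pos - avoid_pos) > min_dist) return(list(chrom = chrom, pos = pos))
  }
}

#' Apply a duplication history to an ancestral genome
#'
#' Runs the simulated history: pathway genes are sampled uniformly; for
#' each WGD event (oldest first) every gene on every chromosome is
#' duplicated onto a new homeologous chromosome preserving order, and each
#' new copy survives with the pathway or background retention probability;
#' between events all lineages accumulate sequence divergence so that
#' pairs separated at an event reach that event's target Ks today. After
#' the WGDs, tandem copies are inserted rank-adjacent to their parent,
#' proximal copies within `proximal_max` ranks, transposed copies at
#' random loci with the parent kept at its (ancestral) locus, and
#' dispersed copies at random loci with the parent relocated as well (so
#' dispersed pairs show no positional conservation on either side). A
#' frozen copy of the pre-WGD ancestor is returned as the outgroup.
#'
#' @param genome result of [simulate_ancestral_genome()].
#' @param params the same [sim_params()].
#' @return An object of class `synthetic_genome`; see
#'   [simulate_genome()].
#' @export
apply_duplication_history <- function(genome, params = sim_params()) {
  set.seed(params$seed + 1L)
  tb <- .sim_tables()
  anc <- genome$catalog
  E <- length(params$wgd_events)

  # state
  chrom_order <- lapply(split(anc$gene_id, anc$chromosome)[
    unique(anc$chromosome)], identity)
  seqs <- lapply(genome$cds, .codon_index)
  root <- stats::setNames(anc$gene_id, anc$gene_id)
  rate <- stats::setNames(
    10^stats::rnorm(nrow(anc), 0, params$wgd_events[[1L]]$log10_sd),
    anc$gene_id)
  pathway_roots <- sample(anc$gene_id, params$pathway_size)
  records <- list()   # child, parent, type, event, order
  rec_n <- 0L
  add_record <- function(child, parent, type, event) {
    rec_n <<- rec_n + 1L
    records[[rec_n]] <<- data.frame(child = child, parent = parent,
                                    type = type, event = event,
                                    order = rec_n, stringsAsFactors = FALSE)
  }

  kss <- vapply(params$wgd_events, `[[`, numeric(1), "ks")
  max_genes <- 10L * nrow(anc)
  growth <- prod(1 + vapply(params$wgd_events, function(e)
    max(e$retention_bg, e$retention_pathway), numeric(1))) *
    (1 + params$rate_td + params$rate_pd + params$rate_trd + params$rate_dsd)
  if (growth * nrow(anc) > max_genes)
    stop("simulation parameters imply more than 10x genome growth")

  for (e in seq_len(E)) {
    ev <- params$wgd_events[[e]]
    for (chrom in names(chrom_order)) {
      genes <- chrom_order[[chrom]]
      if (!length(genes)) next
      p <- ifelse(root[genes] %in% pathway_roots,
                  ev$retention_pathway, ev$retention_bg)
      keep <- stats::runif(length(genes)) < p
      if (!any(keep)) next
      parents <- genes[keep]
      copies <- paste0(parents, "_w", e)
      new_chrom <- paste0(chrom, "w", e)
      chrom_order[[new_chrom]] <- copies
      for (k in seq_along(parents)) {
        seqs[[copies[k]]] <- seqs[[parents[k]]]
        root[copies[k]] <- root[parents[k]]
        rate[copies[k]] <- rate[parents[k]]
        add_record(copies[k], parents[k], "WGD", e)
      }
    }
    # divergence accumulated between this event and the next (or present)
    delta <- (kss[e] - if (e < E) kss[e + 1L] else 0) / 2
    for (g in names(seqs))
      seqs[[g]] <- .evolve_branch(seqs[[g]], delta * rate[[g]],
                                  params$omega)
  }

  # small-scale duplications (present-day, divergence on the copy branch)
  all_genes <- function() unlist(chrom_order, use.names = FALSE)
  n_now <- length(all_genes())
  rec_types <- if (rec_n)
    stats::setNames(vapply(records, `[[`, character(1), "type"),
                    vapply(records, `[[`, character(1), "child"))
  else character(0)
  ancestral_locus <- function(g)
    !(g %in% names(rec_types)) | unname(rec_types[g]) %in% "WGD"

  insert_gene <- function(chrom, pos, id) {
    chrom_order[[chrom]] <<- append(chrom_order[[chrom]], id, after = pos)
  }
  locate <- function(id) {
    for (chrom in names(chrom_order)) {
      p <- match(id, chrom_order[[chrom]])
      if (!is.na(p)) return(list(chrom = chrom, pos = p))
    }
    stop("gene not found: ", id)
  }
  new_small_copy <- function(parent, suffix, type, event_ks) {
    child <- paste0(parent, "_", suffix)
    seqs[[child]] <<- .evolve_branch(seqs[[parent]], event_ks, params$omega)
    root[child] <<- root[parent]
    rate[child] <<- rate[parent]
    add_record(child, parent, type, NA_integer_)
    child
  }

  # small-scale events postdate the WGDs, so their divergence must be
  # younger than the youngest WGD peak
  ss_ks_max <- 0.9 * min(kss)
  counts <- c(td = round(params$rate_td * n_now),
              pd = round(params$rate_pd * n_now),
              trd = round(params$rate_trd * n_now),
              dsd = round(params$rate_dsd * n_now))
  pool <- all_genes()
  for (i in seq_len(counts[["td"]])) {
    parent <- sample(pool, 1L)
    loc <- locate(parent)
    child <- new_small_copy(parent, paste0("td", i), "TD",
                            stats::runif(1, 0.01, ss_ks_max))
    insert_gene(loc$chrom, loc$pos, child)
  }
  pool <- all_genes()
  for (i in seq_len(counts[["pd"]])) {
    parent <- sample(pool, 1L)
    loc <- locate(parent)
    off <- sample(2:max(2L, params$proximal_max - 2L), 1L)
    child <- new_small_copy(parent, paste0("pd", i), "PD",
                            stats::runif(1, 0.01, ss_ks_max))
    insert_gene(loc$chrom, min(loc$pos + off - 1L,
                               length(chrom_order[[loc$chrom]])), child)
  }
  anc_pool <- all_genes()
  anc_pool <- anc_pool[ancestral_locus(anc_pool)]
  for (i in seq_len(counts[["trd"]])) {
    parent <- sample(anc_pool, 1L)
    loc <- locate(parent)
    slot <- .random_slot(chrom_order, loc$chrom, loc$pos,
                         params$proximal_max + 5L)
    child <- new_small_copy(parent, paste0("trd", i), "TRD",
                            stats::runif(1, 0.01, ss_ks_max))
    insert_gene(slot$chrom, slot$pos, child)
  }
  # dispersed duplications are modelled on single-copy families: both the
  # copy and its parent move to random loci, so the pair has no positional
  # conservation on either side and no ancestral-locus relative that would
  # make it look transposed
  pool <- all_genes()
  fam_size <- table(root[pool])
  pool <- pool[fam_size[root[pool]] == 1L]
  for (i in seq_len(counts[["dsd"]])) {
    if (!length(pool)) break
    parent <- sample(pool, 1L)
    pool <- setdiff(pool, parent)
    child <- new_small_copy(parent, paste0("dsd", i), "DSD",
                            stats::runif(1, 0.01, ss_ks_max))
    # copy at a random locus; the parent is relocated too, so neither gene
    # of a dispersed pair retains positional conservation
    loc <- locate(parent)
    chrom_order[[loc$chrom]] <- chrom_order[[loc$chrom]][-loc$pos]
    slot_c <- .random_slot(chrom_order)
    insert_gene(slot_c$chrom, slot_c$pos, child)
    slot_p <- .random_slot(chrom_order, slot_c$chrom, slot_c$pos + 1L,
                           params$proximal_max + 5L)
    insert_gene(slot_p$chrom, slot_p$pos, parent)
  }

  # ---- final catalog -------------------------------------------------------
  chroms_final <- sort(names(chrom_order))
  ids <- unlist(chrom_order[chroms_final], use.names = FALSE)
  chrom_col <- rep(chroms_final, vapply(chrom_order[chroms_final], length,
                                        integer(1)))
  cds_str <- vapply(seqs[ids], .codon_string, character(1))
  lens <- nchar(cds_str)
  starts <- unlist(lapply(chrom_order[chroms_final], function(g)
    (seq_along(g) - 1L) * 3000L + 1L), use.names = FALSE)
  catalog <- gene_catalog(data.frame(
    gene_id = ids, chromosome = chrom_col,
    start = starts, end = starts + lens - 1L,
    strand = sample(c("+", "-"), length(ids), replace = TRUE),
    stringsAsFactors = FALSE))
  cds_str <- cds_str[catalog$gene_id]

  rec_df <- if (rec_n) do.call(rbind, records)
    else data.frame(child = character(0), parent = character(0),
                    type = character(0), event = integer(0),
                    order = integer(0), stringsAsFactors = FALSE)

  # ---- per-gene truth ------------------------------------------------------
  present <- catalog$gene_id
  created_type <- stats::setNames(rec_df$type, rec_df$child)
  created_event <- stats::setNames(rec_df$event, rec_df$child)
  child_types <- split(rec_df$type, rec_df$parent)
  child_events <- split(rec_df$event, rec_df$parent)
  true_mode <- character(length(present))
  true_epoch <- rep(NA_integer_, length(present))
  for (i in seq_along(present)) {
    g <- present[i]
    types <- c(if (g %in% names(created_type)) created_type[[g]],
               child_types[[g]])
    if (is.null(types) || !length(types)) { true_mode[i] <- "singleton"; next }
    true_mode[i] <- .MODES[min(match(types, .MODES))]
    if (true_mode[i] == "WGD") {
      ct <- if (g %in% names(created_type)) created_type[[g]] else NA_character_
      evs <- c(if (identical(ct, "WGD")) created_event[[g]],
               child_events[[g]][child_types[[g]] == "WGD"])
      true_epoch[i] <- E - max(evs, na.rm = TRUE) + 1L
    }
  }
  truth <- data.frame(gene_id = present,
                      root = unname(root[present]),
                      parent = ifelse(present %in% rec_df$child,
                                      rec_df$parent[match(present,
                                                          rec_df$child)],
                                      NA_character_),
                      true_mode = true_mode, true_epoch = true_epoch,
                      is_pathway = unname(root[present]) %in% pathway_roots,
                      stringsAsFactors = FALSE)

  # ---- homolog pairs from parentage ---------------------------------------
  mismatch_frac <- function(a, b)
    sum(charToRaw(a) != charToRaw(b)) / nchar(a)
  fam <- split(present, root[present])
  fam <- fam[lengths(fam) >= 2L]
  pair_rows <- vector("list", length(fam))
  for (f in seq_along(fam)) {
    g <- sort(fam[[f]])
    cmb <- utils::combn(g, 2L)
    pair_rows[[f]] <- data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
                                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows)
    else data.frame(gene_a = character(0), gene_b = character(0))
  if (nrow(pairs)) {
    pm <- vapply(seq_len(nrow(pairs)), function(i)
      mismatch_frac(cds_str[[pairs$gene_a[i]]], cds_str[[pairs$gene_b[i]]]),
      numeric(1))
    L <- nchar(cds_str[pairs$gene_a])
    pairs$pident <- round(100 * (1 - pm), 2)
    pairs$length <- unname(L)
    pairs$mismatches <- round(pm * L)
    pairs$bitscore <- round(2 * L * (1 - pm))
    pairs$evalue <- 0
  }
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL

  # ---- frozen pre-WGD ancestor as outgroup --------------------------------
  outgroup_catalog <- gene_catalog(data.frame(
    gene_id = paste0("out_", anc$gene_id),
    chromosome = paste0("out_", anc$chromosome),
    start = anc$start, end = anc$end, strand = anc$strand,
    stringsAsFactors = FALSE))
  anc_cds <- genome$cds
  og <- data.frame(gene_a = paste0("out_", unname(root[present])),
                   gene_b = present, stringsAsFactors = FALSE)
  pm <- vapply(seq_len(nrow(og)), function(i)
    mismatch_frac(anc_cds[[unname(root[present])[i]]], cds_str[[og$gene_b[i]]]),
    numeric(1))
  L <- nchar(cds_str[og$gene_b])
  og$pident <- round(100 * (1 - pm), 2)
  og$length <- unname(L)
  og$mismatches <- round(pm * L)
  og$bitscore <- round(2 * L * (1 - pm))
  og$evalue <- 0
  og <- og[order(og$gene_a, og$gene_b), , drop = FALSE]
  rownames(og) <- NULL

  structure(list(catalog = catalog, cds = cds_str, pairs = pairs,
                 outgroup_catalog = outgroup_catalog, outgroup_pairs = og,
                 pathway_ids = present[truth$is_pathway],
                 truth = truth, records = rec_df, params = params),
            class = "synthetic_genome")
}

#' Simulate a genome with a known duplication history
#'
#' Convenience wrapper: [simulate_ancestral_genome()] followed by
#' [apply_duplication_history()].
#'
#' @param params a [sim_params()] object.
#' @return An object of class `synthetic_genome`: list with `catalog`,
#'   `cds` (named character vector), `pairs` (within-genome homolog pairs
#'   derived from true parentage, with pseudo-similarity columns),
#'   `outgroup_catalog` and `outgroup_pairs` (the frozen pre-WGD
#'   ancestor), `pathway_ids` (present-day pathway genes), `truth`
#'   (per-gene `true_mode`, `true_epoch`, `is_pathway`, `parent`,
#'   `root`), `records` (every duplication event) and `params`.
#' @export
simulate_genome <- function(params = sim_params()) {
  apply_duplication_history(simulate_ancestral_genome(params), params)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome: ", nrow(x$catalog), " genes on ",
      length(attr(x$catalog, "chromosomes")), " chromosomes (",
      length(x$params$wgd_events), " WGDs)\n", sep = "")
  cat("  true modes: ",
      paste(names(table(x$truth$true_mode)), table(x$truth$true_mode),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  pathway: ", length(x$pathway_ids), " genes; homolog pairs: ",
      nrow(x$pairs), "\n", sep = "")
  invisible(x)
}

#' True duplication mode and epoch of gene pairs
#'
#' Resolves, for each supplied pair, the duplication event at which the
#' two lineages separated (walking the recorded parentage chains back to
#' their last common gene) and reports that event's type and, for WGD
#' splits, its epoch (youngest event = epoch 1).
#'
#' @param sim a `synthetic_genome`.
#' @param pairs data frame `gene_a`, `gene_b`.
#' @return data frame `gene_a`, `gene_b`, `true_mode`, `true_epoch`.
#' @export
truth_pair_modes <- function(sim, pairs) {
  rec <- sim$records
  parent_of <- stats::setNames(rec$parent, rec$child)
  order_of <- stats::setNames(rec$order, rec$child)
  type_of <- stats::setNames(rec$type, rec$child)
  event_of <- stats::setNames(rec$event, rec$child)
  E <- length(sim$params$wgd_events)
  chain <- function(g) {
    ids <- g
    while (ids[1L] %in% names(parent_of))
      ids <- c(parent_of[[ids[1L]]], ids)
    ids
  }
  n <- nrow(pairs)
  mode <- character(n); epoch <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ca <- chain(pairs$gene_a[i]); cb <- chain(pairs$gene_b[i])
    if (ca[1L] != cb[1L]) { mode[i] <- NA_character_; next }
    k <- 1L
    while (k < length(ca) && k < length(cb) && ca[k + 1L] == cb[k + 1L])
      k <- k + 1L
    next_a <- if (length(ca) > k) ca[k + 1L] else NULL
    next_b <- if (length(cb) > k) cb[k + 1L] else NULL
    split_id <- if (is.null(next_a)) next_b
      else if (is.null(next_b)) next_a
      else if (order_of[[next_a]] < order_of[[next_b]]) next_a else next_b
    if (is.null(split_id)) { mode[i] <- NA_character_; next }
    mode[i] <- type_of[[split_id]]
    if (mode[i] == "WGD") epoch[i] <- E - event_of[[split_id]] + 1L
  }
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             true_mode = mode, true_epoch = epoch, stringsAsFactors = FALSE)
}

.write_similarity_tsv <- function(df, path) {
  rows <- sprintf("%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t1\t%d\t%s\t%d",
                  df$gene_a, df$gene_b, df$pident, df$length,
                  df$mismatches, df$length, df$length,
                  format(df$evalue, scientific = TRUE, trim = TRUE),
                  df$bitscore)
  writeLines(rows, path)
}

#' Write a synthetic genome to standard pipeline input files
#'
#' Emits `genome.gff3`, `cds.fasta`, `pairs.tsv` (12-column similarity
#' format), `outgroup.gff3`, `outgroup_pairs.tsv`, `pathway.txt` (one id
#' per line) and `truth.tsv`, all consumable by the genome_io readers.
#' Identical simulations produce byte-identical files.
#'
#' @param sim a `synthetic_genome`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gff3 = file.path(dir, "genome.gff3"),
             fasta = file.path(dir, "cds.fasta"),
             pairs = file.path(dir, "pairs.tsv"),
             outgroup_gff3 = file.path(dir, "outgroup.gff3"),
             outgroup_pairs = file.path(dir, "outgroup_pairs.tsv"),
             pathway = file.path(dir, "pathway.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_gff3(sim$catalog, paths[["gff3"]])
  writeLines(paste0(">", sim$catalog$gene_id, "\n",
                    sim$cds[sim$catalog$gene_id]), paths[["fasta"]])
  .write_similarity_tsv(sim$pairs, paths[["pairs"]])
  write_gff3(sim$outgroup_catalog, paths[["outgroup_gff3"]])
  .write_similarity_tsv(sim$outgroup_pairs, paths[["outgroup_pairs"]])
  writeLines(sort(sim$pathway_ids), paths[["pathway"]])
  .write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
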