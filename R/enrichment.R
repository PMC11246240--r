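# Statistical layer: pathway-vs-genome WGD-retention enrichment (Pearson
# chi-square), duplication-mode composition tables, generic term
# over-representation (hypergeometric + Benjamini-Hochberg), and
# cross-species group comparison (Student's pooled-variance t-test).

#' WGD-retention enrichment of a pathway against the genome
#'
#' Builds the 2x2 contingency table (pathway vs rest-of-genome) x
#' (WGD-derived vs not) from gene-level mode calls and applies the Pearson
#' chi-square test without continuity correction (df = 1). The reported
#' `genome_prop` is the WGD proportion over \emph{all} genes (pathway
#' included), the figure usually quoted as the genome background; the test
#' itself contrasts the pathway against the non-pathway remainder so the
#' two rows are disjoint.
#'
#' @param gene_modes data frame `gene_id`, `mode` (from
#'   [assign_gene_modes()]).
#' @param pathway_ids character vector of pathway gene ids; ids absent
#'   from `gene_modes` are dropped with a warning.
#' @return An object of class `wgd_enrichment` (also a one-row data
#'   frame): `pathway_wgd`, `pathway_total`, `genome_wgd`,
#'   `genome_total`, `pathway_prop`, `genome_prop`, `chi2`, `p_value`.
#' @export
wgd_pathway_enrichment <- function(gene_modes, pathway_ids) {
  pathway_ids <- unique(pathway_ids)
  known <- pathway_ids %in% gene_modes$gene_id
  if (any(!known))
    warning(sum(!known), " pathway id(s) not in the catalog, dropped: ",
            paste(utils::head(pathway_ids[!known], 5), collapse = ", "))
  pathway_ids <- pathway_ids[known]
  if (length(pathway_ids) == 0L)
    stop("no pathway genes left after id filtering")

  in_path <- gene_modes$gene_id %in% pathway_ids
  is_wgd <- gene_modes$mode == "WGD"
  tab <- rbind(pathway = c(wgd = sum(in_path & is_wgd),
                           other = sum(in_path & !is_wgd)),
               rest = c(wgd = sum(!in_path & is_wgd),
                        other = sum(!in_path & !is_wgd)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("degenerate 2x2 table (zero margin): chi-square test undefined")
  ct <- stats::chisq.test(tab, correct = FALSE)

  out <- data.frame(
    pathway_wgd = tab[1, 1], pathway_total = sum(tab[1, ]),
    genome_wgd = sum(is_wgd), genome_total = nrow(gene_modes),
    pathway_prop = tab[1, 1] / sum(tab[1, ]),
    genome_prop = sum(is_wgd) / nrow(gene_modes),
    chi2 = unname(ct$statistic), p_value = unname(ct$p.value))
  class(out) <- c("wgd_enrichment", "data.frame")
  out
}

#' @export
print.wgd_enrichment <- function(x, ...) {
  cat(sprintf(
    "WGD retention: pathway %d/%d (%.1f%%) vs genome %d/%d (%.1f%%)\n",
    x$pathway_wgd, x$pathway_total, 100 * x$pathway_prop,
    x$genome_wgd, x$genome_total, 100 * x$genome_prop))
  cat(sprintf("chi-square (df = 1, no continuity correction) = %.4f, P = %.4g\n",
              x$chi2, x$p_value))
  invisible(x)
}

#' Duplication-mode composition of a gene set
#'
#' Counts and proportions of a gene set over the six mode labels
#' (WGD, TD, PD, TRD, DSD, singleton); zero-count modes are included.
#'
#' @param gene_modes data frame `gene_id`, `mode`.
#' @param gene_set character vector of gene ids (unknown ids dropped with
#'   a warning).
#' @param label optional label for the set.
#' @return data frame `set`, `mode`, `count`, `proportion`.
#' @export
duplication_mode_composition <- function(gene_modes, gene_set,
                                         label = "set") {
  gene_set <- unique(gene_set)
  known <- gene_set %in% gene_modes$gene_id
  if (any(!known))
    warning(sum(!known), " gene id(s) not in the catalog, dropped")
  gene_set <- gene_set[known]
  if (length(gene_set) == 0L) stop("empty gene set")
  modes <- gene_modes$mode[match(gene_set, gene_modes$gene_id)]
  counts <- vapply(.MODES, function(m) sum(modes == m), integer(1))
  data.frame(set = label, mode = .MODES, count = counts,
             proportion = counts / length(gene_set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Term over-representation analysis (hypergeometric)
#'
#' For each annotation term, tests whether the target set overlaps the
#' term's genes more than expected by chance: upper-tail hypergeometric
#' probability of an overlap at least as large as observed, followed by
#' Benjamini-Hochberg adjustment across tested terms.
#'
#' @param gene_terms data frame `gene_id`, `term_id` (one row per
#'   association).
#' @param target_set character vector of target gene ids; must be a
#'   subset of `universe`.
#' @param universe character vector of background gene ids.
#' @param min_genes skip terms with fewer members in the universe,
#'   default 3.
#' @return data frame `term_id`, `term_size`, `overlap`, `expected`,
#'   `p_value`, `p_adjust`, sorted by `p_adjust` then `term_id`.
#' @export
term_overrepresentation <- function(gene_terms, target_set, universe,
                                    min_genes = 3L) {
  universe <- unique(universe)
  target_set <- unique(target_set)
  if (!all(target_set %in% universe))
    stop("target set is not a subset of the universe")
  gt <- gene_terms[gene_terms$gene_id %in% universe, , drop = FALSE]
  gt <- gt[!duplicated(paste(gt$gene_id, gt$term_id)), , drop = FALSE]
  term_genes <- split(gt$gene_id, gt$term_id)
  term_genes <- term_genes[lengths(term_genes) >= min_genes]
  if (length(term_genes) == 0L)
    stop("no terms with >= ", min_genes, " genes in the universe")
  N <- length(universe); n <- length(target_set)
  res <- do.call(rbind, lapply(names(term_genes), function(tid) {
    m <- length(term_genes[[tid]])
    k <- sum(target_set %in% term_genes[[tid]])
    data.frame(term_id = tid, term_size = m, overlap = k,
               expected = n * m / N,
               p_value = stats::phyper(k - 1, m, N - m, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_adjust, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Student's two-sample comparison of group means
#'
#' Two-sided pooled-variance (Student's) t-test, e.g. for comparing
#' per-species WGD-retention proportions between oil-content groups. When
#' the pooled variance is zero and the means are equal, the defined limit
#' t = 0, p = 1 is returned.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @return list of class `group_comparison`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
group_mean_comparison <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(values_a) +
            (nb - 1) * stats::var(values_b)) / df
  dm <- mean(values_a) - mean(values_b)
  if (sp2 == 0) {
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    t_stat <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p, mean_a = mean(values_a),
                 mean_b = mean(values_b), n_a = na, n_b = nb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Student's t-test: t = %.4f, df = %d, P = %.4g (means %.4f vs %.4f)\n",
    x$t_statistic, x$degrees_of_freedom, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}
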