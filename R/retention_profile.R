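# WGD-retention ratio of focal genes and their rank-neighborhoods
# (+/- window genes on the same chromosome), plus a permutation null for
# the peak at offset 0. Neighborhoods are gene-count (rank) based, never
# bp-based, and never cross chromosome ends.

#' Retention profile of focal genes and their neighborhoods
#'
#' For each focal gene and each offset d in `-window..window`, the gene at
#' rank(focal) + d on the same chromosome contributes to offset d's total,
#' and to its retained count iff its gene-level mode is WGD. Offsets
#' falling off the chromosome contribute nothing (the denominator
#' shrinks); the total at offset 0 always equals the number of resolvable
#' focal genes.
#'
#' @param catalog the [gene_catalog()].
#' @param gene_modes data frame `gene_id`, `mode`.
#' @param focal_ids character vector of focal (e.g. pathway) gene ids;
#'   unknown ids are dropped with a warning.
#' @param window neighborhood half-width in genes, default 20.
#' @return An object of class `retention_profile` (also a data frame):
#'   `offset`, `retained`, `total`, `ratio`; attributes `window` and
#'   `n_focal`.
#' @export
compute_retention_profile <- function(catalog, gene_modes, focal_ids,
                                      window = 20L) {
  if (window < 1L) stop("window must be >= 1")
  focal_ids <- unique(focal_ids)
  known <- focal_ids %in% catalog$gene_id
  if (any(!known))
    warning(sum(!known), " focal id(s) not in the catalog, dropped")
  focal_ids <- focal_ids[known]
  if (length(focal_ids) == 0L) stop("no resolvable focal genes")

  retained <- gene_modes$mode[match(catalog$gene_id, gene_modes$gene_id)] == "WGD"
  retained[is.na(retained)] <- FALSE
  offs <- seq.int(-window, window)
  ret_cnt <- tot_cnt <- integer(length(offs))

  by_chrom <- split(seq_len(nrow(catalog)), catalog$chromosome)
  fi <- match(focal_ids, catalog$gene_id)
  for (chrom in unique(catalog$chromosome[fi])) {
    ix <- by_chrom[[chrom]]
    ix <- ix[order(catalog$rank[ix])]          # row index by rank
    ret_chr <- retained[ix]
    n_c <- length(ix)
    f_ranks <- catalog$rank[fi[catalog$chromosome[fi] == chrom]]
    for (w in seq_along(offs)) {
      pos <- f_ranks + offs[w]
      ok <- pos >= 0L & pos < n_c
      tot_cnt[w] <- tot_cnt[w] + sum(ok)
      ret_cnt[w] <- ret_cnt[w] + sum(ret_chr[pos[ok] + 1L])
    }
  }
  out <- data.frame(offset = offs, retained = ret_cnt, total = tot_cnt,
                    ratio = ifelse(tot_cnt > 0, ret_cnt / tot_cnt, NA_real_))
  attr(out, "window") <- window
  attr(out, "n_focal") <- length(focal_ids)
  class(out) <- c("retention_profile", "data.frame")
  out
}

#' @export
print.retention_profile <- function(x, ...) {
  w <- attr(x, "window")
  cat("retention_profile: ", attr(x, "n_focal"), " focal genes, window +/-",
      w, "\n", sep = "")
  at0 <- x$ratio[x$offset == 0]
  far <- x$ratio[abs(x$offset) >= max(1L, w %/% 2L)]
  cat(sprintf("  ratio at offset 0: %.3f; mean ratio at |offset| >= %d: %.3f\n",
              at0, max(1L, w %/% 2L), mean(far, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.retention_profile <- function(x, ...) {
  graphics::plot(x$offset, x$ratio, type = "l", lwd = 2,
                 xlab = "offset from focal gene (genes)",
                 ylab = "WGD retention ratio", ylim = c(0, 1), ...)
  graphics::abline(v = 0, lty = 2, col = "red")
  invisible(x)
}

#' Permutation test for retention at the focal position
#'
#' Null distribution: the retention ratio at offset 0 for `n_perm` random
#' gene sets of the focal set's size, drawn without replacement from all
#' catalog genes. One-sided (enrichment) empirical p-value with add-one
#' smoothing: `p = (1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' @inheritParams compute_retention_profile
#' @param n_perm number of permutations (>= 100), default 999.
#' @param seed integer seed.
#' @return list of class `profile_permutation`: `observed`, `null_mean`,
#'   `null_sd`, `null_quantiles`, `p_value`, `n_perm`, `seed`.
#' @export
profile_permutation_test <- function(catalog, gene_modes, focal_ids,
                                     window = 20L, n_perm = 999L,
                                     seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  focal_ids <- unique(focal_ids)
  focal_ids <- focal_ids[focal_ids %in% catalog$gene_id]
  if (length(focal_ids) == 0L) stop("no resolvable focal genes")
  if (length(focal_ids) > nrow(catalog))
    stop("focal set larger than the catalog")
  retained <- gene_modes$mode[match(catalog$gene_id, gene_modes$gene_id)] == "WGD"
  retained[is.na(retained)] <- FALSE
  observed <- mean(retained[match(focal_ids, catalog$gene_id)])
  if (!is.null(seed)) set.seed(seed)
  nf <- length(focal_ids)
  null <- vapply(seq_len(n_perm), function(i)
    mean(retained[sample.int(nrow(catalog), nf)]), numeric(1))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null_mean = mean(null),
                 null_sd = stats::sd(null),
                 null_quantiles = stats::quantile(
                   null, c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "profile_permutation")
}

#' @export
print.profile_permutation <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed retention %.3f vs null %.3f +/- %.3f; p = %.4g (%d permutations)\n",
    x$observed, x$null_mean, x$null_sd, x$p_value, x$n_perm))
  invisible(x)
}
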