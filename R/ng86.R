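# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Counting conventions:
#  * per codon position, the synonymous site fraction is the number of
#    synonymous single-nucleotide changes divided by the number of changes
#    that do not create a stop codon (stop-producing changes are excluded
#    from the denominator), so s + n = 3 for every codon;
#  * sites are averaged over the two sequences;
#  * codons differing at k > 1 positions are scored by averaging difference
#    counts over all k! substitution orders, skipping orders that pass
#    through a stop codon; if every order hits a stop the codon pair is
#    dropped from the difference counts (sites are kept).

.ng86 <- new.env(parent = emptyenv())

.ng86_tables <- function() {
  if (!is.null(.ng86$codons)) return(invisible(.ng86))
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  nuc <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(codons, ""))

  # per-codon synonymous site count
  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { syn_sites[i] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(nuc, cmat[i, pos])
      n_valid <- 0L; n_syn <- 0L
      for (b in alts) {
        mut <- cmat[i, ]; mut[pos] <- b
        maa <- aa[match(paste(mut, collapse = ""), codons)]
        if (maa == "*") next
        n_valid <- n_valid + 1L
        if (maa == aa[i]) n_syn <- n_syn + 1L
      }
      if (n_valid > 0L) s <- s + n_syn / n_valid
    }
    syn_sites[i] <- s
  }

  # per ordered codon pair: mean synonymous / nonsynonymous differences over
  # valid substitution pathways
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = do.call(rbind, lapply(
                  list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                  as.integer)))
  sd_mat <- matrix(0, 64, 64)
  nd_mat <- matrix(0, 64, 64)
  ok_mat <- matrix(TRUE, 64, 64)
  for (i in seq_len(64)) for (j in seq_len(64)) {
    if (i == j) next
    if (aa[i] == "*" || aa[j] == "*") { ok_mat[i, j] <- FALSE; next }
    diffpos <- which(cmat[i, ] != cmat[j, ])
    d <- length(diffpos)
    pp <- perms[[as.character(d)]]
    sds <- numeric(0); nds <- numeric(0)
    for (r in seq_len(nrow(pp))) {
      cur <- cmat[i, ]; s_cnt <- 0L; n_cnt <- 0L; bad <- FALSE
      for (step in diffpos[pp[r, ]]) {
        nxt <- cur; nxt[step] <- cmat[j, step]
        a1 <- aa[match(paste(cur, collapse = ""), codons)]
        a2 <- aa[match(paste(nxt, collapse = ""), codons)]
        if (a2 == "*") { bad <- TRUE; break }
        if (a1 == a2) s_cnt <- s_cnt + 1L else n_cnt <- n_cnt + 1L
        cur <- nxt
      }
      if (!bad) { sds <- c(sds, s_cnt); nds <- c(nds, n_cnt) }
    }
    if (length(sds) == 0L) ok_mat[i, j] <- FALSE
    else { sd_mat[i, j] <- mean(sds); nd_mat[i, j] <- mean(nds) }
  }

  .ng86$codons <- codons
  .ng86$aa <- aa
  .ng86$syn_sites <- syn_sites
  .ng86$sd_mat <- sd_mat
  .ng86$nd_mat <- nd_mat
  .ng86$ok_mat <- ok_mat
  invisible(.ng86)
}

.split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differences per site for multiple
#' hits, \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}. Returns `NA` where
#' the argument of the logarithm is non-positive (saturation).
#'
#' @param p observed proportion of differing sites, in `[0, 1]`.
#' @return Numeric vector of corrected distances; `NA` where saturated.
#' @export
jukes_cantor <- function(p) {
  arg <- 1 - (4 / 3) * p
  ifelse(arg > 0, -0.75 * log(arg), NA_real_)
}

#' Ka/Ks for an aligned codon pair by Nei-Gojobori (1986) counting
#'
#' Estimates synonymous (Ks) and nonsynonymous (Ka) substitution rates for
#' a pair of in-frame, gap-free aligned coding sequences using the NG86
#' counting method with Jukes-Cantor multiple-hit correction. Synonymous
#' and nonsynonymous site fractions are enumerated per codon position with
#' stop-producing changes excluded from the denominator, averaged over the
#' two sequences; codons differing at more than one position are scored by
#' averaging over all substitution orders that avoid stop codons.
#'
#' Codon columns containing a stop codon or an ambiguous base in either
#' sequence are removed before counting.
#'
#' @param cds_a,cds_b character strings (or objects coercible via
#'   `as.character`) of equal length, a multiple of 3.
#' @return An object of class `ks_estimate`: a list with elements `ka`,
#'   `ks` (`NA` when saturated), `ps`, `pn` (observed proportions),
#'   `s_sites`, `n_sites` (fractional site counts), `syn_diffs`,
#'   `nonsyn_diffs`, `n_codons` (codons retained), `dropped_codons`
#'   (codon pairs whose every substitution pathway hits a stop; excluded
#'   from difference counts only) and `saturated`.
#' @examples
#' a <- strrep("TTT", 10)
#' b <- paste0(strrep("TTT", 9), "TTC")
#' ng86_ka_ks(a, b)$ks  # -0.75 * log(0.6)
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  tb <- .ng86_tables()
  cds_a <- as.character(cds_a); cds_b <- as.character(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned sequences must have equal length (", nchar(cds_a), " vs ",
         nchar(cds_b), ")")
  if (nchar(cds_a) == 0L) stop("empty alignment")
  if (nchar(cds_a) %% 3L != 0L)
    stop("alignment length ", nchar(cds_a), " is not a multiple of 3")

  ia <- match(.split_codons(cds_a), tb$codons)
  ib <- match(.split_codons(cds_b), tb$codons)
  keep <- !is.na(ia) & !is.na(ib) & tb$aa[ia] != "*" & tb$aa[ib] != "*"
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0L) stop("no scorable codons after filtering")

  s_sites <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  n_sites <- 3 * length(ia) - s_sites

  idx <- cbind(ia, ib)
  ok <- tb$ok_mat[idx]
  syn_d <- sum(tb$sd_mat[idx][ok])
  nonsyn_d <- sum(tb$nd_mat[idx][ok])

  ps <- if (s_sites > 0) syn_d / s_sites else 0
  pn <- if (n_sites > 0) nonsyn_d / n_sites else 0
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)

  structure(list(
    ka = ka, ks = ks, ps = ps, pn = pn,
    s_sites = s_sites, n_sites = n_sites,
    syn_diffs = syn_d, nonsyn_diffs = nonsyn_d,
    n_codons = length(ia), dropped_codons = sum(!ok),
    saturated = is.na(ks) || is.na(ka)
  ), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat("NG86 Ka/Ks estimate (", x$n_codons, " codons)\n", sep = "")
  cat(sprintf("  Ks = %s (ps = %.4f over %.2f syn sites)\n",
              ifelse(is.na(x$ks), "saturated", sprintf("%.4f", x$ks)),
              x$ps, x$s_sites))
  cat(sprintf("  Ka = %s (pn = %.4f over %.2f nonsyn sites)\n",
              ifelse(is.na(x$ka), "saturated", sprintf("%.4f", x$ka)),
              x$pn, x$n_sites))
  invisible(x)
}

#' Codon-aware pairwise alignment of two CDS
#'
#' Returns the two sequences as gap-free aligned CDS ready for
#' [ng86_ka_ks()]. Equal-length sequences are used as-is (ungapped
#' comparison). Otherwise the translated proteins are globally aligned and
#' the alignment is back-mapped to codons; codon columns gapped in either
#' sequence are removed.
#'
#' @param cds_a,cds_b in-frame coding sequences (character).
#' @return list with elements `a` and `b`, equal-length codon strings.
#' @export
align_codon_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(as.character(cds_a)); cds_b <- toupper(as.character(cds_b))
  la <- nchar(cds_a) - nchar(cds_a) %% 3L
  lb <- nchar(cds_b) - nchar(cds_b) %% 3L
  cds_a <- substr(cds_a, 1L, la); cds_b <- substr(cds_b, 1L, lb)
  if (la == lb) return(list(a = cds_a, b = cds_b))

  tb <- .ng86_tables()
  trans <- function(x) {
    cod <- .split_codons(x)
    aa <- tb$aa[match(cod, tb$codons)]
    aa[is.na(aa)] <- "X"
    if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    aa[aa == "*"] <- "X"
    paste(aa, collapse = "")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(trans(cds_a)), Biostrings::AAString(trans(cds_b)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cod_a <- .split_codons(cds_a); cod_b <- .split_codons(cds_b)
  out_a <- character(0); out_b <- character(0)
  i <- 1L; j <- 1L
  for (k in seq_along(ap)) {
    if (ap[k] != "-" && as[k] != "-") {
      out_a <- c(out_a, cod_a[i]); out_b <- c(out_b, cod_b[j])
      i <- i + 1L; j <- j + 1L
    } else if (ap[k] != "-") i <- i + 1L else j <- j + 1L
  }
  list(a = paste(out_a, collapse = ""), b = paste(out_b, collapse = ""))
}

#' Ka/Ks estimates for a set of paralog pairs
#'
#' Aligns (via [align_codon_pair()]) and scores each pair of coding
#' sequences with [ng86_ka_ks()].
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @param cds named character vector or list of CDS keyed by gene id.
#' @return data frame with one row per pair: `gene_a`, `gene_b`, `ka`,
#'   `ks`, `s_sites`, `n_sites`, `saturated`. Pairs with a missing
#'   sequence get `NA` estimates and `saturated = NA`.
#' @export
ks_for_pairs <- function(pairs, cds) {
  cds <- unlist(as.list(cds))
  n <- nrow(pairs)
  ka <- ks <- ss <- ns <- rep(NA_real_, n)
  sat <- rep(NA, n)
  for (i in seq_len(n)) {
    sa <- cds[[pairs$gene_a[i]]]; sb <- cds[[pairs$gene_b[i]]]
    if (is.null(sa) || is.null(sb) || is.na(sa) || is.na(sb)) next
    al <- align_codon_pair(sa, sb)
    if (nchar(al$a) == 0L) next
    est <- ng86_ka_ks(al$a, al$b)
    ka[i] <- est$ka; ks[i] <- est$ks
    ss[i] <- est$s_sites; ns[i] <- est$n_sites
    sat[i] <- est$saturated
  }
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             ka = ka, ks = ks, s_sites = ss, n_sites = ns,
             saturated = sat, stringsAsFactors = FALSE)
}
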