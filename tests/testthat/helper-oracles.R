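# Independent oracles: deliberately naive implementations used only to
# check the package's optimised code paths.

# Brute-force NG86 via recursive pathway enumeration (no lookup tables).
oracle_ng86 <- function(a, b) {
  gc_tab <- Biostrings::GENETIC_CODE
  split3 <- function(x) {
    n <- nchar(x) %/% 3
    substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  aa <- function(cod) unname(gc_tab[cod])
  sites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      nv <- 0; ns <- 0
      for (nt in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
        m <- cod; substr(m, p, p) <- nt
        if (aa(m) == "*") next
        nv <- nv + 1
        if (aa(m) == aa(cod)) ns <- ns + 1
      }
      if (nv > 0) s <- s + ns / nv
    }
    s
  }
  paths <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) return(list(c(0, 0)))
    out <- list()
    for (p in dp) {
      m <- c1
      substr(m, p, p) <- substr(c2, p, p)
      if (aa(m) == "*") next
      step <- if (aa(c1) == aa(m)) c(1, 0) else c(0, 1)
      for (s in paths(m, c2)) out[[length(out) + 1]] <- step + s
    }
    out
  }
  ca <- split3(toupper(a)); cb <- split3(toupper(b))
  keep <- aa(ca) != "*" & aa(cb) != "*"
  ca <- ca[keep]; cb <- cb[keep]
  s_sites <- (sum(vapply(ca, sites, 0)) + sum(vapply(cb, sites, 0))) / 2
  n_sites <- 3 * length(ca) - s_sites
  sd_tot <- 0; nd_tot <- 0
  for (i in seq_along(ca)) {
    pw <- paths(ca[i], cb[i])
    if (!length(pw)) next   # all pathways hit stops: dropped
    m <- Reduce(`+`, pw) / length(pw)
    sd_tot <- sd_tot + m[1]; nd_tot <- nd_tot + m[2]
  }
  ps <- sd_tot / s_sites; pn <- nd_tot / n_sites
  jc <- function(p) if (1 - 4 * p / 3 > 0) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(ks = jc(ps), ka = jc(pn), s_sites = s_sites, n_sites = n_sites)
}

# Exhaustive search over all valid chains (depth-first, no pruning).
oracle_max_chain <- function(ra, rb, max_gap, orientation) {
  n <- length(ra)
  best <- 0L
  can_follow <- function(i, j) {
    da <- ra[j] - ra[i]
    db <- if (orientation == "parallel") rb[j] - rb[i] else rb[i] - rb[j]
    da > 0 && da <= max_gap && db > 0 && db <= max_gap
  }
  extend <- function(last, len) {
    best <<- max(best, len)
    for (j in seq_len(n)) if (can_follow(last, j)) extend(j, len + 1L)
  }
  for (i in seq_len(n)) extend(i, 1L)
  best
}

# Random in-frame CDS of n codons (ATG start, no stops).
random_cds <- function(n_codons) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*" & names(gc_tab) != "ATG"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

# Random mutated copy of a CDS (arbitrary substitutions, stop-free).
mutate_random <- function(cds, n_sub) {
  gc_tab <- Biostrings::GENETIC_CODE
  cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  for (k in seq_len(n_sub)) {
    repeat {
      i <- sample(length(cod), 1)
      p <- sample(3, 1)
      m <- cod[i]
      substr(m, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(m, p, p)), 1)
      if (gc_tab[[m]] != "*") { cod[i] <- m; break }
    }
  }
  paste(cod, collapse = "")
}

# Tiny ranked catalog on one or more chromosomes.
make_catalog <- function(n_per_chrom, chroms = "chr1") {
  df <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(gene_id = paste0(ch, "_g", seq_len(n_per_chrom)),
               chromosome = ch,
               start = (seq_len(n_per_chrom) - 1) * 1000 + 1,
               end = (seq_len(n_per_chrom) - 1) * 1000 + 900,
               strand = "+", stringsAsFactors = FALSE)))
  gene_catalog(df)
}
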