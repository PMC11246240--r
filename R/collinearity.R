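# Syntenic block detection on gene-rank coordinates: MCScanX-style chaining
# of homologous anchor pairs by dynamic programming with greedy extraction
# of the best chain first. Chain score is the anchor count.

# Best chain among matches for one orientation. Returns score and the row
# indices of the chain. Ties between equal-score chains are broken by the
# smallest starting (rank_a, rank_b), then smallest end anchor.
.best_chain <- function(ra, rb, max_gap, orientation) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  dp <- rep(1L, n); par <- integer(n)
  sra <- ra; srb <- rb        # start anchor of the best chain ending at j
  for (j in seq_len(n)) {
    da <- ra[j] - ra
    db <- if (orientation == "parallel") rb[j] - rb else rb - rb[j]
    cand <- which(da > 0L & da <= max_gap & db > 0L & db <= max_gap)
    if (length(cand)) {
      best <- max(dp[cand])
      cc <- cand[dp[cand] == best]
      cc <- cc[order(sra[cc], srb[cc], ra[cc], rb[cc])][1L]
      dp[j] <- best + 1L; par[j] <- cc
      sra[j] <- sra[cc]; srb[j] <- srb[cc]
    }
  }
  score <- max(dp)
  ends <- which(dp == score)
  e <- ends[order(sra[ends], srb[ends], ra[ends], rb[ends])][1L]
  chain <- integer(0)
  while (e != 0L) { chain <- c(e, chain); e <- par[e] }
  list(score = score, idx = ord[chain])
}

#' Chain collinear anchors by dynamic programming
#'
#' Chains anchor matches between two chromosomes into syntenic blocks.
#' Matches are sorted by `(rank_a, rank_b)`; match j may extend match i iff
#' `0 < rank_a(j) - rank_a(i) <= max_gap` and the rank_b difference is
#' within `max_gap` in the direction of the orientation (increasing for
#' parallel, decreasing for antiparallel). The highest-scoring chain
#' (score = anchor count) is extracted, its anchors removed, and the
#' process repeats; chains with fewer than `min_anchors` anchors are
#' discarded. Each anchor belongs to at most one block.
#'
#' @param matches data frame with integer columns `rank_a`, `rank_b` (one
#'   row per anchor match; extra columns such as gene ids are carried
#'   along), all on a single chromosome pair.
#' @param max_gap maximum rank gap (gene count) between consecutive chain
#'   members, default 25.
#' @param min_anchors minimum anchors per reported block, default 5.
#' @param orientation orientations to consider: `"parallel"`,
#'   `"antiparallel"`, or both (default). With both, the better chain over
#'   the two orientations is extracted at each round.
#' @return list of blocks; each block is a list with `orientation`,
#'   `n_anchors` and `anchors` (the matching rows of `matches`, ordered
#'   by `rank_a`).
#' @export
chain_anchors_dp <- function(matches, max_gap = 25L, min_anchors = 5L,
                             orientation = c("parallel", "antiparallel")) {
  orientation <- match.arg(orientation, several.ok = TRUE)
  if (max_gap < 1L) stop("max_gap must be >= 1")
  if (min_anchors < 2L) stop("min_anchors must be >= 2")
  blocks <- list()
  remaining <- matches
  while (nrow(remaining) >= min_anchors) {
    cands <- lapply(orientation, function(o)
      c(.best_chain(remaining$rank_a, remaining$rank_b, max_gap, o),
        list(orientation = o)))
    scores <- vapply(cands, `[[`, numeric(1), "score")
    best <- cands[[which.max(scores)]]   # ties: first listed orientation
    if (best$score < min_anchors) break
    anchors <- remaining[best$idx, , drop = FALSE]
    anchors <- anchors[order(anchors$rank_a), , drop = FALSE]
    rownames(anchors) <- NULL
    blocks[[length(blocks) + 1L]] <- list(orientation = best$orientation,
                                          n_anchors = nrow(anchors),
                                          anchors = anchors)
    remaining <- remaining[-best$idx, , drop = FALSE]
  }
  blocks
}

#' Detect syntenic blocks within or between genomes
#'
#' Groups homolog pairs into anchor matches on gene-rank coordinates per
#' chromosome pair and chains them with [chain_anchors_dp()] in both
#' orientations. In intra-genomic mode (`catalog_b = NULL`) each pair is
#' counted once (anchor canonicalised so `(chrom_a, rank_a) <=
#' (chrom_b, rank_b)`) and self-diagonal matches are excluded.
#'
#' A per-gene multiplicity (depth) table reports, for every gene, how many
#' distinct blocks cover its rank — the coverage-depth statistic used to
#' count homologous regions retained from nested polyploidies.
#'
#' @param catalog_a a [gene_catalog()] for the query genome.
#' @param catalog_b a `gene_catalog` for the subject genome, or `NULL` for
#'   intra-genomic detection.
#' @param pairs data frame `gene_a`, `gene_b` of homolog pairs
#'   (`gene_a` in `catalog_a`, `gene_b` in `catalog_b`; either order
#'   accepted intra-genomically).
#' @param max_gap,min_anchors see [chain_anchors_dp()].
#' @return An object of class `synteny_blocks`: list with `blocks` (each
#'   with `chrom_a`, `chrom_b`, `orientation`, `n_anchors`, `anchors`
#'   data frame of `gene_a`, `gene_b`, `rank_a`, `rank_b`),
#'   `multiplicity` (data frame `gene_id`, `chromosome`, `rank`,
#'   `depth`) and `anchor_pairs` (character keys "a|b" of all anchor
#'   pairs).
#' @export
detect_syntenic_blocks <- function(catalog_a, catalog_b = NULL, pairs,
                                   max_gap = 25L, min_anchors = 5L) {
  intra <- is.null(catalog_b)
  if (intra) catalog_b <- catalog_a
  la <- match(pairs$gene_a, catalog_a$gene_id)
  lb <- match(pairs$gene_b, catalog_b$gene_id)
  bad <- unique(c(pairs$gene_a[is.na(la)], pairs$gene_b[is.na(lb)]))
  if (length(bad))
    stop("pairs reference unknown gene ids: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")

  m <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  chrom_a = catalog_a$chromosome[la],
                  chrom_b = catalog_b$chromosome[lb],
                  rank_a = catalog_a$rank[la], rank_b = catalog_b$rank[lb],
                  stringsAsFactors = FALSE)
  if (intra) {
    flip <- (m$chrom_a > m$chrom_b) |
      (m$chrom_a == m$chrom_b & m$rank_a > m$rank_b)
    m[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
      m[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
    m <- m[!(m$chrom_a == m$chrom_b & m$rank_a == m$rank_b), , drop = FALSE]
    m <- m[!duplicated(paste(m$gene_a, m$gene_b)), , drop = FALSE]
  }

  blocks <- list()
  key <- paste(m$chrom_a, m$chrom_b, sep = "\r")
  for (k in sort(unique(key))) {
    sub <- m[key == k, , drop = FALSE]
    if (nrow(sub) < min_anchors) next
    bl <- chain_anchors_dp(sub, max_gap = max_gap, min_anchors = min_anchors)
    for (b in bl) {
      b$chrom_a <- sub$chrom_a[1L]; b$chrom_b <- sub$chrom_b[1L]
      if (intra && b$chrom_a == b$chrom_b) {
        # a same-chromosome block whose two rank spans overlap pairs a
        # region with itself: a tandem/proximal-array artifact of the
        # near-diagonal, not collinearity between two distinct segments
        if (min(b$anchors$rank_a) <= max(b$anchors$rank_b) &&
            min(b$anchors$rank_b) <= max(b$anchors$rank_a)) next
      }
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  # deterministic block order and ids
  if (length(blocks)) {
    o <- order(vapply(blocks, `[[`, character(1), "chrom_a"),
               vapply(blocks, `[[`, character(1), "chrom_b"),
               vapply(blocks, function(b) b$anchors$rank_a[1L], numeric(1)),
               vapply(blocks, function(b) b$anchors$rank_b[1L], numeric(1)))
    blocks <- blocks[o]
    for (i in seq_along(blocks)) blocks[[i]]$block_id <- paste0("block_", i)
  }

  # per-gene coverage depth
  depth <- integer(nrow(catalog_a))
  ix_by_chrom <- split(seq_len(nrow(catalog_a)), catalog_a$chromosome)
  ix_by_chrom_b <- split(seq_len(nrow(catalog_b)), catalog_b$chromosome)
  depth_b <- integer(nrow(catalog_b))
  for (b in blocks) {
    ia <- ix_by_chrom[[b$chrom_a]]
    sel <- ia[catalog_a$rank[ia] >= min(b$anchors$rank_a) &
                catalog_a$rank[ia] <= max(b$anchors$rank_a)]
    depth[sel] <- depth[sel] + 1L
    ib <- ix_by_chrom_b[[b$chrom_b]]
    selb <- ib[catalog_b$rank[ib] >= min(b$anchors$rank_b) &
                 catalog_b$rank[ib] <= max(b$anchors$rank_b)]
    if (intra) depth[selb] <- depth[selb] + 1L
    else depth_b[selb] <- depth_b[selb] + 1L
  }
  multiplicity <- data.frame(gene_id = catalog_a$gene_id,
                             chromosome = catalog_a$chromosome,
                             rank = catalog_a$rank, depth = depth,
                             stringsAsFactors = FALSE)

  anchor_pairs <- unlist(lapply(blocks, function(b)
    paste(pmin(b$anchors$gene_a, b$anchors$gene_b),
          pmax(b$anchors$gene_a, b$anchors$gene_b), sep = "|")))
  if (is.null(anchor_pairs)) anchor_pairs <- character(0)

  structure(list(blocks = blocks, multiplicity = multiplicity,
                 anchor_pairs = anchor_pairs, intra = intra),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks: ", length(x$blocks), " block(s), ",
      length(x$anchor_pairs), " anchor pair(s)",
      if (x$intra) " (intra-genomic)", "\n", sep = "")
  if (length(x$blocks)) {
    na <- vapply(x$blocks, `[[`, numeric(1), "n_anchors")
    cat("  anchors per block: median ", stats::median(na),
        ", range ", min(na), "-", max(na), "\n", sep = "")
  }
  cov <- x$multiplicity$depth
  cat("  gene coverage depth: ",
      paste(names(table(cov)), table(cov), sep = "x", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.synteny_blocks <- function(x, ...) {
  if (!length(x$blocks))
    return(data.frame(block_id = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_anchors = integer(0), anchors = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    block_id = vapply(x$blocks, `[[`, character(1), "block_id"),
    chrom_a = vapply(x$blocks, `[[`, character(1), "chrom_a"),
    chrom_b = vapply(x$blocks, `[[`, character(1), "chrom_b"),
    orientation = vapply(x$blocks, `[[`, character(1), "orientation"),
    n_anchors = vapply(x$blocks, function(b) as.integer(b$n_anchors),
                       integer(1)),
    anchors = vapply(x$blocks, function(b)
      paste(b$anchors$gene_a, b$anchors$gene_b, sep = ":", collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
}
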