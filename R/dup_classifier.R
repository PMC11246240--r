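# Duplication-mode classification in the DupGen_finder tradition: every
# paralog pair receives exactly one of five modes by a fixed priority
# hierarchy (WGD > tandem > proximal > transposed > dispersed), and every
# gene the highest-priority mode among its pairs.

.MODES <- c("WGD", "TD", "PD", "TRD", "DSD", "singleton")

#' Classify paralog pairs into duplication modes
#'
#' Assigns each homolog pair the first matching mode in priority order:
#' \enumerate{
#'   \item WGD — the pair is an anchor in an intra-genomic syntenic block;
#'   \item TD (tandem) — same chromosome, rank distance exactly 1;
#'   \item PD (proximal) — same chromosome, rank distance in
#'     `(1, proximal_max]`;
#'   \item TRD (transposed) — exactly one gene of the pair sits at an
#'     ancestral locus, i.e. is in `outgroup_anchors` (only tested when an
#'     outgroup anchor set is supplied);
#'   \item DSD (dispersed) — everything else.
#' }
#' Without an outgroup the transposed category merges into dispersed
#' (reported with a message) rather than being guessed from intra-genomic
#' data. A pair where both genes are at ancestral loci but not collinear
#' with each other is DSD, not TRD.
#'
#' @param pairs data frame `gene_a`, `gene_b`.
#' @param blocks a [detect_syntenic_blocks()] result (intra-genomic).
#' @param catalog the [gene_catalog()].
#' @param outgroup_anchors optional character vector of gene ids found
#'   syntenic with an outgroup genome (ancestral loci).
#' @param proximal_max maximum rank distance for proximal pairs,
#'   default 10.
#' @return data frame `gene_a`, `gene_b`, `mode`.
#' @export
classify_pair_modes <- function(pairs, blocks, catalog,
                                outgroup_anchors = NULL, proximal_max = 10L) {
  if (proximal_max < 2L) stop("proximal_max must be >= 2")
  pkey <- paste(pmin(pairs$gene_a, pairs$gene_b),
                pmax(pairs$gene_a, pairs$gene_b), sep = "|")
  missing_anchor <- setdiff(blocks$anchor_pairs, pkey)
  if (length(missing_anchor))
    stop("block anchors absent from the pair set: ",
         paste(utils::head(missing_anchor, 5), collapse = ", "))
  ia <- match(pairs$gene_a, catalog$gene_id)
  ib <- match(pairs$gene_b, catalog$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pairs reference genes absent from the catalog")

  same_chrom <- catalog$chromosome[ia] == catalog$chromosome[ib]
  rd <- abs(catalog$rank[ia] - catalog$rank[ib])
  is_anchor <- pkey %in% blocks$anchor_pairs

  mode <- rep("DSD", nrow(pairs))
  if (!is.null(outgroup_anchors)) {
    in_out_a <- pairs$gene_a %in% outgroup_anchors
    in_out_b <- pairs$gene_b %in% outgroup_anchors
    mode[xor(in_out_a, in_out_b)] <- "TRD"
  } else {
    message("no outgroup anchors supplied: transposed duplications are ",
            "reported as dispersed (DSD)")
  }
  mode[same_chrom & rd > 1L & rd <= proximal_max] <- "PD"
  mode[same_chrom & rd == 1L] <- "TD"
  mode[is_anchor] <- "WGD"

  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, mode = mode,
             stringsAsFactors = FALSE)
}

#' Assign gene-level duplication modes
#'
#' Every gene in the catalog receives the highest-priority mode
#' (WGD > TD > PD > TRD > DSD) among the pairs it participates in; genes
#' in no pair are singletons. Mode counts always sum to the catalog size.
#'
#' @param pair_calls result of [classify_pair_modes()].
#' @param catalog the [gene_catalog()].
#' @return data frame `gene_id`, `mode`, `epoch` (`NA`, populated later
#'   by [assign_wgd_epochs()]).
#' @export
assign_gene_modes <- function(pair_calls, catalog) {
  prio <- match(pair_calls$mode, .MODES)
  gene <- c(pair_calls$gene_a, pair_calls$gene_b)
  prio2 <- c(prio, prio)
  best <- tapply(prio2, gene, min)
  mode <- rep("singleton", nrow(catalog))
  hit <- match(catalog$gene_id, names(best))
  mode[!is.na(hit)] <- .MODES[best[hit[!is.na(hit)]]]
  data.frame(gene_id = catalog$gene_id, mode = mode, epoch = NA_integer_,
             stringsAsFactors = FALSE)
}
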