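# Ks mixture modelling: Gaussian mixtures on log10(Ks), fitted by EM for
# K = 1..k_max, model selection by BIC. Successive paleopolyploidies show
# up as separate components ("epochs", numbered youngest first).

#' Fit a Gaussian mixture to a Ks distribution
#'
#' Filters Ks values to `(ks_min, ks_max)`, log10-transforms them, and fits
#' univariate Gaussian mixtures (unequal variances) by
#' expectation-maximization for each K in `1..k_max` via
#' \pkg{mclust}. The K minimizing BIC
#' (\eqn{-2\log L + p\log n}) is returned; fits whose smallest component
#' standard deviation falls below `sd_min` are considered ill-conditioned
#' and skipped with a warning. Components are stored sorted by ascending
#' mean, so component 1 is the youngest peak.
#'
#' @param ks_values numeric vector of Ks estimates (NAs and values outside
#'   the window are dropped).
#' @param k_max maximum number of components, default 4.
#' @param seed integer seed for the EM initialisation.
#' @param ks_min,ks_max analysis window on the Ks scale, defaults 0.005
#'   and 5.0 (drops near-identical allelic artifacts and the saturated
#'   tail).
#' @param sd_min smallest admissible component sd on the log10 scale.
#' @param min_weight smallest admissible component mixing weight (default
#'   0.01): a "peak" carrying less than 1\% of the pairs is an
#'   outlier-capture artifact, not a duplication epoch, so fits containing
#'   one are skipped.
#' @return An object of class `ks_mixture`: list with `n_components`,
#'   `weight`, `mean`, `sd` (per component, on log10(Ks)), `bic`
#'   (selected model), `bic_table` (per candidate K; `NA` where skipped),
#'   `n` (values used), `ks_window`, `loglik`.
#' @export
fit_ks_mixture <- function(ks_values, k_max = 4L, seed = NULL,
                           ks_min = 0.005, ks_max = 5.0, sd_min = 1e-4,
                           min_weight = 0.01) {
  ks <- ks_values[is.finite(ks_values) & ks_values > ks_min &
                    ks_values < ks_max]
  if (length(ks) < 50L)
    stop("need at least 50 Ks values in (", ks_min, ", ", ks_max,
         ") to fit a mixture; got ", length(ks),
         " - supply more paralog pairs")
  x <- log10(ks)
  n <- length(x)
  if (!is.null(seed)) set.seed(seed)

  fits <- vector("list", k_max)
  bic_table <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fit <- tryCatch(
      mclust::Mclust(x, G = k, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$loglik) || !is.finite(fit$loglik)) {
      warning("mixture fit failed for K = ", k, "; skipped")
      next
    }
    sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sds) == 1L) sds <- rep(sds, k)
    if (any(sds < sd_min)) {
      warning("ill-conditioned fit (component sd < ", sd_min,
              ") for K = ", k, "; skipped")
      next
    }
    pro <- as.numeric(fit$parameters$pro)
    if (k > 1L && any(pro < min_weight)) {
      warning("fit for K = ", k, " has a component with weight < ",
              min_weight, " (outlier capture); skipped")
      next
    }
    npar <- 3L * k - 1L
    bic_table[k] <- -2 * fit$loglik + npar * log(n)
    fits[[k]] <- fit
  }
  if (all(is.na(bic_table))) stop("no admissible mixture fit for any K")
  k_best <- which.min(bic_table)
  fit <- fits[[k_best]]
  mu <- as.numeric(fit$parameters$mean)
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, k_best)
  w <- as.numeric(fit$parameters$pro)
  if (is.null(w) || !length(w)) w <- 1
  o <- order(mu)
  structure(list(n_components = k_best,
                 weight = w[o], mean = mu[o], sd = sds[o],
                 bic = bic_table[k_best], bic_table = bic_table,
                 loglik = fit$loglik, n = n,
                 ks_window = c(ks_min, ks_max)),
            class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat("ks_mixture: ", x$n_components, " component(s) on log10(Ks), n = ",
      x$n, ", BIC = ", round(x$bic, 1), "\n", sep = "")
  for (i in seq_len(x$n_components))
    cat(sprintf(
      "  epoch %d: weight %.3f, mean log10(Ks) %+0.3f (Ks ~ %.3f), sd %.3f\n",
      i, x$weight[i], x$mean[i], 10^x$mean[i], x$sd[i]))
  invisible(x)
}

#' Posterior component membership for Ks values
#'
#' @param object a `ks_mixture`.
#' @param ks numeric vector of Ks values.
#' @param ... unused.
#' @return matrix (length(ks) x K) of posterior membership probabilities;
#'   rows for non-finite or non-positive Ks are `NA`.
#' @export
predict.ks_mixture <- function(object, ks, ...) {
  K <- object$n_components
  out <- matrix(NA_real_, length(ks), K)
  ok <- is.finite(ks) & ks > 0
  if (any(ok)) {
    x <- log10(ks[ok])
    dens <- vapply(seq_len(K), function(k)
      object$weight[k] * stats::dnorm(x, object$mean[k], object$sd[k]),
      numeric(sum(ok)))
    dens <- matrix(dens, ncol = K)
    tot <- rowSums(dens)
    tot[tot == 0] <- 1
    out[ok, ] <- dens / tot
  }
  out
}

#' Plot a Ks mixture over its data
#'
#' @param x a `ks_mixture`.
#' @param ks optional numeric vector of the Ks values to histogram.
#' @param ... passed to `hist`.
#' @export
plot.ks_mixture <- function(x, ks = NULL, ...) {
  lim <- log10(x$ks_window)
  grid <- seq(max(lim[1], min(x$mean) - 4 * max(x$sd)),
              min(lim[2], max(x$mean) + 4 * max(x$sd)), length.out = 400)
  dens <- sapply(seq_len(x$n_components), function(k)
    x$weight[k] * stats::dnorm(grid, x$mean[k], x$sd[k]))
  if (!is.null(ks)) {
    v <- log10(ks[is.finite(ks) & ks > x$ks_window[1] & ks < x$ks_window[2]])
    graphics::hist(v, breaks = 50, freq = FALSE, xlab = "log10(Ks)",
                   main = "Ks mixture", ...)
  } else {
    graphics::plot(grid, rowSums(dens), type = "n", xlab = "log10(Ks)",
                   ylab = "density", main = "Ks mixture", ...)
  }
  for (k in seq_len(x$n_components))
    graphics::lines(grid, dens[, k], col = k + 1, lwd = 2)
  graphics::lines(grid, rowSums(dens), col = 1, lty = 2)
  invisible(x)
}

#' Assign WGD pairs and genes to epochs
#'
#' Each WGD-classified pair is assigned to the mixture component with the
#' maximal posterior membership for its Ks (ties broken toward the
#' younger epoch); pairs with saturated or undefined Ks stay unassigned.
#' The gene-level epoch is the epoch of the gene's highest-posterior pair.
#'
#' @param model a [fit_ks_mixture()] result.
#' @param wgd_pair_estimates data frame with `gene_a`, `gene_b`, `ks`
#'   (e.g. the WGD rows of [ks_for_pairs()]).
#' @return list with `pairs` (`gene_a`, `gene_b`, `ks`, `epoch`,
#'   `posterior`; `epoch` is `NA` for unassignable pairs) and `genes`
#'   (`gene_id`, `epoch`, `posterior`).
#' @export
assign_wgd_epochs <- function(model, wgd_pair_estimates) {
  est <- wgd_pair_estimates
  if (nrow(est) == 0L) stop("no WGD pair estimates supplied")
  post <- predict(model, est$ks)
  epoch <- apply(post, 1L, function(p) {
    if (anyNA(p)) return(NA_integer_)
    which(p >= max(p) - 1e-12)[1L]   # tie -> younger epoch
  })
  pp <- vapply(seq_len(nrow(post)), function(i)
    if (is.na(epoch[i])) NA_real_ else post[i, epoch[i]], numeric(1))
  n_un <- sum(is.na(epoch))
  if (n_un) message(n_un, " pair(s) unassigned (saturated or undefined Ks)")
  pairs_out <- data.frame(gene_a = est$gene_a, gene_b = est$gene_b,
                          ks = est$ks, epoch = as.integer(epoch),
                          posterior = pp, stringsAsFactors = FALSE)

  long <- data.frame(gene_id = c(est$gene_a, est$gene_b),
                     epoch = rep(epoch, 2L), posterior = rep(pp, 2L),
                     stringsAsFactors = FALSE)
  long <- long[!is.na(long$epoch), , drop = FALSE]
  if (nrow(long)) {
    long <- long[order(long$gene_id, -long$posterior, long$epoch), ,
                 drop = FALSE]
    genes_out <- long[!duplicated(long$gene_id), , drop = FALSE]
    rownames(genes_out) <- NULL
  } else {
    genes_out <- data.frame(gene_id = character(0), epoch = integer(0),
                            posterior = numeric(0), stringsAsFactors = FALSE)
  }
  list(pairs = pairs_out, genes = genes_out)
}
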