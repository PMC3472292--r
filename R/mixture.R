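#' Fit a 1-D Gaussian mixture by EM with BIC model selection
#'
#' Fits mixtures with 1..`k_max` components by expectation-maximisation
#' (deterministic quantile initialisation, variance floor `1e-6`) and picks
#' the component count by BIC. A fit whose smallest component weight falls
#' below `1/n` is discarded from selection (no empty components).
#'
#' @param x numeric data vector.
#' @param k_max maximum number of components (default 3).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return a `gmm_fit` list: `k`, `weights`, `means`, `variances` (sorted by
#'   mean), `loglik`, `loglik_trace` (selected fit), `bic` (named vector
#'   over k), `n`.
#' @export
fit_gmm <- function(x, k_max = 3, max_iter = 500, tol = 1e-8) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 10) stop("mixture fit refused: fewer than 10 data points")
  fits <- list()
  bic <- stats::setNames(rep(NA_real_, k_max), paste0("k", seq_len(k_max)))
  for (k in seq_len(k_max)) {
    w <- rep(1 / k, k)
    mu <- as.numeric(stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k)))
    v <- rep(max(stats::var(x), 1e-6), k)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sqrt(v[j])), numeric(n))
      dens <- matrix(dens, nrow = n)
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
      ll <- sum(log(rowsum_d))
      ll_trace <- c(ll_trace, ll)
      resp <- dens / rowsum_d
      nk <- colSums(resp)
      nk[nk == 0] <- .Machine$double.eps
      w <- nk / n
      mu <- colSums(resp * x) / nk
      v <- pmax(vapply(seq_len(k), function(j)
        sum(resp[, j] * (x - mu[j])^2) / nk[j], 0), 1e-6)
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    p <- 3 * k - 1
    fit <- list(k = k, weights = w, means = mu, variances = v,
                loglik = ll_trace[length(ll_trace)],
                loglik_trace = ll_trace,
                bic = -2 * ll_trace[length(ll_trace)] + p * log(n), n = n)
    fits[[k]] <- fit
    if (min(w) >= 1 / n) bic[k] <- fit$bic
  }
  if (all(is.na(bic))) bic[1] <- fits[[1]]$bic
  best <- which.min(bic)
  fit <- fits[[best]]
  ord <- order(fit$means)
  structure(list(k = fit$k, weights = fit$weights[ord],
                 means = fit$means[ord], variances = fit$variances[ord],
                 loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                 bic = bic, n = n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("gmm_fit:", x$k, "components on", x$n, "points\n")
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  invisible(x)
}

#' Per-gene expression levels from coverage
#'
#' `level[g]` = mean per-base coverage over the gene's mRNA (exon) bases,
#' scaled by `1e9 / total_aligned_bases`, i.e. coverage per kilobase per
#' million counted bases.
#'
#' @param cov a `coverage_track`.
#' @param ann a `genome_annotation`.
#' @param total_aligned_bases total aligned bases in the sample (sum of
#'   block lengths of the counted reads).
#' @return named numeric vector of levels.
#' @export
expression_levels <- function(cov, ann, total_aligned_bases) {
  if (total_aligned_bases <= 0) stop("total_aligned_bases must be > 0")
  vapply(ann$genes, function(g) {
    v <- unlist(lapply(seq_len(nrow(g$exons)), function(i)
      cov[[g$contig]][(g$exons[i, 1] + 1):g$exons[i, 2]]))
    mean(v) * 1e9 / total_aligned_bases
  }, 0)
}

#' Expression-level distribution and mixture decomposition
#'
#' Log2-transforms the positive expression levels (zero-coverage genes are
#' excluded) and fits Gaussian mixtures with 1..`k_max` components by EM,
#' selecting the component count by BIC.
#'
#' @param levels named numeric vector from [expression_levels()].
#' @param k_max maximum mixture components (default 3).
#' @return list with `log2_levels` (named, expressed genes only),
#'   `n_expressed`, `n_unexpressed` and `fit` (a `gmm_fit`).
#' @export
expression_distribution <- function(levels, k_max = 3) {
  pos <- levels[levels > 0]
  x <- log2(pos)
  list(log2_levels = x, n_expressed = length(pos),
       n_unexpressed = sum(levels <= 0), fit = fit_gmm(x, k_max = k_max))
}
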