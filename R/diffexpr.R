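#' Replicate-ratio ("classical") differential-expression analysis
#'
#' For each gene, computes per-replicate expression ratios
#' `r_i = normA_i / normB_i` from normalised counts, their mean, standard
#' deviation and coefficient of variance (CV = sd / mean), and sorts genes
#' into stringency groups:
#' * group 4 — ratio `<= 0.25` or `>= 4` in all replicates (directionally
#'   consistent: all at/above 4 or all at/below 0.25);
#' * group 3 — mean ratio `<= 0.25` or `>= 4` and CV `< 0.5`;
#' * group 2 — ratio `<= 0.5` or `>= 2` in all replicates (consistent);
#' * group 1 — mean ratio `<= 0.5` or `>= 2` and CV `< 0.5`;
#' * group 0 — all other genes.
#'
#' A gene satisfying several criteria gets the highest group. Ratios are
#' defined only where the denominator is positive; genes with no defined
#' ratio are excluded (`group = NA`). With a single defined ratio the SD
#' (hence CV) is undefined and the CV criteria of groups 3/1 are not met.
#'
#' @param norm numeric matrix of normalised counts (genes x samples).
#' @param samples_a,samples_b column names of the two conditions' replicate
#'   samples; replicate `i` of A is paired with replicate `i` of B when the
#'   numbers match, otherwise all pairwise ratios are used.
#' @return data.frame (`gene_id`, `n_ratios`, `mean_ratio`, `sd_ratio`,
#'   `cv`, `group`) with attribute `ratios` (gene x pair matrix).
#' @export
classical_analysis <- function(norm, samples_a, samples_b) {
  miss <- setdiff(c(samples_a, samples_b), colnames(norm))
  if (length(miss))
    stop("unknown sample(s) in comparison: ", paste(miss, collapse = ", "))
  if (length(samples_a) == length(samples_b)) {
    pairs <- cbind(samples_a, samples_b)
  } else {
    pairs <- as.matrix(expand.grid(samples_a, samples_b,
                                   stringsAsFactors = FALSE))
  }
  ratios <- sapply(seq_len(nrow(pairs)), function(i) {
    a <- norm[, pairs[i, 1]]; b <- norm[, pairs[i, 2]]
    ifelse(b > 0, a / b, NA_real_)
  })
  ratios <- matrix(ratios, nrow = nrow(norm),
                   dimnames = list(rownames(norm), NULL))
  n_ok <- rowSums(!is.na(ratios))
  mean_r <- ifelse(n_ok > 0, rowMeans(ratios, na.rm = TRUE), NA_real_)
  sd_r <- apply(ratios, 1, function(r) stats::sd(r[!is.na(r)]))
  cv <- sd_r / mean_r
  all_dir <- function(hi, lo) {
    up <- rowSums(ratios >= hi, na.rm = TRUE) == n_ok & n_ok > 0
    dn <- rowSums(ratios <= lo, na.rm = TRUE) == n_ok & n_ok > 0
    up | dn
  }
  g4 <- all_dir(4, 0.25)
  g3 <- !is.na(cv) & cv < 0.5 & (mean_r >= 4 | mean_r <= 0.25)
  g2 <- all_dir(2, 0.5)
  g1 <- !is.na(cv) & cv < 0.5 & (mean_r >= 2 | mean_r <= 0.5)
  group <- ifelse(n_ok == 0, NA_integer_,
                  ifelse(g4, 4L, ifelse(g3, 3L, ifelse(g2, 2L,
                                                       ifelse(g1, 1L, 0L)))))
  structure(data.frame(gene_id = rownames(norm), n_ratios = n_ok,
                       mean_ratio = mean_r, sd_ratio = sd_r, cv = cv,
                       group = group, stringsAsFactors = FALSE,
                       row.names = NULL),
            ratios = ratios)
}

#' Bayesian count-ratio estimation (gamma-Poisson model)
#'
#' Per condition, replicate counts are pooled with the per-sample counted
#' totals as exposures; the rate posterior under a Jeffreys prior is
#' `lambda ~ Gamma(sum(k) + 1/2, sum(total))`. Monte-Carlo draws of
#' `lambda_A / lambda_B` yield the posterior mean ratio, an equal-tailed 95%
#' credible interval, and `p_diff = max(P(ratio > 1), P(ratio < 1))`, the
#' posterior probability of differential expression (in `[0.5, 1]`). Genes
#' with zero counts in both conditions are skipped.
#'
#' @param counts_a,counts_b integer matrices (genes x replicates) of raw
#'   counts per condition.
#' @param totals_a,totals_b per-replicate counted-read totals (exposures).
#' @param n_draws Monte-Carlo sample size.
#' @param seed optional RNG seed for reproducible draws.
#' @return data.frame (`gene_id`, `post_mean_ratio`, `ci_lo`, `ci_hi`,
#'   `p_diff`).
#' @export
bayes_ratio <- function(counts_a, counts_b, totals_a, totals_b,
                        n_draws = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (any(totals_a <= 0) || any(totals_b <= 0)) stop("totals must be > 0")
  ka <- rowSums(counts_a); kb <- rowSums(counts_b)
  ta <- sum(totals_a); tb <- sum(totals_b)
  keep <- which(ka + kb > 0)
  out <- lapply(keep, function(i) {
    la <- stats::rgamma(n_draws, ka[i] + 0.5, rate = ta)
    lb <- stats::rgamma(n_draws, kb[i] + 0.5, rate = tb)
    r <- la / lb
    q <- stats::quantile(r, c(0.025, 0.975), names = FALSE)
    c(mean(r), q, max(mean(r > 1), mean(r < 1)))
  })
  m <- do.call(rbind, out)
  ids <- rownames(counts_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts_a)))
  data.frame(gene_id = ids[keep],
             post_mean_ratio = m[, 1], ci_lo = m[, 2], ci_hi = m[, 3],
             p_diff = m[, 4], stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus differential-expression call
#'
#' A gene is called up-regulated (+1) when the mean ratio of the classical
#' analysis AND the Bayesian posterior mean ratio both exceed the threshold
#' `T` (4 for the fourfold set, 8 for the eightfold set), the Bayesian
#' probability of differential expression meets `p_min` (the operational
#' reading of "probability = 1"), and the gene is in classical groups 1-4;
#' down-regulated (-1) symmetrically with both ratios below `1/T`. All other
#' genes — including those missing either component result — are 0.
#'
#' @param classical data.frame from [classical_analysis()].
#' @param bayes data.frame from [bayes_ratio()].
#' @param threshold_set `"fourfold"` (within-tissue comparisons) or
#'   `"eightfold"` (microdissected vs. non-microdissected comparisons, where
#'   lower cutoffs yield excess false positives).
#' @param p_min minimum Bayesian probability (default 0.999; Monte-Carlo
#'   estimates never equal 1 exactly).
#' @return data.frame (`gene_id`, `call` in -1/0/+1, `threshold_set`).
#' @export
consensus_call <- function(classical, bayes,
                           threshold_set = c("fourfold", "eightfold"),
                           p_min = 0.999) {
  threshold_set <- match.arg(threshold_set)
  thr <- if (threshold_set == "fourfold") 4 else 8
  b <- bayes[match(classical$gene_id, bayes$gene_id), ]
  ok <- !is.na(classical$group) & classical$group >= 1 &
    !is.na(b$p_diff) & b$p_diff >= p_min
  up <- ok & classical$mean_ratio > thr & b$post_mean_ratio > thr
  dn <- ok & classical$mean_ratio < 1 / thr & b$post_mean_ratio < 1 / thr
  data.frame(gene_id = classical$gene_id,
             call = ifelse(up, 1L, ifelse(dn, -1L, 0L)),
             threshold_set = threshold_set, stringsAsFactors = FALSE)
}

#' MA-plot table with the +-20 zero conventions
#'
#' `M = log2(a / b)`, with genes whose denominator is zero set to `+20` and
#' genes whose numerator is zero set to `-20`; genes with zero in both are
#' `NA` (no ratio computable). `A` is the average read count `(a + b) / 2`.
#'
#' @param a,b per-gene (mean) counts of the two conditions, equal length.
#' @param gene_id optional gene identifiers.
#' @return data.frame (`gene_id`, `A`, `M`).
#' @export
ma_table <- function(a, b, gene_id = names(a)) {
  if (is.null(gene_id)) gene_id <- as.character(seq_along(a))
  M <- ifelse(a > 0 & b > 0, log2(a / b),
              ifelse(a > 0, 20, ifelse(b > 0, -20, NA_real_)))
  data.frame(gene_id = gene_id, A = (a + b) / 2, M = M,
             stringsAsFactors = FALSE, row.names = NULL)
}
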