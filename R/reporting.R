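#' Top-N gene sets per condition and their overlap table
#'
#' Averages normalised counts across each condition's replicates, takes the
#' `n` genes with the highest average per condition (ties broken
#' lexicographically by gene id for determinism) and enumerates the overlap
#' (Venn) cells over all subset-membership patterns.
#'
#' @param norm numeric matrix of normalised counts (genes x samples).
#' @param condition named character/factor: condition of each sample
#'   (names = column names of `norm`).
#' @param n set size (default 500); when fewer genes exist, all are taken
#'   with a warning.
#' @return list with `sets` (named list of gene-id vectors), `membership`
#'   (logical matrix, union genes x conditions) and `venn` (data.frame: one
#'   row per membership pattern with per-condition indicator columns and
#'   `count`).
#' @export
top_n_sets <- function(norm, condition, n = 500) {
  condition <- condition[colnames(norm)]
  conds <- unique(as.character(condition))
  if (n > nrow(norm)) {
    warning("fewer genes (", nrow(norm), ") than n = ", n, "; taking all")
    n <- nrow(norm)
  }
  avg <- sapply(conds, function(cc)
    rowMeans(norm[, names(condition)[condition == cc], drop = FALSE]))
  sets <- lapply(conds, function(cc) {
    ord <- order(-avg[, cc], rownames(norm))
    rownames(norm)[ord[seq_len(n)]]
  })
  names(sets) <- conds
  union_genes <- sort(unique(unlist(sets)))
  membership <- sapply(conds, function(cc) union_genes %in% sets[[cc]])
  membership <- matrix(membership, nrow = length(union_genes),
                       dimnames = list(union_genes, conds))
  pat <- apply(membership, 1, paste, collapse = "")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(conds)))[-1, ,
                                                                drop = FALSE]
  colnames(grid) <- conds
  key <- apply(grid, 1, paste, collapse = "")
  venn <- data.frame(grid, count = as.integer(table(factor(pat,
                                                           levels = key))),
                     row.names = NULL, check.names = FALSE)
  list(sets = sets, membership = membership, venn = venn)
}
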