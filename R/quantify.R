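# Gene-indexed GRanges of arbitrary per-gene interval sets (0-based in, 1-based GRanges)
gene_intervals_granges <- function(ann, ivs_fun) {
  ivs <- lapply(ann$genes, ivs_fun)
  nr <- vapply(ivs, nrow, 0L)
  iv <- do.call(rbind, ivs[nr > 0])
  lv <- names(ann$contigs)
  if (is.null(iv) || !nrow(iv)) {
    gr <- GenomicRanges::GRanges(seqnames = factor(character(0), levels = lv),
                                 ranges = IRanges::IRanges())
    gr$gene <- integer(0)
    return(gr)
  }
  ctg <- rep(vapply(ann$genes, `[[`, "", "contig"), nr)
  gr <- GenomicRanges::GRanges(factor(ctg, levels = lv),
                               IRanges::IRanges(iv[, 1] + 1, iv[, 2]))
  gr$gene <- rep(seq_along(ann$genes), nr)
  gr
}

# Count reads whose BOTH terminal aligned bases fall in exactly one gene's
# interval set; returns counts + per-read assignment stats.
count_both_ends <- function(aln, ann, target_gr, eligible) {
  ids <- names(ann$genes)
  counts <- stats::setNames(integer(length(ids)), ids)
  idx <- which(eligible)
  stats <- c(counted = 0L, ambiguous = 0L, uncounted = 0L)
  if (!length(idx) || length(target_gr) == 0L) {
    stats["uncounted"] <- length(idx)
    return(list(counts = counts, stats = stats))
  }
  r <- aln$reads[idx, , drop = FALSE]
  e1 <- GenomicRanges::GRanges(r$contig, IRanges::IRanges(r$first0 + 1,
                                                          r$first0 + 1))
  e2 <- GenomicRanges::GRanges(r$contig, IRanges::IRanges(r$last0 + 1,
                                                          r$last0 + 1))
  ov1 <- GenomicRanges::findOverlaps(e1, target_gr)
  ov2 <- GenomicRanges::findOverlaps(e2, target_gr)
  k1 <- paste(S4Vectors::queryHits(ov1),
              target_gr$gene[S4Vectors::subjectHits(ov1)])
  k2 <- paste(S4Vectors::queryHits(ov2),
              target_gr$gene[S4Vectors::subjectHits(ov2)])
  both <- intersect(unique(k1), unique(k2))
  if (length(both)) {
    parts <- matrix(as.integer(unlist(strsplit(both, " ", fixed = TRUE))),
                    ncol = 2, byrow = TRUE)
    ngene <- table(parts[, 1])
    uniq <- as.integer(names(ngene)[ngene == 1L])
    amb <- sum(ngene > 1L)
    gsel <- parts[parts[, 1] %in% uniq, 2]
    tb <- table(factor(gsel, levels = seq_along(ids)))
    counts <- counts + as.integer(tb)
    stats["counted"] <- length(uniq)
    stats["ambiguous"] <- amb
  }
  stats["uncounted"] <- length(idx) - stats[["counted"]] -
    stats[["ambiguous"]]
  list(counts = counts, stats = stats)
}

#' Count reads per gene with the stringent both-ends rule
#'
#' A read is counted for gene `g` iff it is a primary, unique alignment of
#' length at least `min_read_len` (default 35, i.e. strictly longer than 34
#' bases) and BOTH terminal aligned bases (first base of the first block,
#' last base of the last block) lie within exonic intervals of `g` (exons
#' include annotated UTRs). Reads whose ends hit different genes are tallied
#' ambiguous; internal blocks are unconstrained, so intron-spanning spliced
#' reads count.
#'
#' @param aln an `alignments` object.
#' @param ann a `genome_annotation`.
#' @param min_read_len minimum read length to count.
#' @return named integer vector of per-gene counts, with attribute `stats`
#'   (`counted`, `ambiguous`, `uncounted`, `skipped_short`,
#'   `skipped_nonprimary_or_multi`).
#' @export
count_features <- function(aln, ann, min_read_len = 35) {
  exgr <- gene_intervals_granges(ann, function(g) g$exons)
  elig <- aln$reads$is_primary & aln$reads$is_unique &
    aln$reads$read_length >= min_read_len
  res <- count_both_ends(aln, ann, exgr, elig)
  skipped_short <- sum(aln$reads$is_primary & aln$reads$is_unique &
                         aln$reads$read_length < min_read_len)
  structure(res$counts,
            stats = c(res$stats, skipped_short = skipped_short,
                      skipped_nonprimary_or_multi =
                        sum(!(aln$reads$is_primary & aln$reads$is_unique))))
}

#' Count reads in the 3'-window of each transcript
#'
#' The window is the transcript-coordinate interval `[window[1], window[2])`
#' measured from the 3' end (strand-aware), projected to genomic intervals
#' through the exon chain; transcripts shorter than `window[2]` use a
#' truncated window, and transcripts not longer than `window[1]` always
#' count zero. A primary, unique read is counted for gene `g` iff both its
#' terminal aligned bases fall inside `g`'s projected window. Because the
#' window is anchored at the 3' end, these counts are invariant to 5'
#' elongation of the transcript and largely independent of transcript
#' length, which makes them robust to the 3' bias of linearly amplified RNA.
#'
#' @param aln an `alignments` object.
#' @param ann a `genome_annotation` whose mRNA extents include UTRs where
#'   modelled.
#' @param window length-2 numeric, distances (bases) from the 3' end.
#' @return named integer vector of per-gene counts (attribute `stats` as in
#'   [count_features()]).
#' @export
count_3prime_window <- function(aln, ann, window = c(100, 400)) {
  wgr <- gene_intervals_granges(ann, function(g)
    three_prime_window_genomic(g, window))
  elig <- aln$reads$is_primary & aln$reads$is_unique
  res <- count_both_ends(aln, ann, wgr, elig)
  structure(res$counts, stats = res$stats)
}

#' Classify primary alignments by genomic region
#'
#' Every aligned base is labelled exon (within any gene's exon), else intron
#' (within a gene span), else intergenic; a read takes the majority label of
#' its aligned bases, with ties resolved exon > intron > intergenic. A read
#' overlapping two or more genes with no single gene holding a strict
#' majority of its aligned bases is ambiguous. Primary alignments shorter
#' than `min_read_len` are tallied separately as skipped.
#'
#' @param aln an `alignments` object.
#' @param ann a `genome_annotation`.
#' @param min_read_len minimum read length (as in counting).
#' @return a `region_tally` list: `reads_exonic`, `reads_intronic`,
#'   `reads_intergenic`, `reads_ambiguous`, `reads_skipped_short`.
#' @export
classify_regions <- function(aln, ann, min_read_len = 35) {
  prim <- aln$reads$is_primary
  elig <- prim & aln$reads$read_length >= min_read_len
  idx <- which(elig)
  out <- c(reads_exonic = 0L, reads_intronic = 0L, reads_intergenic = 0L,
           reads_ambiguous = 0L,
           reads_skipped_short = sum(prim & !elig))
  if (!length(idx)) return(structure(as.list(out), class = "region_tally"))
  bl <- aln$blocks[elig[aln$blocks$read], , drop = FALSE]
  blgr <- GenomicRanges::GRanges(aln$reads$contig[bl$read],
                                 IRanges::IRanges(bl$start + 1, bl$end))
  aligned <- stats::setNames(rep(0, length(idx)), idx)
  tapsum <- function(ov, q, widths) {
    v <- stats::setNames(rep(0, length(idx)), idx)
    if (length(q)) {
      s <- tapply(widths, bl$read[q], sum)
      v[names(s)] <- s
    }
    v
  }
  albp <- tapply(bl$end - bl$start, bl$read, sum)
  aligned[names(albp)] <- albp
  exgr <- GenomicRanges::reduce(gene_intervals_granges(ann,
                                                       function(g) g$exons))
  spgr <- gene_intervals_granges(ann, function(g)
    matrix(gene_span(g), ncol = 2))
  overlap_bp <- function(gr2) {
    ov <- GenomicRanges::findOverlaps(blgr, gr2)
    if (!length(ov)) return(stats::setNames(rep(0, length(idx)), idx))
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(blgr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(gr2)[S4Vectors::subjectHits(ov)]))
    tapsum(ov, S4Vectors::queryHits(ov), w)
  }
  exon_bp <- overlap_bp(exgr)
  span_red <- GenomicRanges::reduce(spgr)
  body_bp <- overlap_bp(span_red)
  intron_bp <- body_bp - exon_bp
  inter_bp <- aligned - body_bp
  # per-gene body overlap for the ambiguity rule
  ovg <- GenomicRanges::findOverlaps(blgr, spgr)
  amb <- rep(FALSE, length(idx))
  if (length(ovg)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(blgr)[S4Vectors::queryHits(ovg)],
      IRanges::ranges(spgr)[S4Vectors::subjectHits(ovg)]))
    key <- paste(bl$read[S4Vectors::queryHits(ovg)],
                 spgr$gene[S4Vectors::subjectHits(ovg)])
    pg <- tapply(w, key, sum)
    rd <- as.integer(sub(" .*", "", names(pg)))
    ngenes <- table(rd)
    maxbp <- tapply(as.numeric(pg), rd, max)
    multi <- as.integer(names(ngenes)[ngenes >= 2L])
    for (m in multi) {
      pos <- match(as.character(m), names(aligned))
      if (maxbp[as.character(m)] <= aligned[pos] / 2) amb[pos] <- TRUE
    }
  }
  lab <- ifelse(amb, "ambiguous",
                ifelse(exon_bp >= intron_bp & exon_bp >= inter_bp, "exonic",
                       ifelse(intron_bp >= inter_bp, "intronic",
                              "intergenic")))
  out["reads_exonic"] <- sum(lab == "exonic")
  out["reads_intronic"] <- sum(lab == "intronic")
  out["reads_intergenic"] <- sum(lab == "intergenic")
  out["reads_ambiguous"] <- sum(lab == "ambiguous")
  structure(as.list(out), class = "region_tally")
}

#' Assemble a count matrix from per-sample count vectors
#'
#' @param columns named list of equal-length named integer vectors (one per
#'   sample, as from [count_features()]).
#' @return a `count_matrix`: list with `counts` (gene x sample integer
#'   matrix) and `totals` (per-sample total counted reads = column sums,
#'   the normalisation denominator).
#' @export
count_matrix <- function(columns) {
  m <- do.call(cbind, lapply(columns, as.integer))
  rownames(m) <- names(columns[[1]])
  colnames(m) <- names(columns)
  structure(list(counts = m, totals = colSums(m)), class = "count_matrix")
}

#' Normalise counts to counts per million counted reads
#'
#' `norm[g, s] = counts[g, s] / total_counted[s] * 1e6`.
#'
#' @param cm a `count_matrix` (or plain matrix, in which case totals are the
#'   column sums).
#' @return numeric matrix of normalised counts.
#' @export
normalize_counts <- function(cm) {
  if (is.matrix(cm)) cm <- structure(list(counts = cm, totals = colSums(cm)),
                                     class = "count_matrix")
  if (any(cm$totals <= 0))
    stop("zero counted-read total in sample ",
         names(cm$totals)[cm$totals <= 0][1])
  t(t(cm$counts) / cm$totals) * 1e6
}

#' Write / read a TSV count matrix with a totals row
#'
#' @param cm a `count_matrix`.
#' @param path TSV path; first column `gene_id`, one column per sample, a
#'   final `_total_counted` row.
#' @return `path` / a `count_matrix`.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = c(rownames(cm$counts), "_total_counted"),
                   rbind(cm$counts, as.integer(cm$totals)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tot_row <- df$gene_id == "_total_counted"
  m <- as.matrix(df[!tot_row, -1, drop = FALSE])
  rownames(m) <- df$gene_id[!tot_row]
  totals <- if (any(tot_row)) unlist(df[tot_row, -1]) else colSums(m)
  structure(list(counts = m, totals = totals), class = "count_matrix")
}
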