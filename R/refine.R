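#' Build per-base read coverage from alignments
#'
#' Each match block of every primary, unique alignment increments the bases
#' it covers; splice skips contribute nothing.
#'
#' @param aln an `alignments` object.
#' @param contigs named numeric vector of contig lengths; defaults to the
#'   lengths carried in `aln`.
#' @return a `coverage_track`: named list of integer vectors, one per
#'   contig, `cov[[ctg]][i]` = coverage of 0-based position `i - 1`.
#' @export
build_coverage <- function(aln, contigs = aln$contigs) {
  if (!length(contigs)) stop("no contig lengths available")
  keep <- aln$reads$is_primary & aln$reads$is_unique
  b <- aln$blocks[keep[aln$blocks$read], , drop = FALSE]
  ctg <- aln$reads$contig[b$read]
  if (nrow(b)) {
    if (!all(ctg %in% names(contigs)))
      stop("read block on unknown contig ", setdiff(ctg, names(contigs))[1])
    if (any(b$start < 0 | b$end > contigs[ctg]))
      stop("read block outside contig bounds on ",
           ctg[which(b$start < 0 | b$end > contigs[ctg])[1]])
  }
  gr <- GenomicRanges::GRanges(
    factor(ctg, levels = names(contigs)),
    IRanges::IRanges(b$start + 1, b$end))
  rle <- GenomicRanges::coverage(gr, width = as.list(contigs))
  out <- lapply(rle, as.integer)
  structure(out[names(contigs)], class = "coverage_track")
}

#' Extract splice junctions from spliced alignments
#'
#' Every gap between consecutive match blocks of a primary, unique read is
#' one junction observation; observations are aggregated per distinct
#' (contig, donor_end, acceptor_start).
#'
#' @param aln an `alignments` object.
#' @return data.frame (`contig`, `donor_end`, `acceptor_start`, `support`)
#'   sorted by contig and position. `donor_end` is the 0-based exclusive end
#'   of the left block; `acceptor_start` the 0-based start of the right one.
#' @export
extract_junctions <- function(aln) {
  empty <- data.frame(contig = character(0), donor_end = numeric(0),
                      acceptor_start = numeric(0), support = integer(0),
                      stringsAsFactors = FALSE)
  keep <- aln$reads$is_primary & aln$reads$is_unique &
    aln$reads$n_blocks >= 2L
  b <- aln$blocks[keep[aln$blocks$read], , drop = FALSE]
  if (!nrow(b)) return(empty)
  n <- nrow(b)
  same <- b$read[-n] == b$read[-1]
  if (!any(same)) return(empty)
  jx <- data.frame(contig = aln$reads$contig[b$read[-n][same]],
                   donor_end = b$end[-n][same],
                   acceptor_start = b$start[-1][same],
                   stringsAsFactors = FALSE)
  key <- paste(jx$contig, jx$donor_end, jx$acceptor_start, sep = "\r")
  tab <- table(key)
  first <- jx[!duplicated(key), , drop = FALSE]
  first$support <- as.integer(tab[paste(first$contig, first$donor_end,
                                        first$acceptor_start, sep = "\r")])
  first <- first[order(first$contig, first$donor_end, first$acceptor_start), ]
  rownames(first) <- NULL
  first
}

# Longest gap-tolerant covered extension along `covered` (logical vector in
# walk order): the furthest covered position such that every uncovered run
# before it is <= max_gap; gaps are only bridged when flanked by covered runs.
walk_extension <- function(covered, max_gap) {
  if (!length(covered)) return(0L)
  r <- rle(covered)
  ext <- 0L; at <- 0L
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      at <- at + r$lengths[i]
      ext <- at
    } else {
      if (r$lengths[i] > max_gap) break
      at <- at + r$lengths[i]
    }
  }
  ext
}

#' Model UTRs from read coverage
#'
#' For each gene and each side (5', 3'), walks outward from the CDS-side
#' terminus while per-base coverage is at least `min_cov`, bridging up to
#' `max_gap` consecutive sub-threshold bases when flanked by covered runs,
#' and stopping at `max_extent`, the nearest neighbouring gene boundary, or
#' the contig end. A side yields a call when the extension is at least one
#' base.
#'
#' @param ann a `genome_annotation` (typically UTR-less).
#' @param cov a `coverage_track` built from the same genome.
#' @param min_cov minimum per-base read coverage (reads).
#' @param max_gap maximum bridged run of sub-threshold bases.
#' @param max_extent maximum UTR extension (bases).
#' @return data.frame of UTR calls (`gene_id`, `side` in `"5"`/`"3"`,
#'   `contig`, `start`, `end`, `length`, `mean_coverage`).
#' @export
model_utrs <- function(ann, cov, min_cov = 2, max_gap = 10,
                       max_extent = 2000) {
  calls <- list()
  spans <- t(vapply(ann$genes, gene_span, numeric(2)))
  ctgs <- vapply(ann$genes, `[[`, "", "contig")
  for (g in ann$genes) {
    cv <- cov[[g$contig]]
    others <- which(ctgs == g$contig &
                      names(ann$genes) != g$gene_id)
    for (side in c("5", "3")) {
      right <- (g$strand == "+") == (side == "3")  # walk direction
      if (right) {
        from <- g$cds[2]  # first position outside the CDS
        lim <- min(max_extent, length(cv) - from)
        nb <- spans[others, 1]
        nb <- nb[nb >= from]
        if (length(nb)) lim <- min(lim, min(nb) - from)
        if (lim < 1) next
        slice <- cv[(from + 1):(from + lim)]
        k <- walk_extension(slice >= min_cov, max_gap)
        if (k < 1) next
        iv <- c(from, from + k)
      } else {
        from <- g$cds[1]  # walk leftward from cds start
        lim <- min(max_extent, from)
        nb <- spans[others, 2]
        nb <- nb[nb <= from]
        if (length(nb)) lim <- min(lim, from - max(nb))
        if (lim < 1) next
        slice <- rev(cv[(from - lim + 1):from])
        k <- walk_extension(slice >= min_cov, max_gap)
        if (k < 1) next
        iv <- c(from - k, from)
      }
      calls[[length(calls) + 1L]] <- data.frame(
        gene_id = g$gene_id, side = side, contig = g$contig,
        start = iv[1], end = iv[2], length = iv[2] - iv[1],
        mean_coverage = mean(cv[(iv[1] + 1):iv[2]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(gene_id = character(0), side = character(0),
                      contig = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      mean_coverage = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Summarise UTR calls in the four annotation categories
#'
#' @param ann the `genome_annotation` the calls refer to.
#' @param calls data.frame from [model_utrs()].
#' @return data.frame with one row per category (`both`, `utr5_only`,
#'   `utr3_only`, `none`) giving counts and percentages, plus attributes
#'   `median_utr5`/`median_utr3` (median call lengths per side).
#' @export
utr_summary <- function(ann, calls) {
  ids <- names(ann$genes)
  has5 <- ids %in% calls$gene_id[calls$side == "5"]
  has3 <- ids %in% calls$gene_id[calls$side == "3"]
  n <- length(ids)
  cnt <- c(both = sum(has5 & has3), utr5_only = sum(has5 & !has3),
           utr3_only = sum(!has5 & has3), none = sum(!has5 & !has3))
  out <- data.frame(category = names(cnt), genes = as.integer(cnt),
                    percent = if (n) round(100 * cnt / n, 1) else rep(NA, 4),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "median_utr5") <- stats::median(calls$length[calls$side == "5"])
  attr(out, "median_utr3") <- stats::median(calls$length[calls$side == "3"])
  out
}

#' Apply UTR calls to an annotation
#'
#' Sets each called gene's UTR extent and stretches the corresponding
#' terminal exon so the transcribed footprint includes the UTR. Calls are
#' expected to abut the CDS terminus (as produced by [model_utrs()] on a
#' UTR-stripped annotation).
#'
#' @param ann a `genome_annotation`.
#' @param calls data.frame from [model_utrs()].
#' @return the updated `genome_annotation`.
#' @export
apply_utr_calls <- function(ann, calls) {
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    g <- ann$genes[[cl$gene_id]]
    if (is.null(g)) stop("UTR call for unknown gene ", cl$gene_id)
    left <- cl$end <= g$cds[1]  # call extends on the genomic left
    ex <- g$exons
    if (left) ex[1, 1] <- min(ex[1, 1], cl$start)
    else ex[nrow(ex), 2] <- max(ex[nrow(ex), 2], cl$end)
    u5 <- g$utr5; u3 <- g$utr3
    if (cl$side == "5") u5 <- c(cl$start, cl$end) else u3 <- c(cl$start, cl$end)
    ann$genes[[cl$gene_id]] <- gene_model(g$gene_id, g$contig, g$strand, ex,
                                          g$cds, utr5 = u5, utr3 = u3)
  }
  ann
}

#' Confirm and correct intron structures from splice junctions
#'
#' Per gene: a junction identical to an annotated intron confirms it; a
#' junction with support at least `min_support` overlapping an annotated
#' intron but with shifted boundaries replaces that intron; a supported
#' junction fully inside an annotated exon splits the exon (novel internal
#' intron). Junctions outside all genes are reported as candidates only.
#' An adjustment that would invert or empty an exon, break exon ordering, or
#' displace a CDS endpoint out of the exon chain is rejected and reported,
#' leaving the gene unchanged.
#'
#' @param ann a `genome_annotation`.
#' @param junctions data.frame from [extract_junctions()].
#' @param min_support minimum read support to adjust or create an intron.
#' @return list with `annotation` (refined) and `report`: tally of
#'   `confirmed`, `adjusted`, `novel_internal`, `outside`, `rejected`,
#'   `subthreshold`, `unassigned`, plus `candidates` (junctions outside
#'   genes).
#' @export
refine_gene_models <- function(ann, junctions, min_support = 2) {
  tally <- c(confirmed = 0L, adjusted = 0L, novel_internal = 0L,
             outside = 0L, rejected = 0L, subthreshold = 0L, unassigned = 0L)
  cand <- junctions[0, , drop = FALSE]
  spans <- t(vapply(ann$genes, gene_span, numeric(2)))
  ctgs <- vapply(ann$genes, `[[`, "", "contig")
  for (j in seq_len(nrow(junctions))) {
    jc <- junctions[j, ]
    if (jc$acceptor_start <= jc$donor_end)
      stop("invalid junction: donor_end must precede acceptor_start")
    hit <- which(ctgs == jc$contig & spans[, 1] < jc$acceptor_start &
                   spans[, 2] > jc$donor_end)
    if (!length(hit)) {
      tally["outside"] <- tally["outside"] + 1L
      cand <- rbind(cand, jc)
      next
    }
    # best gene by overlap with the junction interval, ties by gene id
    ovl <- pmin(spans[hit, 2], jc$acceptor_start) -
      pmax(spans[hit, 1], jc$donor_end)
    gi <- hit[order(-ovl, names(ann$genes)[hit])[1]]
    g <- ann$genes[[gi]]
    intr <- introns_of(g)
    identical_intron <- nrow(intr) > 0 &&
      any(intr[, 1] == jc$donor_end & intr[, 2] == jc$acceptor_start)
    if (identical_intron) {
      tally["confirmed"] <- tally["confirmed"] + 1L
      next
    }
    if (jc$support < min_support) {
      tally["subthreshold"] <- tally["subthreshold"] + 1L
      next
    }
    ex <- g$exons
    ovl_intr <- if (nrow(intr)) which(intr[, 1] < jc$acceptor_start &
                                        intr[, 2] > jc$donor_end)
                else integer(0)
    new_g <- NULL
    kind <- NULL
    if (length(ovl_intr)) {
      # adjust the most-overlapping annotated intron
      io <- pmin(intr[ovl_intr, 2], jc$acceptor_start) -
        pmax(intr[ovl_intr, 1], jc$donor_end)
      k <- ovl_intr[which.max(io)]
      ex2 <- ex
      ex2[k, 2] <- jc$donor_end        # left exon new end
      ex2[k + 1, 1] <- jc$acceptor_start  # right exon new start
      new_g <- try(gene_model(g$gene_id, g$contig, g$strand, ex2, g$cds,
                              utr5 = g$utr5, utr3 = g$utr3), silent = TRUE)
      kind <- "adjusted"
    } else {
      inside <- which(ex[, 1] < jc$donor_end & ex[, 2] > jc$acceptor_start)
      if (length(inside) == 1L) {
        k <- inside
        ex2 <- rbind(ex[seq_len(k - 1), , drop = FALSE],
                     c(ex[k, 1], jc$donor_end),
                     c(jc$acceptor_start, ex[k, 2]),
                     ex[-seq_len(k), , drop = FALSE][-1, , drop = FALSE])
        new_g <- try(gene_model(g$gene_id, g$contig, g$strand, ex2, g$cds,
                                utr5 = g$utr5, utr3 = g$utr3), silent = TRUE)
        kind <- "novel_internal"
      } else {
        tally["unassigned"] <- tally["unassigned"] + 1L
        next
      }
    }
    if (inherits(new_g, "try-error")) {
      tally["rejected"] <- tally["rejected"] + 1L
    } else {
      validate_gene_model(new_g)
      ann$genes[[gi]] <- new_g
      tally[kind] <- tally[kind] + 1L
    }
  }
  for (g in ann$genes) validate_gene_model(g)
  list(annotation = ann,
       report = list(tally = as.list(tally), candidates = cand))
}
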