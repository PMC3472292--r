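#' Read a text SAM file into an `alignments` object
#'
#' Parses mapped records and decomposes each CIGAR into reference match
#' blocks: M and D advance the reference within a block, N splits blocks
#' (splice skip), I and S consume read bases only. Unmapped records (FLAG
#' 0x4) are skipped. A read is flagged unique when its `NH` tag is 1, or —
#' when no `NH` tag is present — when MAPQ > 3; secondary alignments (FLAG
#' 0x100) are flagged non-primary.
#'
#' @param path SAM file (text, with header).
#' @return an object of class `alignments`: a list with
#'   * `reads`: data.frame (`read_id`, `contig`, `read_length`, `is_unique`,
#'     `is_primary`, `n_blocks`, `first0`, `last0`) — `first0`/`last0` are
#'     the 0-based genomic positions of the first and last aligned base;
#'   * `blocks`: data.frame (`read` index into `reads`, `start`, `end`),
#'     0-based half-open;
#'   * `contigs`: named numeric vector of contig lengths from `@SQ` lines.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  sq <- lines[hdr][startsWith(lines[hdr], "@SQ")]
  contigs <- numeric(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    contigs <- stats::setNames(ln, sn)
  }
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (!length(body))
    return(new_alignments(empty_reads_df(), data.frame(read = integer(0),
                                                       start = numeric(0),
                                                       end = numeric(0)),
                          contigs))
  f <- strsplit(body, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  mapq <- as.integer(vapply(f, `[[`, "", 5L))
  cigar <- vapply(f, `[[`, "", 6L)
  seq <- vapply(f, `[[`, "", 10L)
  nh <- vapply(f, function(x) {
    t <- grep("^NH:i:", x[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("^NH:i:", "", t[1])) else NA_integer_
  }, 0L)

  mapped <- bitwAnd(flag, 4L) == 0L & cigar != "*"
  qname <- qname[mapped]; flag <- flag[mapped]; rname <- rname[mapped]
  pos <- pos[mapped]; mapq <- mapq[mapped]; cigar <- cigar[mapped]
  seq <- seq[mapped]; nh <- nh[mapped]
  if (!length(qname))
    return(new_alignments(empty_reads_df(), data.frame(read = integer(0),
                                                       start = numeric(0),
                                                       end = numeric(0)),
                          contigs))

  bad <- grepl("[0-9]+[^0-9MIDNS]", cigar)
  if (any(bad))
    stop("unknown CIGAR operation in read ", qname[which(bad)[1]],
         " (", cigar[which(bad)[1]], ")")

  irl <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)
  nb <- S4Vectors::elementNROWS(irl)
  ir <- unlist(irl, use.names = FALSE)
  blocks <- data.frame(read = rep(seq_along(cigar), nb),
                       start = IRanges::start(ir) - 1,
                       end = as.numeric(IRanges::end(ir)))
  read_length <- ifelse(seq == "*",
                        GenomicAlignments::cigarWidthAlongQuerySpace(
                          cigar, after.soft.clipping = FALSE),
                        nchar(seq))
  first0 <- blocks$start[c(1, cumsum(nb)[-length(nb)] + 1)]
  last0 <- blocks$end[cumsum(nb)] - 1
  reads <- data.frame(
    read_id = qname, contig = rname, read_length = as.numeric(read_length),
    is_unique = ifelse(is.na(nh), mapq > 3L, nh == 1L),
    is_primary = bitwAnd(flag, 256L) == 0L,
    n_blocks = as.integer(nb), first0 = first0, last0 = last0,
    stringsAsFactors = FALSE)
  new_alignments(reads, blocks, contigs)
}

empty_reads_df <- function() {
  data.frame(read_id = character(0), contig = character(0),
             read_length = numeric(0), is_unique = logical(0),
             is_primary = logical(0), n_blocks = integer(0),
             first0 = numeric(0), last0 = numeric(0),
             stringsAsFactors = FALSE)
}

new_alignments <- function(reads, blocks, contigs = numeric(0)) {
  structure(list(reads = reads, blocks = blocks, contigs = contigs),
            class = "alignments")
}

#' @export
print.alignments <- function(x, ...) {
  cat("alignments:", nrow(x$reads), "reads,", nrow(x$blocks), "blocks on",
      length(unique(x$reads$contig)), "contigs\n")
  invisible(x)
}

# GRanges of all blocks of the selected reads (1-based closed for IRanges).
blocks_granges <- function(aln, keep = rep(TRUE, nrow(aln$reads))) {
  b <- aln$blocks[keep[aln$blocks$read], , drop = FALSE]
  GenomicRanges::GRanges(aln$reads$contig[b$read],
                         IRanges::IRanges(b$start + 1, b$end),
                         read = b$read)
}
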