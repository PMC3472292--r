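#' Gene model
#'
#' A single-transcript gene: its contig, strand, ordered exons, CDS span and
#' (optionally) 5'/3' UTR extents. All coordinates are internal convention:
#' 0-based, half-open. Exons are the transcribed blocks, i.e. they include
#' UTR sequence where UTRs are annotated; `cds` is the genomic span of the
#' coding sequence (it may bridge introns). UTR intervals, when present,
#' abut the CDS on the strand-appropriate side.
#'
#' @param gene_id unique gene identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 0-based half-open exon
#'   intervals; rows may be unordered, they are sorted by start.
#' @param cds length-2 numeric, 0-based half-open genomic CDS span.
#' @param utr5,utr3 optional length-2 numeric UTR intervals.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds,
                       utr5 = NULL, utr3 = NULL) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  g <- structure(
    list(gene_id = as.character(gene_id), contig = as.character(contig),
         strand = strand, exons = exons, cds = as.numeric(cds),
         utr5 = if (!is.null(utr5)) as.numeric(utr5),
         utr3 = if (!is.null(utr3)) as.numeric(utr3)),
    class = "gene_model")
  validate_gene_model(g)
  g
}

#' Validate a gene model's structural invariants
#'
#' Checks exon ordering/disjointness, CDS endpoints falling inside the exon
#' union, and UTR adjacency to the CDS on the correct strand side.
#'
#' @param g a `gene_model`.
#' @return `g`, invisibly; stops on violation.
#' @export
validate_gene_model <- function(g) {
  ex <- g$exons
  if (nrow(ex) < 1L) stop("gene ", g$gene_id, ": no exons")
  if (any(ex[, 2] <= ex[, 1])) stop("gene ", g$gene_id, ": empty exon")
  if (nrow(ex) > 1L && any(ex[-1, 1] < ex[-nrow(ex), 2]))
    stop("gene ", g$gene_id, ": exons overlap or are unsorted")
  if (!g$strand %in% c("+", "-")) stop("gene ", g$gene_id, ": bad strand")
  cds <- g$cds
  if (length(cds) != 2L || cds[2] <= cds[1])
    stop("gene ", g$gene_id, ": bad CDS span")
  in_exon <- function(p) any(p >= ex[, 1] & p < ex[, 2])
  if (!in_exon(cds[1]) || !in_exon(cds[2] - 1))
    stop("gene ", g$gene_id, ": CDS endpoints outside exons")
  # UTRs abut the CDS: 5' UTR upstream, 3' UTR downstream in gene orientation
  chk <- function(u, at, side) {
    if (u[2] <= u[1]) stop("gene ", g$gene_id, ": empty ", side, " UTR")
    if (u[if (at == "left") 2 else 1] != cds[if (at == "left") 1 else 2])
      stop("gene ", g$gene_id, ": ", side, " UTR does not abut CDS")
  }
  if (!is.null(g$utr5)) chk(g$utr5, if (g$strand == "+") "left" else "right", "5'")
  if (!is.null(g$utr3)) chk(g$utr3, if (g$strand == "+") "right" else "left", "3'")
  invisible(g)
}

#' Genome annotation
#'
#' Container for a set of contigs and single-transcript gene models.
#'
#' @param contigs named numeric vector of contig lengths (bases).
#' @param genes list of [gene_model()] objects.
#' @return an object of class `genome_annotation` with elements `contigs`
#'   and `genes` (named by gene id).
#' @export
genome_annotation <- function(contigs, genes = list()) {
  contigs <- stats::setNames(as.numeric(contigs), names(contigs))
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  ann <- structure(list(contigs = contigs, genes = genes),
                   class = "genome_annotation")
  for (g in genes) {
    if (!g$contig %in% names(contigs))
      stop("gene ", g$gene_id, ": unknown contig ", g$contig)
    if (min(g$exons[, 1]) < 0 || max(g$exons[, 2]) > contigs[[g$contig]])
      stop("gene ", g$gene_id, ": exon outside contig bounds")
  }
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$contigs), "contigs,",
      length(x$genes), "genes\n")
  invisible(x)
}

#' Genomic span of a gene (first exon start to last exon end)
#' @param g a `gene_model`.
#' @return length-2 numeric, 0-based half-open.
#' @export
gene_span <- function(g) c(g$exons[1, 1], g$exons[nrow(g$exons), 2])

#' Introns of a gene model
#' @param g a `gene_model`.
#' @return two-column matrix (start, end) of 0-based half-open intron
#'   intervals between consecutive exons; zero rows for single-exon genes.
#' @export
introns_of <- function(g) {
  ex <- g$exons
  if (nrow(ex) < 2L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), 2], end = ex[-1, 1])
}

#' Spliced transcript length of a gene (sum of exon widths)
#' @param g a `gene_model`.
#' @return numeric scalar, bases.
#' @export
transcript_length <- function(g) sum(g$exons[, 2] - g$exons[, 1])

#' Strip UTRs from an annotation
#'
#' Trims every gene's exons to the CDS span and drops UTR fields, producing
#' the CDS-only annotation state that precedes UTR modelling (the input for
#' UTR-recovery runs).
#'
#' @param ann a `genome_annotation`.
#' @return a `genome_annotation` without UTRs.
#' @export
strip_utrs <- function(ann) {
  ann$genes <- lapply(ann$genes, function(g) {
    ex <- g$exons
    ex[, 1] <- pmax(ex[, 1], g$cds[1])
    ex[, 2] <- pmin(ex[, 2], g$cds[2])
    ex <- ex[ex[, 2] > ex[, 1], , drop = FALSE]
    gene_model(g$gene_id, g$contig, g$strand, ex, g$cds)
  })
  ann
}

# Exons in transcript (5'->3') order: for "-" genes, genomically last first.
exons_tx_order <- function(g) {
  ex <- g$exons
  if (g$strand == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
}

#' Project a transcript-coordinate interval onto the genome
#'
#' Maps the half-open transcript slice `[t0, t1)` (0-based, measured 5'->3'
#' along the spliced transcript) through the gene's exon chain, honouring
#' strand.
#'
#' @param g a `gene_model`.
#' @param t0,t1 transcript coordinates, `0 <= t0 < t1 <= transcript_length(g)`.
#' @return two-column matrix of genomic 0-based half-open intervals in
#'   genomic order.
#' @export
project_to_genome <- function(g, t0, t1) {
  L <- transcript_length(g)
  stopifnot(t0 >= 0, t1 > t0, t1 <= L)
  ex <- exons_tx_order(g)
  w <- ex[, 2] - ex[, 1]
  cs <- cumsum(c(0, w))  # transcript start of each exon
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(ex))) {
    a <- max(t0, cs[i]); b <- min(t1, cs[i + 1])
    if (b <= a) next
    if (g$strand == "+") {
      out <- rbind(out, c(ex[i, 1] + (a - cs[i]), ex[i, 1] + (b - cs[i])))
    } else {
      out <- rbind(out, c(ex[i, 2] - (b - cs[i]), ex[i, 2] - (a - cs[i])))
    }
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("start", "end")
  out
}

#' Genomic footprint of the 3'-window of a transcript
#'
#' The window is the transcript interval whose distance from the 3' end lies
#' in `[window[1], window[2])`; for transcripts shorter than `window[2]` the
#' window is truncated at the 5' end, and it is empty when the transcript is
#' not longer than `window[1]`.
#'
#' @param g a `gene_model`.
#' @param window length-2 numeric, distances (bases) from the 3' end,
#'   half-open; default `c(100, 400)`.
#' @return two-column matrix of genomic intervals (possibly zero rows).
#' @export
three_prime_window_genomic <- function(g, window = c(100, 400)) {
  L <- transcript_length(g)
  t0 <- max(L - window[2], 0)
  t1 <- L - window[1]
  if (t1 <= t0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  project_to_genome(g, t0, t1)
}
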