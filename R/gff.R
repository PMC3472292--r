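#' Read a GFF3 annotation into a `genome_annotation`
#'
#' Parses gene/mRNA/exon/CDS (and optional five_prime_UTR/three_prime_UTR)
#' features, resolves the hierarchy through `Parent` attributes and converts
#' GFF's 1-based closed coordinates to the internal 0-based half-open
#' convention. Genes are treated as single-transcript: when a gene carries
#' several mRNAs, the first one in file order is used and a warning is
#' emitted. Contig lengths are taken from `##sequence-region` pragmas unless
#' supplied explicitly.
#'
#' @param path GFF3 file.
#' @param contig_lengths optional named numeric vector overriding/supplying
#'   contig lengths.
#' @return a [genome_annotation()].
#' @export
read_gff <- function(path, contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(contig_lengths)) {
    prag <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(prag)) {
      f <- strsplit(trimws(prag), "[ \t]+")
      contig_lengths <- stats::setNames(
        vapply(f, function(x) as.numeric(x[4]), 0),
        vapply(f, function(x) x[2], ""))
    } else {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (any(is.na(sl)))
        stop("contig lengths unavailable: no ##sequence-region pragma for ",
             paste(names(sl)[is.na(sl)], collapse = ", "),
             "; pass contig_lengths=")
      contig_lengths <- sl
    }
  }
  if (length(gr) == 0L)
    return(genome_annotation(contig_lengths))
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- if (is.null(gr$Parent)) rep(NA_character_, length(gr))
            else vapply(as.list(gr$Parent), function(p)
              if (length(p)) as.character(p[[1]]) else NA_character_, "")
  st <- GenomicRanges::start(gr) - 1  # to 0-based half-open
  en <- as.numeric(GenomicRanges::end(gr))
  ctg <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  gene_rows <- which(type == "gene")
  mrna_rows <- which(type == "mRNA")
  child <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  if (any(child & is.na(parent)))
    stop("malformed GFF hierarchy: ", type[child & is.na(parent)][1],
         " feature without Parent (feature ",
         paste(stats::na.omit(id[child & is.na(parent)])[1]), ")")

  genes <- list()
  for (gi in gene_rows) {
    gid <- id[gi]
    mr <- mrna_rows[parent[mrna_rows] == gid]
    if (length(mr) == 0L)
      stop("malformed GFF hierarchy: gene ", gid, " has no mRNA")
    if (length(mr) > 1L)
      warning("gene ", gid, ": ", length(mr),
              " mRNA isoforms; using the first")
    tid <- id[mr[1]]
    kids <- which(parent == tid)
    span0 <- function(tt) {
      rows <- kids[type[kids] == tt]
      if (!length(rows)) return(NULL)
      c(min(st[rows]), max(en[rows]))
    }
    ex_rows <- kids[type[kids] == "exon"]
    exons <- if (length(ex_rows)) cbind(st[ex_rows], en[ex_rows])
             else { cds_rows <- kids[type[kids] == "CDS"]
                    cbind(st[cds_rows], en[cds_rows]) }
    if (!nrow(exons))
      stop("malformed GFF hierarchy: mRNA ", tid, " has neither exon nor CDS")
    cds <- span0("CDS")
    if (is.null(cds)) cds <- c(min(exons[, 1]), max(exons[, 2]))
    genes[[length(genes) + 1L]] <- gene_model(
      gid, ctg[gi], strand[gi], exons, cds,
      utr5 = span0("five_prime_UTR"), utr3 = span0("three_prime_UTR"))
  }
  genome_annotation(contig_lengths, genes)
}

#' Write a `genome_annotation` as GFF3
#'
#' Emits `##sequence-region` pragmas and, per gene, gene/mRNA/exon lines,
#' per-exon CDS chunks and UTR features where UTR extents are set. Output
#' ordering is deterministic (contig, start, gene id), so write -> read ->
#' write is byte-identical.
#'
#' @param ann a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ct in sort(names(ann$contigs)))
    writeLines(sprintf("##sequence-region %s 1 %d", ct,
                       as.integer(ann$contigs[[ct]])), con)
  if (length(ann$genes)) {
    ord <- order(vapply(ann$genes, `[[`, "", "contig"),
                 vapply(ann$genes, function(g) g$exons[1, 1], 0),
                 vapply(ann$genes, `[[`, "", "gene_id"))
    fmt <- function(ct, tt, s0, e0, strand, attrs)
      sprintf("%s\tlmseq\t%s\t%d\t%d\t.\t%s\t.\t%s",
              ct, tt, as.integer(s0) + 1L, as.integer(e0), strand, attrs)
    for (g in ann$genes[ord]) {
      sp <- gene_span(g); tid <- paste0(g$gene_id, ".t1")
      lines <- c(
        fmt(g$contig, "gene", sp[1], sp[2], g$strand,
            paste0("ID=", g$gene_id)),
        fmt(g$contig, "mRNA", sp[1], sp[2], g$strand,
            paste0("ID=", tid, ";Parent=", g$gene_id)))
      for (i in seq_len(nrow(g$exons)))
        lines <- c(lines, fmt(g$contig, "exon", g$exons[i, 1], g$exons[i, 2],
                              g$strand, paste0("ID=", tid, ".exon", i,
                                               ";Parent=", tid)))
      # CDS emitted per exon chunk
      k <- 0L
      for (i in seq_len(nrow(g$exons))) {
        a <- max(g$exons[i, 1], g$cds[1]); b <- min(g$exons[i, 2], g$cds[2])
        if (b > a) {
          k <- k + 1L
          lines <- c(lines, fmt(g$contig, "CDS", a, b, g$strand,
                                paste0("ID=", tid, ".cds", k, ";Parent=", tid)))
        }
      }
      if (!is.null(g$utr5))
        lines <- c(lines, fmt(g$contig, "five_prime_UTR", g$utr5[1], g$utr5[2],
                              g$strand, paste0("ID=", tid, ".utr5;Parent=", tid)))
      if (!is.null(g$utr3))
        lines <- c(lines, fmt(g$contig, "three_prime_UTR", g$utr3[1], g$utr3[2],
                              g$strand, paste0("ID=", tid, ".utr3;Parent=", tid)))
      writeLines(lines, con)
    }
  }
  invisible(path)
}
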