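# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every rule character-by-character / base-by-base, sharing no code
# with the implementation.

# --- SAM fixture writer -----------------------------------------------------

write_sam_fixture <- function(path, contigs, qname, flag, rname, pos1, mapq,
                              cigar, seq = NULL, qual = NULL, tags = NULL) {
  n <- length(qname)
  if (is.null(seq)) {
    qlen <- vapply(cigar, function(cg) {
      nums <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
      ops <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
      sum(nums[ops %in% c("M", "I", "S")])
    }, 0L)
    seq <- vapply(qlen, function(k) paste(rep("A", k), collapse = ""), "")
  }
  if (is.null(qual)) qual <- vapply(nchar(seq), function(k)
    paste(rep("I", k), collapse = ""), "")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  rec <- paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, seq, qual,
               sep = "\t")
  if (!is.null(tags)) rec <- ifelse(nzchar(tags), paste(rec, tags, sep = "\t"),
                                    rec)
  writeLines(c(hdr, rec), path)
  path
}

# --- CIGAR walking oracle ---------------------------------------------------

cigar_blocks_oracle <- function(cigar, pos1) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  ref <- pos1 - 1
  blocks <- NULL
  bstart <- NA
  for (i in seq_along(ops)) {
    n <- nums[i]
    if (ops[i] %in% c("M", "D")) {
      if (is.na(bstart)) bstart <- ref
      ref <- ref + n
    } else if (ops[i] == "N") {
      if (!is.na(bstart)) blocks <- rbind(blocks, c(bstart, ref))
      bstart <- NA
      ref <- ref + n
    }
    # I and S consume the read only
  }
  if (!is.na(bstart)) blocks <- rbind(blocks, c(bstart, ref))
  blocks
}

random_cigar <- function() {
  k <- sample(1:4, 1)
  parts <- character(0)
  if (runif(1) < 0.2) parts <- c(parts, paste0(sample(1:10, 1), "S"))
  for (i in seq_len(k)) {
    parts <- c(parts, paste0(sample(1:80, 1), "M"))
    if (i < k) {
      op <- sample(c("N", "I", "D"), 1, prob = c(0.6, 0.2, 0.2))
      parts <- c(parts, paste0(sample(1:200, 1), op))
    }
  }
  if (runif(1) < 0.2) parts <- c(parts, paste0(sample(1:10, 1), "S"))
  paste(parts, collapse = "")
}

# --- read-cleaning reference ------------------------------------------------

clean_read_reference <- function(sequence, qualities, min_q = 10,
                                 min_len = 21) {
  if (any(strsplit(sequence, "")[[1]] == "N"))
    return(list(kept = FALSE, cause = "N"))
  q <- utf8ToInt(qualities) - 33L
  n <- length(q)
  while (n > 0 && q[n] < min_q) n <- n - 1
  if (n < min_len) return(list(kept = FALSE, cause = "too_short"))
  list(kept = TRUE, sequence = substr(sequence, 1, n),
       qualities = substr(qualities, 1, n))
}

random_read <- function(len_range = c(15, 60), n_prob = 0.1) {
  len <- sample(len_range[1]:len_range[2], 1)
  alph <- c("A", "C", "G", "T")
  if (runif(1) < n_prob) alph <- c(alph, "N")
  list(sequence = paste(sample(alph, len, replace = TRUE), collapse = ""),
       qualities = intToUtf8(sample(0:41, len, replace = TRUE) + 33L))
}

# --- both-ends counting oracle ----------------------------------------------

count_features_oracle <- function(aln, ann, min_read_len = 35) {
  counts <- stats::setNames(integer(length(ann$genes)), names(ann$genes))
  for (i in seq_len(nrow(aln$reads))) {
    r <- aln$reads[i, ]
    if (!r$is_primary || !r$is_unique || r$read_length < min_read_len) next
    hits <- character(0)
    for (g in ann$genes) {
      if (g$contig != r$contig) next
      in_exon <- function(p) any(p >= g$exons[, 1] & p < g$exons[, 2])
      if (in_exon(r$first0) && in_exon(r$last0))
        hits <- c(hits, g$gene_id)
    }
    if (length(hits) == 1L) counts[hits] <- counts[hits] + 1L
  }
  counts
}

# --- region classification oracle (per-base labelling) ----------------------

classify_regions_oracle <- function(aln, ann, min_read_len = 35) {
  out <- c(reads_exonic = 0L, reads_intronic = 0L, reads_intergenic = 0L,
           reads_ambiguous = 0L, reads_skipped_short = 0L)
  for (i in seq_len(nrow(aln$reads))) {
    r <- aln$reads[i, ]
    if (!r$is_primary) next
    if (r$read_length < min_read_len) {
      out["reads_skipped_short"] <- out["reads_skipped_short"] + 1L
      next
    }
    b <- aln$blocks[aln$blocks$read == i, , drop = FALSE]
    pos <- unlist(mapply(function(s, e) seq(s, e - 1), b$start, b$end,
                         SIMPLIFY = FALSE))
    lab <- rep("intergenic", length(pos))
    gene_bp <- numeric(0)
    for (g in ann$genes) {
      if (g$contig != r$contig) next
      sp <- c(g$exons[1, 1], g$exons[nrow(g$exons), 2])
      in_span <- pos >= sp[1] & pos < sp[2]
      if (any(in_span)) gene_bp[g$gene_id] <- sum(in_span)
      in_ex <- rep(FALSE, length(pos))
      for (k in seq_len(nrow(g$exons)))
        in_ex <- in_ex | (pos >= g$exons[k, 1] & pos < g$exons[k, 2])
      lab[in_ex] <- "exon"
      lab[in_span & !in_ex & lab == "intergenic"] <- "intron"
    }
    if (length(gene_bp) >= 2 && max(gene_bp) <= length(pos) / 2) {
      out["reads_ambiguous"] <- out["reads_ambiguous"] + 1L
      next
    }
    nb <- c(exon = sum(lab == "exon"), intron = sum(lab == "intron"),
            intergenic = sum(lab == "intergenic"))
    cat_r <- names(nb)[which.max(nb)]  # which.max keeps first => the tie order
    out[paste0("reads_", c(exon = "exonic", intron = "intronic",
                           intergenic = "intergenic")[cat_r])] <-
      out[paste0("reads_", c(exon = "exonic", intron = "intronic",
                             intergenic = "intergenic")[cat_r])] + 1L
  }
  out
}

# --- classical group oracle (the four printed criteria, literally) ----------

group_oracle <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  if (!length(r)) return(NA_integer_)
  m <- mean(r)
  cv <- stats::sd(r) / m
  if (all(r >= 4) || all(r <= 0.25)) return(4L)
  if (!is.na(cv) && cv < 0.5 && (m >= 4 || m <= 0.25)) return(3L)
  if (all(r >= 2) || all(r <= 0.5)) return(2L)
  if (!is.na(cv) && cv < 0.5 && (m >= 2 || m <= 0.5)) return(1L)
  0L
}

# --- junction enumeration oracle --------------------------------------------

junctions_oracle <- function(aln) {
  res <- list()
  for (i in seq_len(nrow(aln$reads))) {
    if (!aln$reads$is_primary[i] || !aln$reads$is_unique[i]) next
    b <- aln$blocks[aln$blocks$read == i, , drop = FALSE]
    if (nrow(b) < 2) next
    for (k in seq_len(nrow(b) - 1))
      res[[length(res) + 1]] <- c(aln$reads$contig[i], b$end[k],
                                  b$start[k + 1])
  }
  if (!length(res)) return(character(0))
  sort(vapply(res, paste, "", collapse = ":"))
}

# --- small fixtures ----------------------------------------------------------

two_gene_annotation <- function() {
  # geneA: + strand, two exons with a 100-base intron; geneB: - strand
  ga <- gene_model("geneA", "chr1", "+",
                   exons = rbind(c(100, 300), c(400, 650)),
                   cds = c(150, 600),
                   utr5 = c(100, 150), utr3 = c(600, 650))
  gb <- gene_model("geneB", "chr1", "-",
                   exons = rbind(c(1000, 1400)),
                   cds = c(1050, 1350),
                   utr5 = c(1350, 1400), utr3 = c(1000, 1050))
  genome_annotation(c(chr1 = 5000), list(ga, gb))
}

make_alignments <- function(reads_blocks, contig = "chr1",
                            contigs = c(chr1 = 5000), read_length = NULL,
                            is_unique = TRUE, is_primary = TRUE) {
  # reads_blocks: list of two-column matrices (0-based half-open)
  n <- length(reads_blocks)
  nb <- vapply(reads_blocks, nrow, 0L)
  bl <- do.call(rbind, reads_blocks)
  blocks <- data.frame(read = rep(seq_len(n), nb), start = bl[, 1],
                       end = bl[, 2])
  if (is.null(read_length))
    read_length <- vapply(reads_blocks, function(m) sum(m[, 2] - m[, 1]), 0)
  reads <- data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    contig = rep(contig, length.out = n), read_length = read_length,
    is_unique = rep(is_unique, length.out = n),
    is_primary = rep(is_primary, length.out = n),
    n_blocks = nb,
    first0 = vapply(reads_blocks, function(m) m[1, 1], 0),
    last0 = vapply(reads_blocks, function(m) m[nrow(m), 2] - 1, 0),
    stringsAsFactors = FALSE)
  lmseq:::new_alignments(reads, blocks, contigs)
}
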