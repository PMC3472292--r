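test_that("genome simulation is seeded-deterministic and respects gaps", {
  cfg <- sim_config(seed = 21, n_genes = 20, n_contigs = 2,
                    contig_length = 40000)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$expression, s2$truth$expression)
  # pairwise gaps >= intergenic_gap_min, exhaustively
  for (ct in names(s1$annotation$contigs)) {
    sp <- do.call(rbind, lapply(Filter(function(g) g$contig == ct,
                                       s1$annotation$genes), gene_span))
    sp <- sp[order(sp[, 1]), , drop = FALSE]
    if (nrow(sp) > 1)
      expect_true(all(sp[-1, 1] - sp[-nrow(sp), 2] >=
                        cfg$intergenic_gap_min))
  }
  # n_genes = 0 -> contigs only
  s0 <- simulate_genome(sim_config(seed = 1, n_genes = 0))
  expect_length(s0$annotation$genes, 0)
  expect_length(s0$annotation$contigs, 2)
  # genes that cannot fit raise a config error
  expect_error(simulate_genome(sim_config(seed = 1, n_genes = 50,
                                          n_contigs = 1,
                                          contig_length = 5000)),
               "do not fit")
})

test_that("simulated introns have canonical splice boundaries", {
  sim <- simulate_genome(sim_config(seed = 22, n_genes = 20, n_contigs = 1,
                                    contig_length = 60000,
                                    exons_per_gene = c(2, 3)))
  gseq <- as.character(sim$genome)
  for (g in sim$annotation$genes) {
    intr <- introns_of(g)
    for (k in seq_len(nrow(intr))) {
      don <- substring(gseq[[g$contig]], intr[k, 1] + 1, intr[k, 1] + 2)
      acc <- substring(gseq[[g$contig]], intr[k, 2] - 1, intr[k, 2])
      if (g$strand == "+") {
        expect_equal(don, "GT"); expect_equal(acc, "AG")
      } else {
        expect_equal(don, "CT"); expect_equal(acc, "AC")
      }
    }
  }
})

test_that("FASTQ and SAM record counts are conserved and runs are reproducible", {
  sim <- simulate_genome(sim_config(seed = 23, n_genes = 10, n_contigs = 1,
                                    contig_length = 30000,
                                    reads_per_sample = 3000))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fastq"); s1 <- file.path(d, "a.sam")
  r1 <- simulate_sample(sim, 1, 1, "uniform", f1, s1)
  expect_equal(nrow(read_fastq(f1)), r1$n_reads)
  aln <- read_sam(s1)
  expect_equal(sum(aln$reads$is_primary), r1$n_reads)
  f2 <- file.path(d, "b.fastq"); s2 <- file.path(d, "b.sam")
  simulate_sample(sim, 1, 1, "uniform", f2, s2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(s1), readLines(s2))
})

test_that("uniform bias gives uniform read starts; 3' bias clusters read ends", {
  # single intronless gene so transcript coordinates equal genomic offsets
  cfg <- sim_config(seed = 24, n_genes = 1, n_contigs = 1,
                    contig_length = 20000, exons_per_gene = c(1, 1),
                    cds_exon_length = c(2000, 2000),
                    utr5_length = c(1, 1), utr3_length = c(1, 1),
                    reads_per_sample = 5000, n_rate = 0, bias_decay = 800)
  sim <- simulate_genome(cfg)
  g <- sim$annotation$genes[[1]]
  L <- transcript_length(g)
  d <- withr::local_tempdir()
  simulate_sample(sim, 1, 1, "uniform", file.path(d, "u.fastq"),
                  file.path(d, "u.sam"))
  aln <- read_sam(file.path(d, "u.sam"))
  # transcript start offsets (gene strand-aware)
  t0 <- if (g$strand == "+") aln$reads$first0 - g$exons[1, 1]
        else g$exons[1, 2] - 1 - aln$reads$last0
  ks <- suppressWarnings(stats::ks.test(t0, "punif", 0,
                                        L - cfg$read_length))
  expect_gt(ks$p.value, 0.01)
  simulate_sample(sim, 1, 1, "three_prime", file.path(d, "t.fastq"),
                  file.path(d, "t.sam"))
  aln3 <- read_sam(file.path(d, "t.sam"))
  end3 <- if (g$strand == "+") aln3$reads$last0 - g$exons[1, 1] + 1
          else g$exons[1, 2] - aln3$reads$first0
  dist3 <- L - end3  # distance of the read 3' end from the transcript 3' end
  expect_gt(mean(dist3 <= 2 * cfg$bias_decay), 0.9)
})

test_that("intron-spanning reads get N CIGARs with the intron-length skip", {
  cfg <- sim_config(seed = 25, n_genes = 4, n_contigs = 1,
                    contig_length = 30000, exons_per_gene = c(2, 2),
                    reads_per_sample = 3000, n_rate = 0)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  simulate_sample(sim, 1, 1, "uniform", file.path(d, "x.fastq"),
                  file.path(d, "x.sam"))
  sam <- readLines(file.path(d, "x.sam"))
  sam <- sam[!startsWith(sam, "@")]
  spliced <- grep("N", sub(".*\t([0-9MIDNS]+)\t\\*.*", "\\1", sam),
                  value = FALSE)
  expect_gt(length(spliced), 0)
  intron_lens <- unlist(lapply(sim$annotation$genes, function(g) {
    iv <- introns_of(g); iv[, 2] - iv[, 1]
  }))
  for (i in utils::head(spliced, 50)) {
    cg <- strsplit(sam[i], "\t")[[1]][6]
    skip <- as.integer(sub(".*[M]([0-9]+)N.*", "\\1", cg))
    expect_true(skip %in% intron_lens)
  }
})

test_that("per-gene read counts recover true expression under uniform bias", {
  cfg <- sim_config(seed = 26, n_genes = 100, n_contigs = 4,
                    contig_length = 60000, reads_per_sample = 200000,
                    n_rate = 0)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  r <- simulate_sample(sim, 1, 1, "uniform", file.path(d, "e.fastq"),
                       file.path(d, "e.sam"))
  rho <- stats::cor(r$true_counts, sim$truth$expression[, 1],
                    method = "spearman")
  expect_gt(rho, 0.95)
  # and the counts actually recovered from the SAM agree with the draw
  aln <- read_sam(file.path(d, "e.sam"))
  origin <- sub("^s1\\.1:([^:]+):.*$", "\\1", aln$reads$read_id)
  tab <- table(factor(origin, levels = names(sim$annotation$genes)))
  expect_equal(as.integer(tab), unname(r$true_counts))
})

test_that("transcripts shorter than the read length yield truncated, flagged reads", {
  cfg <- sim_config(seed = 27, n_genes = 2, n_contigs = 1,
                    contig_length = 10000, exons_per_gene = c(1, 1),
                    cds_exon_length = c(20, 20), utr5_length = c(2, 2),
                    utr3_length = c(2, 2), read_length = 50,
                    reads_per_sample = 200, n_rate = 0)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  r <- simulate_sample(sim, 1, 1, "uniform", file.path(d, "t.fastq"),
                       file.path(d, "t.sam"))
  expect_equal(r$truncated, r$n_reads)
  fq <- read_fastq(file.path(d, "t.fastq"))
  expect_true(all(grepl(":T$", fq$read_id)))
  expect_true(all(nchar(fq$sequence) == 24))
})
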