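test_that("coverage counts match a brute-force per-read loop", {
  ann <- two_gene_annotation()
  # no reads -> all-zero track
  aln0 <- make_alignments(list(), contigs = c(chr1 = 5000))
  cov0 <- build_coverage(aln0, c(chr1 = 5000))
  expect_equal(sum(cov0$chr1), 0)
  # one 50M read -> exactly 50 bases at coverage 1
  aln1 <- make_alignments(list(cbind(120, 170)))
  cov1 <- build_coverage(aln1)
  expect_equal(sum(cov1$chr1 == 1), 50)
  expect_equal(sum(cov1$chr1), 50)
  expect_equal(which(cov1$chr1 == 1), 121:170)
  # fuzzed set vs brute force; splice skips contribute nothing
  set.seed(51)
  rb <- lapply(1:300, function(i) {
    s <- sample.int(4000, 1)
    if (runif(1) < 0.3) {
      gap <- sample(30:100, 1)
      rbind(c(s, s + 20), c(s + 20 + gap, s + 50 + gap))
    } else cbind(s, s + sample(20:60, 1))
  })
  aln <- make_alignments(rb)
  cov <- build_coverage(aln)
  brute <- integer(5000)
  for (m in rb) for (k in seq_len(nrow(m)))
    brute[(m[k, 1] + 1):m[k, 2]] <- brute[(m[k, 1] + 1):m[k, 2]] + 1L
  expect_equal(cov$chr1, brute)
  # non-unique / secondary alignments are not counted
  aln_nu <- make_alignments(list(cbind(10, 60)), is_unique = FALSE)
  expect_equal(sum(build_coverage(aln_nu)$chr1), 0)
  # block outside the contig errors
  aln_bad <- make_alignments(list(cbind(4990, 5040)))
  expect_error(build_coverage(aln_bad), "outside")
})

test_that("junction extraction aggregates distinct donor/acceptor pairs", {
  # unspliced reads only -> empty list
  aln_u <- make_alignments(list(cbind(10, 60), cbind(100, 150)))
  expect_equal(nrow(extract_junctions(aln_u)), 0)
  # three reads sharing one junction -> support 3
  spl <- rbind(c(0, 20), c(120, 150))
  aln_s <- make_alignments(list(spl, spl, spl))
  jx <- extract_junctions(aln_s)
  expect_equal(nrow(jx), 1)
  expect_equal(jx$donor_end, 20)
  expect_equal(jx$acceptor_start, 120)
  expect_equal(jx$support, 3)
  # fuzzed spliced reads: multiset equality with the gap-enumeration oracle
  set.seed(52)
  rb <- lapply(1:400, function(i) {
    s <- sample.int(3000, 1)
    nb <- sample(1:3, 1)
    w <- sample(10:40, nb, replace = TRUE)
    gaps <- sample(40:90, max(nb - 1, 0), replace = TRUE)
    starts <- s + cumsum(c(0, w[-nb] + gaps))
    cbind(starts, starts + w)
  })
  aln <- make_alignments(rb)
  jx <- extract_junctions(aln)
  got <- rep(paste(jx$contig, jx$donor_end, jx$acceptor_start, sep = ":"),
             jx$support)
  expect_equal(sort(got), junctions_oracle(aln))
})

test_that("UTR modelling walks coverage with gap tolerance and boundary stops", {
  ann <- strip_utrs(two_gene_annotation())
  # zero coverage -> no calls, all genes in the "none" category
  cov0 <- structure(list(chr1 = integer(5000)), class = "coverage_track")
  calls0 <- model_utrs(ann, cov0)
  expect_equal(nrow(calls0), 0)
  smry <- utr_summary(ann, calls0)
  expect_equal(smry$percent[smry$category == "none"], 100)
  # geneA (+): CDS [150, 600); true 3' UTR covers [600, 720) at 10x with a
  # 6-base hole; empty flanks beyond
  cov <- integer(5000)
  cov[151:720 + 0] <- 10
  cov[701:706] <- 0  # bridged: 6 <= max_gap
  covt <- structure(list(chr1 = cov), class = "coverage_track")
  calls <- model_utrs(ann, covt)
  c3 <- calls[calls$gene_id == "geneA" & calls$side == "3", ]
  expect_equal(nrow(c3), 1)
  expect_equal(c3$start, 600)
  expect_equal(c3$end, 720)
  # a gap larger than max_gap stops the walk
  cov2 <- cov
  cov2[651:662] <- 0  # 12 > max_gap
  calls2 <- model_utrs(ann, structure(list(chr1 = cov2),
                                      class = "coverage_track"))
  c32 <- calls2[calls2$gene_id == "geneA" & calls2$side == "3", ]
  expect_equal(c32$end, 650)
  # extension stops at a neighbouring gene boundary
  ga <- gene_model("gA", "chr1", "+", cbind(100, 300), c(100, 300))
  gb <- gene_model("gB", "chr1", "+", cbind(350, 500), c(350, 500))
  ann2 <- genome_annotation(c(chr1 = 5000), list(ga, gb))
  cov3 <- integer(5000)
  cov3[101:500] <- 10  # continuous coverage across the 50-base gap
  calls3 <- model_utrs(ann2, structure(list(chr1 = cov3),
                                       class = "coverage_track"))
  cA3 <- calls3[calls3$gene_id == "gA" & calls3$side == "3", ]
  expect_equal(nrow(cA3), 1)
  expect_lte(cA3$length, 50)
  expect_equal(cA3$end, 350)
})

test_that("applying UTR calls restores gene models that satisfy invariants", {
  ann_true <- two_gene_annotation()
  ann <- strip_utrs(ann_true)
  calls <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneB"),
    side = c("5", "3", "5", "3"), contig = "chr1",
    start = c(100, 600, 1350, 1000), end = c(150, 650, 1400, 1050),
    length = 50, mean_coverage = 10, stringsAsFactors = FALSE)
  ann2 <- apply_utr_calls(ann, calls)
  for (gid in names(ann_true$genes)) {
    expect_equal(unname(ann2$genes[[gid]]$exons),
                 unname(ann_true$genes[[gid]]$exons))
    expect_equal(ann2$genes[[gid]]$utr5, ann_true$genes[[gid]]$utr5)
    expect_equal(ann2$genes[[gid]]$utr3, ann_true$genes[[gid]]$utr3)
    validate_gene_model(ann2$genes[[gid]])
  }
})

test_that("junctions confirm, adjust and split gene models as specified", {
  ann <- two_gene_annotation()
  # junctions identical to all annotated introns -> fixed point
  jx0 <- data.frame(contig = "chr1", donor_end = 300, acceptor_start = 400,
                    support = 5, stringsAsFactors = FALSE)
  r0 <- refine_gene_models(ann, jx0)
  expect_equal(r0$report$tally$confirmed, 1)
  expect_equal(unname(r0$annotation$genes[["geneA"]]$exons),
               unname(ann$genes[["geneA"]]$exons))
  # shifted junction replaces the annotated intron [300,400) by [305,400)
  jx1 <- data.frame(contig = "chr1", donor_end = 305, acceptor_start = 400,
                    support = 5, stringsAsFactors = FALSE)
  r1 <- refine_gene_models(ann, jx1)
  expect_equal(r1$report$tally$adjusted, 1)
  expect_equal(unname(r1$annotation$genes[["geneA"]]$exons),
               cbind(c(100, 400), c(305, 650)))
  # subthreshold junctions change nothing
  jx1$support <- 1
  r1b <- refine_gene_models(ann, jx1)
  expect_equal(r1b$report$tally$subthreshold, 1)
  expect_equal(unname(r1b$annotation$genes[["geneA"]]$exons),
               unname(ann$genes[["geneA"]]$exons))
  # supported junction inside an exon splits it
  jx2 <- data.frame(contig = "chr1", donor_end = 1100,
                    acceptor_start = 1180, support = 4,
                    stringsAsFactors = FALSE)
  r2 <- refine_gene_models(ann, jx2)
  expect_equal(r2$report$tally$novel_internal, 1)
  expect_equal(unname(r2$annotation$genes[["geneB"]]$exons),
               cbind(c(1000, 1180), c(1100, 1400)))
  # intergenic junction -> candidate list only
  jx3 <- data.frame(contig = "chr1", donor_end = 800, acceptor_start = 900,
                    support = 9, stringsAsFactors = FALSE)
  r3 <- refine_gene_models(ann, jx3)
  expect_equal(r3$report$tally$outside, 1)
  expect_equal(nrow(r3$report$candidates), 1)
  # adjustment that would invert an exon is rejected, gene unchanged
  jx4 <- data.frame(contig = "chr1", donor_end = 90, acceptor_start = 400,
                    support = 9, stringsAsFactors = FALSE)
  r4 <- refine_gene_models(ann, jx4)
  expect_equal(r4$report$tally$rejected, 1)
  expect_equal(unname(r4$annotation$genes[["geneA"]]$exons),
               unname(ann$genes[["geneA"]]$exons))
})
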