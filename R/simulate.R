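#' Simulation configuration
#'
#' Parameters of the synthetic genome/experiment generator. Defaults emulate
#' the study design the pipeline targets: two biological replicates per
#' condition, single-end 50-base reads, one evenly covered ("mycelium-like")
#' condition and one condition with reads clustered towards transcript 3'
#' ends ("LM-like", emulating two rounds of linear RNA amplification).
#'
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @param n_contigs,contig_length number and length (bases) of contigs.
#' @param n_genes number of genes to place.
#' @param exons_per_gene,cds_exon_length,intron_length integer ranges
#'   (length-2) sampled per gene/exon/intron.
#' @param utr5_length,utr3_length integer ranges of true UTR lengths.
#' @param intergenic_gap_min minimum gap (bases) between placed genes.
#' @param n_conditions,replicates_per_condition experimental layout.
#' @param reads_per_sample expected library size per sample.
#' @param read_length single-end read length (bases).
#' @param bias_mode per-condition read-position bias, recycled over
#'   conditions: `"uniform"` or `"three_prime"`.
#' @param bias_decay exponential scale (bases) of the read 3'-end distance
#'   from the transcript 3' end under `three_prime` bias.
#' @param expr_meanlog,expr_sdlog log-normal parameters of per-gene
#'   expression (expected library share).
#' @param de_fraction fraction of genes differentially expressed between
#'   condition 1 and conditions 2+.
#' @param de_fold multiplicative fold change applied (up or down) to DE
#'   genes in conditions 2+.
#' @param noise `"poisson"` or `"nb"` per-gene read-count noise.
#' @param nb_dispersion negative-binomial dispersion (used when
#'   `noise = "nb"`); two biological replicates imply overdispersion, the
#'   Poisson default keeps small tests exact.
#' @param qual_baseline,qual_slope phred baseline and per-base 3'
#'   degradation of simulated qualities.
#' @param n_rate per-base probability of an undetermined (`N`) base.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L, contig_length = 60000L,
                       n_genes = 40L,
                       exons_per_gene = c(1L, 3L),
                       cds_exon_length = c(150L, 450L),
                       intron_length = c(60L, 150L),
                       utr5_length = c(40L, 150L),
                       utr3_length = c(60L, 250L),
                       intergenic_gap_min = 300L,
                       n_conditions = 2L,
                       replicates_per_condition = 2L,
                       reads_per_sample = 20000L,
                       read_length = 50L,
                       bias_mode = c("uniform", "three_prime"),
                       bias_decay = 150,
                       expr_meanlog = 4, expr_sdlog = 1,
                       de_fraction = 0.1, de_fold = 16,
                       noise = c("poisson", "nb"),
                       nb_dispersion = 0.05,
                       qual_baseline = 36, qual_slope = 0.15,
                       n_rate = 0.002) {
  noise <- match.arg(noise)
  cfg <- list(seed = as.integer(seed), n_contigs = n_contigs,
              contig_length = contig_length, n_genes = n_genes,
              exons_per_gene = exons_per_gene,
              cds_exon_length = cds_exon_length,
              intron_length = intron_length,
              utr5_length = utr5_length, utr3_length = utr3_length,
              intergenic_gap_min = intergenic_gap_min,
              n_conditions = n_conditions,
              replicates_per_condition = replicates_per_condition,
              reads_per_sample = reads_per_sample, read_length = read_length,
              bias_mode = bias_mode, bias_decay = bias_decay,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              de_fraction = de_fraction, de_fold = de_fold, noise = noise,
              nb_dispersion = nb_dispersion, qual_baseline = qual_baseline,
              qual_slope = qual_slope, n_rate = n_rate)
  rng <- c("exons_per_gene", "cds_exon_length", "intron_length",
           "utr5_length", "utr3_length")
  for (nm in rng) {
    v <- cfg[[nm]]
    if (length(v) != 2L || any(v <= 0) || v[2] < v[1])
      stop("bad range for ", nm)
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (cfg$read_length <= 0 || cfg$reads_per_sample <= 0)
    stop("read_length and reads_per_sample must be positive")
  structure(cfg, class = "sim_config")
}

sample_range <- function(rg, n = 1L) {
  if (rg[1] == rg[2]) rep(rg[1], n)
  else rg[1] + sample.int(rg[2] - rg[1] + 1L, n, replace = TRUE) - 1L
}

#' Simulate a genome with annotated genes and expression truth
#'
#' Places non-overlapping genes (minimum intergenic gap enforced) on random
#' DNA contigs. Each gene has UTRs of sampled lengths flanking a CDS whose
#' exons are separated by introns with canonical GT..AG boundaries
#' (strand-aware). Per-gene expression is log-normal; a `de_fraction` of
#' genes receives a `de_fold` change (direction random) in conditions 2+.
#' Expression is the gene's expected share of the sequenced library.
#'
#' @param config a [sim_config()].
#' @return an `lm_sim` list: `config`, `genome` (DNAStringSet),
#'   `annotation` ([genome_annotation()] with true UTRs), and `truth` with
#'   `expression` (gene x condition), `de` (gene_id, direction, fold) and
#'   `tx_length`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  ctg_names <- sprintf("contig_%02d", seq_len(config$n_contigs))
  seqs <- lapply(ctg_names, function(x)
    sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE))
  names(seqs) <- ctg_names
  contigs <- stats::setNames(rep(config$contig_length, config$n_contigs),
                             ctg_names)
  genes <- list()
  if (config$n_genes > 0) {
    cursor <- stats::setNames(rep(0, config$n_contigs), ctg_names)
    for (i in seq_len(config$n_genes)) {
      ct <- ctg_names[(i - 1L) %% config$n_contigs + 1L]
      gid <- sprintf("gene_%03d", i)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample_range(config$exons_per_gene)
      ex_len <- sample_range(config$cds_exon_length, n_ex)
      in_len <- if (n_ex > 1L) sample_range(config$intron_length, n_ex - 1L)
                else integer(0)
      u5 <- sample_range(config$utr5_length)
      u3 <- sample_range(config$utr3_length)
      gap <- config$intergenic_gap_min +
        sample.int(max(config$intergenic_gap_min, 1L), 1L)
      s <- cursor[[ct]] + gap
      # genomic-left-to-right component lengths
      u_left <- if (strand == "+") u5 else u3
      u_right <- if (strand == "+") u3 else u5
      ex_g <- if (strand == "+") ex_len else rev(ex_len)
      in_g <- if (strand == "+") in_len else rev(in_len)
      # exon intervals: first exon widened by u_left, last by u_right
      widths <- ex_g
      widths[1] <- widths[1] + u_left
      widths[n_ex] <- widths[n_ex] + u_right
      exon_start <- s + c(0, cumsum(widths[-n_ex] + in_g))
      exons <- cbind(exon_start, exon_start + widths)
      gend <- exons[n_ex, 2]
      if (gend > contigs[[ct]])
        stop("genes do not fit in contigs (", gid, " on ", ct, ")")
      cds <- c(s + u_left, gend - u_right)
      utr5 <- if (u5 > 0) {
        if (strand == "+") c(s, s + u5) else c(gend - u5, gend)
      }
      utr3 <- if (u3 > 0) {
        if (strand == "+") c(gend - u3, gend) else c(s, s + u3)
      }
      g <- gene_model(gid, ct, strand, exons, cds, utr5 = utr5, utr3 = utr3)
      # canonical splice boundaries on the forward strand:
      # "+": GT..AG, "-": CT..AC
      for (k in seq_len(nrow(introns_of(g)))) {
        iv <- introns_of(g)[k, ]
        don <- if (strand == "+") c("G", "T") else c("C", "T")
        acc <- if (strand == "+") c("A", "G") else c("A", "C")
        seqs[[ct]][(iv[1] + 1):(iv[1] + 2)] <- don
        seqs[[ct]][(iv[2] - 1):iv[2]] <- acc
      }
      genes[[length(genes) + 1L]] <- g
      cursor[[ct]] <- gend
    }
  }
  ann <- genome_annotation(contigs, genes)
  ng <- length(genes)
  base <- if (ng) stats::rlnorm(ng, config$expr_meanlog, config$expr_sdlog)
          else numeric(0)
  ids <- names(ann$genes)
  n_de <- round(config$de_fraction * ng)
  # DE genes come from the middle of the expression range: abundant enough
  # to be identifiable at the simulated depth, but not so abundant that a
  # 16-fold change shifts the library total (reads per sample are fixed, so
  # a dominant DE gene would compress every observed ratio)
  de_idx <- if (n_de > 0) {
    pool <- which(base >= stats::quantile(base, 0.2) &
                    base <= stats::quantile(base, 0.7))
    if (length(pool) < n_de) pool <- seq_len(ng)
    sort(sample(pool, n_de))
  } else integer(0)
  de_dir <- if (n_de > 0) sample(c(1, -1), n_de, replace = TRUE) else numeric(0)
  expr <- matrix(rep(base, config$n_conditions), ncol = config$n_conditions,
                 dimnames = list(ids, paste0("condition_",
                                             seq_len(config$n_conditions))))
  if (config$n_conditions > 1 && n_de > 0)
    expr[de_idx, -1] <- expr[de_idx, -1, drop = FALSE] *
      config$de_fold^de_dir
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  structure(list(
    config = config, genome = genome, annotation = ann,
    truth = list(
      expression = expr,
      de = data.frame(gene_id = ids[de_idx], direction = de_dir,
                      fold = rep(config$de_fold, n_de),
                      stringsAsFactors = FALSE),
      tx_length = stats::setNames(
        vapply(ann$genes, transcript_length, 0), ids))),
    class = "lm_sim")
}

# Truncated-exponential distance (integer bases) of the read 3' end from the
# transcript 3' end, support [0, L-1].
r_trunc_exp <- function(n, decay, L) {
  u <- stats::runif(n)
  d <- floor(-decay * log(1 - u * (1 - exp(-(L - 1) / decay))))
  pmin(d, L - 1)
}

#' Simulate one sequencing sample (FASTQ + SAM) from genome truth
#'
#' Draws reads per gene proportional to expression (Poisson or
#' negative-binomial noise). Read positions on the spliced transcript are
#' uniform (`bias_mode = "uniform"`) or have their 3'-end distance from the
#' transcript 3' end following a truncated exponential with scale
#' `bias_decay` (`bias_mode = "three_prime"`). Genomic alignments are
#' obtained by projecting through the exon chain, so intron-spanning reads
#' get multi-block SAM records with `N` skips; the SAM carries the true
#' alignment (no mapping stage). Qualities degrade towards the read 3' end
#' and `N` bases are injected at `n_rate`. Reads on transcripts shorter than
#' the read length are truncated to the transcript and flagged (`:T` suffix
#' in the read id).
#'
#' @param sim an `lm_sim` from [simulate_genome()].
#' @param condition,replicate sample coordinates (1-based).
#' @param bias_mode `"uniform"` or `"three_prime"`.
#' @param fastq,sam output paths.
#' @return invisibly, a list with `n_reads`, `true_counts` (named per-gene
#'   read-origin counts), `truncated` and the output paths.
#' @export
simulate_sample <- function(sim, condition, replicate,
                            bias_mode = c("uniform", "three_prime"),
                            fastq, sam) {
  bias_mode <- match.arg(bias_mode)
  cfg <- sim$config
  set.seed((cfg$seed * 97L + condition * 10007L + replicate * 101L +
              (bias_mode == "three_prime") * 7L) %% 2147483647L)
  ann <- sim$annotation
  ids <- names(ann$genes)
  expr <- sim$truth$expression[, condition]
  p <- expr / sum(expr)
  mu <- p * cfg$reads_per_sample
  n_g <- if (cfg$noise == "poisson") stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  genome_chr <- as.character(sim$genome)
  rl <- cfg$read_length
  qual_template <- phred_string(pmax(2, pmin(
    40, round(cfg$qual_baseline - cfg$qual_slope * (seq_len(rl) - 1)))))

  out_qn <- list(); out_rn <- list(); out_pos <- list(); out_cig <- list()
  out_seq <- list(); out_ql <- list()
  serial <- 0L
  truncated <- 0L
  for (gi in seq_along(ids)) {
    n <- n_g[gi]
    if (n == 0L) next
    g <- ann$genes[[gi]]
    L <- transcript_length(g)
    if (bias_mode == "uniform") {
      t1 <- if (L > rl) rl + sample.int(L - rl + 1L, n, replace = TRUE) - 1L
            else rep(L, n)
      t0 <- pmax(t1 - rl, 0)
    } else {
      d <- r_trunc_exp(n, cfg$bias_decay, L)
      t1 <- L - d
      t0 <- pmax(t1 - rl, 0)
    }
    truncated <- truncated + sum(t1 - t0 < rl)
    ex <- exons_tx_order(g)
    w <- ex[, 2] - ex[, 1]
    cs <- cumsum(c(0, w))
    i0 <- findInterval(t0, cs, rightmost.closed = FALSE)
    i1 <- findInterval(t1 - 1, cs, rightmost.closed = FALSE)
    gseq <- genome_chr[[g$contig]]
    ids_r <- sprintf("s%d.%d:%s:%d:%06d%s", condition, replicate, g$gene_id,
                     t0, serial + seq_len(n), ifelse(t1 - t0 < rl, ":T", ""))
    serial <- serial + n
    single <- i0 == i1
    starts <- numeric(n)
    cigars <- character(n)
    seqs_r <- character(n)
    if (any(single)) {
      j <- i0[single]
      a <- t0[single]; b <- t1[single]
      if (g$strand == "+") {
        gs <- ex[j, 1] + (a - cs[j]); ge <- ex[j, 1] + (b - cs[j])
      } else {
        gs <- ex[j, 2] - (b - cs[j]); ge <- ex[j, 2] - (a - cs[j])
      }
      starts[single] <- gs
      cigars[single] <- paste0(b - a, "M")
      seqs_r[single] <- substring(gseq, gs + 1, ge)
    }
    for (r in which(!single)) {
      iv <- project_to_genome(g, t0[r], t1[r])
      bw <- iv[, 2] - iv[, 1]
      gaps <- iv[-1, 1] - iv[-nrow(iv), 2]
      cigars[r] <- paste0(paste0(bw, "M", c(paste0(gaps, "N"), "")),
                          collapse = "")
      starts[r] <- iv[1, 1]
      seqs_r[r] <- paste0(substring(gseq, iv[, 1] + 1, iv[, 2]),
                          collapse = "")
    }
    # N injection
    lens <- t1 - t0
    nN <- stats::rbinom(n, lens, cfg$n_rate)
    for (r in which(nN > 0)) {
      posN <- sample.int(lens[r], nN[r])
      sr <- strsplit(seqs_r[r], "")[[1]]
      sr[posN] <- "N"
      seqs_r[r] <- paste0(sr, collapse = "")
    }
    out_qn[[length(out_qn) + 1L]] <- ids_r
    out_rn[[length(out_rn) + 1L]] <- rep(g$contig, n)
    out_pos[[length(out_pos) + 1L]] <- starts + 1  # SAM is 1-based
    out_cig[[length(out_cig) + 1L]] <- cigars
    out_seq[[length(out_seq) + 1L]] <- seqs_r
    out_ql[[length(out_ql) + 1L]] <- substring(qual_template, 1, lens)
  }
  qn <- unlist(out_qn); rn <- unlist(out_rn); pos1 <- unlist(out_pos)
  cig <- unlist(out_cig); sq <- unlist(out_seq); ql <- unlist(out_ql)
  # SAM
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", sort(names(ann$contigs)),
                   as.integer(ann$contigs[sort(names(ann$contigs))])))
  rec <- sprintf("%s\t0\t%s\t%d\t50\t%s\t*\t0\t0\t%s\t%s\tNH:i:1",
                 qn, rn, as.integer(pos1), cig, sq, ql)
  writeLines(c(hdr, rec), sam)
  write_fastq(data.frame(read_id = qn, sequence = sq, qualities = ql,
                         stringsAsFactors = FALSE), fastq)
  invisible(list(n_reads = length(qn),
                 true_counts = stats::setNames(n_g, ids),
                 truncated = truncated, fastq = fastq, sam = sam))
}

#' Simulate a full experiment to disk
#'
#' Runs [simulate_genome()] and [simulate_sample()] for every
#' condition/replicate, writing: `genome.fa`, `annotation.gff3` (truth, with
#' UTRs), `annotation_noutr.gff3` (UTR-stripped variant used as input for
#' UTR-recovery), `expression.tsv`, `de_genes.tsv`, `true_counts.tsv`,
#' `samples.tsv` and per-sample `sample_c<cond>_r<rep>.{fastq,sam}`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @param samples optional data.frame (`condition`, `replicate`,
#'   `bias_mode`) overriding the default layout, where `bias_mode` is the
#'   config's `bias_mode` recycled over conditions.
#' @return invisibly, a list with the `lm_sim` object, the sample sheet and
#'   file paths.
#' @export
simulate_experiment <- function(config, outdir, samples = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  if (is.null(samples)) {
    bias <- rep(config$bias_mode, length.out = config$n_conditions)
    samples <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                           condition = seq_len(config$n_conditions))
    samples <- samples[, c("condition", "replicate")]
    samples$bias_mode <- bias[samples$condition]
  }
  samples$sample_id <- sprintf("c%d_r%d", samples$condition,
                               samples$replicate)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_gff(sim$annotation, p("annotation.gff3"))
  write_gff(strip_utrs(sim$annotation), p("annotation_noutr.gff3"))
  utils::write.table(data.frame(gene_id = rownames(sim$truth$expression),
                                sim$truth$expression, check.names = FALSE),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$de, p("de_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tc <- NULL
  for (i in seq_len(nrow(samples))) {
    res <- simulate_sample(sim, samples$condition[i], samples$replicate[i],
                           samples$bias_mode[i],
                           fastq = p(paste0("sample_", samples$sample_id[i],
                                            ".fastq")),
                           sam = p(paste0("sample_", samples$sample_id[i],
                                          ".sam")))
    tc <- cbind(tc, res$true_counts)
  }
  if (!is.null(tc)) {
    colnames(tc) <- samples$sample_id
    utils::write.table(data.frame(gene_id = rownames(tc), tc,
                                  check.names = FALSE),
                       p("true_counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(samples, p("samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(sim = sim, samples = samples, dir = outdir))
}

#' Simulate a count matrix with known differential expression
#'
#' Count-level generator for the DE-only entry point: per-gene expected
#' counts are log-normal, a fraction of genes get a fold change (random
#' direction) in conditions 2+, and observed counts are Poisson or
#' negative-binomial draws. DE genes' baseline expectation is drawn between
#' `min_de_expected` and `5/3 * min_de_expected`: at least `min_de_expected`
#' so the signal is identifiable at the simulated depth, and bounded above
#' so the DE genes never dominate the library total — normalisation to total
#' counted reads compresses observed fold changes when a large share of the
#' library is differentially expressed.
#'
#' @param n_genes,n_conditions,replicates layout.
#' @param mean_count median expected count of a gene.
#' @param sdlog log-normal spread of expected counts.
#' @param de_fraction,de_fold DE truth (fold applied in conditions 2+).
#' @param min_de_expected floor on DE genes' baseline expected count.
#' @param noise,dispersion `"poisson"` or `"nb"` with dispersion.
#' @param seed RNG seed.
#' @return list with `counts` (gene x sample integer matrix, samples named
#'   `c<cond>_r<rep>`), `condition` (per-sample condition), and `truth`
#'   (data.frame `gene_id`, `de`, `direction`).
#' @export
simulate_count_matrix <- function(n_genes = 200, n_conditions = 2,
                                  replicates = 2, mean_count = 600,
                                  sdlog = 0.5, de_fraction = 0.1,
                                  de_fold = 16, min_de_expected = 300,
                                  noise = c("poisson", "nb"),
                                  dispersion = 0.05, seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  ids <- sprintf("gene_%03d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, log(mean_count), sdlog)
  n_de <- round(de_fraction * n_genes)
  de_idx <- sort(sample.int(n_genes, n_de))
  dir <- sample(c(1, -1), n_de, replace = TRUE)
  base[de_idx] <- min_de_expected * stats::runif(n_de, 1, 5 / 3)
  mu <- matrix(rep(base, n_conditions), ncol = n_conditions)
  if (n_conditions > 1)
    mu[de_idx, -1] <- mu[de_idx, -1, drop = FALSE] * de_fold^dir
  cond <- rep(seq_len(n_conditions), each = replicates)
  counts <- sapply(seq_along(cond), function(s) {
    m <- mu[, cond[s]]
    if (noise == "poisson") stats::rpois(n_genes, m)
    else stats::rnbinom(n_genes, mu = m, size = 1 / dispersion)
  })
  colnames(counts) <- sprintf("c%d_r%d", cond,
                              unlist(lapply(seq_len(n_conditions),
                                            function(i) seq_len(replicates))))
  rownames(counts) <- ids
  truth <- data.frame(gene_id = ids, de = seq_len(n_genes) %in% de_idx,
                      direction = 0, stringsAsFactors = FALSE)
  truth$direction[de_idx] <- dir
  list(counts = counts, condition = cond, truth = truth)
}
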