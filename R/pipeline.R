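#' Default end-to-end pipeline configuration
#'
#' A compact synthetic study: two conditions (condition 1 evenly covered,
#' mycelium-like; condition 2 with 3'-clustered reads, LM-like), two
#' biological replicates each, and one LM-vs-mycelium comparison evaluated
#' at the stringent eightfold consensus threshold (the fourfold set is meant
#' for within-tissue comparisons).
#'
#' @param seed integer seed propagated to every stage.
#' @param ... overrides passed to [sim_config()].
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  structure(list(
    sim = sim_config(seed = seed, ...),
    comparisons = list(list(name = "lm_vs_mycelium", a = 2L, b = 1L,
                            threshold_set = "eightfold")),
    clean = list(min_q = 10, min_len_keep = 21),
    refine = list(min_cov = 2, max_gap = 10, max_extent = 2000,
                  min_support = 2),
    count = list(min_read_len = 35, window = c(100, 400)),
    de = list(n_draws = 10000, p_min = 0.999),
    report = list(top_n = 20, k_max = 3)),
    class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> clean -> annotation refinement (pooled coverage and
#' junctions) -> counting (full-length, 3'-window, region tally) ->
#' normalisation -> classical/Bayesian/consensus differential expression ->
#' reports (top-N overlap, expression-level mixture), writing every table
#' under `outdir` plus a `manifest.json` with parameters, seed and file
#' checksums. Deterministic: the same config yields byte-identical outputs.
#'
#' @param config a [default_pipeline_config()].
#' @param outdir output directory.
#' @param sim_dir optional directory with pre-existing inputs (the layout of
#'   [simulate_experiment()]: `samples.tsv`, `annotation.gff3`, per-sample
#'   FASTQ/SAM); when given, the simulation stage is skipped and the files
#'   are ingested as external data.
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config, outdir, sim_dir = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  p <- function(f) file.path(outdir, f)

  sim <- NULL
  if (is.null(sim_dir)) {
    sim_dir <- file.path(outdir, "sim")
    ex <- stage("simulate", simulate_experiment(config$sim, sim_dir))
    samples <- ex$samples
    sim <- ex$sim
    ann_true <- sim$annotation
  } else {
    samples <- stage("config", {
      f <- file.path(sim_dir, "samples.tsv")
      if (!file.exists(f)) stop("no samples.tsv in ", sim_dir)
      utils::read.delim(f)
    })
    ann_true <- stage("config",
                      read_gff(file.path(sim_dir, "annotation.gff3")))
  }

  # cleaning reports (mapping is bypassed downstream; the cleaned FASTQs
  # document the raw-read QC stage)
  clean_rows <- stage("clean", {
    do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      sid <- samples$sample_id[i]
      fq <- file.path(sim_dir, paste0("sample_", sid, ".fastq"))
      rep <- clean_fastq(fq, p(paste0("cleaned_", sid, ".fastq")),
                         min_q = config$clean$min_q,
                         min_len_keep = config$clean$min_len_keep)
      data.frame(sample_id = sid, input = rep$input, kept = rep$kept,
                 discarded_n = rep$discarded_n,
                 discarded_short = rep$discarded_short,
                 bases_trimmed = rep$bases_trimmed)
    }))
  })
  write_tsv(clean_rows, p("cleaning_report.tsv"))

  alns <- stage("ingest", {
    lapply(stats::setNames(samples$sample_id, samples$sample_id),
           function(sid) {
             sam <- file.path(sim_dir, paste0("sample_", sid, ".sam"))
             if (!file.exists(sam))
               stop("missing SAM for declared sample ", sid)
             read_sam(sam)
           })
  })

  refined <- stage("refine", {
    ann0 <- strip_utrs(ann_true)
    # evidence pooled across all samples
    pooled <- new_alignments(
      do.call(rbind, lapply(alns, function(a) a$reads)),
      {
        off <- cumsum(c(0, utils::head(vapply(alns, function(a)
          nrow(a$reads), 0L), -1)))
        do.call(rbind, Map(function(a, o) {
          b <- a$blocks; b$read <- b$read + o; b
        }, alns, off))
      },
      alns[[1]]$contigs)
    cov <- build_coverage(pooled)
    jx <- extract_junctions(pooled)
    calls <- model_utrs(ann0, cov, min_cov = config$refine$min_cov,
                        max_gap = config$refine$max_gap,
                        max_extent = config$refine$max_extent)
    ann1 <- apply_utr_calls(ann0, calls)
    rf <- refine_gene_models(ann1, jx,
                             min_support = config$refine$min_support)
    write_gff(rf$annotation, p("annotation_refined.gff3"))
    write_tsv(jx, p("junctions.tsv"))
    write_tsv(calls, p("utr_calls.tsv"))
    write_tsv(utr_summary(ann0, calls), p("utr_summary.tsv"))
    list(ann = rf$annotation, cov = cov, jx = jx, calls = calls,
         report = rf$report, pooled = pooled)
  })

  counts <- stage("count", {
    cm <- count_matrix(lapply(alns, function(a)
      count_features(a, refined$ann,
                     min_read_len = config$count$min_read_len)))
    cm3 <- count_matrix(lapply(alns, function(a)
      count_3prime_window(a, refined$ann, window = config$count$window)))
    regions <- do.call(rbind, lapply(names(alns), function(sid) {
      t <- classify_regions(alns[[sid]], refined$ann,
                            min_read_len = config$count$min_read_len)
      data.frame(sample_id = sid, unclass(t))
    }))
    write_counts(cm, p("counts.tsv"))
    write_counts(cm3, p("counts_3p.tsv"))
    write_tsv(regions, p("regions.tsv"))
    list(cm = cm, cm3 = cm3, regions = regions)
  })

  de <- stage("diffexpr", {
    norm <- normalize_counts(counts$cm)
    write_tsv(data.frame(gene_id = rownames(norm), norm,
                         check.names = FALSE), p("normalized.tsv"))
    lapply(config$comparisons, function(cp) {
      sa <- samples$sample_id[samples$condition == cp$a]
      sb <- samples$sample_id[samples$condition == cp$b]
      if (!length(sa) || !length(sb))
        stop("comparison ", cp$name, " references an unknown condition")
      cl <- classical_analysis(norm, sa, sb)
      by <- bayes_ratio(counts$cm$counts[, sa, drop = FALSE],
                        counts$cm$counts[, sb, drop = FALSE],
                        counts$cm$totals[sa], counts$cm$totals[sb],
                        n_draws = config$de$n_draws,
                        seed = config$sim$seed + 31L)
      cs <- consensus_call(cl, by, cp$threshold_set,
                           p_min = config$de$p_min)
      tab <- merge(merge(cl, by, by = "gene_id", all.x = TRUE),
                   cs[, c("gene_id", "call")], by = "gene_id")
      tab <- tab[order(tab$gene_id), ]
      write_tsv(tab, p(paste0("de_", cp$name, ".tsv")))
      ma <- ma_table(rowMeans(norm[, sa, drop = FALSE]),
                     rowMeans(norm[, sb, drop = FALSE]),
                     gene_id = rownames(norm))
      write_tsv(ma, p(paste0("ma_", cp$name, ".tsv")))
      list(name = cp$name, classical = cl, bayes = by, consensus = cs,
           ma = ma)
    })
  })

  reports <- stage("report", {
    norm3 <- normalize_counts(counts$cm3)
    cond <- stats::setNames(paste0("condition_", samples$condition),
                            samples$sample_id)
    top <- top_n_sets(norm3, cond, n = min(config$report$top_n,
                                           nrow(norm3)))
    write_tsv(top$venn, p("venn_top_n.tsv"))
    write_tsv(data.frame(gene_id = rownames(top$membership),
                         top$membership, check.names = FALSE),
              p("top_n_membership.tsv"))
    total_bases <- sum(refined$pooled$blocks$end -
                         refined$pooled$blocks$start)
    lv <- expression_levels(refined$cov, refined$ann, total_bases)
    dist <- expression_distribution(lv, k_max = config$report$k_max)
    write_tsv(data.frame(gene_id = names(lv), level = lv,
                         log2_level = ifelse(lv > 0, log2(lv), NA)),
              p("expression_levels.tsv"))
    write_tsv(data.frame(component = seq_len(dist$fit$k),
                         weight = dist$fit$weights, mean = dist$fit$means,
                         variance = dist$fit$variances),
              p("mixture_fit.tsv"))
    list(top = top, dist = dist)
  })

  manifest <- stage("manifest", {
    files <- sort(list.files(outdir, recursive = TRUE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(outdir, files))
    m <- list(package = "lmseq",
              version = as.character(utils::packageVersion("lmseq")),
              seed = config$sim$seed,
              parameters = config[c("clean", "refine", "count", "de",
                                    "report")],
              sim = unclass(config$sim),
              checksums = as.list(stats::setNames(unname(sums), files)))
    jsonlite::write_json(m, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    m
  })

  invisible(list(sim = sim, samples = samples, refined = refined,
                 counts = counts, de = de, reports = reports,
                 manifest = manifest))
}
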