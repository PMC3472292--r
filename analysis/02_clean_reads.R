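#!/usr/bin/env Rscript
# Stage 2 — raw-read cleaning.
#
# Reads with undetermined bases are dropped; 3'-terminal bases with phred
# quality below 10 are trimmed consecutively; only reads longer than 20 bases
# after trimming are kept. The simulated qualities degrade towards the 3'
# end, so the trimming mostly nibbles read tails.

library(lmseq)

outdir <- "results/analysis"
samples <- read.delim(file.path(outdir, "sim", "samples.tsv"))

rows <- lapply(samples$sample_id, function(sid) {
  rep <- clean_fastq(file.path(outdir, "sim",
                               paste0("sample_", sid, ".fastq")),
                     file.path(outdir, paste0("cleaned_", sid, ".fastq")))
  data.frame(sample_id = sid, input = rep$input, kept = rep$kept,
             discarded_n = rep$discarded_n,
             discarded_short = rep$discarded_short,
             bases_trimmed = rep$bases_trimmed)
})
report <- do.call(rbind, rows)
write.table(report, file.path(outdir, "cleaning_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

stopifnot(report$input == report$kept + report$discarded_n +
            report$discarded_short)
cat("Cleaning report:\n")
print(report, row.names = FALSE)
cat(sprintf("Overall %.1f%% of reads kept; %.1f%% dropped for N bases.\n",
            100 * sum(report$kept) / sum(report$input),
            100 * sum(report$discarded_n) / sum(report$input)))
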