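# lmseq

RNA-seq analysis for laser-microdissected (LM) tissue, where the RNA of a
few excised cells must be linearly amplified before sequencing. Two rounds
of T7-based amplification progressively lose transcript 5' ends, so read
coverage clusters towards the 3' end of most transcripts. That geometry
breaks two assumptions ordinary RNA-seq pipelines make: that reads sample
the whole transcript (so full-length counts are comparable across
libraries), and that the annotation's gene extents capture where reads
fall (3'-biased reads pile into unannotated 3' UTRs and are lost to
strict counting). `lmseq` implements a quantification chain built for this
regime, developed around fungal fruiting-body development where the
structures of interest (protoperithecia, ~20 µm) can only be obtained by
microdissection. Everything is exercised end to end on seeded synthetic
data with known ground truth.

## What it does

1. **Read cleaning** — reads containing undetermined bases (`N`) are
   removed; 3'-terminal bases with phred quality < 10 are trimmed
   consecutively (stopping at the first good base); reads longer than 20
   bases are kept.
2. **Annotation refinement** — per-base coverage and splice junctions are
   built from the alignments (`M`/`D` extend reference blocks, `N` splits
   them). UTRs are modelled by walking outward from each CDS terminus while
   coverage ≥ 2, bridging gaps ≤ 10 bases, up to 2 kb or the nearest
   neighbouring gene. Junctions confirm annotated introns, replace shifted
   intron boundaries (support ≥ 2), or split exons containing novel
   introns.
3. **Quantification** — stringent both-ends counting: a read (> 34 bases,
   primary, unique) counts for a gene only if *both* terminal aligned bases
   lie in that gene's exons (UTRs included). A 3'-window variant counts
   only reads whose ends fall 100–400 bases from the transcript 3' end —
   counts that are independent of transcript length and robust to
   amplification bias. Counts are normalised to counts per million counted
   reads.
4. **Differential expression** — two routes that must agree:
   - *classical analysis*: per-replicate normalised ratios `r_i = A_i/B_i`,
     their mean, SD and CV, and stringency groups — group 4: all `r_i ≥ 4`
     or all `≤ 0.25`; group 3: mean beyond 4-fold and CV < 0.5; group 2:
     all beyond 2-fold; group 1: mean beyond 2-fold and CV < 0.5;
   - *Bayesian ratio*: pooled counts with library totals as exposures give
     gamma posteriors `λ ~ Gamma(Σk + ½, Σtotal)`; Monte-Carlo draws of
     `λ_A/λ_B` yield the posterior mean ratio, 95% credible interval and
     `p_diff = max(P(r>1), P(r<1))`.
   A consensus call (±1) requires both mean ratios beyond the threshold
   (4-fold for within-tissue comparisons, 8-fold for LM vs. ordinary
   libraries), `p_diff ≥ 0.999` and classical group 1–4.
5. **Reports** — top-N most abundant genes per condition from 3'-window
   counts with Venn-style overlap cells; MA tables with zero-count
   conventions `M = ±20`; per-gene expression levels (coverage per kilobase
   per million aligned bases) decomposed into Gaussian components by EM
   with BIC selection.

A seeded generator (`simulate_genome()`, `simulate_sample()`,
`simulate_count_matrix()`) produces genomes, annotations (with UTR and
intron truth), and FASTQ/SAM samples with configurable 3' bias, expression
levels, fold changes and replicates, so every stage is testable against
ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R` … `06_report.R`, tables land in
`results/analysis/`). The same flow in a session:

```r
library(lmseq)

cfg <- sim_config(seed = 42, n_genes = 60, n_contigs = 3,
                  contig_length = 60000, reads_per_sample = 30000,
                  qual_slope = 0.6)
ex  <- simulate_experiment(cfg, "sim")          # FASTA, GFF3, FASTQ, SAM
rep <- clean_fastq("sim/sample_c1_r1.fastq", "clean.fastq")
rep
#> cleaning_report: 30083 in, 27269 kept, 2814 with N, 0 too short, 136345 bases trimmed

aln  <- read_sam("sim/sample_c2_r1.sam")        # LM-like, 3'-biased sample
ann0 <- read_gff("sim/annotation_noutr.gff3")   # UTR-less starting annotation
cov  <- build_coverage(aln)
ann  <- apply_utr_calls(ann0, model_utrs(ann0, cov))
cnt  <- count_features(aln, ann)                # both-ends counts
w3   <- count_3prime_window(aln, ann)           # bias-robust 3'-window counts
```

On this dataset the pipeline recovers all six simulated 16-fold genes at
the eightfold consensus with zero false positives among the 54 null genes
(`analysis/05_differential_expression.R` prints `recovered: 6; false: 0`),
and the intron-junction evidence confirms all 62 annotated introns
(`analysis/03_refine_annotation.R`).

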