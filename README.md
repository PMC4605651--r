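# ighseq

Molecular-barcoded B-cell receptor heavy chain (IGH) repertoire sequencing
analysis, for labs monitoring the net state of immunosuppression — for
example after heart transplantation, where clinicians must balance drug
dosing against rejection risk with little direct readout of immune
activity.

Activated B cells express IGH transcripts that differ from naive B cells in
three measurable ways: isotype class switch (IgM → IgG/IgA/IgE), somatic
hypermutation in the V segment, and much higher expression. `ighseq`
quantifies this signal from paired-end reads carrying a 16-nt unique
molecular identifier (UID, 8 nt contributed by each primer):

1. reads are grouped by UID — one group per original transcript molecule —
   and error-corrected by per-position majority vote (coverage ≥ 2);
2. consensus pairs are annotated by local alignment: V segment and mutation
   rate from the forward read, isotype from the reverse read;
3. each sample is subsampled to a fixed depth of 4,000 aligned molecules
   and collapsed into clones (identical forward consensus + isotype);
4. the **ABS level** (activated B cell sequence level) is computed:

   ABS = (# highly expressed clones that are class-switched or mutated IgM) / (total molecules),

   where "highly expressed" means represented by more than one molecule;
5. cohort statistics relate ABS to clinical metadata: Pearson correlation
   with tacrolimus trough level (Fisher r-to-z CI), one-sided Mann-Whitney
   tests between rejection categories, ROC c-statistics against cfdDNA- and
   biopsy-defined rejection (percentile bootstrap CIs),
   sensitivity/specificity/PPV/NPV at a fixed ABS threshold with
   continuity-corrected Wilson intervals, and exponential fits
   y = a·exp(b·t) of pre-rejection ABS dynamics.

A ground-truth repertoire simulator (references, clones, UIDs, reads,
sequencing error) makes every stage testable without external data.

## Worked example

```r
library(ighseq)

refs  <- make_germline_refs(n_v = 6, v_len = 80, seed = 42)
cfg   <- sim_config(n_clones = 5400, seed = 7)    # ~6,000 molecules
truth <- sample_true_repertoire(cfg, refs)
reads <- synthesize_reads(truth, cfg)             # ~30,000 read pairs
res   <- process_sample(reads, refs, pipeline_config(), sample_id = "S1")
res$summary
```

```
Repertoire summary for S1
  molecules: 4000  clones: 3532  highly expressed: 278
  ABS level: 160/4000 = 0.0400
```

Of the 4,000 molecules kept after depth standardisation, 3,532 distinct
clones were observed; 278 clones had two or more molecules, and 160 of
those were class-switched or mutated IgM — an ABS level of 0.040. (The
depth-matched ground truth for this simulated sample is
`true_abs_level(truth, depth = 4000)` = 0.0223; the gap is the documented
upward bias from sequencing errors inside the molecular barcode, which is
constant across samples and cancels in between-sample comparisons — see the
methods vignette.)

The cohort path mirrors a longitudinal monitoring study:

```r
design <- simulate_cohort_design(seed = 500)       # 12 patients, 6 rejectors
base   <- sim_config(n_clones = 2000)
# write FASTQ per sample with simulate_cohort_sample() + write_paired_fastq(),
# then:
st <- run_pipeline(pipeline_config(subsample_depth = 1500),
                   samples, refs, metadata, "out/")
st
```

```
Cohort statistics over 72 samples
  ABS vs tacrolimus: r = -0.293 (95% CI -0.492 to -0.066, n = 72)
  mod_severe_ACR vs none: U = 180.0, one-sided p = 2.518e-05 (exact)
  elevated_cfdDNA vs none: U = 360.0, one-sided p = 1.101e-08 (exact)
  vs cfdDNA: c-statistic = 1.000 (95% bootstrap CI 1.000 to 1.000; 6+/66-)
  vs biopsy: c-statistic = 0.976 (95% bootstrap CI 0.927 to 1.000; 3+/62-)
  pre-rejection trend: Exponential fit y = a*exp(b*t): a = 0.05596, b = 0.002306 (RSS 0.000855, n = 28)
```

Samples inside a planted rejection window have elevated ABS levels, which
the ROC against cfdDNA-defined rejection separates cleanly; the
pre-rejection fit recovers the rising exponential trend leading into the
events. A thin command-line wrapper with `simulate` and `run` subcommands
is installed at `inst/scripts/ighseq.R`.

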