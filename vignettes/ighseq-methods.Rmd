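---
title: "Measuring immunosuppression from barcoded IGH repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring immunosuppression from barcoded IGH repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighseq)
```

## The measurement problem

Pharmacological immunosuppression after organ transplantation is steered
almost blindly: drug trough levels say more about toxicity than about how
suppressed the recipient's immune system actually is. The B-cell compartment
offers a direct readout. When a B cell is activated it switches isotype
(IgM to IgG/IgA/IgE), accumulates somatic hypermutation in the V region of
its IGH transcript, and expresses that transcript at much higher levels.
A suppressed immune system therefore shows fewer highly expressed,
class-switched, mutated IGH sequences in circulation.

`ighseq` implements the full measurement chain for this signal from
molecular-barcoded paired-end sequencing of IGH transcripts:

1. **UID consensus** (`extract_uid_and_trim()`, `group_by_uid()`,
   `build_consensus()`): each cDNA molecule carries a 16-nt unique
   identifier (UID), 8 nt from the constant-region primer and 8 nt from the
   V-FR3 primer. All reads sharing a UID derive from one transcript
   molecule; a per-position majority vote across the group corrects
   sequencing errors whenever two or more reads cover the molecule.
   Coverage-1 groups pass through uncorrected but still count as one
   molecule.
2. **Annotation** (`annotate_molecules()`): the forward consensus is
   locally aligned to germline V references (mismatches per aligned base =
   somatic mutation rate) and the reverse consensus to the five constant
   regions (isotype).
3. **Depth-standardised clone table** (`subsample_molecules()`,
   `collapse_clones()`): every sample is subsampled to exactly 4,000
   aligned molecules (shallower samples are discarded), and molecules with
   identical forward consensus and isotype are combined into clones whose
   molecule count is their expression level.
4. **ABS level** (`abs_level()`): the count of highly expressed clones
   (at least two molecules) that are class-switched or mutated IgM, divided
   by the total number of molecules. This is the per-sample
   immunosuppression statistic.
5. **Cohort diagnostics** (`cohort_statistics()`): Pearson correlation of
   ABS with tacrolimus level (Fisher r-to-z interval), one-sided
   Mann-Whitney comparisons of rejection categories, ROC c-statistics
   against cfdDNA- and biopsy-defined rejection with percentile-bootstrap
   intervals, sensitivity/specificity/PPV/NPV at a fixed ABS threshold with
   continuity-corrected Wilson intervals, and exponential trend fits of
   pre-rejection dynamics.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `uid_len_each` | 8 nt | UID bases contributed by each mate |
| `max_primer_mismatches` | 2 | tolerance when matching the primer region |
| `align_params()` | +1/-1, gap 2+k, identity >= 0.80 over >= 40 columns | local-alignment scoring and hit acceptance |
| `mutated_igm_min_rate` | 0.01 | V mutation rate from which IgM counts as mutated (closed bound) |
| `subsample_depth` | 4,000 molecules | depth standardisation |
| `highly_expressed_min` | 2 molecules | "highly expressed" clone cutoff |
| `abs_threshold` | 0.023 | ABS decision threshold for rejection calls (score >= threshold is positive) |
| `cfddna_threshold` | 1% donor DNA | cfdDNA elevation cutoff |

The mutated-IgM rate threshold deserves a note: the distinction between
mutated and unmutated IgM is biologically real but any rate cutoff is a
convention. We use 1% of aligned V bases — one mismatch on a typical
80-base aligned V segment — and expose it as configuration. Likewise,
annotation uses an in-process affine-gap local aligner with explicit
scoring rather than an external search tool such as BLAST; what the
pipeline relies on is only "best reference by score with an
identity/length acceptance cutoff", and the test suite pins the aligner to
an exhaustive Smith-Waterman dynamic program. Gap columns
are counted as mismatches when computing identity and mutation counts.

Deterministic tie-breaks are used everywhere ties can occur: consensus
votes break ties by summed base quality, then by the alphabetically
smallest base; best-hit alignment ties resolve in reference order;
subsampling seeds default to a hash of the sample identifier so a rerun of
the same sample reproduces the same subset.

## What the simulator emulates

`sim_config()` / `sample_true_repertoire()` / `synthesize_reads()` generate
a repertoire with known ground truth:

* clones draw an isotype (IgM-dominated with a class-switched minority), an
  activation flag, and a molecule count from a truncated zipf law — a
  heavy-tailed abundance distribution in which activated clones
  (exponent 2) reach much higher expression than naive clones
  (exponent 5, almost all singletons);
* class-switched clones always carry V-segment hypermutation and IgM clones
  carry it with probability 0.15, at a per-base rate drawn from 2–8%,
  planted at interior V positions so local alignment recovers the exact
  planted substitutions;
* every molecule gets a random 16-nt UID (collisions possible and
  recorded), coverage per molecule is 1 + Poisson(4) read pairs, and every
  read base — UID and primer included — is flipped independently with
  probability 0.001, the error rate of roughly Q30 Illumina data.

Simulation scale in the shipped tests (~6,000 molecules and ~30,000 read
pairs per sample, 12-patient cohorts of 72 samples at 2,000 clones and
depth 1,500) was chosen as the smallest scale at which subsampling noise,
clone-size tails and cohort statistics behave like the full-size assay;
real studies standardise at depth 4,000, which the defaults reflect.

The simulator deliberately omits V(D)J recombination machinery, indels,
chimeric PCR products and amplification bias. Consequences: consensus and
annotation are only exercised on substitution errors (the consensus is not
indel-aware, and length-discordant UID groups are dropped and counted), and
clone identity via exact forward-consensus equality is cleaner in
simulation than in real data, where UMI and PCR artefacts blur it.
Passing tests show the pipeline implements its definitions exactly and
robustly under substitution noise; they do not certify performance on real
indel-bearing libraries.

## The ABS level is a pipeline statistic, not an unbiased estimator

Two systematic effects are worth understanding before interpreting absolute
ABS values.

**Depth dependence.** A clone with two molecules among 6,000 survives
subsampling to 4,000 with probability (4000/6000)^2 = 0.44, so the ABS
numerator shrinks faster than the denominator as depth falls. ABS is
therefore only comparable *at a fixed depth* — which is exactly why the
pipeline standardises at 4,000 molecules. Ground-truth comparisons in the
tests use `true_abs_level(rep, depth = 4000)`, the depth-matched estimand.

**Molecular-barcode errors.** A sequencing error inside the 16-nt UID
(probability about 1.6% per read at Q30) creates a spurious coverage-1
"molecule" carrying its source clone's payload. Because clone collapsing
merges it back into the same clone, singleton clones gain a second molecule
with probability roughly coverage x 1.6% and cross the highly-expressed
cutoff. At the simulator's default coverage this inflates ABS by about
+0.017 at depth 4,000 — several subsampling standard errors. The inflation
scales with coverage and error rate, both sample-level properties that are
constant across a cohort, so *between-sample comparisons — the diagnostic
use of the ABS level — are unaffected* (the synthetic-cohort ROC against
planted rejection labels is essentially perfect). Removing the bias would
require collapsing near-identical UIDs (directional barcode networks),
which this package intentionally does not do: the design equates one UID
group with one molecule, and the recovery tests report the discrepancy
honestly rather than hiding it.

## Numerical and design choices

* **Mann-Whitney exact branch.** With midrank ties, textbook exact tables
  do not apply; the package counts the full permutation distribution of
  the rank sum by dynamic programming over doubled midranks (integers even
  under ties), which is exactly equivalent to enumerating all group
  assignments, and switches to a tie-corrected normal approximation with
  continuity correction when `n_a * n_b > 400`.
* **Bootstrap.** C-statistic intervals use 2,000 percentile-bootstrap
  resamples with a fixed default seed; degenerate resamples (one class
  absent) are redrawn.
* **Wilson intervals.** Continuity-corrected Wilson (Newcombe) bounds,
  clamped to [0, 1], with lo = 0 at k = 0 and hi = 1 at k = n.
* **Fisher r-to-z.** tanh(atanh(r) ± z/sqrt(n-3)); at |r| = 1 the
  transform diverges and the interval degenerates to the point.
* **Exponential trends.** y = a·exp(b·t) by nonlinear least squares
  (Levenberg-Marquardt), initialised from a log-linear regression; if the
  NLS machinery rejects a degenerate start (e.g. an exact fit), the start
  is polished by direct RSS minimisation. Pre-rejection fits align time at
  each patient's first rejection-positive day and use samples in a
  configurable window (default the preceding 240 days).
* **Pooling.** Pooled ratios sum numerators and molecule totals across
  samples but never merge clones across samples: IGH sequences are
  personal, and an identical consensus in two patients is still two clones.
* **Clone flags.** A clone is mutated if *any* member molecule is mutated
  (OR); a majority rule would be less sensitive to the mutated-IgM class at
  low coverage. The clone's V segment is the most frequent member call.
* **No multiplicity correction** is applied to the four group comparisons;
  they are reported raw.

## Known limitations

* No indel-aware consensus or alignment-based clone clustering.
* No UMI-network error collapsing (see the bias discussion above).
* The cfdDNA fraction is consumed as a metadata column; its estimation from
  shotgun sequencing is out of scope.
* The simulator's clone-size law is a configurable stand-in: the real
  clone-size distribution of post-transplant repertoires is not known well
  enough to claim more than "heavy-tailed with a highly expressed
  minority".

## A five-minute worked example

```{r example, eval = FALSE}
refs <- make_germline_refs(n_v = 6, v_len = 80, seed = 42)
cfg <- sim_config(n_clones = 5400, seed = 7)
truth <- sample_true_repertoire(cfg, refs)
reads <- synthesize_reads(truth, cfg)
res <- process_sample(reads, refs, pipeline_config(), sample_id = "S1")
res$summary
true_abs_level(truth, depth = 4000)
```

The cohort-level path is exercised by `simulate_cohort_design()` +
`simulate_cohort_sample()` + `run_pipeline()`; see the README for a worked
cohort example with its printed output.
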