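---
title: "Methods: depth-rate CNV detection and variant triage for capture panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-rate CNV detection and variant triage for capture panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paneldx)
```

This vignette documents the models, rules and numerical choices behind
`paneldx`, and what its synthetic fixtures do and do not establish.

## 1. Read QC: the unqualified-read filter

A read is removed whole (never trimmed) when any of four rules fires, in a
fixed order so every removal has one recorded reason:

| order | rule | default | interpretation notes |
|---|---|---|---|
| 1 | adapter pollution | ≥ 10 adapter bases aligned, ≤ 1 mismatch | any placement of the adapter inside the read, including 3′ read-through |
| 2 | ambiguous bases | N fraction **>** 0.10 | strict `>`: "more than 10%" |
| 3 | mean quality | arithmetic mean Phred **<** 10 | plain mean of Phred scores, not error-probability averaging; simplest faithful reading, swappable |
| 4 | low-quality bases | **≥** 50% of bases with Phred < 5 | the rule states a threshold, not an excess, so the inclusive reading is used; configurable |

All thresholds live in `qc_thresholds()`. Paired mates are removed
together when either fails (the survivor is counted under its partner's
reason), which keeps paired FASTQ files in lock-step. Quality encoding is
Phred+33 by default with a `phred64` switch.

## 2. Coverage statistics

`coverage_stats()` works per base over the *merged* target (overlapping
capture regions count once): mean target depth, percent of target bases at
each threshold (non-increasing in the threshold by construction), and the
same for the 200 bp flanking regions, excluding any base inside the target
and clipping at position 1. Capture specificity is reported as
`mapped_on_target / mapped_total`; read-level counting is the default
interpretation because published panel summaries are consistent with read
ratios rather than base ratios, and both are just arguments here.

## 3. CNV detection from depth rates

**Model.** The depth rate `rate(s, r) = meanDepth(s, r) / meanDepth(s)`
removes library-size differences between samples. What remains is dominated
by per-region capture efficiency, which is shared across the samples of a
sequencing run — this is why depths of one region are strongly correlated
(r > 0.7) across samples of a lane, and why the *same region in the other
samples of the run* is the right baseline. Each region of a tested sample
is scored as

z(s, r) = (rate(s, r) − mean of rate(·, r) over the other samples) / SD over the other samples,

a leave-one-out z-score with the sample (n−1) standard deviation.

**Choices worth stating.**

* *Baseline orientation.* The normalization could also have been read as
  comparing a region against the *other regions of the same sample*; that
  would conflate region-to-region capture-efficiency differences with CNV
  signal, and it is not what the cross-sample correlation argument
  supports. Leave-one-out across samples is implemented.
* *No √n term.* The statistic tests a single observation against a
  baseline distribution, not a mean of n observations; dividing the SD by
  √n would shrink the denominator until ordinary depth noise always
  exceeded |z| = 3.
* *Cutoff.* Strict inequalities at ±3: a region at exactly z = −3 is not
  called. Under a normal baseline the cutoff corresponds to the one-tailed
  99.86th ≈ 99.9th percentile (`zscore_percentile(3)`).
* *Degeneracy.* Baselines with SD below 1e−6 are uninformative (`NA`,
  never called); fewer than 3 baseline samples is an error, not a guess.
* *Granularity and merging.* One z per capture region (exon); consecutive
  same-direction flagged exons of one gene merge into a single call.
  Uninformative regions interrupt a merge — adjacent evidence cannot be
  bridged through a region with no usable baseline.

**Expected false-positive load.** The leave-one-out z under the null is
approximately t-distributed and slightly over-dispersed (SD ≈ 1.1 with a
13-sample baseline), so roughly 1–2% of region–sample pairs exceed |z| = 3
by chance. On a 60-region panel that is of order one borderline call per
sample. The method is a screen; single-exon calls near the cutoff need
orthogonal confirmation (MLPA in practice). The null-calibration property
test pins exactly this behaviour.

## 4. Variant filtering and four-tier triage

`filter_candidates()` keeps a variant iff all of: caller quality ≥ 20;
functional consequence (SNVs: nonsense, splice-site, missense; indels:
frameshift, in-frame coding, splice-site); allele frequency < 0.01 in
**every** database where the variant is observed (absence passes — the
permissive "rare in at least one database" reading would keep common
variants, contrary to diagnostic practice); and, optionally, membership of
a phenotype-specific candidate-gene set.

`classify_variants()` then assigns exactly one tier by the first matching
rule, recording every satisfied evidence clause:

1. **pathogenic** — exact match in the knowledge table of reported
   mutations, or loss of function (nonsense/frameshift);
2. **suspected pathogenic** — otherwise-novel variant with supporting
   evidence: conserved missense, splice variant breaking a canonical GT/AG
   dinucleotide, or damaging verdicts from ≥ 2 of the in-silico predictors;
3. **polymorphism** — present in the local control cohort;
4. **unknown significance** — everything else.

Choices: the predictor-consensus threshold defaults to ≥ 2 of the four
standard tools — the source phrasing "more than two" most plausibly
translates "two or more", and the literal ≥ 3 is one `triage_config()`
argument away. Conservation and GT/AG disruption are consumed as
annotations (`CONSERVED`, `GTAT` INFO flags), with a positional fallback
for splice variants inside the panel's `splice_site` regions; recomputing
them from alignments is out of scope. Known-variant matching is exact on
(chrom, pos, ref, alt) with no indel re-normalization — a documented
limitation. Summary percents round to 2 decimals; cohort gene shares to
integers.

## 5. Benchmarking

`confusion_counts()` counts positionally over the covered base set (target
bases at ≥ 20× in the evaluated sample, making TN well-defined), after
discarding calls failing the quality filters (score ≥ 20, depth ≥ 20,
alt-read fraction ≥ 28%). A covered position with a call matching the truth
allele is a TP; a call with no truth support an FP; truth with no
surviving call an FN; an allele-mismatched position books one FP *and* one
FN (a wrong call and a missed truth), which preserves call/truth symmetry.
TP+TN+FP+FN equals the covered base count by construction. Indels are
excluded; matching is site-level (position + alt allele), with genotype
concordance deliberately out of the counts.

`bench_report()` reports precision as the positive predictive value
TP/(TP+FP). The source material's *formula* for precision, TP/(TP+FN), is
inconsistent with its own printed precision value, which equals TP/(TP+FP);
the printed value wins, and the text formula remains available via
`precision_formula = "tp_over_tp_fn"` (it then equals the TP ratio).

## 6. The synthetic world

The generator is a stated world, not a tuning knob; its defaults were fixed
once:

* **Depth model.** Region mean depth ~ NB(mu, size) with
  `mu = depth_mean × sample_scale × region_effect × copy_factor`;
  `depth_mean = 412` (the published panel's mean on-target depth),
  log-normal per-region capture efficiency with sd 0.4 (regions differ
  several-fold, as hybridization capture does), log-normal per-sample
  library size with sd 0.2, and NB size 150 (≈ 9% excess CV at depth 400 —
  the overdispersion typical of capture data). The shared region effect is
  what produces the r > 0.7 cross-sample correlation of region depths; the
  generator satisfies it by design, and a test verifies it.
* **Copy factors** are restricted to 0 (homozygous deletion), 0.5
  (heterozygous deletion), 1.5 (heterozygous duplication) and 2; event
  zygosity is not specified upstream, so both are generated.
* **Variant cohort.** Implanted classes carry annotations that *force* a
  tier under the default configuration, so expected answers are exact;
  filler classes (synonymous, common polymorphisms at AF 0.05,
  control-cohort polymorphisms at AF 0.005, rare benign missense) are
  dosed so the post-filter candidate count lands in the 3–10 band reported
  for real samples.
* **The `cohort70` preset** emulates the clinical study design at desk
  scale: 70 samples in runs of 14; 63 implanted small causal variants
  (15 frameshift, 5 nonsense, 31 known + 5 novel-conserved missense,
  7 canonical-splice — 51 expected pathogenic, 12 expected suspected);
  7 whole-exon CNVs (4 het deletions, 3 duplications); per-gene shares
  GCK 26 / HNF1A 28 / HNF4A 9 / KCNJ11 3 / HNF1B 2 / INS 2. Coordinates
  live on a fictional contig (`panelsim1`) so nothing can silently depend
  on a real reference.
* **Benchmark pairs** plant truth SNVs and flip calls at configured rates
  (defaults fp 6e−5 per covered negative base, fn 0.09 per truth site,
  mirroring the published error profile); the generator tallies expected
  counts as it draws, so the comparison is exact, not statistical.

**What a green run does not establish.** The fixtures are region-level and
annotation-driven: they exercise the statistics and the rule engine, not
alignment, base calling, annotation accuracy, GC-dependent capture bias, or
segmental-duplication artifacts. Real-data panel averages (raw yield, mean
depth, 99.37%/96.95% breadth, 53.72% specificity) are properties of the
actual instrument run and are intentionally not reproduced. Full-cohort
recovery on the preset is a scaled surrogate for the study's 100% detection
claim on real patients, nothing more.

## 7. Reproducibility

Every generator is a deterministic function of its configuration (seed
included): regenerating a bundle and re-writing it yields byte-identical
files. Written VCFs carry no timestamp for the same reason. Heterozygous
single-exon events at the default noise sit around |z| ≈ 4–5, so recovery
is expected but not logically guaranteed at every seed; the homozygous case
is saturated.
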