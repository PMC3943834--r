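# paneldx

Targeted gene-panel sequencing diagnostics in R: read QC, coverage
statistics, read-depth CNV detection, rule-based variant triage, and
truth-set benchmarking — with a synthetic fixture generator so the whole
pipeline is testable offline.

## The problem

Capture-based gene-panel sequencing is the workhorse of molecular diagnosis
for monogenic disease (the motivating use case is monogenic diabetes:
*HNF4A*, *GCK*, *HNF1A*, *HNF1B*, *INS*, *KCNJ11*). A diagnostic pipeline on
such data has to answer four questions:

1. **Are the reads usable?** Remove "unqualified" reads before alignment:
   adapter-polluted reads, reads with > 10% ambiguous bases, mean Phred
   < 10, or ≥ 50% of bases below Phred 5.
2. **Is the target covered?** Mean on-target depth, breadth at ≥ 1×/≥ 20×,
   capture specificity, flanking-region coverage.
3. **Which variants matter?** Filter calls to rare functional candidates and
   triage them into four tiers — *pathogenic*, *suspected pathogenic*,
   *polymorphism*, *unknown significance* — and, separately, detect large
   exon deletions/duplications from read depth.
4. **How good are the calls?** TP/TN/FP/FN against a reference truth set
   over covered target bases, with accuracy and precision.

## The CNV statistic

For sample *s* and capture region *r*, the **depth rate** is

```
rate(s, r) = meanDepth(s, r) / meanDepth(s)
```

i.e. the region's mean depth normalized by the sample's overall mean depth.
Because per-region capture efficiency is shared by samples sequenced in the
same run (depths of one region are strongly correlated across samples,
r > 0.7), each region's rate is scored against the other samples of the run:

```
z(s, r) = (rate(s, r) − mean_{s'≠s} rate(s', r)) / sd_{s'≠s} rate(s', r)
```

A region with z < −3 is a deletion candidate, z > +3 a duplication
candidate (±3 is the ~99.9th one-tailed percentile of a normal baseline);
consecutive flagged exons of one gene merge into a single call.

## Worked example

Everything below runs offline on the bundled synthetic cohort generator
(`gen_cohort70`): 70 samples in runs of 14, 63 with one implanted small
causal variant, 7 with one implanted whole-exon CNV.

```r
library(paneldx)
bundle <- gen_cohort70(seed = 1)

# CNV scan of sample S10 against its run's leave-one-out baseline
rates <- region_depth_rates(bundle$runs[["run1"]])
z     <- cnv_zscores(rates, "S10")
call_cnvs(z, bundle$panel, sample_id = "S10")
#>       chrom  start    end  gene   direction z_extreme n_regions
#> 1 panelsim1 101000 101150   GCK    deletion -5.246858         1
#> 2 panelsim1 302500 302650 HNF1B duplication  3.679085         1
```

The implanted single-exon *GCK* deletion is recovered at z ≈ −5.2. The
borderline *HNF1B* "duplication" at z ≈ 3.7 is a false positive — the plain
z-score method flags roughly 1–2% of region–sample pairs under the null, so
single-region calls near the cutoff need orthogonal confirmation (MLPA in
practice).

```r
# variant triage for one sample, restricted to the six panel genes
cfg  <- triage_config(restrict_genes = attr(bundle$panel, "genes"))
cand <- filter_candidates(bundle$samples[["S01"]], cfg)
classify_variants(cand, bundle$known, cfg, bundle$panel)[, c("pos", "gene", "consequence", "tier")]
#>      pos   gene consequence                 tier
#> 1    558  HNF4A    missense unknown_significance
#> 2 104117    GCK    missense           pathogenic
#> 3 300051  HNF1B    missense         polymorphism
#> 4 401065    INS    missense unknown_significance
#> 5 501572 KCNJ11    missense unknown_significance
```

Filtering narrows each sample to a handful of candidates (3–9 here); the
implanted known *GCK* mutation is tiered pathogenic, a control-cohort
variant is recognized as a polymorphism, and the rare benign fillers land
in unknown significance.

```r
# full pipeline over all 70 samples
recover_cohort(bundle)
#> <recovery_report> 70/70 implanted events recovered (100.0%)
#>   candidate variants per sample: median 6 (range 3-9)
```

## Acceptance script

`scripts/acceptance.R` regenerates the 70-sample synthetic cohort from the
given seed, runs the complete triage + CNV pipeline on it, and writes the
percentage of implanted causal events recovered as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin wrapper over the package functions lives at
`inst/scripts/panel-dx.R` (subcommands `qc`, `coverage`, `cnv`, `triage`,
`bench`, `simulate`); the R functions are the primary interface.
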