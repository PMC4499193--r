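# paneltriage

Panel-based clinical variant triage for Mendelian disease: the variant
filtration cascade used by symptom-based gene-panel diagnostics, with the
surrounding machinery that makes it operable — a versioned panel registry,
an accumulating in-house occurrence database, microarray CNV
classification, diagnostic-performance accounting, and a synthetic cohort
generator for end-to-end validation.

## The problem

A diagnostic lab running broad, symptom-based gene panels (Vision,
Neurology, Renal, ... spanning the ~3000 known Mendelian genes) faces a
funnel problem: each sample produces on the order of a thousand annotated
calls, of which an expert can realistically review a handful. The
standard answer is a fixed five-stage filtration cascade. Writing
`C` for the retained functional classes, `MAF_pub` for the public minor
allele frequency, `occ` for the in-house occurrence count, `Q` for the
Phred-like call quality and `z` for zygosity, a variant survives iff

```
class ∈ C  ∧  (MAF_pub unknown ∨ MAF_pub ≤ 0.01)  ∧  occ ≤ 20
          ∧  Q ≥ 100  ∧  zygosity-compatible(z, inheritance mode)
```

with `C` excluding intronic/UTR/synonymous by default, and the zygosity
clause active only when an inheritance mode is indicated (recessive →
homozygous; X-linked → homozygous or hemizygous). Boundary sides matter
clinically and are fixed: frequency and occurrence cutoffs are strict
("more than"), the quality cutoff is inclusive ("met or exceeded"). The
per-stage survivor counts form the *funnel report*; the final set is the
conjunction above and is independent of stage order.

Around the cascade the package provides:

* **`panel_registry`** — `load_panels()`, feature-to-panel routing
  (`assign_panel()`), versioned `spike_in()` gene additions,
  `redundancy_fraction()`.
* **`inhouse_db`** — `occurrence_db()` with dosage-aware
  `ingest_sample()`, in-house MAF, `flag_common_pathogenic()` (catalogued
  pathogenic variants common in the cohort, tiered >1 % / >5 %) and
  `homozygous_inactivating_challenge()`.
* **`cnv_classifier`** — gains at log2 ≥ 0.58, losses at ≤ −1, noise
  filters (≥50 probes; ≥500 kb gains, ≥200 kb losses), benign-track and
  parental matching by ≥0.5 reciprocal overlap, de-novo-only pathogenic
  calls.
* **`evaluation`** — analytical sensitivity/specificity, clinical yield
  and missed-case breakdowns as `x % (n/m)` rate reports.
* **`synthetic_data`** — seeded cohorts with consanguinity-driven excess
  homozygosity, spiked causal variants, per-type detection dropout.
* **`cli_io`** — VCF in (multi-allelic split, left-normalized), TSV/VCF
  reports out, YAML run configs, and a thin `triage` command-line
  dispatcher in `inst/cli/`.

## Worked example

```r
library(paneltriage)

## a small synthetic cohort: 3 samples, ~400 calls each, 43 % of samples
## carrying a spiked causal homozygous variant
co  <- generate_cohort(cohort_params(n_samples = 3,
                                     variants_per_sample = 400, seed = 7))
res <- recover_cohort_yield(co)
res$funnels[[1]]
#>        stage remaining
#> 1      input       445
#> 2 functional       131
#> 3  public_db        44
#> 4 inhouse_db        44
#> 5    quality        16
#> 6   zygosity         2
res$yield
#> 33 % (1/3)
```

The funnel shows the cascade at work on one sample: 445 raw calls, 131
after dropping intronic/UTR/synonymous classes, 44 after the public-MAF
filter, 16 after the quality cutoff, 2 homozygous candidates for review.
The recovered yield (1 of 3 samples solved) is the truth-table check: a
sample counts as solved only if its spiked variant survived to the
candidate list.

Performance accounting runs from record-level tables (bundled versions of
a 642-control validation set and a 2357-referral cohort ship with the
package; the case table is synthetic at per-panel resolution):

```r
analytical_sensitivity(bundled_eval_records("controls"))$overall
#> 79 % (507/642)
analytical_sensitivity(bundled_eval_records("controls"),
                       exclude_design_flaws = TRUE)$by_type
#>   variant_type detected total percent
#> 1        indel      109   152      72
#> 2          snv      398   428      93
clinical_sensitivity(bundled_eval_records("cases"))$overall
#> 43 % (1018/2357)
```

CNV calls follow the printed thresholds; a 620 kb de novo duplication
with 72 probes and no benign match is pathogenic:

```r
seg <- data.frame(sample_id = "p1", chrom = "7", start = 1e7,
                  end = 1.062e7, mean_log2 = 0.8, n_probes = 72)
no_cnvs <- seg[0, ]   # both parents tested, no reportable segments
classify_cnvs(seg, mother = no_cnvs, father = no_cnvs)
#>   state passes_filters inheritance classification
#> 1  gain           TRUE     de_novo     pathogenic
```

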