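---
title: "Methods: panel-based variant triage, in-house frequencies, and CNV classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-based variant triage, in-house frequencies, and CNV classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paneltriage)
```

## The diagnostic setting

`paneltriage` models the informatics core of symptom-based gene-panel
diagnostics for Mendelian disease. A referred patient is routed, from their
single most prominent *primary clinical feature*, to exactly one of a set
of broad clinical-theme panels (Vision, Neurology, Renal, ...) drawn from
the ~3000 genes with established single-gene disease links. The sample is
sequenced on that panel, variants are called and annotated, and a short
list of candidate causal variants is produced by a fixed filtration
cascade. Because the cascade is the part of the process that turns
thousands of raw calls into a reviewable handful, its rules — and their
exact boundary behavior — are the heart of this package.

## The five-stage filtration cascade

Each sample's annotated variants pass through five filters, in a fixed
order, with the surviving count recorded after every stage (the *funnel*):

1. **Functional class.** Intronic, UTR and synonymous calls are removed;
   missense, nonsense, frameshift, in-frame indel, splice-site and other
   exonic classes are retained. The retained set is configuration, because
   annotation vocabularies differ between tools.
2. **Public population frequency.** Variants with a known public minor
   allele frequency *strictly above* 1 % are removed. A variant absent
   from public databases is retained: absence of frequency evidence is not
   evidence of commonness.
3. **In-house cohort frequency.** Variants seen *strictly more than* 20
   times in the accumulating in-house database are removed. The cutoff of
   20 occurrences is treated as a fixed operating point of the pipeline
   (chosen upstream to preserve sensitivity); we do not re-derive it.
4. **Call quality.** Variants whose Phred-like quality *met or exceeded*
   100 are retained — an inclusive boundary.
5. **Zygosity, when indicated.** Under a recessive working hypothesis only
   homozygotes are retained (in consanguineous families the causal
   genotype is typically autozygous); under an X-linked hypothesis,
   homozygotes and hemizygotes. With a dominant hypothesis, or no
   hypothesis, nothing is excluded. The default mode is `none`.

Three design points deserve emphasis. First, every threshold's boundary
side is deliberate and tested: MAF exactly 0.01, occurrence count exactly
20 and quality exactly 100 are all *retained*. The frequency rules are
phrased as "more than", hence strict; the quality rule is phrased as "met
or were higher", hence inclusive. Second, the five filters are pure
predicates, so the final candidate set is their conjunction and is
invariant to stage order; only the intermediate funnel counts depend on
the order, which is fixed to the conventional reporting order
(functional, public DB, in-house DB, quality, zygosity). The suite checks
this order-invariance against a brute-force conjunction oracle on
randomized inputs. Third, each filter is idempotent, so re-running a
partially filtered set is harmless.

`run_cascade()` returns the candidates and a `funnel_report`;
`average_funnels()` reproduces the per-panel mean-survivors-per-stage
table (means are kept exact, with a rounded `display` column for
tabulation). `rank_candidates()` orders the survivors for expert review —
feature-matched gene first, then known-pathogenic flag, then a
deleteriousness tier (loss-of-function class above missense predicted
damaging at SIFT ≤ 0.05 or PolyPhen ≥ 0.85), with genomic coordinate as a
stable tie-break. Ranking is advisory; it never removes a candidate.

## The in-house occurrence database

The cohort-frequency filter needs a database that accumulates across all
samples ever processed. `occurrence_db()` tracks, per left-normalized
variant key, the allele-dosage count (heterozygous and hemizygous +1,
homozygous +2), the number of carrier samples, and the number of
homozygous carriers. Ingestion is order-invariant and guarded against
double counting the same sample; serialization is a sorted TSV whose
header carries the sample registry, so merges and diffs are reproducible.

Two definitional choices the upstream description leaves open are made
explicit here:

* **The unit of "occurrence"** for the >20 rule is the allele-dosage
  count by default (the natural allele-frequency proxy); a configuration
  switch (`occurrence_unit = "sample"`) selects carrier-sample counts
  instead.
* **The in-house MAF denominator** is `2 × n_samples` under a diploid
  assumption. X-linked variants in males are therefore slightly
  underestimated; with overwhelmingly autosomal panels we accept this
  rather than require per-sample sex metadata.

The database also supports the cohort-level annotation analyses:
`flag_common_pathogenic()` reports catalogued disease variants whose
in-house MAF is strictly above 1 % (tiered at strictly above 5 %), with a
discordance flag when the public MAF is known and below 1 % — the
signature of a population-specific common variant mislabelled as
pathogenic. `homozygous_inactivating_challenge()` lists genes carrying
loss-of-function variants homozygous in more than a configurable fraction
(default 1 %) of the cohort, a strong argument against their disease-gene
status (with the usual caveat of reduced penetrance, which we log rather
than model).

## CNV classification

Microarray CNV analysis of panel-negative patients is modelled from the
segment level down: segmentation itself is upstream. A segment is a gain
when its mean log2 ratio is ≥ 0.58 and a loss when ≤ −1 (both inclusive,
partitioning the real line). Noise filters require at least 50 consecutive
probes and a minimum size of 500 kb for gains and 200 kb for losses, all
bounds inclusive, with lengths computed on 1-based inclusive coordinates
(`end − start + 1`). The 50-probe rule is applied to losses as well as
gains; the source phrasing attaches it grammatically to gains only, but a
probe-count floor is a noise control and we see no reason to exempt
losses (documented here as our reading).

A filtered gain/loss is *pathogenic* if and only if it is de novo (found
in neither parent) and does not match a benign track (population CNV
catalogues or in-house normals). "Match" and "found in a parent" both use
same-state reciprocal overlap at a configurable fraction, default 0.5 —
the community convention, since no canonical fraction is stated. The
reciprocal-overlap computation is backed by `GenomicRanges` and verified
against a per-base brute-force oracle in the suite. Missing parental data
yields `inheritance = "unknown"` and never a pathogenic call.

## Evaluation statistics

All performance accounting flows through `rate_report()`, which stores the
numerator and denominator and prints the percentage rounded to the nearest
integer, *half away from zero* — the convention that matches clinical
reporting of every rate this package reproduces. Analytical sensitivity
supports excluding *design-flaw* controls (known mutations in genes absent
from the appropriate panel — remediable by `spike_in()` rather than a
platform limit) from the denominator; per-type rates are computed on the
design-covered subset. Clinical sensitivity (diagnostic yield) reports
panel-solved cases over referrals, per group and overall, with an optional
denominator adjustment that removes cases solved by another modality.

The packaged case table (`bundled_eval_records("cases")`) is **synthetic**
at the per-panel level: only per-panel totals, rounded per-panel
percentages and the overall solved count are public, so per-panel solved
counts were reconstructed to satisfy all of those constraints
simultaneously, and the attribution of CNV-/WES-rescued cases to panels is
arbitrary (it does not affect any reported rate). The control and
validation tables are exact count expansions.

## The synthetic cohort generator

`generate_cohort()` exists so the whole pipeline is testable without any
patient data. Its defaults *are* the study conditions the package targets:

| Parameter | Default | Rationale |
|---|---|---|
| `variants_per_sample` | 1138 | typical all-panel average input |
| `detection_prob` | snv 0.93, indel 0.72 | per-type analytical sensitivities |
| `causal_fraction` | 0.43 | overall diagnostic yield |
| `consanguinity_f` | 0.0625 | first-cousin-offspring inbreeding coefficient |
| `quality_mean/sd` | 95 / 20 | places a realistic mass on both sides of the 100 cutoff |
| class mix | 70 % intronic/UTR/synonymous | so stage 1 removes the bulk of calls |
| MAF spectrum | 20 % point mass at 0, 5 % unknown, Beta(0.5, 1.5) tail | novel variants plus a polymorphism-heavy tail |

Genotypes at a site of frequency `p` follow the inbreeding-adjusted
frequencies: homozygous-alternate `p² + f·p·q`, heterozygous
`2pq(1 − f)`. At `f = 0` this is Hardy–Weinberg; at `f = 1` every carrier
is homozygous — both limits are property-tested via
`sample_genotypes()`. Spiked causal variants are constructed to pass every
cascade filter (novel, functional, quality in [100, 160], zygosity
matching the inheritance mode) and are included in the sample's calls if
and only if an independent Bernoulli draw at the per-type detection
probability marks them detectable; the truth table records every draw, so
end-to-end recovery is exact, not statistical, at full detectability.

What the generator does **not** emulate: linkage disequilibrium, sequence
context (indel dropout is a flat per-type Bernoulli, abstracting the
homopolymer mechanism), site sharing between samples (background variants
are drawn i.i.d., so in-house occurrence counts are simulated as
annotations rather than accumulated across the synthetic samples), and
any real population's frequency spectrum. Passing tests therefore
demonstrate the correctness of the *rules* under controlled structure,
not performance on real cohorts.

Indel under-detection is deliberately decoupled from the cascade: a
dropped causal indel simply never appears in the call list, which is how
an upstream caller failure presents in practice.

## Numerical and degenerate-input choices

* Percent rounding is half away from zero (`round_half_up()`), not banker's
  rounding, and every reported percentage is recomputed from its own
  counts.
* Empty inputs are legal everywhere they can arise: an empty sample yields
  an all-zero funnel; an empty panel catalog loads to an empty registry
  with a warning; an empty benign track matches nothing. Undefined
  statistics (frequency on an empty database, redundancy of an empty
  registry, a rate with denominator zero) raise errors rather than
  returning sentinels.
* Variant identity is the left-normalized `chrom:pos:ref:alt` key;
  multi-allelic VCF records are split before keying; coordinates are
  1-based in memory and converted only at BED export (0-based half-open).
* Panel-size plausibility (96–758 genes, the production range) is a soft
  report (`validate_panel_sizes()`), never an error, so miniature test
  panels remain legal.
* Cross-panel gene redundancy is defined as *distinct genes present in ≥ 2
  panels over distinct genes*; whether the statistic should instead be
  panel-pair-weighted is genuinely open upstream, so the definition is
  pinned here and documented on `redundancy_fraction()`.

## Problem sizes used by the suite

The test suite and acceptance script are sized for a single CPU: cohorts
of 30–400 samples (the end-to-end yield run uses 400 samples at the
default 1138 variants each), 1000 randomized cascade-oracle cases, 200
parameter-recovery replicates at the real control-set sizes (428 SNV, 152
indel), and per-base overlap oracles on intervals of a few hundred bases.
These sizes give binomial standard errors comfortably inside the asserted
tolerances while keeping the full suite under a minute of compute.

## Known limitations

* The ranking heuristic is a fixed lexicographic key, not a calibrated
  score, and full ACMG classification is out of scope.
* The occurrence database is an in-memory hash keyed by variant string;
  it is appropriate for cohort scales of 10³–10⁴ samples, not biobank
  scale.
* X-chromosome allele frequencies assume diploidy (see above).
* The synthetic case table reproduces printed marginals, not patient-level
  reality; per-panel synthetic yields should never be quoted as findings.
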