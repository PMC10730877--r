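---
title: "Multi-analyte cfDNA classification: models, conventions, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-analyte cfDNA classification: models, conventions, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfescc)
```

## The problem

Esophageal squamous cell carcinoma (ESCC) is usually diagnosed late because
early disease is asymptomatic and endoscopy is too invasive for population
screening. Plasma cell-free DNA (cfDNA) offers a non-invasive readout: a
fraction of a patient's cfDNA derives from the tumor, and both the chemistry
(5-hydroxymethylcytosine, 5hmC) and the physics (fragment length, cleavage
end motifs, nucleosome footprints) of that DNA differ from the healthy
background. `cfescc` implements the full analysis path from aligned cfDNA
fragment coordinates to an integrated multi-analyte classifier, together
with a seeded synthetic-cohort generator so that every stage is testable
without sequencing data.

Four analyte feature families are extracted per sample:

* **5'-end motifs** — the four reference bases at each fragment's 5'
  terminus, tallied over all 256 4-mers. End-motif composition reflects the
  serum nuclease repertoire (e.g. DNASE1L3 activity) and shifts
  systematically in cancer.
* **Nucleosome footprint (NF) scores** — expressed genes leave a
  nucleosome-depleted region at their transcription start site (TSS), so
  cfDNA coverage dips at active promoters. Per gene,
  `NF = (background1 + background2)/2 − promoter`, where each term is the
  mean per-bp coverage in a TSS-relative window, depth-normalized to
  fragments-per-million.
* **Fragment-size features** — tumor-derived cfDNA is shorter than the
  ~166 bp mononucleosomal mode. The genome is tiled into fixed bins
  (1 Mb for a human genome) and the per-bin fraction of short (100–150 bp)
  among short + long (151–220 bp) fragments is the feature.
* **5hmC signal** — fragments over each gene's promoter (TSS ± 1 kb) ∪
  gene-body region, expressed as FPKM
  (`count / ((len/1000) · (depth/10^6))`); high-confidence peaks are those
  with `q < 1e-12` and fold enrichment `> 8` (both strict), and per-sample
  high-confidence peak counts rise with tumor stage (tested with the
  Mann–Kendall trend statistic).

## Classification

Selection is staged per analyte, on the training split only:

| analyte  | stages |
|----------|--------------------------------------------------------|
| motif    | Wilcoxon rank-sum (keep p < 0.05) → LASSO              |
| NF       | zero-fraction (drop if > 10% zeros) → Wilcoxon (p < 0.001) → LASSO |
| fragment | LASSO                                                  |
| 5hmC     | Wilcoxon (p < 0.001) → RFE-CV (linear-SVM ranking)     |

Each analyte then gets an SVM head: a grid search over kernel ∈ {linear,
RBF}, cost ∈ {0.1, 1, 10, 100} and, for RBF, γ = (1/p)·{0.1, 1, 10} on
standardized features, scored by seeded stratified 10-fold CV accuracy,
refit with Platt probability calibration so scores live in [0, 1], with the
decision cutoff chosen at the best training accuracy (candidates are
midpoints between adjacent distinct scores; ties break toward higher
specificity). The four analyte scores are combined by logistic integration

$$Z = \beta_0 + \beta_1\,\mathrm{NF} + \beta_2\,\mathrm{Fragment} +
\beta_3\,\mathrm{Motif} + \beta_4\,\mathrm{5hmC}, \qquad
p = \frac{e^Z}{1+e^Z},$$

either with the fixed published combination weights
$(\beta_0,\ldots,\beta_4) = (-2.57,\ 3.35,\ 0.05,\ 0.75,\ 1.74)$
(`integrated_model("fixed")`) or refit by unpenalized maximum likelihood on
the training analyte scores (`refit_integration()`; under perfect
separation a lightly L2-penalized fit is substituted with a warning).
Evaluation uses the Mann–Whitney rank formulation of the AUC (ties count
1/2) with a DeLong 95% CI by default (stratified bootstrap as an
alternative), plus sensitivity/specificity/accuracy at the chosen cutoff
and per-stage accuracies.

Whether the analyte scores entering the integration are calibrated
probabilities or raw margins is a genuine design choice; calibrated
probabilities are used here because the fixed coefficients are on a scale
consistent with [0, 1] inputs and because probabilities compose sensibly
across analytes.

## Sample-size calculation

For a study that must estimate an expected AUC with precision $d$ at
confidence $1-\alpha$, the closed-form chain is

$$\alpha^\* = \Phi^{-1}(\mathrm{AUC})\times\sqrt{2},\qquad
V(\widehat{\mathrm{AUC}}) = \left(0.0099\,e^{-\alpha^{*2}/2}\right)
\left(6\alpha^{*2}+16\right),\qquad
n = \left\lceil\frac{z_{\alpha/2}^2\,V}{d^2}\right\rceil\ \text{per group}.$$

Two conventions are exposed. `z_mode = "exact"` uses the full-precision
normal quantile and $\sqrt 2$; `z_mode = "published"` uses the truncated
factor 1.414, and `z_override` substitutes an externally quoted quantile,
so that published arithmetic can be reproduced digit-for-digit. For a
target AUC of 0.934 the exact quantile is 1.50626; the widely quoted value
1.5153 differs from it (its provenance is unclear — it is not
$\Phi^{-1}(0.934)$ under any rounding we tried), which is precisely why
both modes exist. With the quoted value, $\alpha^\* = 2.142634$,
$V = 0.043419$ and $n = 67$ per group (134 total) at $d = 0.05$, 95%
confidence. Rounding is by ceiling, the conservative choice.

One analytic note: $V'(\alpha^\*) = 0.0099\,\alpha^\*
e^{-\alpha^{*2}/2}(-4-6\alpha^{*2}) < 0$ for $\alpha^\* > 0$, so $V$ is
strictly decreasing with its supremum at $\alpha^\* \to 0$ — higher target
AUCs always need fewer samples at fixed precision.

## Coordinate and threshold conventions

* All interval inputs and outputs are 0-based half-open (BED convention);
  the 5' end of a plus-strand fragment is `start`, of a minus-strand
  fragment the base at `end − 1`.
* Motif counting defaults to **both** fragment ends (each end's 4-mer read
  on its own template strand, i.e. reverse-complemented at the right end);
  this matches how end-motif catalogs are built from double-stranded
  molecules. A single-end mode keyed on the strand field is available.
  Chromosome Y and any end whose 4-mer contains a non-ACGT base are
  excluded; excluded ends do not enter the denominator.
* NF windows default to promoter = TSS ± 1000 bp, background1 =
  [−3000, −1000), background2 = [1000, 3000) in transcription-direction
  offsets. These are this package's convention (the footprint contrast is
  robust to the exact flanks) and are fully configurable via
  `nf_windows()`. Coverage is normalized to fragments-per-million before
  differencing so NF scores are depth-comparable across samples.
* Genome bins use the ceiling convention (a truncated final bin per
  chromosome). The bin count is always derived from the supplied
  chromosome sizes, never hard-coded: with the embedded hg19 chr1–22+X
  sizes at 1 Mb this yields 3053 bins.
* Fragments are assigned to bins by midpoint (deterministic for bins
  straddled by a fragment). Bins with no short/long fragment are flagged
  missing rather than imputed. The per-bin statistic entering the
  classifier is the short fraction itself; the within-sample z-score is
  also computed but would remove a genome-wide size shift, which is
  exactly the class signal when no regional copy-number structure exists.
* Every quoted filter threshold is strict: q < 1e-12, fold > 8,
  duplicate rate < 0.15 (WGS) / < 0.65 (5hmC), mapping rate > 0.95,
  enrichment fold > 95, Wilcoxon p < 0.05 / < 0.001, zero fraction
  "more than 10%".
* Region overlap counting uses the ≥ 1 bp rule by default
  (`overlap = "midpoint"` is available); a fragment is counted once per
  gene even when the merged promoter ∪ body region has several pieces.

## Numerical choices

* Wilcoxon p-values are exact for combined n ≤ 25 without ties, otherwise
  the normal approximation with tie and continuity correction; constant
  features get p = 1. Raw p-value thresholds are the convention of this
  selection procedure; a Benjamini–Hochberg option exists but is off by
  default.
* The LASSO penalty is chosen by seeded stratified 10-fold CV
  (`lambda.min`); features are standardized internally. When CV selects a
  penalty that eliminates everything (a signal-free cohort), the fit backs
  off along the path to the largest penalty retaining at least one
  feature, with a warning; an explicitly supplied penalty is honored
  exactly. Similarly, `select_markers()` carries the five best-ranked
  features past a univariate stage that would empty the set, so a null
  pipeline completes and honestly reports chance-level AUC.
* RFE drops the lowest-|weight| 10% of features per round (at least one),
  with fold assignment fixed once per call so subset scores are
  comparable; ties in the CV score go to the smaller subset.
* Fold assignment is stratified by class and, when sample ids are
  available, performed in id-sorted order so results do not depend on the
  order samples arrive in.
* The Mann–Kendall p uses the tie-corrected variance with continuity
  correction; an exhaustive permutation p is used for sequences of length
  ≤ 8 and a sampled one above that. For grouped inputs the sequence is
  per-sample values ordered by group rank with the within-group order
  randomized under a fixed seed; a group-median variant is reported
  alongside, since the correct within-group ordering is not identifiable.
* All randomness flows from a single master seed through stable integer
  hashing (`seed · 1000003 + 7919 · i mod 2^31−1`); reruns are
  byte-identical.

## What the synthetic cohort emulates

`cohort_config()` defaults describe a 171-subject study: 71 healthy
controls and 100 ESCC cases with stage composition 0/I/II/III/IV =
27/23/26/20/4 and a monotone stage→tumor-fraction map (0.01, 0.03, 0.06,
0.12, 0.20). Each sample draws `depth` fragments from a healthy/tumor
mixture:

* **sizes**: discretized lognormals with healthy mode 166 bp and tumor
  mode 145 bp (sdlog 0.15), so a pure-tumor sample has median size below
  150 bp;
* **motifs**: a fraction of tumor-affected fragments start at genome
  positions whose 4-mer begins with `CC`, tilting the end-motif profile
  through the genome itself rather than by editing counts;
* **NF**: tumor-affected fragments seated on marker-gene promoters are
  relocated, depleting promoter coverage at the 25 marker genes;
* **5hmC**: a fraction proportional to tumor fraction is placed into
  marker gene bodies, and the per-sample peak table adds
  Poisson(rate × tumor fraction) extra high-confidence peaks on top of a
  jittered baseline template, so peak counts rise with stage.

The end-motif, fragment-size and NF effects carry a class-level
("systemic") component on top of the tumor-fraction-proportional one.
This is deliberate: those signals arise partly from systemic nuclease and
chromatin alterations and are empirically detectable even at stage 0,
whereas 5hmC enrichment scales with the amount of tumor-derived DNA. The
generator therefore reproduces the qualitative structure that motivates
integration — fragmentomic analytes rescue stage-0 cases that the 5hmC
analyte alone misses. Setting every tumor fraction to 0 switches all
effects off and yields a pure null cohort.

What it does **not** emulate: GC and mappability bias, sequencing error,
PCR duplication structure, batch effects between cohorts, real chromatin
architecture, or separate 5hmC and WGS libraries (one fragment pool serves
both assays). Passing tests on this cohort therefore demonstrate that the
statistical machinery is correct and that the pipeline recovers planted
effects of realistic size — not that the classifier would achieve any
particular AUC on real plasma.

## Problem sizes

The default synthetic genome is two 1-Mb autosomes plus a 200-kb decoy
chrY (so chromosome-exclusion rules are exercised), 120 genes with TSS at
least 5 kb apart, 25 of them markers, and 10,000 fragments per sample at
100-kb fragment bins — sizes chosen so a full simulate→evaluate pipeline
run takes tens of seconds on one core while keeping per-window fragment
counts in a regime where the planted effects are neither trivial nor
undetectable. Unit tests use a further reduced 38-sample cohort.

## Known limitations

* The NF window layout and the promoter flank for 5hmC gene regions are
  package conventions; comparisons against externally computed NF scores
  require matching windows.
* DeLong CIs are degenerate (zero width) when the AUC is exactly 1, and a
  point CI is reported when a class has a single sample.
* `refit_integration()` recovers the generating coefficients only as well
  as the binomial information allows; with a few hundred samples the
  per-coefficient standard errors are in the 0.2–0.4 range, so refit
  coefficients should be read as weights, not as precise estimates.
* The SVM probability calibration (Platt scaling inside the final fit)
  introduces the only seed-sensitivity in the model path; it is pinned by
  the training seed.
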