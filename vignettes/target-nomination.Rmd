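---
title: "Methods: nominating NEPC-specific cell-surface targets from RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nominating NEPC-specific cell-surface targets from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfnom)
```

## The problem

Neuroendocrine prostate cancer (NEPC) is an aggressive,
androgen-receptor-indifferent subtype that emerges under the pressure of
AR-targeted therapy. Antibody-based modalities (ADCs, CAR-T, bispecific
engagers) need targets that sit on the cell surface, are expressed in
NEPC tumors, and are quiet in benign prostate, in localized
adenocarcinoma (PCa), in castration-resistant adenocarcinoma (CRPC), and
across normal tissues. `surfnom` implements that nomination logic as a
sequential filtering cascade over bulk RNA-seq count data, at both the
gene and the transcript-isoform level, together with a synthetic-cohort
generator that makes every stage testable without access to protected
patient data.

## Quantification

Counts are converted to abundance units directly from annotated feature
lengths. TPM is the rate normalization
$\mathrm{TPM}_{ij} = 10^6 \, (c_{ij}/\ell_i) / \sum_k (c_{kj}/\ell_k)$,
and FPKM is $10^9 c_{ij} / (\ell_i N_j)$ with $N_j$ the sample's total
count. We use the annotated length as the effective length: no
fragment-length correction is applied, because the cascade consumes
relative within-cohort comparisons for which a common length model
cancels. Presence filters aggregate per group with the median (mean of
the two central order statistics for even group sizes); the mean is
available via `cascade_config(presence_statistic = "mean")`. The
abundance unit of the presence filters defaults to TPM and is
configurable, since pipelines differ in whether they carry TPM or
rescaled FPKM through this step.

## The differential-expression engine

The engine is a deliberately compact negative-binomial Wald test:

* **Normalization** — median-of-ratios size factors over the features
  with nonzero counts in every sample. There is no pseudo-reference
  fallback; an input without an all-nonzero feature is rejected loudly.
* **Dispersion** — per-feature method of moments on normalized counts,
  $\hat\alpha = \max(\mathrm{floor}, (V - m)/m^2)$ with $V$ the
  within-group variance pooled across the design's groups and $m$ the
  pooled mean (variance model $\mu + \alpha\mu^2$). The floor is
  `1e-8`. No empirical-Bayes shrinkage is applied.
* **Test** — per feature, the two group means are fitted by maximum
  likelihood on the raw counts with log link, size factors as offsets
  and $\alpha$ fixed. The per-group log-likelihood is strictly concave
  in the log mean, so a damped Newton iteration (vectorized across
  features, steps clamped to ±3, convergence at $10^{-12}$) is exact
  and fast. The Wald statistic is
  $z = \log_2(\mu_\mathrm{num}/\mu_\mathrm{den}) / \mathrm{SE}$ with
  the SE from the observed information of the two fits; positive
  log2 fold change means higher in the numerator (NEPC in every
  cascade comparison).
* **Degenerate features** — all-zero in both groups: fold change 0,
  p = 1, flag `zero_both`. All-zero in exactly one group: the log2
  fold change is capped at ±10 (`lfc_cap`), the information evaluated
  at the capped fit, the feature flagged `lfc_capped`. Capped features
  therefore carry large standard errors and are rarely significant,
  which is the statistically honest behavior for one-sided zeros at
  these group sizes.
* **Multiple testing** — Benjamini–Hochberg within each pairwise
  comparison independently; comparisons are never pooled. All tested
  features enter the adjustment (no independent filtering: the
  cascade's own TPM presence filters play that role).

The omissions relative to the full DESeq2-style machinery — dispersion
shrinkage, LFC moderation, covariates, likelihood-ratio tests — are
intentional: the engine stays self-contained and checkable against an
independent numeric oracle (a generic optimizer maximizing the same
likelihood, with a numerical Hessian), which the test suite holds to
$|\Delta z| < 0.05$ on a 50-feature fixture. The cost of the unshrunk
plug-in dispersion is mild anticonservatism at small sample sizes: on
null two-group cohorts of 10+10 samples the suite measures a fraction
of $p < 0.05$ of about 0.06–0.07 rather than 0.05. Fold-change gates
use the raw (unshrunk) estimate, applied to the signed value — the
cascade nominates overexpression only.

## The cascade

Five stages, in a fixed order, each recorded in a `filter_trace` with
per-feature drop reasons:

1. **NEPC vs benign**: adjusted $p < 0.05$ (strict) and fold change
   $\ge 2$ (inclusive, on the signed log2 estimate), plus the presence
   rule: drop if benign median TPM $> 1.0$ or NEPC median TPM $< 1.0$
   (both strict).
2. **NEPC vs PCa**: the same construction at $p < 0.1$, fold change
   $\ge 1.5$, with PCa in the reference role of the presence rule.
3. **Surfaceome restriction**: keep features whose gene belongs to the
   union of the annotation sources (CD-nomenclature lists, CSPA, and
   the GO terms for ion transmembrane transport, transmembrane
   transport, and membrane). Union ("any of") rather than intersection
   is the reading of the sources as alternative evidence of surface
   localization; identifiers are matched verbatim with no alias
   resolution, which keeps the catalog database-version-agnostic.
4. **Tissue breadth**: drop a feature whose median TPM exceeds 3.0 in
   five or more tissues of the GTEx-style median matrix. The tissue
   set is whatever the matrix provides; an exclusion list is supported
   but off by default.
5. **NEPC vs CRPC**: $p < 0.1$, fold change $\ge 1.5$ — the stage that
   separates NEPC-specific from pan-aggressive candidates.

Stages 1–2 both run before the annotation step, matching the narrative
order of the published pipeline. When a feature fails both the DE and
the presence component of a combined stage, both reason codes are
recorded (`de_benign+presence_benign`).

Candidates are ranked by NEPC-vs-CRPC log2 fold change (descending) —
the quantity the final, most discriminating stage tests — with ties
broken by NEPC-vs-benign adjusted p (ascending) and then lexically by
feature ID, giving a reproducible total order on identical inputs.

The **isoform branch** runs the identical logic on a transcript-level
matrix, resolving surfaceome membership through `tx2gene`. It does not
attempt read-level isoform deconvolution (a Cuffdiff-style model needs
the reads themselves); transcript counts are taken as given. Nominated
isoforms whose parent gene was *not* nominated at gene level are
flagged `isoform_specific` — the pattern of a gene with flat total
output that swaps to an NEPC-exclusive isoform, as in the CDH2-type
finding.

## The synthetic cohort

`simulate_cohort()` emulates the statistical structure the cascade
assumes, not any particular dataset: NB counts
($\mathrm{Var} = \mu + \alpha\mu^2$, $\alpha = 0.2$) with group-specific
means, per-sample depth factors log-uniform in $[0.5, 2]$, background
baseline means log-normal($\log 50$, 1) over 2,000 genes, and a cohort
of 20/20/20/12 benign/PCa/CRPC/NEPC samples — a scaled-down echo of the
66/68/72/27 study cohort. Tissue medians are generated directly rather
than via simulated tissue samples, because the breadth filter consumes
only medians.

Each planted class is constructed to exercise exactly one stage:
true targets (NEPC-only surface genes, fold change 8), benign-leaky
decoys (NEPC-high but benign median TPM > 1 — die at stage 1's
presence rule while passing its DE gate), non-surface decoys (stage 3),
broad-tissue decoys (elevated in 5–12 tissues — stage 4), CRPC-shared
decoys (high in both NEPC and CRPC — stage 5), and isoform-switch genes
(flat gene totals; isoform usage 0.9/0.1 reversing to 0.1/0.9 in NEPC,
so the minor isoform carries a planted fold change of 9 while the gene
is invisible to the gene branch). Gene rows of switch genes are the
exact sum of their two isoform rows, so conservation holds by
construction; `simulate_isoforms()` therefore takes the realized cohort
object rather than a configuration, which guarantees the two levels
share one realization.

Two generator constants deserve explanation. Planted features carry a
20-kb length and an off-state mean of 1.5 counts. At this cohort's
scaled-down depth (roughly $10^5$ reads per sample over 2,000 genes), a
TPM of 1.0 for a typical 1-kb gene corresponds to ~0.1 counts — far
harsher than in a full transcriptome at $3\times10^7$ reads, where 1
TPM is tens of counts. Long planted features restore the realistic
regime in which the presence threshold sits near 4 counts, several-fold
above the off state and several-fold below the NEPC state; the margins
were chosen from exact NB tail probabilities so that each gate outcome
is realized by construction rather than by luck. The surface catalog
additionally includes 25% of background genes spread over the five
source types, so catalog membership is not a ground-truth oracle.

What the simulator does **not** emulate: batch and library-prep
effects, GC and positional bias, correlated genes, mixed tumor purity,
isoform-sharing of reads, and real annotation databases. Passing the
suite therefore demonstrates the pipeline's logic and calibration under
its stated model, not performance on real cohorts; in particular the
published stage counts (996 → 117 → 78 → 49 genes; 66,235 → 895 → 28
isoforms) depend on the protected cohort and versioned databases and
are documentation examples only.

## Problem sizes and reproducibility

The test suite and the acceptance script rerun the full pipeline on
40 simulated cohorts (gene branch), 20 cohorts (isoform branch), and
20 null cohorts of 10+10 samples × 2,000 features (type-I error),
sizes chosen to estimate the operating characteristics to within a few
percent while keeping a complete run in the low minutes on one core.
All randomness flows from a single master seed (sub-seeds are drawn
once from it), every writer can embed a `run_metadata()` block
(version, resolved configuration, input checksums, seed), and
identical seed + configuration reproduce outputs byte-identically.

## Known limitations

* The Wald test with unshrunk moment dispersions is anticonservative
  at small $n$ (measured above); for cohorts much smaller than the
  defaults an established shrinkage-based engine is preferable.
* Effective lengths ignore fragment-length correction, so FPKM/TPM
  values for short features are biased relative to
  fragment-model-aware quantifiers.
* Verbatim identifier matching makes catalog coverage the user's
  responsibility (`report_unannotated()` surfaces the gap).
* The isoform branch inherits transcript-level counts as given;
  quantification uncertainty from read sharing between isoforms is not
  propagated.
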