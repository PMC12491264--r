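---
title: "Methods: pan-cancer multi-omic RCD signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer multi-omic RCD signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multioptosis)
```

# The model

`multioptosis` implements a pan-cancer screen of regulated-cell-death (RCD)
genes. The unit of discovery is the *mono-omic, multi-phenotypic signature*:
a group of features from a single omic layer (protein, mutation, CNV, miRNA,
transcript isoform, mRNA or CpG methylation) that, within one cancer type,
(i) reaches genome-wide significance for rank correlation with one of three
tumor-intrinsic indices — tumor mutation burden (TMB), microsatellite
instability (MSI) or a tumor stemness metric (TSM) — and (ii) shares every
contexture code: correlation sign (SCS), tumor-vs-normal polarity (TNC), Cox
hazard contexture (HRC) and Kaplan–Meier survival contexture (SMC) over four
endpoints (DSS, DFI, PFI, OS), microenvironment (TMC) and immune-infiltrate
(TIC) contexture, and the gene-level RCD-form set. Each signature is encoded
as an eleven-component identifier
`CTAB-GSI.GFC.PFC.SCS.TNC.HRC.SMC.TMC.TIC.RCD`, ranked for clinical
meaningfulness, and optionally validated against an independent meta-Z
table of gene–overall-survival associations.

## Screening and multiple testing

Each (cancer × layer × phenotype) run is one screening family: every
feature's Spearman correlation with the phenotype index (average-rank ties,
p-value from the large-sample t approximation) is Holm-adjusted within that
family, and a feature enters the signature pool only at adjusted
p < 5 × 10⁻⁸. Defining the family per run is what makes a genome-wide
threshold meaningful at genome scale; it is the one reading of the screen
under which that threshold does real work, and it is isolated in
`spearmanScreen()` should a different family be preferred. Features with
zero variance are excluded and reported, never emitted as rho = 0. All
downstream per-feature associations (Wilcoxon polarity, Cox, log-rank,
cell-infiltrate correlations) are individually evaluated at unadjusted
p < 0.05, except the tumor-vs-normal test, which is Benjamini–Hochberg
adjusted across genes within a cancer type — the conventional
transcriptome-wide choice where the adjustment method is otherwise
unspecified.

## Bi-layer annotation

Phenotypic contexture needs a continuous, expression-like signal. For
protein, mutation, CNV and methylation features, TNC, HRC and the TMC/TIC
correlation profile are therefore computed from the *companion mRNA* of the
same gene locus, while SMC group construction keeps the native categories
where they are defined: mutation contrasts carriers (MT) vs wild type (WT);
CNV contrasts Deleted ({−2, −1}) vs Duplicated ({1, 2}) with neutral samples
excluded, falling back to pooled non-neutral vs neutral (letter D) when the
two-group contrast is unavailable or not significant. A feature whose parent
gene has no mRNA row receives no-data codes (TNC 0, TMC/TIC 4, all-A
endpoint arrays) rather than being dropped.

## Survival coding

HRC fits a univariate Cox model per endpoint — deliberately without
clinical covariates, since the goal is large-scale discovery, not adjusted
effect estimation — and codes B (risky) for p < 0.05 with HR > 1, C
(protective) for p < 0.05 with HR < 1, A otherwise. Endpoints with fewer
than two events, constant covariates or non-converging fits are coded A
with an explicit flag. SMC dichotomizes continuous features at the median;
samples exactly at the median go to the Low group, a deterministic,
documented tie rule (the quantile used for dichotomization is a declared
design choice — the methodology we follow does not state one). The letter
reports the group with poorer survival (higher observed-than-expected
events in the log-rank contrast) when p < 0.05.

## Microenvironment and immune contexture

The feature's expression is correlated with 29 deconvoluted cell-type
scores. The *presence sign* of each correlation is read through the TNC
lens: for underexpressed features the correlation sign is inverted (a
positive correlation with an underexpressed feature indicates a lower
presence of that cell type). TMC sums |rho| over significant
presence-indicating cells per tumor role (anti-tumoral / pro-tumoral /
dual) and takes the largest aggregate; TIC sums presence-adjusted rho over
hot markers (CD8 T, activated NK, M1) vs cold markers (M2, Tregs), with
near-ties re-decided after doubling the CD8/NK weights. The aggregation
statistic — a simple sum of magnitudes over presence-indicating significant
cells — is the simplest reading of "combined magnitude considering signs";
the exact published weighting is supplementary-only, so the statistic is
deliberately isolated in one function (`tmcRoleScores`, `classifyTIC`) for
replacement. Tie detection uses an epsilon of 10⁻⁹ on the aggregate scale,
i.e. exact ties under floating point. The 29-cell role assignment ships as
an editable TSV (`inst/extdata/cell_categories.tsv`); since the panel
contains both resting and activated NK subsets and the marker set must be
exactly five cells, the activated subset is designated the NK hot marker.

## Grouping, identifier and ranking

Annotations are partitioned by exact equality of the full grouping key;
members of a signature therefore agree on every identifier component,
including an *identical* gene-level RCD-form set (intersection = union —
features whose parent genes differ in form set are never merged). GSI
numbers are assigned by sorting a cancer's signatures on (layer code,
phenotype code, first member id) and numbering from 1: the published
material never defines GSI order, so determinism is the requirement the
rule serves. Composite signature scores are the raw member-wise sum, as the
construct is defined (a z-score option exists behind a flag); when
composite re-evaluation disagrees with the shared member codes the
member-level codes stay authoritative for the identifier and the
disagreement is surfaced via a consistency flag.

The HRC/SMC array ↔ integer mapping is data-driven. The published
component definitions pin only three codes (AAAA → 0, AAAB → 1,
BBBB → 44) and state 128 combinations, yet four positions over three
letters give 81 and over four letters 256, and no positional base
reproduces 44; the complete published table is supplementary-only. The
package therefore ships a complete lexicographic fallback (codes 0–255,
reproducing anchors 0 and 1) and a published-anchors table with exactly the
three pinned codes; every codec result is interpreted relative to the
loaded table, whose identity is carried in the result.

The default rank map is additive and fully overridable: TIC hot/variable/
cold/no-data contribute 3/2/1/0, TMC likewise, each non-A HRC or SMC letter
contributes 1, informative TNC (codes 2, 3) contributes 1, and each member
beyond the first contributes 1 capped at 5. It preserves the orderings the
codes express (hot, anti-tumoral, all-endpoint signatures rank highest) but
does not — and does not try to — reproduce published rank integers, whose
exact mapping is supplementary-only. Representative selection takes, per
RCD form or per omic layer, the maximum under the lexicographic comparison
(rank, member count, TIC, TMC, SMC, HRC), with a logged deterministic
fallback on the identifier key; selecting per omic layer inherently
guarantees every layer with at least one signature is represented.

Meta-Z validation takes the median score over member genes found in the
table (missing genes are excluded and counted), and validates at |Z| > 3.09
with the sign matching the direction implied by HRC: a risky OS letter
implies poor prognosis, a protective OS letter favorable, otherwise the
majority of B vs C letters decides and an unresolved mix skips validation
with a reason.

# The synthetic-data generator

The generator exists so every stage is testable without external
downloads. What it emulates, and how:

* **Planted rank correlations** use a Gaussian copula: feature latents are
  tied to the phenotype latent with Pearson r = 2·sin(π·ρ/6), which gives
  the target Spearman ρ exactly for continuous marginals. Expression
  layers add a per-feature log-scale baseline (monotone, so ρ is
  preserved); methylation maps latents through a probit to beta values;
  mutation thresholds the latent at a 5% default prevalence (rare
  mutations being the biologically interesting regime) and CNV cuts it at
  {0.02, 0.18, 0.60, 0.18, 0.02} quantiles — a plausible
  gistic-thresholded shape. Discretization attenuates the realized rank
  correlation on those two layers; recovery tests therefore use the
  continuous layers.
* **TMB/MSI/TSM** are continuous standard-normal indices. No
  distributional description of the real indices is available to us, and
  the screen consumes them only through ranks, so any continuous marginal
  is equivalent for the tested pipeline.
* **Survival** is exponential with hazard `baseline × exp(lp)` and
  administrative censoring at the (1 − rate) quantile of the drawn event
  times, making the realized censoring fraction reproducible.
* **Infiltration scores** are noise plus a shared latent immune axis
  (loading 0.3); planted profiles add ±0.5 loadings of the (standardized)
  feature latent onto chosen cell types, so TMC/TIC classification can be
  checked against planted ground truth.
* **The inventory generator** controls three headline fractions jointly:
  the apoptosis marginal (default 0.814), the multi-form fraction (default
  2403/5913) and the apoptosis-only fraction (default 2511/5913), by
  drawing multi-form status first and apoptosis membership with the
  conditional probabilities those targets imply,
  feasibility-adjusted for degenerate requests. The relative weights of
  the other 24 forms are invented — only their ordering (alkaliptosis,
  lysosome-dependent cell death and methuosis rarest) is anchored — and
  act solely as sampling weights for non-apoptosis slots.

What it does **not** emulate: batch effects, tumor subtype structure,
realistic gene–gene correlation, copy-number segment structure, or any
read-level process. Passing tests therefore demonstrate the pipeline's
statistical behavior under its stated model — calibration under the null,
recovery of planted effects, invariance and determinism properties — not
performance on real tumor data.

# Problem sizes and numerical choices

The test suite's calibrated run uses four cohorts of 2,000 genes (two
isoforms each), 250 tumor and 40 normal samples, with a dozen planted
effects per cohort spread over all seven layers; the same conditions drive
`scripts/acceptance.R`. The cohort-size analysis uses a ladder of eight
cohorts of 300 genes with fixed planted effects and 80–500 patients, so
the signature yield grows with statistical power exactly as the
cohort-size correlation describes. Null calibration of the Cox screen uses
1,000 simulated features at n = 100 with 30% censoring. These sizes are
the package's chosen synthetic study conditions; the generator scales to
larger runs by configuration.

Numerical conventions: printed ratios and percentages round half away from
zero at the printed precision (13.14 = 1564/119 at two decimals); Spearman
p-values use the t approximation (exact enumeration appears only in test
oracles); Holm and BH adjustments delegate to `stats::p.adjust`; Cox and
log-rank fits delegate to the `survival` package, with non-convergence
mapped to the no-effect code plus a flag rather than an error.

# Known limitations

* The array ↔ code table and the rank-map integers are reconstructions up
  to the published anchors; results that depend on the full published
  assignments must load them as data.
* Bi-layer annotation assumes the companion mRNA is an adequate contexture
  proxy for mutation/CNV/methylation/protein features; that is a modeling
  commitment, not a validated equivalence.
* Rank-correlation planting is exact only for continuous layers; binary
  and ordinal layers attenuate, so planted-effect guarantees are stated
  for expression layers.
* The generator's independence assumptions (features independent given
  the planted structure) make the Holm family size an upper bound on the
  effective number of tests; real data with correlated features would be
  more conservative under Holm, not less.
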