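---
title: "Mapping eQTLs from qPCR expression traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping eQTLs from qPCR expression traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlpanel)
```

`eqtlpanel` maps expression quantitative trait loci (eQTLs) when transcript
abundance is measured by RT-qPCR across a diversity panel of hybrids that
share one common tester parent. Because every hybrid has the tester in
common, between-hybrid expression differences trace back to the line-side
alleles, and a genome-wide scan of the line genotypes is equivalently a test
of allele-specific expression imbalance at each locus. This vignette
explains the models, the tunable parameters, the synthetic-data generator
used for validation, and the numerical choices, in that order.

## From Ct values to traits

qPCR yields one cycle-threshold (Ct) value per well. With technical
replicates averaged first on the Ct scale, relative expression of a target
in a sample is computed against a panel of reference genes:

$$\Delta C_t \;=\; \overline{C_t^{\text{ref}}} - C_t^{\text{target}},
\qquad \text{relative expression} = 2^{\Delta C_t},$$

so the log2 relative expression used everywhere downstream *is* the
delta-Ct. Two conventions are deliberate:

* references are aggregated by the **arithmetic mean of their Ct values**
  (equivalently the geometric mean of their linear quantities), the
  dominant multi-reference qPCR convention;
* technical replicates are averaged **before** the delta is taken, so a
  missing technical replicate degrades precision but not the estimator.

A sample missing its target or any requested reference is propagated as
missing; a line with no usable sample is dropped with a warning.

Repeatability — called "heritability" in this assay context — is estimated
from the replicate-level model `Expression ~ Genotype (random)` by REML
(`lme4`), and reported as

$$H = \frac{V_g}{V_g + V_e / n},$$

the reliability of a genotype mean given `n` biological replicates
(`n` = the median replicate count when unbalanced; the design here is 3
biological × 2 technical replicates). `H` is invariant to shifting or
rescaling the trait; the balanced-design method-of-moments ANOVA estimator
is used as an independent oracle in the tests.

Descriptive statistics mirror standard practice for structured panels:
Kruskal–Wallis omnibus tests across admixture groups with Holm-adjusted
pairwise Wilcoxon tests (stars at 0.1/0.05/0.01), and a PCA on
unit-variance-scaled traits with case-wise deletion.

## The association scan

For each trait (genotypic means over biological replicates) the scan fits
the single-locus mixed model

$$Y = \mu + X\beta + G + E, \qquad
G \sim N(0, \sigma^2_g K), \quad E \sim N(0, \sigma^2_e I),$$

where `X` is the dosage of the tested marker and `K` a genomic relationship
matrix (VanRaden method 1 on mean-imputed dosages,
`K = ZZ' / 2Σp(1−p)`). To prevent the tested signal from being absorbed
into the polygenic term, `K` is recomputed **excluding the chromosome of
the tested marker** (leave one chromosome out, LOCO).

Numerics: a single eigendecomposition of each LOCO kinship turns the GLS
problem into weighted least squares in the rotated basis. Variance
components are estimated once per (trait × chromosome) by REML — a 64-point
grid on `log δ ∈ [−12, 12]`, `δ = σ²e/σ²g`, followed by Brent refinement —
and reused for every marker of that chromosome (the P3D/EMMAX
approximation; exact per-marker refitting is available behind
`refit = TRUE`). The marker effect is tested with a 1-df F statistic;
markers with MAF ≤ 0.05 are excluded and `-log10(p) ≥ 5` declares
significance, both panel-scale conventions carried as defaults in
`scan_config()`. The approximation is slightly conservative for very large
effects (validated in the tests: exact refitting only increases the lead
`logp`, by under 15% in relative terms).

Variance explained by a marker is the likelihood-ratio form
`r²_LR = 1 − exp(−(2/n)(LL₁ − LL₀))` with the profiled-scale ML
likelihoods; in the identity-kinship limit this reduces exactly to the
classical regression R², which the tests exploit.

Two scan variants handle the artifact corrections below: a **conditional
scan** (marker dosages added as fixed covariates — a tested marker
collinear with a covariate is reported with missing statistics, not
dropped) and a **subpanel scan** (kinship and variance components
re-derived on a restricted line set).

## From significant SNPs to eQTLs

Significant SNPs are clustered by **kinship-corrected LD windows**:

* `r²K` is the squared correlation between two dosage vectors after
  whitening by `K^{-1/2}`, computed as a GLS correlation (centering on the
  whitened intercept) so the value does not depend on the square-root
  factorization. With `K = I` it is the classical `r²`.
* Each significant SNP gets a window by scanning outward (default radius
  2 Mb): the boundary on each side is the last marker with `r²K ≥ 0.1`
  seen before `min_run = 3` consecutive markers fall below the threshold.
* SNPs whose windows overlap (closed intervals, transitive closure per
  chromosome) form one eQTL, delimited by the outermost window limits. The
  lead SNP is the most significant member; `logp` ties break to the
  smallest physical position.
* An eQTL is **local** if the trait gene's transcribed interval is strictly
  contained in the eQTL interval, and **distant** otherwise — terms chosen
  over cis/trans because containment asserts nothing about mechanism.

Coordinates are 1-based inclusive internally (GFF3 convention); BED export
converts to 0-based half-open. Colocalization between eQTL sets is
closed-interval overlap of at least 1 bp.

When a local eQTL is very strong (lead `-log10(p) > 12`, the pipeline's
configurable trigger), `run_pipeline()` re-scans with the lead SNP as
covariate. This clears the "tail" of redundant associations in moderate LD
with the main signal and can reveal secondary local eQTLs hidden under it.

## qPCR-specific artifact handling

Two failure modes are specific to qPCR-based expression traits, and both
are planted in the synthetic generator so the corrections can be scored:

1. **A reference gene with its own eQTL.** Any genetic effect on a
   reference gene biases the delta-Ct of *every* target in carrier lines
   (diluted by the number of references). `check_reference_gene_eqtl()`
   flags any called eQTL whose interval overlaps a reference gene's
   transcribed region — the eQTL interval already embodies the local LD
   extent, so no extra distance margin is used. Both corrections are
   provided: re-normalizing without the contaminated reference, or keeping
   it and conditioning the scan on the flagged lead SNP. The covariate
   route is the default recommendation because it leaves the expression
   values of all other targets untouched.
2. **A polymorphism under a qPCR primer.** An allele that disrupts primer
   annealing inflates the target's Ct in carrier lines, creating a
   spurious, technically-driven local eQTL. Given user-supplied primer
   coordinates, `primer_polymorphism_filter()` lists genotyped markers
   inside them, partitions the panel (favorable homozygotes — by default
   the majority class — vs. unfavorable homozygotes vs. heterozygotes) and
   emits the line mask for `subpanel_scan()`; the spurious signal
   disappears while genuine signals elsewhere persist.

QC never edits association statistics; it only changes inputs (reference
set, covariates, line mask), so every corrected run replays from its
logged configuration.

## The reporter-assay model

The promoter-swap validation assay measures, per transformed cell, total
reporter (mVenus) and normalizer (mCherry) fluorescence; the readout is
`log2(reporter/normalizer)`, which cancels transformation efficiency and
exposure. The 2×2 design (promoter background × promoter-indel
presence) is fitted by REML as

`log2_ratio ~ background * indel + (1 | experiment)`

with a random intercept per replication batch. Fixed effects use treatment
coding with the first background and "indel absent" as reference, so the
indel coefficient reads directly as the deviation its presence causes.
Inference is by Wald t with residual degrees of freedom (hundreds of cells
and a handful of fixed effects make this essentially exact; a
likelihood-ratio alternative is available via `test = "lrt"`). At the
design scale of the validation (3 experiments × ~40 cells per condition,
residual SD 0.6), a planted −0.5 indel effect is recovered within ±0.15
with over 90% power, and the null type-I error is within [0.03, 0.07] —
both recomputed by `scripts/acceptance.R`.

## The synthetic panel: what it emulates, and what it does not

`simulate_panel()` generates the line-side dosages of a tester-hybrid
diversity panel. Defaults mirror the panel design the package targets:
252 hybrids in six admixture groups of 32/34/32/16/36/102 lines, mostly
homozygous dosages with rare heterozygous calls (`het_rate = 0.005`) and
1% missingness at random.

* **Group structure** is Balding–Nichols: group allele frequencies are Beta
  draws around a shared ancestral frequency with variance
  `differentiation × p(1−p)`. A Hudson-type estimator over many markers
  recovers the `differentiation` parameter (tested at 0.3 ± 0.05); the
  default 0.1 reflects the modest divergence of elite breeding pools.
* **LD** is blockwise: ancestral and group frequencies are drawn once per
  LD block and shared by its markers (co-segregating alleles have similar
  frequencies, which is what sustains high within-block `r²`), and each
  line carries a latent Gaussian AR(1) along the chromosome whose
  autocorrelation decays slowly within a block and resets at block
  boundaries. The result is strong within-block LD decaying with distance
  and independence across blocks — a haplotype-mosaic caricature that is
  sufficient for window/clustering logic, but it is **not** a coalescent:
  no allele-frequency spectrum realism, no LD beyond one block, no
  selection. Conclusions about window sizes on real data should not be
  read off these simulations.
* **Architecture** is planted by `plant_architecture()`: causal markers
  with additive effects, a polygenic component
  `N(0, σ²_poly · K(genotypes))`, optional group shifts and line-level
  noise. `effect_for_variance_fraction()` sizes an effect to a target
  variance share given the realized MAF.
* **The measurement layer** (`simulate_ct()`) reproduces the assay design:
  3 biological × 2 technical replicates, shared reference genes, target
  Ct = baseline − (trait + biological noise) + technical noise. The
  published assay does not state its Ct noise magnitudes; the defaults
  (biological 0.4 Ct, technical 0.15 Ct) are package choices representative
  of SYBR-green assays, exposed in `assay_artifact_config()`. The helper
  `expression_residual_variance()` gives the implied residual variance of
  the delta-Ct readout, `(σ²_bio + σ²_tech/n_tech)(1 + 1/n_ref)`, used to
  plant exact repeatabilities.

## Validation scenarios and the problem sizes used

The `scenario_*()` functions freeze the study conditions used by the test
suite and by `scripts/acceptance.R`:

* `scenario_structured_null()` — 150 lines, 10 chromosomes × 200 markers,
  LD blocks of 50 kb, polygenic and line-level variance 0.5 each. Over 20
  seeds the scan's pooled type-I error at p < 0.05 is ~0.056 and the
  genomic-control λ ~1.05. The small excess over the nominal 0.05 is not a
  defect of the test statistic (with the full kinship in place of LOCO the
  scan is calibrated to ~0.050): under LOCO, the tested marker's own share
  of the kinship-derived polygenic background is genuine signal, worth
  roughly `n/m` noncentrality per marker — visible at 2,000 markers,
  negligible at full genotyping density. Many short blocks are used for
  this scenario precisely to mirror the full-density regime where one
  marker tags a tiny genome fraction.
* `scenario_local_eqtl()` — 150 lines, 3 chromosomes × 300 markers over
  10 Mb each; one causal marker mid-block on chromosome 2 sized to half
  the trait variance (the magnitude of a major promoter polymorphism),
  with the 3-kb trait gene placed around it. The pipeline recovers it as
  the single, top-ranked local eQTL containing the causal position in
  ≥95% of seeds, and conditioning on it clears its LD block.
* `scenario_reference_gene_artifact()` — adds a 4-Ct genetic effect on one
  of three reference genes, sized (after dilution by the three-reference
  mean) so the artifact eQTL is unambiguous at this panel size, alongside a
  genuine local eQTL for the target that the corrections must not destroy.
* `scenario_primer_artifact()` — a +2 Ct primer-dropout allele carried by
  the minority homozygote class (~15% of lines) plus a genuine distant
  eQTL (40% of variance) that must survive the subpanel correction.

These sizes keep each scenario under a second per seed; rates are measured
over 50 seeds.

## Known limitations

* The P3D approximation under-states very large effects slightly;
  `refit = TRUE` is exact but linear in markers × REML cost.
* LD windows use the per-SNP outward scan with a consecutive-miss stop
  rule; other window definitions (e.g. decay-curve-based) would shift
  interval edges, and the `min_run`/`scan_radius_bp` parameters are the
  knobs to explore that sensitivity. Whether distant "tails" on the same
  chromosome should merge across gaps is left to those parameters.
* `heritability()` treats technical replicates as part of the biological
  replicate mean; no amplification-efficiency calibration or ΔΔCt
  calibrator logic is included.
* The simulator draws the line-side dosage directly and absorbs the common
  tester; specific line × tester interaction is outside its model.

## A worked run

```{r pipeline, eval = FALSE}
sc <- scenario_local_eqtl(seed = 101)
cfg <- pipeline_config(
  simulate = list(panel = sc$config, architectures = list(PIPsim = sc$arch)),
  gene_models = sc$gene, out_dir = "eqtl_run", seed = 101)
res <- run_pipeline(cfg)
res$heritability
res$eqtls_initial$PIPsim
```

The run writes `heritability.tsv`, per-trait association tables, initial
and covariate eQTL tables (TSV + BED), a QC report (JSON), a recovery
summary against the planted truth, and the resolved configuration with its
seed, from which the whole run replays bit-identically.
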