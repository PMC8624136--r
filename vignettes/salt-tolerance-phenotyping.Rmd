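---
title: "Methods: spectral and yield-based salt-tolerance phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral and yield-based salt-tolerance phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halotype)
```

# The problem

Breeding salt-tolerant wheat requires ranking many genotypes by how well
they yield under saline irrigation relative to normal irrigation.
Harvest-based screening is slow and destructive, so canopy hyperspectral
reflectance — measured in minutes per plot at anthesis — is attractive as
an indirect criterion: pigment status shapes the visible region
(400–700 nm), biomass and leaf structure the near-infrared (700–1300 nm),
and canopy water content the water absorption features in the NIR/SWIR
(970, 1170, 1450, 1950 nm).

`halotype` implements the full analysis chain for a two-treatment
(control vs. saline irrigation), multi-year, replicated field trial:

1. **Spectra handling** — a 350–2500 nm, 1-nm wavelength grid (2151
   samples spanning 2150 one-nm bands), masking of the atmospheric
   absorption windows 1825–1915 nm and 2470–2500 nm (122 samples),
   nearest-band lookup, replicate-scan averaging, wide/long text I/O.
2. **Spectral reflectance indices (SRIs)** — 20 registry-defined indices
   (10 vegetation, 10 water) evaluated per plot.
3. **Stress tolerance indices (STIs)** — YSI, SSI, STI, TOL, GMP per
   genotype from mean control/salinity yields.
4. **Tolerance grouping** — Ward minimum-variance clustering of
   genotypes on the seven yield features, cut at k = 3 and labelled
   salt-tolerant / salt-sensitive / moderately salt-tolerant.
5. **Association screening** — Pearson correlations of genotype-mean
   SRIs against yields and STIs with a critical-|r| significance flag.
6. **Index selection** — partial-F stepwise multiple linear regression
   (SMLR), plus per-group best linear/quadratic fits.
7. **Split-plot ANOVA** — per-year fixed-effects decomposition with the
   whole-plot error for the salinity test.
8. **Synthetic trial generator** — group-structured yields and canopy
   spectra so that every stage is testable without field data.

# Models and formulas

## Stress tolerance indices

For a genotype with mean yields $GY_c$, $GY_s$ (t ha⁻¹, averaged over
years × replicates) and population means $\bar{GY}_c$, $\bar{GY}_s$ over
all genotypes:

$$\mathrm{YSI} = \frac{GY_s}{GY_c}, \qquad
\mathrm{SSI} = \frac{1 - GY_s/GY_c}{1 - \bar{GY}_s/\bar{GY}_c}, \qquad
\mathrm{STI} = \frac{GY_c \cdot GY_s}{\bar{GY}_c^2},$$
$$\mathrm{TOL} = GY_c - GY_s, \qquad
\mathrm{GMP} = \sqrt{GY_c \cdot GY_s}.$$

The STI and GMP formulas are the canonical Fernandez forms; published
tables of these indices occasionally print them with dropped terms, and
only the canonical forms reproduce worked group-mean values such as
$\sqrt{5.18 \times 3.93} = 4.51$ and
$(6.23 \times 4.01)/5.670^2 = 0.78$ (with $\bar{GY}_c$ the size-weighted
mean over groups of 25/19/20 genotypes). Report tables round half away
from zero to 2 decimals (`round_half_up()`); internal values are never
rounded.

## Spectral index registry

Each index is a string formula over `R<wavelength>` terms, e.g. NDVI-1 is
`(R750 - R705)/(R750 + R705)`. Two conventions deserve a note:

* **NMDI** is implemented in the standard normalized multi-band drought
  form $(R_{860} - (R_{1640} - R_{2130}))/(R_{860} + (R_{1640} -
  R_{2130}))$. Printed versions of this index sometimes lose the outer
  brackets, which would not be a well-formed index; the corrected form is
  the only one consistent with observed NMDI ranges (roughly 0.1–0.8 on
  crop canopies).
* **WBI** is kept as the source study defines it,
  $(R_{1500}-R_{531})/(R_{1500}+R_{531})$, although other "water band
  index" conventions exist; likewise **BNDVI** uses 970 nm as its NIR
  term even though 970 nm sits on a weak water absorption band. The
  registry is data, so users who prefer other conventions can export it
  (`write_sri_registry()`), edit, and re-import without code changes.

Missingness is always explicit: a masked required band, a zero
denominator or a non-positive radicand under a square root (possible for
SWSI-1/2) produces `NA` plus a reason string, never a silent zero and
never a complex number.

## Grouping, association, selection

* **Clustering** uses all seven features (GYc, GYs, YSI, SSI, STI, TOL,
  GMP), z-standardized (population sd) because the features mix scales
  (t/ha vs. ratios). Distance is Euclidean, linkage is Ward's
  minimum-variance criterion (`hclust(method = "ward.D2")` on unsquared
  Euclidean distances). The source analysis names only "Ward's minimum
  variance"; standardization and the metric are this package's choices,
  fixed here. Labels come from group feature means — highest GYc *and*
  STI → salt-tolerant; of the rest, higher YSI and lower SSI →
  moderately salt-tolerant — and any disagreement or tie is an error
  requesting manual labels rather than a silent guess.
* **Correlation screening** is done on genotype means within a spectral
  scope (measurement treatment × year or combined), matching the n = 64
  critical threshold $|r| \ge t^*/\sqrt{t^{*2}+n-2} \approx 0.25$ at
  $\alpha = 0.05$. Strength bands are ns / weak (< 0.50) / moderate
  (< 0.70) / strong (≥ 0.70), boundaries assigned upward so reporting is
  deterministic. No multiple-testing correction is applied, matching the
  source analysis; the screen is exploratory by design.
* **SMLR** uses the classical partial-F thresholds `alpha_enter = 0.05`,
  `alpha_remove = 0.10` (configurable; `alpha_remove < alpha_enter` is
  rejected because it can cycle). Entry ties resolve by candidate order,
  which is the registry (report-table) order, so duplicated candidates
  select deterministically. RMSE is $\sqrt{SSE/n}$ — the denominator `n`
  rather than $n-p$ is a documented, test-pinned choice. The per-group
  quadratic is preferred over the linear fit only when it gains more
  than 0.01 in $R^2$ (parsimony margin; "highest $R^2$" alone would
  always pick the quadratic).

## Split-plot ANOVA

Salinity cannot be randomized within a block, so the layout is a
randomized complete block with salinity on main plots and genotype on
subplots. Per year, with r = 3 blocks, a = 2 treatments, b = 64
genotypes: df(ST) = 1 tested against the Rep×ST whole-plot error
(df = 2), df(G) = df(ST×G) = 63 tested against the subplot residual
(df = 252), total df = 383. Only the per-year fixed-effects analysis is
implemented; a combined-years mixed model (years random) is out of scope
— it adds REML machinery without changing the testable decomposition.
STIs have one value per genotype per year in this model, so their
genotype effect is assessed by a one-way RCBD ANOVA (`rcbd_anova()`) on
per-replicate STI values (`sti_per_replicate()` pairs control and
salinity plots within genotype × year × replicate).

# The synthetic trial generator

No field data accompany the method, so the generator is the package's
stand-in for the study conditions and is labelled synthetic throughout.

**Yields.** 64 genotypes in planted groups of 25/19/20 with group mean
control yields 6.23/5.45/5.18 t/ha and salinity yields 4.01/3.41/3.93
t/ha. Per genotype: $GY_{c,i} \sim N(\mu_g, 0.12)$ truncated positive;
$YSI_i \sim N(\bar{y}_g, 0.02)$ truncated to (0.40, 0.90) — bounds taken
from the observed YSI extremes (0.429–0.869) rounded outward; $GY_{s,i}
= YSI_i \, GY_{c,i}$. Plot yields add genotype × treatment × year
effects (sd 0.10 t/ha) and plot noise (sd 0.18 t/ha).

**Spectra.** Plot yield and treatment map affinely to three latent
canopy proxies in (0, 1]: chlorophyll `c`, biomass `b`, water `w`, each
reduced under salinity by a fixed factor (defaults 8%, 5%, 12%) plus
Gaussian noise (sd 0.02). The reflectance curve is

$$R(\lambda) = \mathrm{clip}\Big(\mathrm{base}(\lambda; b, w)
 - c \sum_{\mu \in \{450, 680\}} d_\mu G(\lambda; \mu, \sigma_\mu)
 - w \sum_{\mu \in \{970, 1170, 1450, 1950, 2500\}} d_\mu G(\lambda; \mu, \sigma_\mu)
 + \varepsilon(\lambda),\; 0.01, 0.99\Big)$$

where `base` is a logistic red-edge step from a visible shelf (0.28) up
to a NIR plateau $0.25 + 0.35\,b$, declining to a SWIR shelf scaled by
$(0.95 - 0.55\,w)$; $G$ are Gaussian absorption wells (depths
0.22/0.22 for the pigment wells; 0.06, 0.09, 0.28, 0.32, 0.20 × `w` for
the water wells, widths 25–120 nm); the 2500-nm well is a long-wavelength
water absorption tail that makes ~2200 nm a genuine local maximum, as
observed on real canopies. $\varepsilon$ is white noise convolved with a
30-nm Gaussian kernel and rescaled to sd 0.004, so index values vary
realistically rather than averaging the noise away within an index.

This construction reproduces, by design: valleys near 960/1170 nm, peaks
near 1640/2200 nm, the tolerant group lowest in the visible and highest
in the NIR, and positive vegetation-SRI–yield correlations.

**What the generator does not emulate.** (i) Min–max yield ranges: the
within-group spreads are set so that the three planted groups are
statistically recoverable (see below), which makes the generated
genotype-mean ranges narrower than real trial extremes (real data span
roughly 3.9–7.8 t/ha under control; the generator spans about 4.7–6.7).
Group separability and field-scale extremes cannot both hold with the
fixed group means, and recoverability is the property the tests need.
(ii) Radiative-transfer physics (PROSPECT/SAIL), soil background,
view-geometry and row-structure effects. (iii) Correlated genotype ×
year rank changes (year effects are independent noise). Consequently a
passing test suite demonstrates the *machinery* — formulas, error terms,
selection procedure, recovery — not field-level predictive performance.

# Numerical choices and degenerate inputs

* **Band count convention**: "2150 continuous 1-nm bands" over
  350–2500 nm is read as 2150 bands between 2151 samples.
* **Nearest-band tolerance**: 3 nm, the native VIS–NIR sampling interval
  of the field spectroradiometer; ties break toward the lower
  wavelength. A target with no unmasked sample within tolerance raises a
  classed `halotype_missing_band` condition that the index evaluator
  converts to a flagged missing value.
* **Mask windows** are closed intervals, inclusive at both ends
  (1825–1915 masks 91 samples, 2470–2500 masks 31).
* **Percent-scale detection**: reflectance > 1.5 anywhere triggers
  division by 100 with a warning (canopy reflectance fractions cannot
  reach 1.5).
* **Stepwise degenerate cases**: once a fit is exact (SSE ≈ 0 relative
  to SST), no candidate can enter (its partial-F gain is 0 → p = 1), and
  collinear candidates are skipped via rank checks, so a duplicated
  predictor can never join its twin.
* **Constant features/columns**: standardization errors on constant
  features (naming them); correlation cells with a constant column are
  flagged undefined, not set to zero; a constant ANOVA response yields
  all-zero sums of squares.
* **Reproducibility**: every generator entry point is seeded;
  `generate_trial()` funnels all randomness through one seed.

# Problem sizes used by the tests

The test suite exercises: the default 64-genotype trial (768 plot
spectra of 2151 samples) for the pipeline and recovery checks; 20 seeds
for clustering recovery (mean adjusted Rand index ≥ 0.9 against planted
groups, every seed ≥ 0.8); 100 seeds for stepwise recovery of a planted
spectral predictor at true $R^2 \approx 0.7$ against unrelated noise
candidates; 1000 null replicates for the 5% type-I error of the
correlation flag; 100 random spectra for bit-level (1e−12) agreement of
the registry evaluator with a direct-arithmetic oracle; and 32,000
genotypes for the law-of-large-numbers check of the yield generator.
The stepwise recovery test deliberately uses noise competitors: several
registry indices are near-duplicates by construction (e.g. NWI-1 vs
NWI-2 share 2 of 2 bands up to a swap, r > 0.99 on generated data), so
"which family member enters first" is not identifiable among
near-collinear siblings — a known limitation of stepwise selection, not
of this implementation.

# Known limitations

* Per-year fixed-effects ANOVA only; no combined-years mixed model.
* No multiple-testing correction in the correlation screen (matching the
  source analysis); users screening many indices should interpret
  borderline flags accordingly.
* Stepwise selection inherits the instability of all stepwise methods
  under collinearity; the registry's index families are strongly
  correlated, so selected-index identity (though not fit quality) can
  change with small data perturbations.
* The generator is a phenomenological curve model, not a
  radiative-transfer simulation; absolute index values are plausible but
  not calibrated to instrument data.
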