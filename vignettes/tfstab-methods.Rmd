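---
title: "Methods: environment stability and the transcription-factor repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment stability and the transcription-factor repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfstab)
```

## The scientific question

Transcription factors (TFs) let prokaryotes reprogram gene expression when
conditions change. Regulation is only worth its genomic cost where the
environment actually varies, so communities from seasonally dynamic waters
should carry systematically more — and different — TF genes per genome than
communities from stable waters. `tfstab` estimates how much of the
between-sample variation in TF gene content of marine metagenomes is
attributable to the seasonal *stability* of the environment, how much to
spatial separation as such, and how much to neither.

The package treats the problem as a chain of standard, individually testable
inferential steps. This vignette records the model behind each step, the
tunable parameters with their defaults and units, the numerical conventions,
and the design decisions taken where more than one defensible choice exists.

## Environment stability from gridded climatologies

**Interpolation.** Climatologies arrive as monthly fields on a regular
latitude × longitude × depth grid (one value per degree and depth level, as
in standard ocean atlas products). The value of a parameter at a sampling
site for month *m* is an inverse-distance-weighted (IDW) average of nearby
grid nodes,

$$\hat v = \frac{\sum_i d_i^{-p}\, v_i}{\sum_i d_i^{-p}},$$

over the `k_neighbors` nearest non-missing horizontal nodes at the depth
level closest to the site's depth. Defaults: power `p = 2` and
`k_neighbors = 4` — the textbook IDW configuration for a quasi-regular
one-degree grid, where four nodes bracket any interior query. Both are
configurable because IDW has no canonical neighbourhood; reproductions of
third-party interpolations may therefore differ in detail. Node distances
are great-circle distances, so longitude wrap-around at ±180° is handled
correctly. A query within 1 m of a node returns the node value exactly
(zero-distance short-circuit). Depth is matched to the nearest standard
level rather than interpolated vertically: epipelagic samples (≤ 30 m) sit
where standard levels are 10 m apart, so vertical interpolation would add
machinery without information. Sites outside the grid bounding box are
errors; a month whose entire neighbourhood is missing (land or unsampled
cells) marks the whole series "unavailable" — the analysis then drops the
site rather than fabricating a value, which is also how sites with known
unreliable coastal interpolations should be treated (see
`validation_exclude`).

**Stability.** The stability of a parameter at a site is the sample standard
deviation of its twelve monthly interpolated values
($N - 1 = 11$ in the denominator). Lower values mean a more stable
environment. A constant series has stability 0; for a noise-free sinusoidal
seasonal cycle of amplitude $A$ sampled at the twelve month points the value
is exactly $A\sqrt{6/11}$, which the test suite uses as a closed-form
oracle.

**Z-scoring.** Stabilities of different parameters live on incomparable
scales (°C vs µmol l⁻¹), so each column is transformed to
$z = (x - \mu)/\sigma$ with mean and SD taken across all samples. After the
transformation every column has mean 0 and sample SD 1; the transformation
is idempotent and refuses constant columns.

**Collinearity pruning.** Strongly co-varying stability measures (nutrient
pairs, the oxygen-derived trio) would make ordination coefficients
uninterpretable. All pairwise Spearman rank correlations are computed;
whenever $|\rho| > 0.6$ and the correlation test is significant (two-sided
p < 0.05), the lower-priority member is dropped. The default priority —
temperature > salinity > phosphate > silicate > dissolved oxygen > nitrate >
AOU > oxygen saturation — prefers directly measured, mechanistically primary
parameters over derived oxygen quantities and over nutrients that shadow
each other through stoichiometric coupling. Two conventions had to be fixed
by decision: the threshold applies to $|\rho|$ (a strong negative
correlation is as collinear as a positive one), and pairs exceeding the
threshold without statistical significance are *retained* with a warning
(at small n a large $\rho$ can be noise). The greedy keep-by-priority rule
makes the retained set independent of column order.

**Validation against in-situ measurements.** Where shipboard measurements
exist, the package regresses interpolated (response) on measured
(explanatory) values in identical units and reports slope, intercept, R²
and the model p-value, plus the site with the largest absolute residual. A
slope near 1 with high R² justifies using interpolations where measurements
are missing; a gross residual flags a site whose local water mass the
gridded product cannot represent (lagoons, mangrove systems, strong
terrestrial influence) — such sites should be excluded from downstream
stability analysis rather than averaged over.

## TF and SCG abundances from HMMER3 searches

The package consumes HMMER3 `--domtblout` per-domain tables (reads searched
against profile HMMs; one row per domain alignment). A hit is *significant*
when all three hold:

1. domain independent E-value < `evalue_max` (default 0.001);
2. `hmm_to − hmm_from` ≥ `coverage_fraction` × model length (default 0.20)
   — the span is the printed difference, without the +1 of an inclusive
   length, and the comparison is ≥, so exact 20 % coverage passes;
3. `bias × bias_ratio ≤ score` (default ratio 10, "an order of magnitude
   smaller"); ties pass.

Each significant domain record counts once, so two domains of one model on
one read count twice (per-domain counting; per-read counting is a
documented alternative the caller can implement by deduplicating
`read_id`). Counts are assembled into model × sample matrices; hits to
models outside the requested list are counted and reported but ignored.

**Genome-equivalent standardization.** Single-copy genes occur once per
genome, so a sample's mean SCG count estimates the number of genome
equivalents sequenced. Dividing TF counts by it yields per-genome TF
abundances that are invariant under uniform scaling of a sample's counts —
the property that makes samples of 10⁴ and 10⁶ reads comparable. Variants
`mean ± k·SD` (default k = 2) bracket the sensitivity of results to the
divisor; they exist because individual SCGs are demonstrably over- or
under-represented in real surveys. The accompanying diagnostics flag an SCG
as an outlier within a sample when it falls outside median ± 1.5 · IQR of
that sample's SCG counts, and as systematically over-/under-represented
when it is a high/low outlier in more than half of the samples. This
concrete rule is a package decision — robust, scale-free, and standard for
skewed counts — chosen because outlier tallies in the literature are
reported without a formula; the flagged sets under other reasonable rules
will differ, and the diagnostics are descriptive, not an acceptance
surface.

**Sample selection.** Samples enter the analysis when the filter-size range
targets prokaryotes (within 0.1–0.8 µm), the habitat is not freshwater, the
sample is not on a named contamination list, and the mean SCG count exceeds
1 (a sample with at most one genome equivalent cannot support abundance
estimates). Each exclusion is logged with the first rule that fired.

## Space

Pairwise site distances are great-circle (haversine) distances on a sphere
of radius 6371 km. The source wording for such analyses ("Cartesian
distances" from a GIS module) is ambiguous between surface and chord
distances, so straight-line chords through the sphere are available as an
option (`mode = "chord"`); at ocean-basin scales the two are nearly
proportional and the downstream ordination is insensitive to the choice.
Composite samples that pool material from several stations get the mean of
their constituents' distances to every other sample.

Principal coordinate analysis double-centres $-D^2/2$ and eigendecomposes;
the first two eigenvectors scaled by the square roots of their eigenvalues
are the spatial axes X1, X2. Great-circle distance matrices are mildly
non-Euclidean; negative eigenvalues are reported but their axes discarded
without Lingoes/Cailliez correction, which at these scales would only
inflate all axes by a near-constant. Axis signs are made reproducible by
flipping each axis so its largest-magnitude coordinate is positive. The
spatial predictor table adds element-wise powers of the *centred* axes up
to degree 3 (X1, X2, X1², X1³, X2², X2³); centring before powering is not
universal practice but markedly reduces collinearity between an axis and
its own powers.

## Ordination and variation partitioning

Redundancy analysis is implemented from first principles: the response
matrix (sites × TFs, SCG-standardized, column-centred) is projected onto
the column space of the centred predictors via QR least squares; canonical
axes are the principal components of the fitted matrix; explained variance
is $R^2 = \mathrm{SS(fitted)}/\mathrm{SS(total)}$ and
$\mathrm{adj}R^2 = 1-(1-R^2)(n-1)/(n-m-1)$. The response is centred but not
column-standardized by default — after genome-equivalent standardization
all TFs are on one scale, and standardizing would up-weight rare, noisy
models; correlation-based RDA is available via `scale_y = TRUE`. Canonical
ordination axes use scaling 2 for biplots (TF scores scaled by axis
standard deviations, so angles approximate correlations).

Significance uses the pseudo-F statistic
$(\mathrm{SS_{fit}}/m)/(\mathrm{SS_{res}}/(n-m-1))$ with
$p = (1 + \#\{F^* \ge F\})/(1 + n_\mathrm{perm})$. Full models permute rows
of the response; partial (conditioned) tests residualize response and added
predictors on the covariables and permute the reduced-model residuals. The
default is 999 permutations (1000 relabelings including the observed one);
the seed is a required argument everywhere randomness occurs.

Forward/backward selection adds, at each forward step, the candidate with
the smallest partial permutation p-value, provided p ≤ `alpha_enter`
(default 0.05) *and* the enlarged model's adjusted R² does not exceed the
adjusted R² of the all-candidate model — the global cap that prevents
forward selection from assembling an overfit model one significant sliver
at a time. Backward steps then drop any term whose partial p rises above
the threshold, and the phases alternate to a fixed point. Ties break by
candidate order, making the procedure deterministic; the historical
selection heuristics this emulates varied between implementations, so exact
term sets from other software may differ and the rule here is the
documented contract.

Variation partitioning between environment terms A and space terms B uses
three RDA fits: unique fractions $[a] = \mathrm{adj}R^2(A{\cup}B) -
\mathrm{adj}R^2(B)$ and $[c] = \mathrm{adj}R^2(A{\cup}B) -
\mathrm{adj}R^2(A)$, shared $[b] = \mathrm{adj}R^2(A) + \mathrm{adj}R^2(B)
- \mathrm{adj}R^2(A{\cup}B)$, residual $[d] = 1 - \mathrm{adj}R^2(A{\cup}B)$,
so $[a]+[b]+[c]+[d] = 1$ identically. $[b]$ is not an independently
fittable component: it is a difference of differences, can be negative, and
carries no p-value. Adjusted R² is the standard convention because raw R²
fractions grow mechanically with the number of terms; the raw fractions are
reported alongside, since published percentages do not always state their
convention and either scale can then be compared. A partition *within* the
environment set (e.g. temperature vs phosphate stability) conditions both
sets on the selected spatial terms by including them in every model — one
of several defensible conditioning conventions, fixed here by decision.

## Per-TF regression

Each TF's standardized abundance is regressed on the same candidates
(retained stability z-scores, X1, X2 and polynomial terms) by
both-direction stepwise least squares minimizing
$\mathrm{AIC} = n\log(\mathrm{RSS}/n) + 2k$, starting from the
intercept-only model, at most `max_steps = 1000` steps, ties broken by
candidate order. Models are then manually pruned: while any term has a
two-sided t-test p-value above `p_max = 0.1`, the worst term is removed and
the model refit (idempotent by construction). TFs whose final model keeps
at least one term and explains more than `r2_min = 0.3` of the variance are
tabulated, sorted by R² within DBD / non-DBD category, with binned term
p-values (< 0.001, < 0.01, < 0.05, < 0.1).

Two caveats are deliberate. Per-term p-values come from the final fit only —
no selection-adjusted inference — and no multiple-testing correction is
applied across TFs; the screen is exploratory, and its false-positive
behaviour is characterized empirically in the test suite (at n = 44 with 10
candidates, AIC admits noise terms at roughly the p ≈ 0.16 level, pruning
trims them to a minority, and about 5 % of pure-noise TFs still pass the
30 % screen). Any exact reproduction of a published table additionally
depends on which stepwise variant produced it; the named R² values of
strong, temperature-dominated models are robust to that choice, full row
sets are not.

## The synthetic study system

`synthetic_spec()` fixes the simulated study conditions; the defaults are
the conditions under which the package's claims are tested: 44 sites, 65 TF
models, 53 SCG models, planted variance fractions 0.35 (environment) and
0.06 (space), roughly 300 genome equivalents per sample (a mid-range value
for shotgun surveys whose per-sample read counts span 10⁴–10⁶), a
one-degree grid over a subtropical-to-temperate ocean window, and seasonal
amplitudes / spatial gradients / grid noise per parameter at
oceanographically plausible magnitudes (e.g. 4 °C seasonal amplitude,
−0.3 °C per degree latitude, 0.5 °C grid noise for temperature).

The generator builds, in order: climatologies
(`base + trend·lat + A·sin(2πm/12) + N(0, σ)`; phase 0 so the stability has
the closed form above), uniformly placed sites, and counts. For each TF a
latent standardized abundance is a *fixed* signal plus *random* noise: a
random linear combination of the z-scored stability columns scaled to
variance `env_fraction`; a combination of the spatial axes residualized
against the stability columns (so the two signal parts are orthogonal and
the planted "shared" fraction is zero) scaled to `space_fraction`; and
i.i.d. Gaussian noise carrying the remainder. Because the noise is i.i.d.
rather than orthogonalized in-sample, adjusted R² is an approximately
unbiased estimator of the planted fractions — the property the recovery
tests rely on. The latent layer is mapped to a positive expected abundance
`mu_j (1 + 0.3·latent)` (per-TF means `mu_j` log-normal around one copy per
genome, coefficient of variation 0.3 across samples), genome equivalents
are Gamma-distributed around `mean_depth_of_coverage` (CV 0.3), SCG counts
are Poisson(g), and TF counts Poisson(abundance · g). Poisson thinning is a
stand-in: no noise model for metagenomic domain counts is established, and
read-sampling of gene copies is the simplest mechanism consistent with the
data type. Its main visible consequence is a small attenuation of recovered
fractions (about 0.01 at the default depth), which is why recovered
environment fractions average slightly below the planted 0.35.

`make_domtblout()` closes the loop at the file-format level: every counted
hit becomes a record satisfying all three significance criteria, and decoy
records each fail exactly one criterion, cycling through the three, so the
filter's per-criterion behaviour is exercised and
parse → filter → count reproduces the source counts identically at any
decoy rate.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real surveys: taxonomic composition and its
covariance with the environment; spatially autocorrelated noise (noise here
is independent across sites, so planted fractions are recovered more
cleanly than field data would allow); heterogeneous effect sizes across TFs
(every synthetic TF carries the same planted fractions, which is why the
synthetic per-TF screen passes most TFs while real screens pass a
minority); sequencing artifacts such as the systematic SCG over-/
under-representation the diagnostics exist to detect; and any non-linear
environment–abundance relationship.

## Numerical conventions and problem sizes

Degenerate inputs fail loudly: constant stability columns (z-score), rank-
deficient predictor matrices (RDA), all-missing interpolation
neighbourhoods, non-positive standardization divisors, fewer than three
validation pairs. Eigenvalues below 10⁻⁸ of the largest count as zero in
PCoA and RDA. Permutation p-values never reach 0 by construction. All
tie-breaks (selection order, pruning order) follow input column order and
are documented above. The test suite verifies the RDA projection against an
independent normal-equations oracle to 10⁻⁹ and against `vegan` on larger
cases, the partition identity to 10⁻⁹, the permutation test's type-I error
on 200 null data sets, and fraction recovery over 20 replicate synthetic
worlds at the default study conditions; interpolation-heavy tests use
coarser synthetic grids (2°, ~10° windows) and the recovery runs use four
of the eight parameters, sizes chosen to exercise every code path with
comfortable margins.

## Known limitations

Interpolated monthly climatologies cannot see sub-monthly variability, so
"stability" here means seasonal-scale stability. IDW reproductions of other
systems' interpolations match only approximately (neighbourhood and power
are not standardized). Metagenomes expose genomic potential, not
expression. The linear-model machinery quantifies linear dependencies only.
And with collinear stability measures pruned to one representative, an
effect attributed to, say, temperature stability is equally an effect of
anything that co-varies with it — the analysis quantifies, but cannot
mechanistically attribute.
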