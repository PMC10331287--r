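---
title: "Targeted odd-chain lipidomics with oddlipid: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted odd-chain lipidomics with oddlipid: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddlipid)
library(dplyr)
```

Odd-chain fatty acids (15:0, 17:0 and relatives) make up roughly 1% of
the acyl pool in human tissues, and the complex lipids that carry them
are usually invisible to untargeted lipidomics. `oddlipid` implements a
targeted workflow for them on triple-quadrupole instruments: it
enumerates the odd-chain lipid space in silico, derives the multiple
reaction monitoring (MRM) ion pairs each subclass supports, predicts
retention times from an equivalent-carbon-number (ECN) model so the
acquisition can be scheduled, and carries quantification through
internal-standard (IS) normalization, QC filtering and differential
statistics. This vignette explains the models behind each step, the
parameters that matter, and the design decisions taken where the
workflow was genuinely open.

## The lipid space and its chemistry

The library is the combinatorial closure of a small set of rules rather
than a downloaded list: an odd acyl pool (13:0–23:0, up to two double
bonds), an optional even partner pool (12–22 carbons) for mixed species
such as PI 17:0/18:1, and one formula-construction rule per subclass
(glycerol or glycero-3-phosphate backbone plus head group, minus one
water per condensation; a fixed d18:1 sphingoid base, d18:0 for dhCer,
with the variable chain in the N-acyl position). Every species keeps an
exact elemental formula, so each double bond shows up as precisely 2 Da
against the saturated analogue — the mass-defect rule the method uses to
co-generate unsaturated species:

```{r}
lipid_species("TAG", c("15:0", "15:0", "15:0"))[, c("name", "formula", "neutral_mass")]
```

Double-bond positions and sn-positions are deliberately not modelled:
unit-resolution MRM cannot distinguish them, and the canonical name
sorts acyls by (carbons, double bonds) to make that explicit.

## Fragmentation rules behind the ion pairs

Each subclass contributes transitions through the dissociation channel
it actually supports:

* **TAG** ionizes as the ammonium adduct; collision-induced loss of one
  fatty acid plus ammonia gives one transition per distinct acyl (at most
  three), with nominal neutral losses of 259/287/315 Da for
  15:0/17:0/19:0.
* **DAG** fragments to the protonated, dehydrated monoacylglycerol of
  the retained acyl (nominal 299/327/355 for 15:0/17:0/19:0).
* **Glycerophospholipids** are read in negative mode as carboxylate
  anions [FA−H]⁻, one channel per distinct acyl; identical acyls merge
  into a single channel annotated with both sn sites.
* **Sphingolipids** use the fixed head-group or long-chain-base
  fragments (m/z 184.0733 for SM, 264.2686/266.2842 for the d18:1/d18:0
  base); **FFA** is carried as a Q1 = Q3 pseudo-transition.

Two conventions needed a decision. PC and LPC have no protonatable
negative-mode ion, so their precursor is the acetate adduct
[M+CH3COO]⁻ — consistent with the ammonium-acetate mobile phase and
overridable per call. And all m/z values include the electron mass
(±0.000549 Da): it is far below what a quadrupole resolves, but it makes
every number in the package bit-reproducible from the atomic masses.
Nominal values (259, 299, …) are displayed as rounded exact masses;
computation always uses the exact ones.

Because one sum composition hides many acyl combinations (TAG 51:3 alone
admits 15:0-17:1-19:2, 15:0-17:0-19:3, …), `isomer_candidates()`
enumerates the full multiset space behind a sum composition, and
`validate_by_coelution()` accepts a species only when all its channels
elute together (default tolerance 0.1 min, about the narrowest observed
peak width); channels that split into RT clusters more than the
tolerance apart are reported as isomer groups rather than failures.

## The ECN retention model

Within a subclass, retention time on reverse phase is a smooth function
of chain length, shifted down by unsaturation. The package fits

$$ y = a + b x + c x^2, \qquad x = \mathrm{CN}/\mathrm{CN_{max}}, \quad
   y = \mathrm{RT}/\mathrm{gradient\ length} $$

by ordinary least squares, one curve per (subclass, double-bond count)
stratum. Choices worth stating:

* **CN_max** is the largest calibrated carbon number of the subclass, so
  x stays in (0, 1]; it is a normalization constant, not a fit
  parameter.
* **Gradient length** defaults to 17 min (the method's total runtime).
  The normalizing denominator could equally be the 15-min end of the
  hold; since both y and the predictions rescale together, R² and the
  predicted minutes are unaffected by the choice, and it is exposed as
  an argument.
* **Stratification**: unsaturation is treated as its own stratum rather
  than pooled, because added double bonds shift rather than reshape the
  curve; strata with fewer than three distinct carbon numbers fall back
  to the saturated curve plus a constant offset estimated from the
  stratum's points. Pooled fitting is available via
  `pool_double_bonds = TRUE`.
* Fitting is plain unweighted OLS — the quality criterion of the
  workflow is the correlation coefficient, and nothing in the data
  motivates a robust loss.

Predictions more than four carbons outside the calibrated range are
returned but flagged `extrapolated`. `rt_deviation_report()` compares
predictions with observations and flags species deviating by more than
0.5 min — the worst-case error the model is designed to keep, and
therefore the default scheduling half-window.

```{r}
cfg <- sim_config(seed = 42)
panel <- simulate_is_panel(cfg, subclasses = "TAG")
glance(fit_ecn(panel$calibration))
```

## Scheduling under a cycle-time budget

A scheduled-MRM method watches each transition only inside an RT window.
The designer assigns each transition a half-width (default 0.5 min,
widened per species when the deviation report says so) and a dwell time
by abundance tier — high-abundance species get the minimum dwell
(default 3 ms), low-abundance up to three times it, following the
principle that scarce ions need longer counting. Target dwells are then
shrunk toward the minimum by the largest single factor that keeps the
concurrent cycle time (sum of dwell plus a 2-ms pause per co-scheduled
transition) within the budget at every point of a 0.01-min grid. The
budget default of 0.75 s comes from requiring eight points across the
narrowest plausible peak (FWHM 0.1 min). Two properties are guaranteed
and tested: the budget holds everywhere on the grid, and contention in
one elution cluster never shrinks dwells in a non-overlapping cluster
(the rescale is computed per connected component of overlapping
windows). If even minimum dwells cannot fit, scheduling fails loudly,
naming the congested RT interval — the correct response is narrower
windows, a larger budget, or splitting the method.

## Quantification and QC

Peak areas are divided by the area of the matched internal standard in
the same injection; the match is by subclass with the nearest chain
length, then nearest double-bond count, ties toward the shorter chain,
and species of a subclass with no IS are flagged rather than silently
defaulted. Because analyte and IS share the injection's drift factor,
normalization cancels instrument drift exactly in the generator and
approximately on real data. Filters follow the method's criteria: CV
across QC injections below 20% (sample standard deviation, n−1), mean
study signal above five times the mean blank signal, and median S/N of
at least 10. Whether the blank rule should aggregate by mean or median
is not fixed by the criterion's wording; the mean is the default and the
median is an option. Filters are pure per-species predicates, so the
kept set is independent of application order — a property the tests
check. For downstream statistics, species with more than 30% missing
cells are dropped and the rest imputed with half the species minimum,
the standard detection-floor surrogate in metabolomics.

## Differential statistics

The statistical chain mirrors standard metabolomics practice:
interquartile-range filtering (default: drop the least variable 10%),
log transform, Pareto scaling (centering and dividing by the square root
of the standard deviation — a compromise between no scaling and unit
variance that keeps large fold changes from dominating), Welch two-sided
tests with Bonferroni correction, fold changes on the raw scale, PCA for
outlier review, and PLS-DA for supervised separation.

The supervised model is NIPALS partial least squares against a ±1 class
response, with per-species importance
$$ \mathrm{VIP}_j = \sqrt{\; p \sum_a \mathrm{SS}_a\, w_{ja}^2 \Big/ \sum_a \mathrm{SS}_a } $$
which satisfies `sum(VIP^2) = p` identically. The original workflow used
OPLS-DA in commercial software; for a two-class model the orthogonal
rotation redistributes variance between components but leaves the
predictive subspace — and in practice the VIP ranking — unchanged, so
the package implements plain PLS-DA and states so prominently. Q² comes
from 7-fold cross-validation, stratified by group and seeded (default
20230529) so folds are reproducible. S-plot coordinates are the
covariance and correlation of each species with the first predictive
score; the SUS-plot pairs the correlations of two comparisons, putting
species that rise in one transition and fall in the other off-diagonal.

Selection applies the workflow's two rules: *differential* = raw
P < 0.05 and VIP > 1 and a direction-agnostic fold change of at least
20% (`max(FC, 1/FC) ≥ 1.2`); *volcano* = fold change ≥ 2 at P < 0.1.
Two ambiguities were resolved as follows: the selection threshold uses
the raw P (the correction is reported alongside, and `use_adjusted`
flips the rule), and "FC ≥ 20%" is read direction-agnostically because
the workflow reports both up- and down-regulated species under it.

## What the generator emulates — and what it does not

`simulate_study()` produces the full input stack: an IS panel on true
ECN curves (RT noise 1% of the gradient, the level at which fitted R²
stays at or above 0.97), a three-group design of 12 samples per group
matching the colon-tissue study layout (CC-A distant normal, CC-B
adjacent, CC-C tumor), 10 QC injections with 7% multiplicative
log-normal noise (the level that keeps median CV well under the 20%
criterion), blanks at 5% of the study signal, and planted two-fold
effects — 25 TAG species up in CC-B and 25 phospholipids down, the
qualitative signature the method was built to detect. Biological
variation is log-normal with σ = 0.35 on the natural-log scale, a
mid-range value for tissue lipidomics chosen once so that a two-fold
effect at n = 12 is comfortably but not trivially detectable; per-sample
drift (σ = 0.05) is shared between analytes and their IS so that
normalization cancels it by construction. FWHM is drawn uniformly on
0.1–0.7 min, the observed band of the method.

The generator emulates integrated peak tables, not chromatograms: there
is no peak-shape model, no ionization suppression, no co-elution
interference, no missingness mechanism beyond what the filters create,
and IS areas track drift exactly rather than approximately. Passing the
closed-loop tests (≥90% of planted species recovered at ≤10% false
positives) therefore validates the *pipeline arithmetic* under the
stated noise model — it does not certify performance on real extracts,
where matrix effects and integration errors dominate.

Problem sizes in the tests and the acceptance script — 12-point
calibration panels over 200 replicates, 100-species QC panels over 50
replicates, a ~130-species study library — were chosen as the smallest
sizes at which the medians being tested are stable across seeds.

## Known limitations

* Ether and vinyl-ether lipids, oxidized species, charge states above 1
  and isotopologue structure are out of scope.
* The ECN model transfers only within a subclass and gradient; no
  cross-batch RT alignment is provided.
* OPLS-DA's orthogonal components themselves (and their diagnostics) are
  not reproduced, only the predictive-component quantities.
* The scheduler optimizes dwell under a hard budget but does not model
  ion statistics; tiers are a proxy for expected abundance.
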