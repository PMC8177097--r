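---
title: "Methods: depletion-corrected binding analysis for heme-protein titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depletion-corrected binding analysis for heme-protein titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemebind)
```

## The binding model and its assumptions

All fitting assumes a single 1:1 protein–ligand equilibrium,
P + L ⇌ PL, with dissociation constant $K_d = [P][L]/[PL]$. Because
porphyrin affinities for lipocalins range from low-micromolar (heme) down
to sub-nanomolar (hematoporphyrin) while assay concentrations sit in the
same range, ligand depletion cannot be neglected, and the free-ligand
("hyperbolic") isotherm would bias $K_d$ badly. `complex_concentration()`
therefore solves the exact mass balance — the Morrison tight-binding
quadratic — taking the smaller root

$$[PL] = \tfrac{1}{2}\left(s - \sqrt{s^2 - 4[L]_0[P]_0}\right),
\qquad s = [L]_0 + [P]_0 + K_d.$$

The discriminant satisfies $s^2 - 4LP \ge (L-P)^2 \ge 0$, so the root is
always real; it is evaluated as $2LP/(s + \sqrt{s^2-4LP})$, which is
algebraically identical but immune to catastrophic cancellation when
$K_d \gg L, P$ (the weak-binding limit, where the naive form subtracts two
nearly equal numbers).

Two observables are modelled, both linear in species concentrations with
a 1 cm path length assumed throughout:

* **Absorbance at the Soret readout (411 nm).**
  $A = [PL]\,\varepsilon_{PL} + A_{\mathrm{free}}([L]_0 - [PL])$. The
  free-ligand term is *not* Beer–Lambert for heme: free hemin
  self-associates in aqueous buffer, so its apparent extinction falls with
  concentration. The calibrated law $A_{\mathrm{free}}(c)$ absorbs this
  (below). Hematoporphyrin stays monomeric at assay concentrations and is
  calibrated linearly.
* **Tryptophan emission at 354 nm (excitation 290 nm).**
  $I = [PL]\,I_{PL} + ([P]_0 - [PL])\,I_P$: porphyrin binding quenches the
  tryptophans, and the signal is a population-weighted sum of quenched and
  free protein. Inner-filter effects of the added porphyrin are *not*
  modelled; at the 0.8–50 nM ligand range of the fluorescence assay their
  absorbance is negligible, but the omission matters if the model is
  applied at micromolar ligand.

Equilibrium is assumed instantaneous (no incubation-time or
photodegradation effects), stoichiometries other than 1:1 are out of
scope, and cooperative or multi-site models are not provided.

## Free-ligand extinction calibration

`fit_extinction()` fits $A_{\mathrm{free}}(c)$ by zero-intercept least
squares: a polynomial (default degree 2) for aggregating chromophores
tagged `heme`/`hemin`, a straight line for `HP`. Choices made where the
procedure was genuinely open:

* **Zero intercept.** Buffer blanks are subtracted upstream, and
  Beer–Lambert forces $A(0)=0$; the intercept is therefore constrained
  rather than estimated, and concentration 0 is always part of the
  calibrated domain.
* **Degree 2 default.** The minimal model with curvature for a
  monomer–dimer equilibrium over a one-decade concentration range; it is a
  parameter, not a constant.
* **"At that concentration".** A concentration-dependent extinction
  coefficient can be evaluated at the *free* equilibrium concentration or
  at the *initial* ligand concentration; the difference only matters for a
  curved law. Both are supported in `predict_absorbance()`
  (`free_conc_mode`), and the default is `"free"`, which is the
  thermodynamically coherent reading (the free-ligand absorbance is
  produced by the free ligand that is actually present). The two
  conventions coincide exactly for a linear law, which the tests verify.

Evaluation beyond the calibrated maximum extrapolates the polynomial and
records a warning — polynomial extrapolation is the single most dangerous
numerical operation in the pipeline and is never silent.

## Least-squares estimation of Kd

`fit_kd_absorbance()` and `fit_kd_fluorescence()` minimize the sum of
squared residuals over all points and replicates by Levenberg–Marquardt
(`minpack.lm::nls.lm`, relative function tolerance $10^{-10}$, at most
$10^4$ evaluations). Numerical design:

* **Parameterization.** $K_d$ is fitted as $\log K_d$, making positivity
  structural instead of a constraint.
* **Multi-start.** Three starts span the schedule (median/20, median,
  20× the larger of schedule and protein concentration); the winner is the
  lowest RSS, ties broken toward the smaller $K_d$. Refits of perturbed
  copies of the same data (replicates, bootstrap) start from the full
  solution instead.
* **Coefficients are co-fitted.** $\varepsilon_{PL}$ (or $I_{PL}$) is
  estimated jointly with $K_d$, with the starting value profiled linearly
  at each $K_d$ start. The free-protein emission $I_P$ is fixed from the
  mean zero-ligand baseline by default — that point measures it directly —
  with options to supply or co-fit it.
* **Tight-binding identifiability.** When $[P]_0/K_d > 10$ the titration
  approaches a piecewise-linear saturation curve whose shape carries little
  information about $K_d$; the fluorescence fit emits an explicit warning
  in that regime rather than failing, because the estimate is still
  unbiased, just imprecise.
* **Degenerate inputs** (fewer than 3 distinct ligand concentrations,
  all-zero observable, no zero-ligand point when one is needed) are
  rejected with targeted errors, and non-convergence is flagged on the
  result, never silently ignored.

Uncertainty comes in two flavours because titration reports rarely state
which one their ± values are: `replicate_sd` (standard deviation of
per-replicate fits) and `residual_bootstrap` (seeded resampling of fit
residuals, default B = 200, with a percentile confidence interval).
Neither is asserted to be "the" published convention; both are reported by
the pipeline.

## The synthetic-data generator

`synthetic_config()` fixes the ground truth the simulations are built
from. Raw titration tables are generally not published, so the generator's
default coefficient values are stand-ins chosen once at the scale of
published titration figures, not measured constants: complex extinction
0.1 AU·µM⁻¹ (a 5 µM saturated complex reads ≈ 0.5 AU at the Soret band),
free-heme law $0.05c - 0.001c^2$ AU over a 0–11 µM range, free-protein
emission 100 counts per concentration unit with the quenched complex at
20%. Noise is additive Gaussian (homoscedastic, the simplest model
consistent with a double-beam spectrophotometer readout) plus an optional
multiplicative component used in the fluorescence scenario; defaults are
configurable, and a fixed seed makes every output bit-reproducible,
restoring the caller's RNG state afterwards.

The free-heme nonlinearity can be generated either from the polynomial
directly or from an explicit monomer–dimer equilibrium
(`free_ligand_law = list(mode = "monomer_dimer", ...)`), so the downstream
polynomial calibration can be exercised as a genuine approximation rather
than a self-fulfilling round trip.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: wavelength-resolved spectra and baseline drift,
heteroscedastic or correlated noise, incubation-time kinetics,
photodegradation of hematoporphyrin, inner-filter effects, and impurities
in the ligand stock. Parameter-recovery results here demonstrate
correctness of the estimator under the stated model, not robustness to
violations of it.

Problem sizes used by the shipped tests: 12-point schedules in
triplicate (36 observations per fit), ensembles of 10 datasets for the
recovery checks, 100 simulations × 200 bootstrap refits for the
confidence-interval coverage property. These sizes make the full suite run
in about a minute while keeping the coverage estimate's binomial error
around ±4%.

## Mass identification

Monoisotopic masses and isotope patterns are computed from an embedded
IUPAC table (2021 masses and representative abundances), so nothing is
fetched at run time. Ion m/z bookkeeping is explicit: each added proton
contributes 1.00727647 Da and any remaining charge is carried by electron
removal/addition, so an even-electron metal-centred cation such as ferric
heme `[C34H32FeN4O4]+` is the neutral-formula mass *minus one electron
mass*. At four-decimal Orbitrap precision the electron (0.00055 Da,
≈ 0.9 ppm at m/z 616) decides whether the printed values reconcile.

The observed precursor is deliberately matched against *both* ion
hypotheses — `[M+H]+` of a 615-Da species and the intact cation `[M]+` of
the 616-Da formula — and `match_precursor()` reports the ppm error of
every candidate instead of deciding which label the original experiment
intended.

Isotopologue envelopes are built by iterated convolution of per-element
distributions aggregated at nominal-mass (1 Da) resolution — the
resolution at which Orbitrap precursor envelopes are compared visually —
with no pruning, which keeps the result exactly independent of element
order. Iron's ⁵⁴Fe isotope produces the diagnostic A−2 peak (≈ 6% of the
base peak for heme) that distinguishes an iron tetrapyrrole from an
isobaric organic.

## Structural analysis

Coordinates are parsed through bio3d (PDB and mmCIF); alternate locations
are resolved to the highest-occupancy copy, author residue numbering is
kept, and hydrogens — absent from typical ~2 Å models — are excluded from
all geometry. Decisions where the published criteria were not stated:

* **Contact census.** "Within 4.0 Å" is interpreted as any heavy atom of
  a residue within 4.0 Å of any heavy atom of the ligand. Waters and
  non-protein entities are tabulated separately and never counted in the
  amino-acid census.
* **Hydrogen bonds** are geometric inferences from heavy atoms: polar
  (N/O/S) pairs within 3.5 Å filtered by a ≥ 90° angle proxy at each
  partner's covalent antecedent. This is a plausibility filter, not an
  energetic assignment, and is documented as such.
* **π-stacking**: ring-centroid distance ≤ 5.5 Å and interplanar angle
  ≤ 30° between aromatic side chains (Phe/Tyr/Trp/His) and the four
  pyrrole rings; porphyrin rings are named I–IV following the NA–ND
  nitrogen atom names of the chemical-component dictionary (ring A = I …
  ring D = IV).
* **Superposition** is a from-scratch Kabsch solve (SVD with determinant
  correction, so the rotation is always proper); bio3d's fitting serves as
  an independent cross-check in the tests, not as the implementation.
  Near-collinear reference sets are flagged as degenerate. Pairing is by
  residue number by default, with optional sequence-alignment pairing via
  Biostrings when installed.
* **Porphyrin plane rotation** between two complexes is measured after
  protein superposition: best-fit planes through the 24 core atoms
  (4 N + 16 pyrrole C + 4 meso C), with the in-plane angle taken between
  the Fe→NA reference vectors projected into the first complex's plane,
  and the normal–normal tilt reported separately so an out-of-plane
  difference is never disguised as an in-plane rotation.

The deposited coordinates the original analyses ran on (6VRI, 3MBT, 4XMC)
are not redistributed with the package; the corresponding checks run when
the user places the files locally, and all geometric machinery is
exercised on constructed synthetic fixtures with known answers.

## Known limitations

Single-site 1:1 binding only; no kinetic fitting; no inner-filter
correction; hydrogen-bond and stacking calls are geometric only; no
crystallographic symmetry expansion (contacts across the asymmetric-unit
boundary must be present in the file to be seen); isotope abundances are
representative terrestrial values, so unusual isotopic sources shift
envelopes; and the synthetic generator's realism limits are listed above.
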