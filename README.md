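# hemebind

Quantitative analysis of porphyrin binding to proteins: depletion-corrected
equilibrium binding fits from spectrophotometric and fluorometric
titrations, free-ligand extinction calibration, exact-mass identification of
heme by high-resolution MS, and binding-pocket structural analysis — with a
seeded synthetic-data generator so every stage is testable end to end
without external data.

The package grew out of the characterization of heme binding by the
bacterial lipocalin Blc (an eight-stranded β-barrel, PDB 6VRI): a ligand
copurifying with the protein was identified as heme B by exact mass and
isotopologue pattern, affinities were measured by Soret-band absorbance and
tryptophan-quenching fluorescence titrations, and the binding pocket was
characterized from the deposited coordinates. All of those analyses are
reusable here for any 1:1 protein–porphyrin system.

## The model

When the dissociation constant is comparable to the reactant
concentrations, the free-ligand approximation fails and the equilibrium
complex concentration must account for depletion (Morrison's tight-binding
quadratic):

```
[PL] = ( [L]0 + [P]0 + Kd − sqrt( ([L]0 + [P]0 + Kd)² − 4 [L]0 [P]0 ) ) / 2
```

The observables are linear in the species concentrations:

* absorbance at the Soret readout (411 nm):
  `A = [PL]·ε_PL + A_free([L]0 − [PL])`, where `A_free(c)` is the calibrated
  free-ligand law — polynomial for free heme, whose self-association makes
  the apparent extinction concentration dependent; linear for
  hematoporphyrin;
* tryptophan emission at 354 nm (excitation 290 nm):
  `I = [PL]·I_PL + ([P]0 − [PL])·I_P`, quenched complex plus residual
  free-protein emission.

`Kd` and the complex coefficient are estimated jointly by multi-start
Levenberg–Marquardt least squares on `log Kd` (positivity by construction),
with replicate-SD and residual-bootstrap uncertainty.

The mass module computes monoisotopic masses and isotopologue envelopes from
an embedded IUPAC isotope table with explicit proton/electron bookkeeping —
for the intact ferric heme cation `[C34H32FeN4O4]+` the 0.00055 Da electron
matters at Orbitrap precision. The structure module reports the ligand
contact shell at a heavy-atom cutoff, geometric hydrogen-bond and
π-stacking calls, Kabsch Cα superposition, and the in-plane rotation of a
porphyrin between two complexes.

## Worked example

```r
library(hemebind)

# simulate a triplicate hemin titration at the experimental conditions:
# 5 uM protein, 0.5-11 uM hemin, 0.003 AU noise, true Kd = 1.4 uM
cfg <- synthetic_config(true_kd = 1.4, protein_conc = 5,
                        ligand_concs = c(0.5, 1:11),
                        noise_sd = 0.003, n_replicates = 3, seed = 42)
sim <- simulate_absorbance_titration(cfg)

# calibrate the free-heme extinction law from a noiseless dilution series
calib <- simulate_free_ligand_absorbance(
  synthetic_config(1.4, 5, c(0.5, 1:11), noise_sd = 0),
  seq(0.25, 11, length.out = 20))
ext <- fit_extinction(calib$conc, calib$absorbance, ligand = "heme")

fit <- fit_kd_absorbance(sim$series, ext)
fit$kd_sd <- estimate_uncertainty(fit, sim$series,
                                  method = "replicate_sd")$kd_sd
print(fit)
#> Binding fit (absorbance model): Kd = 1.362 uM +/- 0.059
#>   complex coefficient 0.09964; RSS 0.000316 over 36 points; converged
```

The fitted `Kd = 1.362 ± 0.059 uM` recovers the simulated truth of 1.4 uM:
the point estimate is within one experimental error bar, and the complex
extinction coefficient (0.0996 AU/uM) matches the generating value (0.1).

```r
theo <- ion_mz(ion_spec("C34H32FeN4O4", charge = 1, added_protons = 0))
ppm_error(616.1774, theo)
#> ferric heme [M]+ theoretical m/z: 616.1767; observed 616.1774 -> +1.07 ppm
```

A +1.07 ppm match identifies an observed precursor at m/z 616.1774 as the
intact ferric heme cation.

A command-line front end wrapping the same functions lives at
`inst/cli/hemebind.R` (subcommands `simulate`, `calibrate`, `fit-abs`,
`fit-fluor`, `mass-id`, `contacts`, `superpose`, `run`, `show-config`).

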