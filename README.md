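# coronathermo

Tools for characterising how a serum protein binds a self-assembling
amphiphilic-dendrimer (AD) nanomicelle — the kind of protein-corona
question that comes up whenever a cationic nanocarrier meets blood
plasma. The package covers the four experimental/computational readouts
of such a study in one tested pipeline:

* **Fluorescence quenching** — ordinary and modified Stern–Volmer
  analysis of tryptophan-quenching titrations. The classic plot fits
  `F0/F = 1 + K_SV [Q]`; the modified (double-logarithmic) plot,
  `log10((F0−F)/F) = −log10(K_D) + log10([AD] − (F0−F)[HSA]/F0)`,
  yields the dissociation constant `K_D`. A peak finder for 3D
  excitation–emission matrices with first-order Rayleigh masking is
  included.
* **Isothermal titration calorimetry** — a micelle-aware
  "one set of sites" fit. Total amphiphile is converted to micelle
  concentration by mass conservation,
  `[AD_tot] = [AD_mon] + N_agg × [AD_mic]` (monomer pinned at the CMC),
  the micelle carries `n` independent protein sites, and the bound
  complex per injection comes from the 1:1 mass-action quadratic under
  the overflow-cell dilution convention. The fit returns
  `K_d`, `ΔH`, `n` and the decomposition
  `ΔG = RT ln K_d`, `−TΔS = ΔG − ΔH`.
* **Circular dichroism** — mean residue ellipticity
  `MRE208 = mdeg / (10 Cp n l)`, helicity
  `α-helix % = (−MRE208 − 4000)/29000 × 100`, and two-state sigmoid
  melting fits at 222 nm.
* **Trajectory analysis** — per-residue contact fingerprints (6.5 Å
  minimum-distance cutoff), salt-bridge occupancy and ≥50 % persistence,
  radius of gyration and gyration-tensor semi-axes (`a_i = sqrt(5 λ_i)`),
  radial distributions around the micelle centre of mass, Shrake–Rupley
  SASA and surface-area stoichiometry, and a Kabsch–Sander H/E/T/C
  secondary-structure subset — all over multi-model PDB trajectories.

A synthetic-data module (`gen_quenching`, `gen_itc`, `gen_cd_spectrum`,
`gen_melt_curve`, `gen_toy_complex`, `gen_ideal_helix`) generates inputs
with exactly the statistical structure each stage assumes, so every
operation is exercisable and testable without instrument data.

## Worked example

```r
library(coronathermo)

# a synthetic quenching titration at the documented defaults
titr <- gen_quenching(generator_spec(seed = 1), "modified_sv")
fit_modified_stern_volmer(titr)
#> Modified Stern-Volmer binding fit
#>   K_D   = 3.226e-05 M (se 6.5e-06)
#>   slope = 0.9705 (diagnostic, ~1 expected)
#>   R^2   = 0.9975

# a synthetic ITC isotherm under the 208 uL / 30 uM / 900 uM / 19 x 2 uL
# design, fitted with the micelle transform (N_agg = 17)
fit_one_site(gen_itc(generator_spec(seed = 1)))
#> One-set-of-sites ITC fit (micelle mass-conservation transform)
#>   K_d     = 9.867e-06 M (se 3.4e-06)
#>   dH      = -3.929 kcal/mol (se 0.27)
#>   n_sites = 5.38 (se 0.36)
#>   reduced chi^2 = 0.007581, discarded injections = 0
#>   dG    =  -6.826 kcal/mol
#>   dH    =  -3.929 kcal/mol
#>   -TdS  =  -2.897 kcal/mol
```

A single noisy replicate scatters around the generating values
(K_D 32 µM vs the generated 22.9 µM here; K_d 9.9 µM, ΔH −3.93
kcal/mol, n 5.4 against generated 13.4 µM, −4.02 kcal/mol, n = 6);
medians over 100 replicates land within a few percent — that is what
`scripts/acceptance.R` measures. The thermodynamic decomposition closes
exactly (`ΔG = ΔH + (−TΔS)`).

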