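---
title: "Models and methods behind coronathermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coronathermo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronathermo)
```

`coronathermo` analyses the binding of a serum protein (HSA, 585
residues, single tryptophan fluorophore) to cationic amphiphilic-dendrimer
(AD) nanomicelles — assemblies of ~17 amphiphiles above a critical
micellar concentration (CMC) of a few micromolar. This vignette explains
the models, the tunable parameters, the synthetic-data generators the
tests rely on, and the numerical choices that were genuinely open.

## Fluorescence quenching

Quenching of the protein's intrinsic tryptophan fluorescence by the
titrant is analysed two ways.

**Stern–Volmer.** `fit_stern_volmer()` regresses $F_0/F$ on quencher
concentration by ordinary least squares. The slope is $K_{SV}$
(M$^{-1}$). The intercept is deliberately left free rather than pinned
at 1: its deviation from 1 is a useful diagnostic for baseline drift.
A titration in which $F$ never changes is reported as $K_{SV} = 0$ with
an explicit `no_quenching` flag instead of an undefined $R^2$.

**Modified Stern–Volmer.** `fit_modified_stern_volmer()` implements the
double-logarithmic form

$$\log_{10}\frac{F_0 - F}{F} \;=\; -\log_{10} K_D \;+\;
  \log_{10}\!\Big([AD] - \frac{(F_0-F)[HSA]}{F_0}\Big),$$

i.e. $(F_0-F)/F = [AD]_{free}/K_D$, where the bracketed term corrects
the total titrant concentration for the fraction bound to protein
(identifying the quenched fraction with the bound fraction). The
regression slope is left free and reported as a diagnostic — for a
single class of independent sites it is $\approx 1$. $K_D =
10^{-\mathrm{intercept}}$, with its standard error propagated from the
intercept by the delta method. Base-10 logarithms are used throughout,
the convention of this plot. Points with $F \ge F_0$ or a non-positive
free-titrant argument are excluded with a warning rather than silently
dropped. No inner-filter correction is applied.

**3D fluorescence.** `locate_eem_peaks()` masks the first-order Rayleigh
diagonal ($|\lambda_{em} - \lambda_{ex}| \le 10$ nm by default) and
reports local maxima above mean + 3 SD of the unmasked cells. For an
HSA-like emitter the dominant peak sits near
$\lambda_{ex}/\lambda_{em} = 280/343$ nm.

## Micelle-aware ITC

The titrant self-assembles, so the binding species is the micelle, not
the monomer. `micelle_concentration()` applies mass conservation

$$[AD_{tot}] = [AD_{mon}] + N_{agg}\,[AD_{mic}],$$

with the monomer pool pinned at the CMC above the CMC and
$[AD_{mic}] = ([AD_{tot}] - \mathrm{CMC})/N_{agg}$. Defaults are
$N_{agg} = 17$ and CMC $= 4.5\ \mu$M — the midpoint of the reported
3.2–5.7 µM range, exposed as a configuration knob because no single
value is canonical.

`simulate_isotherm()` is the forward model: the syringe concentration is
converted to micelle concentration once (the syringe, at 900 µM, is far
above the CMC, and post-injection monomer re-equilibration in the cell
is neglected — the titration is designed so the cell stays above the CMC
throughout). Each injection dilutes everything already in the cell by
$(1 - dV/V_0)$ and adds $dV \cdot c_{syr}/V_0$ of new titrant — the
overflow ("perfusion") cell convention that is the de-facto standard for
this instrument class. With protein $H$ and sites $S = n\,[mic]$, the
bound complex is the smaller root of the 1:1 mass-action quadratic,

$$[HS] = \tfrac{1}{2}\Big(H + S + K_d - \sqrt{(H+S+K_d)^2 - 4HS}\Big),$$

evaluated in the numerically stable conjugate form $2HS/(b+\sqrt{\cdot})$.
The injection heat is $\delta Q_i = Q_i - Q_{i-1} +
(dV_i/V_0)(Q_i + Q_{i-1})/2$ with $Q_i = [HS]_i\,\Delta H\,V_0$. The
micelle is treated as a multivalent species with $n$ independent,
identical sites and $\Delta H$ is per mole of protein bound; this
reproduces both the site-level one-set-of-sites mathematics and a ~6:1
protein:micelle stoichiometry.

`fit_one_site()` fits $(K_d, \Delta H, n)$ by nonlinear least squares.
$\Delta H$ (and an optional constant heat offset, for data whose control
subtraction left a residual) enters the model linearly and is profiled
out exactly; the outer search over $(\log_{10} K_d, \log n)$ runs
Nelder–Mead from 8 multi-starts log-spaced over $K_d \in
10^{-9}\ldots10^{-3}$ M, keeping the best SSE. The data-driven start for
$n$ comes from the steepest-descent injection (sites $\approx$ protein
at the inflection). Standard errors derive from the numerical Hessian of
the SSE at the optimum. Whether the original analysis floated or fixed
$n$ is unknowable from the report, so both are exposed
(`fit_n`/`n_fixed`); `discard_first` (common practice for the first,
diffusion-compromised aliquot) defaults to off.

`derive_thermodynamics()` closes the triplet with
$\Delta G = RT\ln K_d$ ($R = 1.9872\times10^{-3}$ kcal mol$^{-1}$
K$^{-1}$, standard state 1 M) and $-T\Delta S = \Delta G - \Delta H$;
the closure holds to machine precision on every fit object.

## Circular dichroism

`mre_at_208()` computes the mean residue ellipticity
$\mathrm{MRE}_{208} = \mathrm{mdeg}/(10\,C_p\,n\,l)$, interpolating the
spectrum linearly at 208 nm and using the spectrum as-is (no smoothing —
accumulation averaging is an instrument-side step). `helix_fraction()`
applies the two-point calibration

$$\alpha\text{-helix }\% = \frac{-\mathrm{MRE}_{208} - 4000}{33000 - 4000}
  \times 100,$$

clamping out-of-range values (legitimate for noisy spectra) with a flag
instead of erroring. The default path length is 0.1 cm: the source
material states both 0.2 cm (methods) and 0.1 cm (the narrative tied to
the helicity formula and its 59.3 % result); we default to the value
consistent with the published helicity and expose `path_cm`.

`fit_melting()` fits the two-state sigmoid
$\theta(T) = \theta_F + (\theta_U - \theta_F)/(1 + e^{(T_M - T)/w})$
with temperature-independent baselines (initialised from the first/last
10 % of points, $T_M$ from the maximum finite-difference slope) by
Levenberg–Marquardt, falling back to a $(T_M, w)$ grid with per-node
linear baseline solves if the iteration fails. Monotone curves raise a
"no transition" error rather than returning a boundary artefact.

## Trajectory operations

All structure operations run per frame on an in-memory trajectory
(multi-model PDB via `read_pdb_trajectory()`; residue indices 1-based,
distances in Å, masses from an element table with a warned 12.0 default).

* `radius_of_gyration()` / `gyration_tensor()`: mass-weighted by default
  (a geometric option exists). Semi-axes use $a_i = \sqrt{5\lambda_i}$,
  the uniform-solid-ellipsoid convention: for a uniform ellipsoid the
  second moment along a principal axis is $a_i^2/5$, and the reported
  complex semi-axes (81.8, 80.2, 71.4 Å) close with the reported $R_g$
  (60.01 Å) only under this scaling (within 1 %); the literal
  $\sqrt{\lambda}$ convention is available behind a flag.
* `contact_fingerprint()`: per-residue minimum distance to the micelle
  per frame; contact below 6.5 Å; frequencies per (chain, residue) so
  each corona protein gets its own fingerprint panel, with the full
  minimum-distance trace retained.
* `salt_bridges()`: group-level (chain, residue) cation–anion pairs
  bridged below 4.0 Å — the field-standard N–O heavy-atom criterion,
  configurable because only the 50 % persistence threshold is dictated —
  and `fraction_stable_cations` as the fraction of cationic terminals
  with at least one stable bridge. The analysis window is whatever
  trajectory you pass in (e.g. the final stretch of a production run).
* `rdf_from_com()`: distances from the per-frame reference COM; `"gr"`
  mode normalises by shell volume and by the mean density inside the
  histogram sphere (uniform gas ⇒ $g(r) = 1$), `"count"` mode gives the
  unnormalised distribution for visual comparison with published panels.
* `sasa()`: Shrake–Rupley with a deterministic Fibonacci sphere lattice
  (default 960 points, probe 1.4 Å), van der Waals radii from a
  documented element table with per-atom overrides for bead systems.
  960 points reproduce the two-sphere analytic cap area within 2 % and
  rotation invariance within 0.5 %.
* `assign_secondary_structure()`: the Kabsch–Sander electrostatic
  H-bond energy ($E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} -
  1/r_{OH} - 1/r_{CN})$ kcal/mol, bond below $-0.5$), with the amide H
  rebuilt 1 Å from N along the preceding C=O direction. Only the
  four-class H/E/T/C subset is assigned (helix = consecutive
  $i \to i+4$ bonds, strand = parallel/antiparallel bridge rules,
  turn = $i \to i+3$), since only helix/turn/sheet fractions are of
  interest; residues with incomplete backbones are coil by contract.

## Synthetic data: what it emulates, and what it does not

Every generator implements exactly the forward model its paired analysis
inverts, plus a 1 % multiplicative Gaussian noise default
(`generator_spec(noise_sd_rel = 0.01)`); identical specs give
bit-identical output, and the generator restores the caller's RNG state.

* `gen_quenching()`: $F_0 = 100$ a.u. (arbitrary scale — both fits are
  scale invariant); the modified-SV branch solves the binding quadratic
  for the quenched fraction, so zero-noise data are inverted to
  $10^{-6}$ relative accuracy. Default concentrations 2–20 µM with the
  protein fixed at 2 µM.
* `gen_itc()`: the printed design (208 µL cell, 30 µM protein, 900 µM
  syringe, 19 × 2 µL, 298 K) with 1 % multiplicative plus 0.1 µcal
  additive baseline noise — an instrument-plausible integration-noise
  model chosen once; the source reports no noise model.
* `gen_cd_spectrum()`: helicity-weighted sum of a helix basis (two
  negative Gaussian bands at 208/222 nm, depth calibrated so
  $\mathrm{MRE}_{208}$ inverts the helicity formula exactly at 100 %)
  and a coil basis ($\mathrm{MRE}_{208} = -4000$). Only the 208 nm
  values are calibrated; band shapes elsewhere are cosmetic.
* `gen_melt_curve()`: the two-state sigmoid on a 25–95 °C, 1 °C grid.
* `gen_toy_complex()`: a bead-scale complex — 17 three-bead amphiphiles
  (tail/linker/cationic head at radii 15/28/40 Å, overall $R_g \approx
  29.5$ Å) plus six ~50-bead protein chains on a 36–44 Å shell that
  interpenetrates the head layer, with planted contact/salt-bridge
  pairs placed at 3.5 Å for exactly $\lceil \mathrm{occupancy} \times
  n_{frames} \rceil$ frames and beyond 10 Å otherwise.
* `gen_ideal_helix()`: an N/CA/C/O backbone built from standard internal
  coordinates by NeRF extension; $\phi = -57°, \psi = -47°$ gives the
  canonical helix, $\phi = \psi = 180°$ the extended-chain control.

What passing tests show is that each analysis inverts its own forward
model under realistic noise, and that the structure operators agree with
brute-force/closed-form oracles. What they cannot show: real spectra
have wavelength-correlated baselines, real ITC has first-injection
artefacts and heat-of-dilution structure, real trajectories have
force-field-shaped fluctuations, and real proteins are not bead chains.
Printed-number checks (thermodynamic closure, surface-area
stoichiometry, gyration closure) are the only bridges to the original
measurements.

One bias is worth knowing about: at the default noise the
modified-Stern–Volmer $K_D$ recovery has a small positive median bias
(a few percent to ~10 %), because symmetric intensity noise propagates
asymmetrically through $\log((F_0-F)/F)$ where quenching is weak. This
is a property of the estimator under the stated conditions, not of the
implementation.

## Problem sizes and other choices

Recovery studies use 100 replicates (medians are reported; the full ITC
study runs in well under a minute). Oracle and property tests use small
randomized instances — 50–60-atom clouds, 1000-case conservation and
quadratic-vs-bisection sweeps, a $10^4$-point uniform sphere for the
second-moment checks. The mass-action quadratic is evaluated in its
conjugate form to avoid catastrophic cancellation at extreme $K_d$;
eigenvalues are clipped at zero before taking square roots; rank
deficiency in the gyration tensor is flagged, not errored. The JSON
configuration (`load_config()`) rejects unknown keys outright — silent
typos in cutoff names are worse than a hard error.

Known limitations: no inner-filter correction and no quenching-mechanism
classification; single-site ITC only (no sequential/multi-site models,
no $\Delta C_p$); helicity from the 208 nm calibration only (no
multivariate deconvolution); four-class secondary structure; PDB is the
only trajectory format, which is deliberate for desk-scale systems.
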