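---
title: "Methods: voxel Monte Carlo dosimetry for transcranial near-infrared light"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel Monte Carlo dosimetry for transcranial near-infrared light}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Photobiomodulation (PBM) delivers low-intensity red/near-infrared light
(typically 600–1100 nm, 1–100 mW/cm²) to the head in the hope of modulating
brain tissue. Whether any given LED placement actually delivers a meaningful
dose to gray matter — and whether it stays within skin and ocular exposure
limits — cannot be measured in vivo. This package answers those questions by
simulation: it builds a voxelized optical model of the head, transports
photon packets through it with a Monte Carlo engine, and summarizes where the
energy goes.

The pipeline is:

1. **Phantom synthesis** (`build_phantom()`): tissue probability maps (one
   volume per class, as produced by probabilistic MRI segmentation) are
   converted into per-voxel optical parameter volumes — absorption `mua`
   (mm⁻¹), scattering `mus` (mm⁻¹), anisotropy `g`, refractive index `n` —
   at each requested wavelength, using a spectral tissue-optics library.
2. **Transport** (`run_mc()`): photon packets are launched from disk or
   rectangular LED models and propagated with Henyey–Greenstein scattering,
   continuous absorption, Fresnel refraction at refractive-index steps, and
   Russian roulette, recording per-voxel fluence (optionally per time gate).
3. **Analysis** (`roi_dose()`, `energy_flow()`, `profile_along_ray()`,
   `extract_tpsf()`, `response_matrix()`, `pearson_matrix()`,
   `hierarchical_cluster()`, `linear_regression()`, `group_compare()`):
   dose tables over atlas regions and tissue classes, Sankey-style energy
   flows, depth profiles of the effective attenuation coefficient
   μ_eff = √(3 μ_a (μ_a + μ_s′)), temporal point spread functions, and the
   statistical machinery for region-response clustering and dose–response
   regression.
4. **Safety** (`mpe_skin()`, `mpe_ocular_extended()`, `safety_margin()`):
   ANSI Z136.1 maximum-permissible-exposure limits in the 700–1400 nm band.

## The optical model and its assumptions

Light transport is treated as radiative transfer of unpolarized,
incoherent photon packets: polarization, coherence, fluorescence and
nonlinear effects are ignored, and tissue is locally isotropic (scattering
described by the one-parameter Henyey–Greenstein phase function whose mean
deflection cosine is `g`). These are the standard assumptions of tissue
optics in this wavelength band; they break down only at sub-mm coherence
scales irrelevant to dose accounting.

A voxel containing several tissues gets probability-weighted parameters
(`mix_properties()`): `mua`, `mus` and `n` mix arithmetically; `g` is
averaged with weights `w·mus` because anisotropy is only meaningful where
scattering occurs (a plain weighted mean is used in the zero-scattering
corner case). Any probability deficit from 1 is assigned to air
(`mua = mus = 0`, `n = 1`), which keeps background and sinus voxels inert
without renormalizing the segmentation. Every mixed parameter is provably
inside the range spanned by its components, which the test suite checks by
property testing.

The spectral library is a plain JSON file, tissue class × wavelength →
(mua, mus, g, n). The shipped defaults cover the six head classes and eight
ocular classes at 670/810/850/980/1070 nm with literature-plausible values;
they are explicitly configurable stand-ins, not measurements — quantitative
work on real anatomy should substitute measured spectra. Between tabulated
wavelengths each parameter is interpolated linearly; extrapolation is
refused rather than guessed.

### Sparse annotation and boundary interpolation

Probabilistic segmentation blurs thin layered structures (cornea, lens,
orbital fat). `annotate_and_interpolate()` therefore accepts expert-placed
sample points along explicit 1-D profile lines and replaces the parameter
profile between nodes with an interpolant sampled at voxel centers. Two
interpolants are provided: piecewise-linear, and the natural cubic spline —
the C²-continuous cubic Hermite interpolant with zero second derivative at
the line ends, which preserves gradient continuity at tissue boundaries and
suppresses staircase artifacts. Interpolation is deliberately along 1-D
profiles rather than as 3-D scattered interpolation: it matches how such
annotations are collected (along an anatomical axis) and keeps the behavior
auditable voxel by voxel. The implementation evaluates the spline with
`stats::spline(method = "natural")`; the test suite checks it against an
independently coded tridiagonal natural-spline solver to 10⁻⁹.

## The transport engine

The engine (C++, single-threaded, bit-reproducible for a given seed) uses
the track-length estimator with continuous absorption:

* The sampled dimensionless optical depth τ = −ln ξ is consumed against the
  **scattering** coefficient only; along a segment of length s the packet
  weight decays as `exp(-mua·s)` and the voxel tally receives
  `w(1−exp(−mua·s))/mua` (limit `w·s` as `mua → 0`). This keeps the fluence
  estimate unbiased in non-absorbing voxels such as CSF, where an
  interaction-site estimator would record nothing. Absorbed energy per voxel
  is `fluence × mua × voxel volume`.
* Voxel traversal is a 3-D DDA with optical depth carried across faces;
  exact face/corner hits are resolved by nudging 10⁻⁷ mm along the direction
  of travel. The nudge skips ~10⁻⁷ mm of path per crossing, which bounds the
  error of closed-form comparisons at ~10⁻⁸ per 100 crossings — the test
  suite asserts Beer–Lambert decay at 10⁻⁶ accordingly.
* At faces where `n` changes (including entry from ambient air and escape),
  the unpolarized Fresnel reflectance decides stochastically between
  specular reflection and Snell refraction; total internal reflection is
  handled exactly.
* Packets below `weight_threshold` (default 10⁻⁴) undergo Russian roulette
  with survival probability 0.1 and reweighting by 10× — the MCML
  convention; both are configurable and the estimator stays unbiased for
  any choice. With roulette disabled, absorbed + escaped + capped energy
  equals the launched energy to ~10⁻¹¹ relative (asserted at 10⁻⁹).
* Photon time advances by `Σ ℓᵢ·nᵢ/c`; when time gating is on, each deposit
  is indexed by the segment's start time into gates of width
  `time_gate_ns` (default 0.3 ns). Arrivals later than the last gate go to
  one overflow gate, so the gate series always sums exactly to the
  steady-state tally — a deliberate trade: the overflow gate's shape is not
  meaningful, but energy is never silently dropped.
* A `max_path_mm` cap (default 20 m) guards against the pathological
  zero-attenuation infinite walk; capped weight is tallied separately, and
  is zero in all shipped configurations.

Emission is collimated (surface-normal) across the LED face; the divergence
profile of clinical arrays is generally unspecified, and an extended planar
source into a scattering medium randomizes direction within a transport
length anyway. An isotropic point source is provided for physics validation.
Multiple sources share the photon budget in proportion to their power
(power density × emitting area); per-source volumes can be retained for
energy-flow and region-response analysis.

Randomness comes from a xoroshiro128+ generator seeded via splitmix64 from
the user seed (per-source streams are derived deterministically), so runs
are reproducible bit for bit independent of R's RNG state.

### Validation against independent physics

Three analytic oracles anchor the engine (all in the test suite):

* **Beer–Lambert**: in a pure absorber the plane-summed fluence ratio over
  10 mm equals e⁻¹ essentially exactly (see the nudge bound above).
* **Diffusion theory**: for an isotropic point source in a homogeneous
  high-albedo medium (μ_a = 0.01, μ_s = 10, g = 0.9), shell-averaged fluence
  at r = 10/15/20 mm matches φ(r) = exp(−μ_eff r)/(4πDr),
  D = 1/(3(μ_a+μ_s′)), within 15% (observed agreement ≈ 2%).
* **Henyey–Greenstein first moment**: the sample mean of 10⁶ deflection
  cosines reproduces g within ±0.005 for g ∈ {0, 0.5, 0.9}.

## The synthetic layered head

`make_layered_head()` generates the study medium: a five-layer spherical
head (scalp soft tissue, skull, CSF, gray-matter shell, white-matter core)
with 1 mm isotropic voxels, plus a hemispheric (optionally octant) atlas.
Default radii (84/72/65/62/53 mm) give anatomically plausible layer
thicknesses: ~7 mm skull, 3 mm CSF, 9 mm cortical gray shell.

A concentric sphere is a poor stand-in for one salient feature of real
heads: the extracerebral soft tissue is thin over the forehead and vertex
and thick over the occiput and skull base (nuchal muscles, facial and basal
structures). On a perfectly concentric phantom every scalp entry point is
equivalent by symmetry, and the clinically observed ranking of entry sites
could not even be posed. The generator therefore offsets the outer scalp
sphere posterior-inferiorly by default (`scalp_offset = c(0, -6, -5)` mm,
chosen once from gross anatomy: ~6 mm of scalp over the forehead versus
~16 mm over the occiput), which reproduces the qualitative ordering of
gray-matter energy deposition across treatment paradigms — forehead ≥
vertex ≥ ocular ≥ occipital/oral/nasal — as a geometric consequence, not a
fitted one. `scalp_offset = c(0, 0, 0)` restores the concentric sphere.

What the fixture does **not** emulate: gyral folding, the longitudinal
fissure's CSF channel, orbits/sinuses (the ocular path is available
separately as a layered `make_eye_slab()`), and any inter-individual
variability. Passing the ordering test on this phantom demonstrates that the
transport and accounting machinery respond correctly to extracerebral
thickness — it does not certify patient-specific dose values, which require
real segmented MRI inputs through the same file contracts (NIfTI probability
maps + label atlas + TSV lookup).

## Statistical machinery

The analysis layer mirrors how small PBM cohorts are analyzed:

* **Region responses** are the mean fluence rate each atlas region receives
  from each source (`response_matrix()`), correlated across regions by
  Pearson's r (`pearson_matrix()`; zero-variance regions are flagged and
  reported as 0 rather than dropped silently).
* **Clustering** is agglomerative UPGMA (unweighted average Euclidean
  distance) implemented in the package with deterministic lowest-index tie
  breaking, returning a standard `hclust` object. It is verified both
  against a brute-force oracle that re-averages all pairwise distances from
  scratch at every merge, and against `stats::hclust(..., "average")`.
* **Group comparisons** (`group_compare()`) follow the decision tree used
  in the field: Kolmogorov–Smirnov normality on each sample (or on paired
  differences) and Levene's test for variance equality, then Student's
  t-test when both gates pass at p > 0.05, otherwise the Wilcoxon
  rank-sum/signed-rank test; two-tailed p-values with 95% CIs. No
  multiple-testing correction is applied by default, matching common
  practice in exploratory pilot analyses; `stats::p.adjust(..., "BH")` can
  be applied over a family of comparisons where appropriate.
* **Dose–response regression** (`linear_regression()`) is ordinary least
  squares with the slope's two-tailed t-test on n−2 degrees of freedom.
* The **extracerebral penetration rate** (`penetration_rate()`) is defined
  in this package as (energy deposited in GM + WM + CSF)/(total absorbed
  energy). Competing conventions exist (e.g. normalizing by launched
  energy); the definition is stated prominently because the literature is
  not uniform.

## Safety evaluation

`mpe_skin()` implements the ANSI Z136.1 long-exposure (CW, > 10 s) skin
limit 0.2·C_A W/cm², with C_A = 10^(2(λ−0.700 μm)) below 1.050 μm and 5.0
above. `mpe_ocular_extended()` implements the extended-source ocular chain
C_E = min(α,100)/1.5, T₂ = 10·10^((min(α,100)−1.5)/98.5) s, and limit
1.8·C_A·C_E·T₂^(−1/4) mW/cm² (700–1050 nm) or 9.0·C_C·C_E·T₂^(−1/4) mW/cm²
(1050–1150 nm, C_C = 1). Limits are computed in W/cm² per the standard and
reported in mW/mm² (×10). At the two clinical wavelengths these evaluate to
3.32 and 10.0 mW/mm² (skin) and 0.63 and 1.90 mW/mm² (ocular, α = 100 mrad),
leaving ≥ 10× headroom over a 20 mW/cm² (= 0.20 mW/mm²) LED array. Pulsed
and short-exposure branches of the standard are refused with an error, not
silently approximated; the ~0.2% step of the piecewise C_A definition at
1.050 μm is inherent to the standard and asserted as such in the tests.

## Numerical choices and problem sizes

Defaults chosen once and used throughout: head-mask threshold 0.01 on total
tissue probability (robust to segmentation noise at the scalp edge);
roulette 10⁻⁴ / 0.1; time gate 0.3 ns; voxel 1 mm isotropic; all volumes in
RAS with the world origin at the grid center (anterior-commissure
convention for real data).

The test suite runs its physics checks at desk scale, stated here as the
package's own choices: 10⁵ packets for conservation and Beer–Lambert
(whose checks are essentially deterministic), 3×10⁵ packets for the
diffusion-theory comparison (shell-level Monte Carlo error ≈ 1%, an order
of magnitude inside the 15% acceptance band), and 3×10⁵ packets per run for
the six-paradigm ordering on the layered head over three seeds (the ordered
gray-matter percentages are separated by tens of standard errors at this
size). Production simulations of clinical questions should use 10⁷–5×10⁷
packets, as is conventional; photon count is a plain configuration value
and the estimator variance scales as 1/√n, which the suite also checks.

## Known limitations

* The phantom generators are geometric idealizations (see above); all
  quantitative claims about real heads require real segmentation inputs.
* The shipped optical library is a documented default, not a measurement
  set; dose tables scale directly with these parameters.
* Collimated emission ignores LED divergence; a strongly divergent source
  in contact with skin would shift shallow-layer dose slightly.
* The engine is voxel-based: surfaces are staircase approximations at the
  1 mm scale, mitigated but not eliminated by probability-weighted mixing
  and sparse-annotation interpolation.
* Registration of phantoms to a standard space is applied
  (`apply_rigid_transform()`), never estimated — estimating rigid
  registration belongs to upstream neuroimaging tools.
* Simulation results are persisted as NIfTI volumes plus a JSON sidecar
  (`write_sim_result()`), keeping every artifact in neuroimaging-standard,
  text-adjacent formats readable by external viewers.
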