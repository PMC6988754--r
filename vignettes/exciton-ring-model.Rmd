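---
title: "Modelling LH2 ring excitons: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LH2 ring excitons: methods and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonring)
```

# The physical model

LH2, the peripheral antenna of purple bacteria, arranges 27
bacteriochlorophylls in two concentric rings with exact nine-fold
symmetry: an 18-pigment ring (absorbing near 850 nm in the high-light
form, near 820 nm in the low-light form) whose α and β pigments
alternate around the circle, and a 9-pigment ring absorbing near
800 nm. The optical properties are governed by a Frenkel exciton
Hamiltonian over the local Q~y~ excitations, optionally extended by a
manifold of inter-pigment charge-transfer (CT) states:

$$
H \;=\; \sum_i \varepsilon_i \,|i\rangle\langle i|
 \;+\; \sum_{i\neq j} V_{ij}\,|i\rangle\langle j|
 \;+\; \sum_m \varepsilon^{CT}_m |m\rangle\langle m|
 \;+\; \sum_{i,m} V^{CT}_{im}\big(|i\rangle\langle m| + \mathrm{h.c.}\big),
$$

with site energies $\varepsilon_i$, excitonic couplings $V_{ij}$, CT
energies $\varepsilon^{CT}_m$ and LE–CT couplings $V^{CT}_{im}$; CT–CT
couplings are zero by construction, and CT basis states carry no
transition dipole. All energies are in cm^-1^, coordinates in Å and
dipoles in Debye throughout the package.

`lh2_site_parameters()` ships the MD-averaged parameters of the three
complexes this model is usually applied to — the high-light (HL) and
low-light (LL) forms and a homology-modelled PucD — three site-energy
classes (α, β, B800) and the two dominant couplings of the 18-ring:
the inter-chain $V_{1\alpha\beta}$ (pigments of adjacent protomer
units) and intra-chain $V_{2\alpha\beta}$ (pigments of the same unit),
with their per-class standard deviations over 50 trajectory frames.

# Synthetic ring generator

`build_ideal_ring()` constructs an idealised C~9~ double ring. The
defaults are deliberately simple but dimensionally realistic:

* 18-ring radius 26 Å, 9-ring radius 31 Å, axial offset 16.5 Å — the
  crystallographic length scales of the complex;
* transition dipoles of 6.3 D (a typical BChl *a* Q~y~ value; only the
  relative intensities depend on it, the energies never do);
* α and β sites offset by ∓9° from the unit axis, so intra-unit pairs
  sit closer (8.1 Å) than inter-unit pairs (9.9 Å), mirroring
  $V_2 > V_1$;
* in-plane, near-tangential dipoles, antiparallel between α and β
  (which makes nearest-neighbour couplings positive, of the order of
  several hundred cm^-1^, as in the tabulated parameters) with an
  alternating ±10° tilt.

Every geometric choice is a function argument; the exact C~9~ symmetry
is what downstream symmetry analysis relies on and is guaranteed by
construction.

## Static disorder and correlated jitter

`disorder_model()` + `sample_ensemble()` emulate what an MD trajectory
provides: per-frame site energies drawn from role-specific Gaussians
(defaults: the tabulated per-class standard deviations, ~270–330
cm^-1^), an in-plane orientational wobble of each transition dipole,
and a radial displacement of each center.

The orientational wobble carries the package's one structural
hypothesis: hydrogen bonds tether a pigment's orientation to its
neighbour. Correlation is realised with shared Gaussian draws — the
α/β partners of a unit share a $\sqrt{\rho_\text{intra}}$-weighted
component, β of unit *u* and α of unit *u*+1 share a
$\sqrt{\rho_\text{inter}}$-weighted component, the remainder is
private. The construction yields the exact pairwise correlations but
requires $\rho_\text{intra} + \rho_\text{inter} \le 1$ (validated with
an informative error); a full ring-stationary Gaussian process would
lift that restriction at the cost of a covariance-matrix model, which
the data do not call for.

One RNG stream, seeded once, drives everything; within each frame the
draw order is fixed (site energies in site order, shared intra-unit
draws, shared inter-unit draws, private B850 draws, B800 draws, radial
draws), so ensembles are bit-reproducible from the manifest written by
`write_ensemble_manifest()`.

A property worth knowing when choosing the wobble width: a *common*
rotation of two in-plane dipoles changes the orientation factor κ only
at second order (the first-order term cancels for the near-tangential
pair geometry), while *independent* rotations contribute at first
order. The tethering contrast — correlated pairs giving narrower κ
distributions — is therefore a small-wobble effect; for wobbles beyond
roughly 6–8° the second-order common-mode term catches up and the
contrast washes out. The tests probe the mechanism at a 4° wobble,
comfortably inside the regime where the first-order picture holds.

## Charge-transfer manifold

`make_ct_manifold()` creates both transfer directions (α→β and β→α)
for every adjacent 18-ring pair — 36 CT states for the nonameric ring.
CT energies are Gaussian around a configurable mean (default: 2500
cm^-1^ above the highest site energy, so the manifold sits above the
exciton band) and are then lowered by an alignment shift (default
−1008 cm^-1^), the a-posteriori correction that reconciles the
electronic-structure level used for CT states with the one used for
the local excitations. Each CT state couples to its donor and acceptor
LE states; a user coupling table referencing non-adjacent pairs is
rejected.

# Geometry descriptors

The descriptors mirror what one measures on structures: the macrocycle
center as the mean of the four pyrrole nitrogens; the Förster
orientation factor
$\kappa = \hat\mu_1\!\cdot\!\hat\mu_2 - 3(\hat\mu_1\!\cdot\!\hat r)(\hat\mu_2\!\cdot\!\hat r)$,
bounded by [−2, 2]; signed IUPAC torsions (cis = 0°, trans = 180°);
heavy-atom hydrogen-bond distances (acetyl O to Tyr OH / Trp NE1 —
hydrogens are rarely resolvable). `descriptor_distributions()`
evaluates distance and κ per frame for every symmetry-equivalent pair
of the `inter_chain`/`intra_chain` classes, the pair classification
matching the $V_1$/$V_2$ definitions.

For structures read from PDB files, the Q~y~ dipole axis is taken
between two configurable macrocycle nitrogens (the N~B~→N~D~
convention; `ring_selection_rules()`), since the file format does not
store dipoles. The acetyl-torsion atom quadruple is likewise
configuration, not a hard-coded choice, because naming conventions
vary between depositions.

# Couplings

Three routes of increasing realism:

1. **Point dipole** — $V = C\,\kappa\,\mu_1\mu_2/r^3$ with
   $C = 5034.12$ cm^-1^ D^-2^ Å^3^ (CODATA conversion;
   $e^2/4\pi\varepsilon_0 = 116140.97$ cm^-1^ Å per $e^2$,
   1 D = 0.2081943 e·Å).
2. **Transition charges** — the Coulomb sum between two-point ±q
   charge sets placed along each dipole axis and reproducing |μ|
   exactly. This is the minimal classical stand-in for a transition
   density; it converges to the point-dipole value in the far field
   and deviates by a few percent at nearest-neighbour distances.
   For real structures a user-supplied charge table would replace it
   (deriving charges from ab initio densities is out of scope).
3. **Environment screening** — polarizable sites (isotropic α, Å^3^)
   acquire induced dipoles in the transition field of pigment *j*,
   solved self-consistently, and interact with the field of pigment
   *i*: $v_\text{env} = -\sum_k \mu^\text{ind}_k(j)\cdot E_i(r_k)$.
   The sign convention is the interaction energy of a dipole in a
   field; for a polarizable medium between two pigments it opposes the
   bare Coulomb term (screening). Because the linear response is
   symmetric, $v_\text{env}$ is reciprocal in *i* ↔ *j*; the tests
   verify reciprocity numerically rather than assuming a universal
   sign of the effect.

The induced-dipole solver is a damped Jacobi (successive
over-relaxation, ω = 0.7) iteration with a 10^-8^ D convergence
threshold on the largest dipole change and a 500-iteration cap; it
reports divergence rather than returning a doubtful fixed point. An
optional exponential Thole-style damping of the dipole–dipole tensor
is available for closely spaced synthetic sites (off by default — the
bare tensor is the honest default and the fixtures keep sites
physically separated). Like any undamped classical polarization model,
the fixed point ceases to exist when polarizabilities are large at
short range; the direct dense solve used as a test oracle has the same
physical pathology even where it remains algebraically solvable.

# Exciton analysis

`diagonalize_hamiltonian()` yields ascending eigen-energies,
orthonormal coefficients, state dipoles
$\vec\mu_s = \sum_i c_{si}\vec\mu_i$ and strengths $|\vec\mu_s|^2$;
total dipole strength is conserved (checked to 10^-6^ relative).

**Ring quantum numbers.** `assign_k()` labels each state by the
18-site Fourier mode holding the largest share of its power, with
labels in −8…9. The momentum is measured in the gauge where
neighbouring dipoles are phase-aligned: when adjacent ring dipoles are
antiparallel (detected from the dipoles themselves), the coefficients
are de-alternated first. With positive couplings this reproduces the
standard convention — dark *k* = 0 at the bottom, the bright
*k* = ±1 pair just above, the weakly allowed *k* = ±8 pair near the
top. A state whose best ±k pair holds less than half its power (strong
disorder, B800- or CT-dominated states) stays unlabelled.

**Exciton width.** Defined as the energy difference between the
*k* = ±8 and *k* = ±1 pair means. Under disorder the width is
computed on the *symmetry-averaged* Hamiltonian
(`symmetry_average()`): the per-frame matrices are averaged over
frames and over all C~9~-equivalent matrix elements, giving the
average homogeneous ring, which commutes exactly with the ring
rotation. Per-frame widths can be computed but are non-canonical —
disorder mixes the labels. Whether one uses pair means or individual
pair members is immaterial for the symmetric ring (exact degeneracy);
pair means are used so the definition extends continuously to weakly
perturbed rings.

**Degeneracy and brightness.** Pairs are counted at a 10^-4^ cm^-1^
energy tolerance and states are bright above 10^-6^ of the maximum
dipole strength. For the ideal ring the selection rules then give 4
bright and 14 dark states organised as 8 degenerate pairs plus 2
singlets; static disorder redistributes strength into formerly dark
states, which the census reports as a growing bright count.

**CT shifts.** `ct_shift()` matches LE-only states to CT-including
states by maximal eigenvector overlap on the LE block (ties broken by
energy proximity, matches below 0.5 overlap flagged) and reports the
exact shift next to the second-order estimate
$\sum_m |{\textstyle\sum_i c_i V_{im}}|^2/(E_s - \varepsilon^{CT}_m)$.
At a CT gap roughly ten times the coupling the two agree to a few
percent; as the CT manifold is lowered the *k* = ±1 downshift deepens
monotonically.

# Spectra and the perturbation experiments

`lorentzian_spectrum()` convolves the stick spectrum with Lorentzians,
$I(\nu) = \sum_s D_s\,\Gamma_s/\pi\,[(\nu - E_s - \Delta)^2 +
\Gamma_s^2]^{-1}$. The HWHM is assigned per band; rather than an
energy cutoff (the reference treatment assigns widths per band without
defining the split), each state's band is identified from its dominant
basis weight — B850-dominated states take the low-energy-band width,
B800- and CT-dominated states the high-energy width — with an explicit
`band_split` energy cutoff available as an override. Reference widths:
150 cm^-1^ (high-light), 280 cm^-1^ (low-light forms, low band), 180
cm^-1^ (high band); a single rigid shift (−1247 cm^-1^ by default)
aligns the absolute scale with experiment, absorbing the systematic
error of the underlying excited-state method. All broadening sources
are lumped into one symmetric lineshape; vibronic or asymmetric
lineshapes are out of scope.

The default grid is 9 000–15 000 cm^-1^ at 1 cm^-1^. A Lorentzian
integrates to 99% of its strength only within ±64 HWHM, so the
normalization attribute flags grids that clip the tails; the
conservation tests use wide grids on purpose. Wavelengths are derived
as $10^7/\nu$ nm; spectra are stored on the uniform wavenumber grid.

Two perturbation experiments close the loop on the scientific
questions:

* `apply_site_corrections()` adds role-wise diagonal shifts — the
  acetyl-torsion correction (+220 cm^-1^ α, +120 cm^-1^ β) that
  compensates the classical force field's over-planarization of the
  acetyl group, leaving couplings untouched;
* `scale_coupling_class()` / `scale_coupling_sweep()` rescale one
  coupling class; reducing the intra-chain $V_2$ from 1.0 toward 0.65
  blue-shifts the *k* = ±1 exciton monotonically, the mechanism
  proposed for the strongly blue-shifted PucD complex.

# Statistical layer

`fit_bond_length_regression()` is ordinary least squares of site
energy on macrocycle bond lengths (no regularisation — collinear
designs fail loudly naming the offending columns), with
`predict_site_energy()` for held-out structures and broom-style
`tidy()`/`glance()` accessors. `plant_regression_data()` +
`noise_sd_for_r2()` generate data with a known population R² for
recovery tests. `class_statistics()` reports group means, *n*−1
standard deviations and Student-*t* 95% confidence intervals (the CI
method is a documented choice; the reference figures do not state
theirs). `contribution_ledger()` is a deliberately classical
first-order estimate of per-residue shifts (difference charges ×
residue charges, optional induced-dipole response); it reproduces
signs, additivity and distance trends of a switch-off analysis, not
quantum-mechanical magnitudes.

# Problem sizes, tolerances and what the tests do (and do not) show

The test-suite fixtures use 18–27-site rings, 50-frame ensembles for
parameter recovery (2000 frames once, for a spread check), 1000-sample
regressions, 5–30-site polarizable clusters, and wide spectral grids —
sizes chosen so the whole suite runs in well under a minute while
keeping Monte-Carlo tolerances (3 standard errors; ±0.05 on R²)
meaningful.

Key numerical tolerances, collected: eigen-solver vs analytic
two-band dispersion 10^-8^ cm^-1^; induced dipoles vs dense solve
10^-8^; dipole-strength completeness 10^-6^ relative; C~9~
commutation 10^-9^; degeneracy pairing 10^-4^ cm^-1^; bright threshold
10^-6^ relative; Lorentzian normalization 1% on wide grids.

The synthetic generator emulates the *statistical* structure of an MD
ensemble — per-class Gaussian energies, orientational wobble with
bond-level correlations, radial jitter — not its dynamics, anharmonic
tails, or coupling fluctuations driven by wavefunction overlap. A
nearest-neighbour Hamiltonian built only from the two tabulated
couplings understates the exciton width of the full coupling set by
roughly 3–7% (beyond-nearest-neighbour couplings are not tabulated in
the main parameter table), which is why width checks carry a 10%
band while the closed-form oracle checks are at 10^-8^. Passing tests
therefore demonstrate correctness of the machinery and of the
mechanisms (tethering → narrow κ; coupling loss → blue shift), not
quantitative agreement with any particular real complex.

# A worked pipeline

```{r pipeline, eval = FALSE}
library(excitonring)

ring <- build_ideal_ring()
ens <- sample_ensemble(
  ring,
  disorder_model(orient_jitter_deg = 4, corr_intra = 0.8),
  n_frames = 50, seed = 1
)

# geometry descriptors
desc <- descriptor_distributions(ens)
attr(desc, "summary")

# per-frame Hamiltonians -> symmetry average -> exciton analysis
hams <- lapply(split(ens, ens$frame), function(fr) {
  fr <- dplyr::select(fr, -frame)
  assemble_hamiltonian(fr, couple_frame(fr))
})
st <- assign_k(diagonalize_hamiltonian(symmetry_average(hams)))
glance(st)

# spectrum
sp <- lorentzian_spectrum(st, hwhm_low_band = 150, hwhm_high_band = 180)
peak_positions(sp)
autoplot(sp)
```
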