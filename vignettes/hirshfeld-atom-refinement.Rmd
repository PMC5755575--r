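---
title: "Aspherical-atom refinement with qcrefine: model, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aspherical-atom refinement with qcrefine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcrefine)
```

## The model

An X-ray diffraction experiment measures structure-factor magnitudes
$|F_o(\mathbf h)|$, the Fourier components of the thermally smeared
unit-cell electron density. The smeared density is modelled as a sum of
atom-centred static densities convolved with harmonic probability
distributions for the nuclear motion. In the independent atom model (IAM)
the static atomic densities are spherical free atoms; `qcrefine`
additionally implements the aspherical alternative, Hirshfeld atom
refinement (HAR), in which a molecular electron density is partitioned into
overlapping atomic fragments by the stockholder rule
$$ w_A(\mathbf r) \;=\;
   \frac{\rho^0_A(|\mathbf r-\mathbf R_A|)}
        {\sum_B \rho^0_B(|\mathbf r-\mathbf R_B|)}, $$
where $\rho^0_B$ are spherical reference-atom densities. The Hirshfeld atom
$w_A \rho$ is Fourier-transformed numerically into a complex, aspherical
atomic scattering factor referenced to its nucleus,
$$ f_A(\mathbf h) = \int w_A(\mathbf r)\,\rho(\mathbf r)\,
   e^{2\pi i\,\mathbf h^*\!\cdot(\mathbf r-\mathbf R_A)}\, d\mathbf r , $$
and the calculated structure factor assembles all symmetry copies $s$ with
Debye–Waller smearing (CIF convention, $\beta$-transport of $U^{ij}$ under
rotations):
$$ F_c(\mathbf h) = \sum_s \sum_A \mathrm{occ}_A\,
   f_A(R_s^{\mathsf T}\mathbf h)\,
   T_A(R_s^{\mathsf T}\mathbf h)\,
   e^{2\pi i\,\mathbf h\cdot(R_s\mathbf x_A + \mathbf t_s)},
   \qquad
   T = \exp\!\Big(-2\pi^2 \textstyle\sum_{ij} h_i h_j a^*_i a^*_j U^{ij}\Big). $$
Positions, displacement tensors (hydrogens included, anisotropic by
default) and one overall scale $k$ are refined by weighted least squares on
$|F|$, minimizing $\sum_h w_h (|F_o| - k|F_c|)^2$ with $w_h =
1/\sigma^2(F)$. Because the partitioned density moves with the nuclei, the
two steps — density evaluation/partition and least squares at fixed form
factors — alternate until the parameters are stationary. A crystal-field
model (stockholder point charges and dipoles of all whole neighbouring
molecules within a radius, or an explicit cluster of neighbours) can be
attached for densities that respond to their environment.

Key assumptions: harmonic nuclear motion (no anharmonicity), a single
scale, no extinction or absorption corrections, and a partition that is
held fixed while atoms vibrate. Refinement is against $|F|$, never $F^2$.

## Density providers

The engine is agnostic about where the molecular density comes from: a
`DensityProvider` returns density values at arbitrary Cartesian points,
spherical per-atom reference densities for the stockholder weights, and can
be rebuilt at a new geometry. The package ships two families:

* **Analytic Gaussian-atom models** (`makeToyCrystal`,
  `gaussianDensityProvider`): every atom is a sum of Gaussian shells, some
  of which may be displaced along a bond to mimic bonding asphericity.
  Form factors and structure factors then have closed forms
  ($f(h) = \sum_j n_j e^{-\pi^2|h^*|^2/\alpha_j} e^{2\pi i h^*\cdot d_j}$),
  which makes these models exact, independent oracles for the quadrature,
  assembly and refinement machinery.
* **Free-atom references** (`freeAtomDensity`): spherical neutral-atom
  densities represented as Gaussian expansions consistent with the standard
  tabulated scattering factors (H–Kr). They define the promolecule, the
  stockholder denominators and the IAM route. Only neutral references are
  implemented; a `chargeState` argument exists but is restricted to 0, so
  ionic promolecule references remain an explicit extension point.

A self-consistent-field backend is deliberately out of the package: any
density source satisfying the provider contract can drive the refinement.

## What the synthetic generator emulates — and what it does not

The toy presets cover the failure modes separately: a single atom
(quadrature and scale), a centrosymmetric homonuclear pair (phase
restriction to $0/\pi$), a polar X–H pair whose hydrogen density centroid
sits 0.10 Å from the proton towards the heavy atom (the classic
foreshortening of X–H bonds under spherical-atom refinement), an ionic
pair (crystal-field enumeration and charge conservation), a $Z'=1/2$
molecule in $P\bar 1$ (fragment growth) and a molecule on a mirror plane
(special-position constraints). Simulated data carry relative Gaussian
noise on $|F|$ with $\sigma = \text{noise}\times|F|$, matching the
refinement weights exactly; noise-free sets carry a small constant nominal
$\sigma$ ($10^{-4}$ of the mean $|F|$) so weights stay finite.

Passing these tests shows that the numerical chain — partition, Fourier
transform, symmetry transport, derivatives, constraints, uncertainties —
is correct and statistically calibrated *under the stated error model*.
Real data add what the generator deliberately omits: absorption,
extinction, thermal diffuse scattering, anharmonicity, detector
systematics, and densities whose deformation is not a sum of displaced
Gaussians. Conclusions about those effects cannot be drawn from the toys.

A caution discovered with the toys and kept as a regression test: starting
a refinement *exactly* at a configuration with a non-crystallographic point
symmetry (e.g. a perfectly collinear diatomic at its symmetric geometry)
makes the objective an even function of some transverse displacements, so
their gradient vanishes identically and the normal matrix is singular. The
engine reports this rather than silently regularizing it; practical starts
(a preceding spherical-atom refinement, or any perturbed geometry) do not
sit on such points.

## Numerical choices

* **Quadrature.** Atom-centred product grids: Gauss–Legendre radial nodes
  under the Treutler–Ahlrichs M4 mapping (scale 0.6 Å), Gauss–Legendre in
  $\cos\theta$ times a uniform azimuthal rule, and Becke's smooth cell
  functions (stiffness 3, equal radii) to partition space. Presets
  `"test"` (30 radial × 128 angular points per atom), `"standard"`
  (60 × 392) and `"fine"` (90 × 1152). The product rule is exact for
  spherical harmonics up to degree $2n_t-1$; the M4 mapping integrates
  Gaussian shells, exponential cusps and the oscillatory Fourier kernels to
  near machine precision at the `"standard"` level (single-atom form
  factors agree with closed forms to ~$3\times10^{-10}$ e; `"fine"` reaches
  ~$10^{-13}$ e). Unique reflections only are integrated; symmetry copies
  are retrieved by index rotation on the symmetry-expanded index set.
* **Constraints.** Site stabilizers are detected numerically; allowed
  coordinate and $U^{ij}$ subspaces are the fixed subspaces of the group
  averaging operators (transported through the dimensionless
  $\beta^{ij} = U^{ij}a^*_ia^*_j$ form, where rotations act congruently).
  Floating origins in polar space groups are fixed by constraining the
  occupancy- and $Z$-weighted centre along each polar direction.
* **Least squares.** Analytic derivatives of $|F_c|$ with respect to
  coordinates and $U^{ij}$ at fixed form factors; shifts from the
  constrained normal equations; s.u.s from the inverse normal matrix scaled
  by the goodness of fit. Steps are capped at 0.5 in native parameter units
  and halved (up to 8 times) whenever the weighted residual would rise, so
  $wR_2$ is non-increasing across cycles. Convergence: max |shift|/s.u.
  below 0.01 (inner), parameter change below $10^{-6}$ between outer
  cycles. Non-positive-definite $U$ tensors are eigenvalue-clamped at
  $10^{-5}$ Å$^2$ with a warning and reported as a quality flag.
* **Scale.** One overall $k$, initialized at its closed-form optimum
  $\sum w|F_o||F_c| / \sum w|F_c|^2$ and refined jointly.
* **Reflection handling.** Default observation cut $F > 3\sigma(F)$, fixed
  for the whole refinement. $F^2$-dialect files are converted on input with
  $\sigma_F = \sigma_{F^2}/(2|F|)$; non-positive $F^2$ is truncated to
  $|F| = 0$ with $\sigma_F = \sqrt{\sigma_{F^2}}$ (simple, monotone, and
  logged — full intensity-statistics treatments are out of scope). Width
  auto-detection labels fixed-format files as $F^2$ (the common
  convention); F-content files need the explicit dialect flag.
* **Degenerate inputs.** Cells with non-positive volume, overlapping nuclei
  (< 0.3 Å), empty pruned sets, all-non-positive reflection files, and
  singular normal matrices raise errors that name the offending item.

## Validation statistics

The metrics module reproduces the standard comparison toolbox:
$R_1$, $wR_2$ and GOF; difference Fourier maps (calculated phases, no
F(000) term, FFT-based, symmetry- and Friedel-expanded) with their
fractal-dimension curves; the error-weighted root-mean-square difference
$$ \mathrm{wRMSD} = \sqrt{\tfrac1N \sum_i
   (v_{X,i}-v_{N,i})^2 / (\sigma_{X,i}^2+\sigma_{N,i}^2)} , $$
which equals 1 when two determinations agree statistically; mean ADP
ratios and mean absolute ADP differences with sample standard deviations,
partitioned into hydrogen and non-hydrogen blocks; the rigid-bond test
(differences of mean-square displacements along bonds, near zero for rigid
covalent bonds, with 0.001 Å² the customary limit for non-hydrogen
bonds); and bond-length comparison statistics per bond class.

Two averaging conventions are defensible for the ADP ratio tables: pooling
all diagonal components, or averaging within each atom first. Both are
implemented (`pooling = "components"` is the default; `"atoms"` is the
alternative); on the test fixtures the difference is far below the quoted
sample standard deviations. Ratio and difference statistics are computed on
$U^{ij}$ in the crystal (CIF) basis by default, matching deposited values;
a Cartesian option exists. The wRMSD for ADPs uses all six components per
atom.

The fractal-dimension curve counts, for each density level, the voxels
within half a level-bin of that level on the full map and on subsampled
copies (every 2nd, 4th, 8th voxel per axis); the dimension is the log–log
slope of count versus subsampling factor. With this construction a pure
white-noise map gives $d_f(0)\approx 3$ and a smooth iso-surface gives
$\approx 2$, so the curve separates featureless residuals from systematic
model error; the flat map of a perfect model is returned as a degenerate
empty curve.

## Fragment growth and bonding

Molecules are completed across symmetry and lattice translations with a
covalent criterion of 1.15 × (sum of covalent radii), at most one bond per
hydrogen. Alkali and alkaline-earth cations (Li, Na, K, Mg, Ca) are treated
as isolated ions — their contacts are ionic, and the covalent criterion
with their large radii would otherwise fuse salt networks into one
unbounded "molecule". Radius clusters add every whole molecule with any
atom inside the radius; growth past 10⁴ atoms aborts with advice to shrink
the radius. Occupancies below 1 are refined as given (fixed), since partial
disorder carries no extra machinery here.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run on the toy presets at
resolutions of 0.5–0.7 Å⁻¹ (about 400–800 unique reflections, 10–19
parameters), with the `"fine"` grid where closed-form agreement at the
10⁻⁶ level is asserted, `"standard"` for refinement accuracy and the
20-replicate calibration, and `"test"` for bulk statistical loops. These
sizes were chosen so every property of interest (quadrature convergence,
recovery, calibration, foreshortening) is already fully expressed while a
complete run stays in the minutes range on one core.

## Known limitations

* No SCF backend is bundled; quantum-mechanical densities enter only
  through the provider contract.
* Extinction, absorption, anharmonic motion, twinning and restraints are
  not modelled; refinement against $F^2$ is intentionally absent.
* Heavy elements (beyond Kr) and transition metals are refused by the
  file-level drivers without an override, since reliable aspherical
  reference densities are not available for them here.
* The core-CIF subset covers cell, symmetry operation loops, atom sites and
  anisotropic U loops; space-group symbols without an operations loop are
  understood only for P1 and P$\bar 1$.
* Hirshfeld charges and dipoles inherit the free-spherical-atom bias of the
  stockholder partition; the partition is not iterated (no Hirshfeld-I).
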