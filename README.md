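# qcrefine

Quantum-crystallographic refinement of X-ray diffraction data in R.

Crystallographers routinely refine atomic positions and anisotropic
displacement parameters (ADPs) against structure-factor magnitudes |F(h)|
using spherical free-atom scattering factors — the independent atom model
(IAM). Spherical atoms cannot represent bonding density, and the
best-known casualty is every element–hydrogen bond: the single hydrogen
electron is dragged into the bond, so IAM refinements place the proton
about 0.1 Å too close to its partner and cannot produce meaningful
hydrogen ADPs.

`qcrefine` implements the aspherical alternative, **Hirshfeld atom
refinement (HAR)**: a molecular electron density is partitioned into
overlapping atomic fragments by the stockholder rule

    w_A(r) = rho0_A(|r - R_A|) / sum_B rho0_B(|r - R_B|),

each Hirshfeld atom `w_A * rho` is Fourier-transformed numerically into a
complex aspherical scattering factor f_A(h) referenced to its nucleus, and

    F_c(h) = sum_s sum_A occ_A * f_A(R_s^T h) * T_A(R_s^T h)
             * exp(2 pi i h . (R_s x_A + t_s))

is fitted to |F_obs| by weighted least squares (weights 1/sigma^2,
Debye–Waller factor T in the CIF U^ij convention), iterating density
evaluation and refinement to convergence. Hydrogens are refined freely and
anisotropically by default. The package also provides the IAM route on the
identical least-squares machinery, crystal-field models (stockholder point
charges and dipoles, or explicit clusters of whole neighbouring
molecules), core-CIF and SHELX hkl I/O, and the standard validation
toolbox: R factors, difference-Fourier residual maps with
fractal-dimension (Henn–Meindl-style) curves, the rigid-bond (DMSDA)
test, error-weighted RMS differences (wRMSD), and ADP/bond-length
comparison statistics.

Molecular densities enter through a `DensityProvider` contract; the
package ships analytic Gaussian-atom toy crystals whose form factors and
structure factors have closed forms, so the entire pipeline is verifiable
against exact oracles without any external quantum-chemistry program.

## Worked example: the X–H foreshortening, and its cure

The `polar_XH_P1` toy is an O–H-like pair (true bond length 1.000 Å)
whose hydrogen density centroid sits 0.10 Å from the proton towards the
heavy atom — exactly the situation that defeats spherical atoms.

```r
library(qcrefine)

toy  <- makeToyCrystal("polar_XH_P1")
st   <- toy$structure
refl <- simulateReflections(st, toy$model, resolution = 0.7,
                            noiseFraction = 0, seed = 1)
start <- perturbModel(st, 0.02, 0.002, seed = 3)
opts  <- refinementOptions(gridLevel = "standard")

iam <- iamRefine(start, refl, opts, toy$provider)
har <- harRefine(start, refl, opts, toy$provider)
iam
#> RefinementResult: converged after 2 outer cycle(s)
#>   R1 = 0.00035  wR2 = 0.00041  GOF = 4.871  k = 0.99970(5)
#>   N_obs = 776  N_param = 16
har
#> RefinementResult: converged after 5 outer cycle(s)
#>   R1 = 0.00013  wR2 = 0.00015  GOF = 1.736  k = 0.99982(2)
#>   N_obs = 776  N_param = 16

r <- function(res) {
  m <- orthogonalize(crystalCell(st))$toCartesian(
    as.matrix(atomSites(refinedStructure(res))[, c("x", "y", "z")]))
  sqrt(sum((m[1, ] - m[2, ])^2))
}
cat(sprintf("true r(O-H) = 1.000 A | IAM: %.3f A | HAR: %.3f A\n",
            r(iam), r(har)))
#> true r(O-H) = 1.000 A | IAM: 0.888 A | HAR: 1.002 A
```

The spherical-atom refinement forshortens the bond by 0.112 Å and fits
the data visibly worse (higher R1 on noise-free data means pure model
error); the aspherical route recovers the true distance to ~0.002 Å.
`writeCifResult()` emits the refined model as a CIF with s.u.s in the
conventional parenthesis notation, and `compareStructures()` produces the
ADP-ratio, rigid-bond and bond-length comparison tables between two
models.

A thin command-line front end over the same functions is installed at
`inst/scripts/qcrefine` (subcommands `har`, `iam`, `compare`,
`simulate`; exit codes 0 converged / 2 cycle limit / 3 input error).

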