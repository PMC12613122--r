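---
title: "Hole-electron descriptors and small-data QSPR for singlet-oxygen quantum yields"
author: "phidelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hole-electron descriptors and small-data QSPR for singlet-oxygen quantum yields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phidelta)
```

# The problem

Photodynamic therapy kills tumor tissue with reactive oxygen species that a
light-activated photosensitizer generates in situ; for type-II
photosensitizers the key figure of merit is the singlet-oxygen quantum yield
$\Phi_\Delta \in (0, 1]$, the fraction of absorbed photons that end up
producing $^1\mathrm{O}_2$. Hexacoordinate transition-metal complexes (Ru,
Ir, Re, Os, ...) are attractive photosensitizers because heavy-atom
spin-orbit coupling makes their $S_1 \to T_1$ intersystem crossing
efficient, but measured $\Phi_\Delta$ values are scattered across solvents,
irradiation wavelengths and ligand designs, and datasets are small (on the
order of $10^2$ measurements). `phidelta` implements, end to end, a
descriptor engine and a small-data modeling protocol for predicting
$\Phi_\Delta$ of such complexes from excited-state electronic structure,
molecular structure, metal identity and measurement conditions.

The package deliberately stops short of electronic-structure theory itself:
it consumes the *outputs* of TD-DFT calculations (orbitals, configuration
coefficients, energies, transition dipoles, a spin-orbit coupling matrix
element) through a versioned JSON "excitation bundle" or a Molden file, and
everything downstream of that interface is computed here.

# Hole-electron analysis

An excited state from linear-response TD-DFT is a combination of singly
excited configurations $i \to a$ with coefficients $w_i^a$ and (outside the
Tamm-Dancoff approximation) de-excited configurations with coefficients
$w_i^{\prime a}$. Where the excitation removes charge (the *hole*) and
where it deposits it (the *electron*) is captured by two densities, each a
local part plus a cross part:

$$\rho^{hole} = \sum_{i\to a} (w_i^a)^2 \phi_i^2
  + \sum_{i\to a}\sum_{j \ne i \to a} w_i^a w_j^a \phi_i \phi_j
  \;-\; (\text{the same two terms in } w'),$$

$$\rho^{ele} = \sum_{i\to a} (w_i^a)^2 \phi_a^2
  + \sum_{i\to a}\sum_{i \to b \ne a} w_i^a w_i^b \phi_a \phi_b
  \;-\; (\text{the same two terms in } w').$$

The hole cross terms couple configurations that share the *virtual*
orbital; the electron cross terms couple configurations that share the
*occupied* orbital, iterated as ordered pairs. With orthonormal orbitals
both densities integrate to $\sum w^2 - \sum w'^2$; the cross terms
integrate to zero. Pointwise negativity is allowed (the definitions permit
it for full-TD inputs); only the integrals are constrained, and the moment
code flags any state whose density is negative on more than 5% of the
total absolute weight.

From the densities the package computes the standard scalar indices, with
all spatial quantities reported in Angstrom:

* $S_r = \int \rho^{hole}\rho^{ele}\,dr$ — hole-electron overlap;
* $D$ — distance between the two centroids;
* $\sigma_\lambda^s = \sqrt{\int (\lambda - \Gamma_s)^2 \rho_s\,dr}$ —
  per-axis spreads, $\Delta\sigma = |\sigma^{ele}| - |\sigma^{hole}|$;
* $H_\lambda = (\sigma^{ele}_\lambda + \sigma^{hole}_\lambda)/2$ and
  $H_{CT} = |\mathbf{H}\cdot \mathbf{u}_{CT}|$ — mean spread, and mean
  spread along the charge-transfer direction;
* $H = (|\sigma^{ele}| + |\sigma^{hole}|)/2$, $t = D - H_{CT}$ — overall
  width and net separation;
* $HDI, EDI = 100\int \rho^2\,dr$ — delocalization (uniformity) indices.

Two conventions deserve comment, both exposed as explicit options with the
choice recorded in the output:

* **$H_{CT}$ as a projection, and its coordinate frame.** The defining
  formula is sometimes typeset with a vector product,
  $|\mathbf{H} \times \mathbf{u}_{CT}|$, but the quantity it names is the
  *average spread in the CT direction*, which is the projection
  $|\mathbf{H}\cdot\mathbf{u}_{CT}|$; the package defaults to the dot
  product and keeps the cross-product variant behind
  `hct_variant = "cross"` for audits. A subtler point: the per-axis
  spreads $\sigma_\lambda$ are coordinate-frame quantities, so the
  conventional per-axis form of $H_{CT}$ — and therefore $t$ — changes
  when the molecule is rigidly rotated (it is exact only under
  translation). Descriptor values therefore depend on the orientation the
  upstream calculation used, which is also true of the established
  implementations of these indices. Where frame independence matters the
  package provides `hct_variant = "covariance"`, which computes the true
  spread along the CT direction from the full second-moment matrices,
  $(\sqrt{u^T\Sigma^{ele}u} + \sqrt{u^T\Sigma^{hole}u})/2$; the
  rigid-motion invariance tests assert $D$, $\Delta\sigma$, $H$, $S_r$,
  $HDI$, $EDI$ under the defaults and $H_{CT}$, $t$ under this form. When
  the centroids coincide the CT direction is undefined; $H_{CT}$ is then
  defined as 0 and the record flagged.
* **"as-printed" vs. "compat" overlap.** $S_r$, $HDI$ and $EDI$ are often
  defined with square roots ($\int\sqrt{\rho^{hole}\rho^{ele}}\,dr$, which
  is 1 for identical normalized densities). The default `"as-printed"`
  mode uses the plain products above; `"compat"` applies the square-root
  forms. Both are regression-tested and the mode travels with every
  record, because the two are *not* interchangeable numerically.

The MLCT fraction has no universal formula; the package uses an
independent-fragment product — (hole share on the metal fragment) x
(electron share on the ligand fragments), with Becke fuzzy-atom population
shares — and records that definition in its output. It is a documented
stand-in, not a claim about what any particular upstream code computes.

## Quadrature

Gaussian densities peak sharply near nuclei, so the default molecular grid
is atom-centered: Gauss-Chebyshev (second kind) radial nodes under the
Becke mapping $r = r_m(1+x)/(1-x)$, a spherical product angular rule
(Gauss-Legendre in $\cos\theta$ times a uniform azimuthal rule — chosen
over tabulated Lebedev rules because it reaches arbitrary order from closed
forms with no hard-coded coefficient tables), and Becke fuzzy-Voronoi
partition weights (three iterations of the $\tfrac32\mu - \tfrac12\mu^3$
switching polynomial, equal atomic radii). Five resolution levels are
exposed; the default level 3 (45 radial shells x 200 angular points per
atom) integrates valence-like Gaussian densities to well below $10^{-3}$
relative error, which is the package's default integral tolerance. A
rectilinear uniform grid is provided for Gaussian-cube export and serves as
the brute-force reference integrator in the test suite.

# The descriptor table

Each complex contributes 73 descriptors in four blocks:

* **Quantum-chemistry (40):** the twelve per-state indices ($S_r$, $D$,
  $\Delta\sigma$, $H_{CT}$, $H$, $t$, $HDI$, $EDI$, excitation energy,
  MLCT fraction, transition electric/magnetic dipole magnitudes) for $S_1$
  and $T_1$, their differences (D-block, $S$ value minus $T$ value), plus
  the $S_1$-$T_1$ spin-orbit coupling (cm$^{-1}$, parsed from upstream
  relativistic output, never computed here), the $S_1$ absorption
  wavelength $\lambda = 1239.841984/E(\mathrm{eV})$ nm, and the length- and
  velocity-gauge oscillator strengths $f_1 = \tfrac23 E |\mu_{len}|^2$,
  $f_2 = \tfrac23 |\mu_{vel}|^2 / E$ (atomic units).
* **Structure (24):** charges (complex cation `nc`, ligands `lc`,
  metal-bound donor atoms `cc`), atom count, molecular mass, and 19
  functional-group/ring/bond counts from an annotated connection table.
  Matching applies a containment hierarchy — each carbonyl is counted once
  as the largest group it belongs to (amide > ester > aldehyde > plain
  carbonyl), BODIPY cores subsume their pyrrole rings — while the raw ring
  (`n-r5`, `n-r6`) and multiple-bond counts are taken on the whole graph.
  Rings come from a smallest-set-of-smallest-rings perception (per-edge
  shortest cycles, reduced to an independent basis over GF(2)); named
  aromatic rings (phenyl, pyridine, pyrazine, pyrrole) are
  composition-matched on those smallest rings and require ring
  unsaturation (at least two ring-internal double bonds, or
  aromatic-flagged bonds). Fused-ring conventions that the field leaves
  ambiguous — e.g. whether a phenanthroline's central rings count as
  pyridines — are fixed by these rules and exercised in the test fixtures.
* **Metal-centered (6):** center count, period, metal charge, and the
  outermost s/d/f electron counts of the *free neutral atom* (e.g. Ru,
  [Kr]4d$^7$5s$^1$: `cs` = 1, `cd` = 7, `cf` = 0), from a bundled table
  that encodes the anomalous ground states (Cr, Cu, Nb, Mo, Ru, Rh, Pd,
  Ag, Pt, Au) rather than an Aufbau heuristic.
* **Condition (3):** static and infinite-frequency dielectric constants of
  the solvent from a bundled, citable table of standard continuum-solvation
  values, plus the irradiation wavelength in nm. (One descriptor-glossary
  row in circulation describes `wl` as an electron count — an evident
  copy-paste slip; `wl` here is the irradiation wavelength.)

Preprocessing applies two rules before modeling: measurements with
$\Phi_\Delta < 0.01$ are dropped, and a complex whose yields differ
excessively across irradiation wavelengths alone is dropped as a group.
"Excessively" is not quantified in the sources this protocol descends
from; the package uses a configurable max/min ratio with default 2.0 and
logs every exclusion with the rule that fired.

# The modeling protocol

Descriptors are min-max normalized with training-set statistics only
($x \mapsto (x - x_{min})/(x_{max} - x_{min})$; SOC is log10-transformed
first, with a $10^{-3}$ cm$^{-1}$ floor so zero-SOC toy inputs stay
finite); test rows are transformed with the training statistics and never
clipped. The dataset splits 90:10 (a 136-row table gives 122/14), and
leave-one-out $Q^2$ on the training set measures stability, with the
normalizer refit inside every fold so the left-out point never leaks into
the scaling.

Six single-model families are supported — SVR (`e1071`), kernel ridge
(closed form $(K+\alpha I)^{-1} y$, RBF kernel), Gaussian-process
regression (`kernlab`; its implementation requires the noise variance to
exceed $10^{-3}$, so smaller sampled values are floored there), XGBoost,
random forest (`ranger`) and a weighted Minkowski k-NN. Hyperparameters are
tuned by a seeded random search over standard small-data ranges (SVR
$C \in [10^{-2}, 10^3]$ log, $\varepsilon \in [10^{-4}, 10^{-1}]$ log,
kernel in {RBF, linear, poly}; KRR $\alpha \in [10^{-6}, 10]$,
$\gamma \in [10^{-4}, 10^2]$ log; GPR noise $\in [10^{-8}, 10^{-1}]$,
length scale $\in [10^{-2}, 10^2]$ log; XGBoost depth 2-8, learning rate
$[10^{-3}, 0.3]$ log, 50-500 rounds, subsample/colsample $[0.5, 1]$;
random forest 50-500 trees, depth 2-12, feature fraction $[0.2, 1]$; k-NN
$k \in [1, 15]$, uniform/distance weights, $p \in \{1, 2\}$), maximizing
5-fold cross-validated $R^2$ by default (leave-one-out is switchable but
too costly inside a search loop for the tree families). Random search was
chosen as the optimizer because it is simple, seeded-deterministic, and
statistically adequate at these budgets; the search space, budget and seed
are all part of the model specification, and identical specifications
reproduce identical models bit for bit.

Descriptor filtering follows the protocol's two-stage design: train on all
descriptors, rank by Shapley attribution, then retrain on the top-k subsets
for $k \in \{30, 35, 40, 45, 50\}$ and report training $R^2$, test $R^2$
and LOO $Q^2$ per size. No single printed rule reproduces every published
size choice, so the package's default selection criterion is the highest
LOO $Q^2$ with ties broken toward fewer descriptors, and the criterion is a
documented, switchable knob. A fitted model passes the QSPR gate when
cross-validated $Q^2 \ge 0.6$ *and* external-test $R^2 \ge 0.6$.

Attribution backends: XGBoost models use the exact tree-path attribution
built into the booster; all other families use a permutation-sampling
Shapley estimator (random feature orderings; features switched one at a
time from a background row to the explained row, crediting the output
change to the switched feature). The estimator is seeded and its
permutation count is a parameter; ranking stability under it is part of
the test suite.

## Hybrid models

The **delta-learning model** stacks a base regressor (default SVR) with one
or more delta layers (default KRR) fitted to the previous stage's training
residuals; the prediction is the base output plus all corrections. With an
interpolating delta layer the training residuals vanish by construction —
the test suite asserts this limit, and that adding a delta layer never
increases training MSE.

The **mixture-of-experts** fits each expert independently and predicts a
global convex combination $\sum_k w_k \hat y_k$. The weight vector is
chosen by seeded search over the probability simplex; the candidate pool
always contains the unit vectors, so the mixture can never do worse than
its best single expert on the weight-fitting set. Weights are scored
against out-of-fold cross-validated expert predictions by default: scoring
against raw training fits is available (`weight_on = "fit"`), but it lets
whichever expert overfits hardest absorb all the weight, which defeats the
ensemble's purpose. Expert weights are global; input-dependent gating is
out of scope.

# Synthetic data

Real inputs require TD-DFT runs, so the package ships two generators that
make every stage testable offline.

`gaussian_excitation_fixture()` builds a one-configuration toy excitation
between two s-type Gaussians with known closed forms: per-axis spread
$\sigma = 1/(2\sqrt\alpha)$, centroid distance equal to the chosen
separation, and Gaussian self-overlap values for the delocalization
integrals. Every expected value carries its provenance (closed form), so
the engine is always checked against independent arithmetic, not against
itself.

`synthetic_qspr_table()` emulates the *shape* of the modeling problem: 136
rows by default, the full 73-column production manifest (so pipeline tests
cannot drift from production paths), block-appropriate marginal
distributions (overlap indices in $[0,1]$, counts as small integers, SOC
log-normal around $10^2$ cm$^{-1}$), and a target that is a stated smooth
function of five signal descriptors spanning the blocks
($S$-ee, $T$-ee, soc, mw, eps) plus a mild $\sin$ nonlinearity and
Gaussian noise of 5% of the signal SD. The signal is planted on the
modeling scale (SOC enters through its logarithm, mirroring the
normalizer), and the raw signal is squashed into $(0,1]$ by a gentle
logistic map, $\Phi = \mathrm{logis}(0.6\,(\text{raw} + \text{noise}))$ —
the gain keeps targets spread over the mid-range of $(0,1)$ the way
measured quantum yields are, instead of piling them into the saturated
tails. Generation is byte-identical under a fixed seed.

What passing on these tables shows — and what it does not: the generators
exercise schema, determinism, information barriers, and recovery of a
known planted signal. They do not mimic the correlation structure of real
transition-metal-complex descriptors, the heteroscedastic noise of
literature $\Phi_\Delta$ assays, or inter-laboratory bias; conclusions
about real-data accuracy require real DFT-derived tables.

# Numerical choices and problem sizes

* Integral tolerance $10^{-3}$ relative at grid level 3; the oracle suite
  checks closed forms at that tolerance and grid-refinement convergence
  across levels.
* Kernel ridge falls back to a $10^{-8}$ diagonal bump if the kernel
  matrix is numerically singular; the event is logged in the fit.
* Degenerate normalization columns (max = min) map to the constant 0 with
  a warning rather than NaN.
* The test suite runs entirely on generated data at deliberately modest
  sizes — toy excitation systems of 2-6 Gaussians on level 2-3 grids, one
  $96^3$ brute-force reference grid, QSPR tables of 15-136 rows, search
  budgets of 8-16 trials, 10-seed stochastic repetitions — sizes chosen so
  the whole suite gives sharp answers in minutes on one core while leaving
  clear headroom above every asserted bound.

# Known limitations

* The engine consumes Cartesian s/p/d Gaussians from Molden files;
  spherical-harmonic (5D) exports and f shells are rejected rather than
  mis-read.
* Effective-core-potential information beyond what the orbital file
  carries is not modeled; descriptor values for heavy metals inherit
  whatever valence representation the upstream calculation used.
* MLCT uses the documented fragment-product definition; other codes'
  MLCT numbers need not coincide.
* No attempt is made to reproduce published per-dataset $R^2$ tables:
  those depend on the authors' DFT-derived descriptor tables and
  unreported split seeds. The package's claims are the property-based ones
  its tests compute.
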