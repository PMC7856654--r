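---
title: "FEM-based EEG/MEG sensitivity mapping on synthetic sphere phantoms"
author: "sensmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FEM-based EEG/MEG sensitivity mapping on synthetic sphere phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

EEG electrodes measure the electric potential and MEG coils the magnetic
field generated by the same dipolar current sources in the brain, but the two
modalities see those sources very differently: the magnetic field of a
radially oriented dipole vanishes outside a spherically symmetric conductor,
and both signals attenuate with source depth at different rates, with the
highly conductive cerebrospinal fluid (CSF) shunting scalp potentials.
Per-source signal-to-noise-ratio (SNR) maps make this sensitivity structure
explicit and help decide which modality — or combination — best serves an
experiment or diagnostic question.

`sensmap` implements the full chain needed to compute such maps: a
volume-conductor head model, finite-element (FEM) forward solutions for both
modalities, dipole source spaces with depth and orientation covariates, and
the SNR statistics. Everything runs on synthetic multi-shell sphere phantoms
so that each stage can be validated against quasi-analytic solutions.

# Volume conduction and the FEM forward problem

Under the quasi-static approximation, the electric potential $u$ obeys
$\nabla\cdot(\sigma\nabla u) = \nabla\cdot j^p$ in the head $\Omega$ with an
insulating boundary, where $\sigma$ is the (possibly tensorial) conductivity
and $j^p$ the primary current of a point dipole with moment $q$ at $r_0$.

`assembleStiffness()` discretizes this with first-order Lagrangian (P1)
basis functions on a labeled tetrahedral mesh:
$K_{ij} = \sum_E |E|\, \nabla\varphi_i \cdot \sigma_E \nabla\varphi_j$,
with element-wise constant gradients and tensors. $K$ is symmetric positive
semi-definite; its nullspace is the constant vector (potentials are defined
up to a reference).

The dipole enters through the *partial integration* load vector
(`partialIntegrationRhs()`): on the host element of the dipole,
$f_i = q\cdot\nabla\varphi_i$, zero elsewhere. The four nonzeros sum to zero
because the shape-function gradients do, so the right-hand side is always
compatible with the pure-Neumann operator. A dipole on a shared face is
assigned to the lowest element index; cortical dipoles are placed at element
centroids, so ties are rare by construction.

## Transfer matrices and the linear solver

Computing the forward solution for hundreds of sensors and thousands of
dipoles is reorganized by the transfer-matrix approach
(`computeTransferMatrix()`): for each sensor row $r_k$ (a point-electrode
selector, or a MEG integration row) one adjoint system $K t_k = r_k^T$ is
solved once; every dipole then costs a sparse four-element dot product
$t_k\cdot f$ instead of a full solve.

The singular constant mode is handled by projecting right-hand sides to zero
mean and grounding one node during factorization; solutions are re-centered
to zero mean. EEG leadfields are additionally average-referenced across
electrodes, which makes all reported values reference-independent.

The default solver is a sparse Cholesky factorization of the grounded system
(via the Matrix package): for the problem sizes used here (5,000–200,000
elements, up to a few hundred adjoint solves per study) one factorization
amortized over all sensors is both faster and more accurate than an
iterative method, and the residual of every transfer row is checked against
the configured tolerance (default relative residual `1e-8`). A
Jacobi-preconditioned conjugate-gradient solver operating in the zero-mean
subspace is available (`solver = list(method = "cg")`) and agrees with the
direct path to solver tolerance in the test suite.

## The MEG forward model

The magnetic reading of a coil at $r$ with unit axis $o$ is split into the
primary (infinite-medium) part, evaluated in closed form
(`primaryBField()`), and the secondary field of the volume currents,

$$B_{sec}(r) = -\frac{\mu_0}{4\pi}\sum_E \sigma_E \nabla u_E \times
  \int_E \frac{r - x}{|r - x|^3}\,dx,$$

assembled per coil into a dense row over mesh nodes
(`megIntegrationRows()`). The element integrals use a fixed 4-point
quadrature rule (degree 2); a guard rejects coils closer to the mesh than
one element diameter, where that rule would degrade.

Two sensor-axis conventions matter in spherical geometry:

* **axial (radial) axes** — the study convention, matching axial
  gradiometers treated as point sensors. The volume currents contribute
  exactly zero to a radial reading in a sphere, so radial-dipole columns are
  numerically null (measured ratio of a radial to a co-located tangential
  column norm: a few times $10^{-4}$ at the meshes used).
* **tilted axes** (`coilTilt`) — mix in a tangential component, so the
  secondary field contributes at full strength. The Sarvas comparison in the
  validation suite uses 45° tilted axes precisely so the volume-current code
  path is actually exercised (tangential-dipole RDM ≈ 0.06–0.08 at a 36k
  element mesh).

A known limitation: with tilted axes the *radial-dipole* field is a
near-total cancellation of the primary term by the secondary one, and its
residual is dominated by the P1 gradient error in the elements next to the
source. That residual (5–30% of a tangential column) does not shrink
monotonically under uniform refinement; resolving it would need adaptive
refinement or a regularized source model near the dipole, both out of scope.
The radial-null property is therefore quantified under the axial convention,
where it is a property of the physics rather than of the cancellation.

# Analytic oracles

`eegSpherePotential()` evaluates the multilayer concentric-sphere solution
as a Legendre series. Per harmonic degree $n$ the radial problem is a small
linear system over per-layer coefficients $A_j r^n + B_j r^{-(n+1)}$; basis
functions are rescaled to their layer interfaces so matrix entries stay
O(1) up to degree 200 (naive powers overflow). Truncation is adaptive:
summation stops when 10 further terms change no electrode value by more than
`1e-8` relative. Dipoles above 0.95 eccentricity are rejected rather than
silently mis-summed. The series is validated in the test suite against the
classical central-dipole closed form and an independent per-degree RK4
shooting oracle.

`megSphereField()` is the Sarvas closed form for the total field outside a
spherically symmetric conductor; it is checked against a Geselowitz
surface-integral oracle (primary field plus the boundary integral of the
series potential) and reproduces the radial-source null exactly.

Forward accuracy is summarized by the usual pair of error measures
(`rdmMag()`): the relative difference measure
$\mathrm{RDM} = \lVert b/\lVert b\rVert - b^\*/\lVert b^\*\rVert\rVert$
(topography) and the magnitude ratio
$\mathrm{MAG} = \lVert b\rVert / \lVert b^\*\rVert$. On the default 4-shell
study mesh (~59,000 elements, 6 mm target edge) the EEG solution stays
within RDM ≤ 0.09 and $|\ln \mathrm{MAG}|$ ≤ 0.05 of the series for radial
and tangential dipoles up to 0.8 eccentricity.

# The synthetic head model

The generator replaces subject-specific MRI-derived meshes with layered
sphere phantoms; every default below is the study condition used by the
tests and the acceptance script.

* **Geometry** (`buildLayeredSphereMesh()`): shells at 78 / 80 / 86 / 92 mm
  (brain / CSF / skull / scalp outer radii — standard 4-layer EEG phantom
  radii); the 6-compartment variant splits the brain shell at 60 mm
  (white / gray) and the skull shell at 83 mm (spongiosa / compacta). The
  mesh is an icosphere-shell extrusion: prisms between nested icospheres,
  split into tetrahedra with a sorted-index diagonal rule so the mesh is
  conforming, plus a tetrahedral core. Every compartment interface
  coincides with a layer, which is what makes thin shells (the 2 mm CSF)
  resolvable at all; the angular subdivision matches the target edge length
  at mid-radius, giving ~59k elements at the 6 mm default.
* **Conductivities** (`assignConductivities()`, S/m): brain 0.33, CSF 1.79,
  skull 0.01, scalp 0.43; in the 6-compartment variant white 0.14, gray
  0.33, spongiosa 0.025, compacta 0.008. Variants with fewer compartments
  reuse the same mesh and only collapse labels (CSF into brain for 3CI),
  so model comparisons isolate the conductivity effect from geometry.
* **Anisotropy**: white-matter tensors are built from a synthetic radially
  oriented fiber field with a 10:1 longitudinal:transversal ratio and the
  "fit the mean eigenvalue" constraint — the mean of the three eigenvalues
  equals the 0.14 S/m isotropic reference. This keeps the orientation-
  averaged conductivity fixed while introducing directionality.
* **Sensors** (`placeSensors()`): Fibonacci-lattice electrodes snapped to
  scalp mesh nodes (point-electrode convention; the EEG restriction matrix
  is then a 0/1 selector) and coils on a sphere 20 mm outside the scalp
  with radial axes; defaults 71 electrodes / 271 coils.
* **Cortex** (`synthCortexSurface()`): a radially perturbed icosphere
  $r(\hat n) = \rho_0 + A f(\hat n)$ with $\rho_0 = 60$ mm, $A = 8$ mm and a
  phase-modulated sinusoidal fold field pushed towards a square wave
  (`tanh`), frequency 6 folds across the diameter (≈20 mm sulcal
  wavelength). Normals are computed **analytically** from the differentiable
  fold field, so the gyral-crown-to-sulcal-wall orientation range is not
  capped by mesh resolution; with the defaults about 30% of normals tilt
  beyond 60° and the central "tangential" angle bin is well populated.
  Because the surface is a radial graph, tilts cannot exceed 90°: the
  phantom has no overhanging sulci, so the last two angle bins (108–180°)
  stay empty — flipped-orientation antisymmetry is tested directly instead.
* **Subcortical regions** (`synthSubcorticalRegions()`): nine small
  tetrahedral balls named after the standard deep structures (cerebellum,
  thalamus, caudate, putamen, pallidum, hippocampus, amygdala, accumbens
  area, ventral diencephalon) at anatomically inspired positions strictly
  inside the brain shell; their mesh nodes carry Cartesian-triplet dipoles
  (~1,200 at default resolution), reflecting that deep nuclei have no
  preferred net orientation.
* **Noise** (`synthNoiseBaseline()`): zero-mean white Gaussian baseline
  samples, 10 µV² per EEG channel and 10⁴ fT² per MEG channel — the orders
  of magnitude of pretrigger baselines of averaged evoked recordings.
  Real baselines are colored and spatially correlated; the phantom noise is
  deliberately white, so absolute SNR levels are calibrated rather than
  reproduced and only directional/structural findings are meaningful.

# Source covariates and SNR mapping

Cortical dipoles sit at the centroid of the gray-matter element closest to
each cortex vertex and take the vertex normal as orientation
(`corticalDipolesFromSurface()`); several vertices may share a centroid and
then share a group id, each keeping its own SNR value. Depth is the
Euclidean distance to the closest inner-skull surface *vertex* and the angle
is measured against that vertex's outward normal (`sourceDepths()`,
`sourceAngles()`) — nearest-vertex rather than point-to-triangle, so the
inner-skull sampling (2 mm default) bounds the metric accuracy. Depths and
angles are clustered into five equal-width bins (depth range 0–50 mm, angle
0–180°), right-open except the last bin; five-number summaries use
linear-interpolation (type 7) quartiles.

The SNR of dipole $i$ with leadfield column $b_{\cdot i}$ (µV/nAm or
fT/nAm), source amplitude $a$ (default 10 nAm) and per-channel noise
variances $s_k^2$ is

$$\mathrm{SNR}_i = 10\log_{10}\Bigl(\frac{a^2}{N}\sum_{k=1}^N
  \frac{b_{ki}^2}{s_k^2}\Bigr),$$

and the differential map is $D_i = \mathrm{SNR}^{MEG}_i -
\mathrm{SNR}^{EEG}_i$. A dipole with an exactly zero column maps to a
$-\infty$ sentinel that is kept in maps but excluded from summaries.

For subcortical triplets, `svdProject()` decomposes the $n\times 3$ MEG
leadfield $L = USV^T$; the third column of $V$ (smallest singular value) is
the quasi-radial direction the MEG is nearly blind to, and both modalities
are projected onto $V$'s columns. The SVD is taken on the raw, unwhitened
MEG leadfield; a noise-whitened variant exists behind the `whiten` argument
because orthogonal-projection energy conservation only holds exactly in the
whitened metric when noise is heterogeneous. $V$ columns are sign-fixed
(largest-magnitude entry positive) and component SNRs apply the amplitude to
the unit-norm projected orientation, matching the cortical convention.

# The study pipeline and its findings

`runSensitivityStudy()` chains everything with one global seed expanded
deterministically into per-stage seeds (`deriveSeed()`), so adding a stage
never perturbs earlier stages, and embeds a canonical configuration hash in
every artifact; reruns are byte-identical. The validation suite runs the
study at 32 electrodes / 64 coils with ~2,600 cortical and ~1,200
subcortical dipoles on the 59k-element mesh (about a minute of compute) and
checks the directional structure of the results:

* superficial cortical sources (depth < 15 mm) have higher median EEG SNR
  under 3CI than under 4CI — omitting the CSF overestimates EEG sensitivity;
* the differential SNR median is highest in the central (tangential) angle
  bin and lowest in the radial bins;
* along depth, the MEG advantage peaks at shallow-but-not-superficial depths
  (the very first bin is dominated by radially oriented gyral crowns, where
  MEG is weak) and falls off monotonically beyond the peak, with the deepest
  occupied bin favoring EEG. The depth comparison is therefore evaluated from
  the peak bin onward rather than from bin one;
* subcortical radial components: EEG median SNR far exceeds MEG's;
* subcortical tangential components: EEG and MEG interquartile ranges
  overlap — deep sources with sufficient tangential orientation are visible
  to MEG.

These are structural claims about map shape, not absolute levels: with
synthetic white noise and sphere geometry the dB values themselves are not
comparable to any measured dataset.

# Numerical choices and degenerate inputs

* Mesh generation refuses edge lengths exceeding the innermost shell radius
  and non-increasing radii; every generated tetrahedron is checked for
  positive volume.
* Stiffness assembly errors on zero-volume elements by index; the assembled
  matrix is symmetrized exactly and its row sums vanish to rounding.
* `locateElements()` uses barycentric membership with a `1e-9` slack and a
  lowest-index tie-break.
* Degenerate binning ranges (all values equal) expand by a unit rather than
  erroring; values outside an explicit range are excluded from counts.
* All I/O is plain text: Gmsh MSH v2.2 and legacy VTK for meshes, NOFF for
  surfaces with normals, VTK PolyData for scalar surface maps, TSV for
  sensors/dipoles, and full-precision (`%.17g`) TSV with JSON sidecars for
  leadfields and recordings, giving bit-exact round trips. Readers reject
  truncated files.

# Known limitations

* The phantom cortex cannot produce source angles beyond 90°, and its
  spherical symmetry means "depth" and "eccentricity" are interchangeable —
  real geometry decouples them.
* The MEG radial-null cancellation with non-radial sensor axes is limited by
  the P1 near-source gradient error (see above).
* Point sensors only: no electrode surface model, no realistic pickup-coil
  integration or gradiometer baselines.
* White uncorrelated noise only; no noise covariance, hence no whitened SNR
  beyond the per-channel variances of the defining formula.
* No source reconstruction: the package maps sensitivity, it does not
  invert.
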