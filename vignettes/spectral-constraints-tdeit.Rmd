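---
title: "Multi-frequency time-difference EIT with spectral constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-frequency time-difference EIT with spectral constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sceit)
```

## The problem

Electrical impedance tomography (EIT) reconstructs the electrical
conductivity inside a body from currents injected and voltages measured at
surface electrodes. Time-difference EIT (tdEIT) images the *change* in
conductivity between a reference (background) frame and a later
(foreground) frame; referencing cancels much of the modelling and
instrumentation error and is what clinical EIT systems run in practice.

The catch is data volume. A 16-electrode system under the opposite-drive,
adjacent-measurement protocol yields K = 192 voltage differences per frame
per frequency, against hundreds of unknown per-element conductivities —
and measurements at different frequencies cannot simply be pooled, because
tissue conductivity itself changes with frequency: every added frequency
adds as many unknowns as it adds equations.

`sceit` implements a reconstruction that breaks this deadlock with a
**tissue volume-fraction model**. Each mesh element n is described by
fractions $f_{nj} \in [0,1]$, $\sum_j f_{nj} = 1$, of $T$ candidate
tissues whose conductivity spectra $\varepsilon^{t_j}(\omega_i)$ are known
(e.g. measured ex vivo). The element conductivity at frequency
$\omega_i$ is the weighted sum

$$\sigma_n(\omega_i) = \sum_{j=1}^{T} f_{nj}\,\varepsilon^{t_j}(\omega_i),
\qquad \boldsymbol\sigma(\omega_i) = A(\omega_i)\,F,$$

with $A(\omega_i)$ the sparse $N \times TN$ block matrix carrying the
spectra. The fractions do not depend on frequency, so the linearised
per-frequency systems $J(\omega_i) A(\omega_i)\,\Delta F =
\Delta\upsilon(\omega_i)$ can be stacked over all M frequencies into one
overdetermined system for the single unknown $\Delta F$ — the
**spectral-constraints (SC)** reconstruction. The baseline it is compared
against is **damped least squares (DLS)**: single-frequency Tikhonov with
$R = \mathrm{diag}(J^\top J)$, the stable workhorse of clinical tdEIT.

## The SC iteration

`sc_reconstruct()` runs a small fixed number of damped Gauss–Newton steps
(default 2):

1. Start from the homogeneous reference, $F^0$ = pure background tissue.
2. Linearise: compute $J(\omega_i)$ at
   $\sigma^{k-1}(\omega_i) = A(\omega_i)F^{k-1}$ on the inverse mesh and
   stack $S = [J(\omega_i)A(\omega_i)]_i$. The unit-sum constraint is
   folded in by the substitution $f_{n1} = 1 - \sum_{j\ge2} f_{nj}$, which
   turns each element's columns into contrast columns (tissue j minus
   tissue 1) and gives the reduced matrix $S'$ actually inverted.
3. Solve the standard-form Tikhonov problem
   $\Delta F_{T-1} = (S'^\top S' + \lambda R)^{-1} S'^\top \Delta\upsilon$
   with $R = \mathrm{diag}(S'^\top S')$.
4. Clamp: add the update to $F^{k-1}$, clip the non-reference fractions to
   $[0,1]$, rescale them proportionally if their element sum exceeds one,
   and set the reference row to one minus that sum. The clamp is the
   second pillar of SC: it bounds every element's conductivity inside the
   span of the tissue spectra and deletes the sign-flipped half of the
   background noise, which is why SC images are visibly cleaner than DLS
   even without iteration.
5. Update the residual and repeat.

Two choices in this loop were genuinely open and are resolved as follows.

**Residual update.** The loop's "update $\Delta\upsilon$" step is
implemented as the standard difference-imaging Gauss–Newton residual
$$\Delta\upsilon^{(k)} = (\upsilon^{fg}_{meas} - \upsilon^{bg}_{meas})
 - \big(\upsilon_{sim}(\sigma^{k-1}) - \upsilon_{sim}(\sigma^{0})\big),$$
with both simulations on the inverse mesh. Referencing the simulated
difference (rather than subtracting a raw simulated foreground from the
measured one) keeps the forward/inverse mesh discretisation mismatch out
of the data term, which is the whole point of difference imaging; it is
also what makes the second step well-posed enough to help. The same update
drives the iterated DLS variant, whose background conductivity is floored
at a small positive value if an update overshoots.

**Regularisation weight.** $\lambda$ is chosen by the L-curve criterion —
the grid value maximising the discrete curvature of the
(log residual norm, log solution seminorm) curve over 30 log-spaced
candidates spanning $10^{-8}$ to $1$ on the column-equilibrated scale
(with $R = \mathrm{diag}(S'^\top S')$ the equilibrated normal matrix has
unit diagonal, so the grid needs no further scaling). The weight is
re-selected at every iteration, with one safeguard: after the first step
the residual is increasingly noise-dominated and the discrete L-curve can
lose its corner entirely, occasionally electing a near-zero weight that
blows up the step for *both* algorithms; damping is therefore constrained
to be non-decreasing across the limited iterations. Selection was checked
against an exhaustive true-error scan on Shaw's classic ill-posed test
problem; note the L-curve is known to under-smooth very smooth solutions
(e.g. Phillips-type problems), a limitation inherited from the criterion
itself.

## Forward model and meshes

The forward solver uses first-order triangular finite elements with
point (gap) electrodes — nodal current sources, no contact impedance — and
the potential grounded at the central node. The shape-function order and
electrode model are not dictated by the reconstruction; point electrodes
reproduce the study's structure at 2-D simulation scale and a complete
electrode model is a natural extension hook. The solver was verified
against the closed-form disk potential for boundary point sources
($u = \tfrac{I}{\pi\sigma}\ln|x-b|/|x-a|$), against reciprocity, and
against its scaling laws; the Jacobian (adjoint/compensation method)
against central finite differences.

Meshes are deterministic ring triangulations: ring $r$ of $R$ carries
$8r$ nodes, giving exactly $8R^2$ elements. $(R=10)$ yields the
800-element/441-node forward mesh and $(R=8)$ the 512-element/289-node
inverse mesh of the validation study; distinct meshes for simulation and
reconstruction are enforced at run time (the inverse-crime guard).
Determinism makes every matrix in the pipeline bit-reproducible, at the
price of lower modelling error between the two structured meshes than an
unstructured mesh pair would show — see the caveat below.

## The synthetic validation study

`run_numerical_validation()` reproduces the study design: an elliptical
target (semi-axes 45 × 30 px, set in configuration; the source text's
printed target size is internally inconsistent, so the default was fixed
once at a visually comparable scale) of ischaemic tissue in a normal-brain
background, at radial offsets 0, 60, 120, 180, 240 px along +x (midway
between two electrodes); data at the three tabulated frequencies; white
Gaussian noise at 60 and 80 dB SNR added independently to background and
foreground frames (SNR defined on the RMS of the whole 192-vector frame),
five noise realisations per cell, seeds derived deterministically from one
base seed. Images are scored on the middle-frequency conductivity-change
image for both algorithms (SC's $\Delta F$ is mapped through
$A(\omega_2)$), with:

* **PE** — centroid-distance error of the region of perturbation (RP:
  elements deviating from the image mean by more than half the maximum
  deviation, largest edge-connected cluster), over the mesh diameter;
* **SD** — mean x/y bounding-box extent error of the RP against the true
  ellipse, over the mesh diameter;
* **IN** — background standard deviation over target/background contrast
  (inverse CNR);
* **TE = PE + SD + IN.**

The spectral-error study (`run_spectral_error_study()`) reconstructs with
randomly perturbed spectra (relative spread 1–10%) from data simulated
with the exact spectra, pairing the measurement-noise seeds across error
levels so differences are attributable to the spectral error alone; it
uses one-step SC at 80 dB on the mid-offset target by default. The
three-tissue scenario adds blood (flat 0.7 S/m) and reconstructs on a
288-element inverse mesh so that the stacking condition
$MK \ge (T-1)N$ holds with M = 3.

## Matrix diagnostics

Rank and condition number are computed from the singular values of the
reduced stacked matrix $S'$ (the matrix that is inverted), with the
standard numeric-rank tolerance $\max(\mathrm{dim})\cdot\epsilon\cdot
s_{max}$ and the condition number taken over the above-tolerance
spectrum. At a homogeneous background the per-frequency Jacobians are
exact scalar multiples of one another, so
$\mathrm{rank}(S') = \mathrm{rank}(J(\omega_i)A(\omega_i)) =
\mathrm{rank}(J(\omega_i))$ — stacking adds equations but no independent
ones (on the replicated inverse mesh all three equal 76, with a sharp
singular-value cliff). The *unreduced* stack has rank $T \times 76$,
because reference and contrast columns carry different frequency weight
profiles; the identity belongs to the inverted matrix. Once the first SC
update makes the background uneven, the Jacobians stop being proportional
and the rank of $S'$ grows — the mechanism by which iteration buys SC
extra independent information that single-frequency DLS can never get.

## What the generator does and does not emulate

The synthetic study emulates the geometry, protocol, spectra, noise
levels and mesh sizes of the validation design. It does not emulate
contact impedance, electrode movement, 3-D current spreading,
instrumentation drift, or the modelling error of an unstructured mesh
pair: both meshes here are structured ring triangulations of the ideal
disk, so the discretisation mismatch between simulation and
reconstruction is smaller than a practical setting would produce. All
directional conclusions (SC below DLS on every averaged metric at both
iteration settings; larger gains at two steps; monotone degradation with
spectral error) reproduce robustly. The *sizes* of the averaged percent
reductions are regime-dependent — diagnostic runs at lower SNR give far
larger reductions — and under these low-modelling-error conditions the
IN/SD/TE reductions come out smaller than in a noisier, less idealised
setting; passing tests therefore demonstrate the ordering and the
mechanism, not a universal effect size.

## Numerical choices

* Rank tolerance $\max(\mathrm{dim})\cdot\epsilon\cdot s_{max}$, exposed
  as an argument of `matrix_diagnostics()`.
* Fraction clamp: clip non-reference tissues, proportional rescale on
  overflow, reference row restored — idempotent, always feasible.
* L-curve ties and degenerate inputs: an all-zero data vector returns the
  mid-grid weight with a warning; the selected weight is always a grid
  member, making runs bit-reproducible.
* RP clusters use shared-edge adjacency (not shared-vertex), the stricter
  rule, avoiding diagonal leakage; size ties break by total area then
  lowest index. A constant image has no RP and metric evaluation is
  refused rather than silently scored.
* True-target membership on the inverse mesh is centroid-in-ellipse (the
  meshes differ, so a geometric rule is required).
* Seeds: every stochastic component (per frame role, frequency,
  repetition, spectral-error draw) gets a child seed derived by an
  integer hash from one base seed; results are bit-reproducible.
* Problem sizes used by the shipped studies: 800/512-element meshes,
  5 targets × 2 SNRs × 5 noise seeds for the comparison study and
  5 error levels × 20 paired seeds for the spectral study — large enough
  for stable averages while keeping a full run in the order of a minute.

## Known limitations

* Real-valued conductivity only; no complex admittivity or dispersion
  fitting.
* Point electrodes; no complete electrode model.
* The L-curve criterion inherits its known failure mode on very smooth
  solutions, and after the first Gauss–Newton step its corner can vanish
  (handled by the monotone-damping safeguard).
* Condition numbers of severely rank-deficient EIT systems depend
  strongly on where the singular spectrum is truncated; values are
  comparable across algorithms within this package but not across
  packages with different truncation conventions.
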