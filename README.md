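# sceit — multi-frequency time-difference EIT with spectral constraints

`sceit` is an R toolbox for two-dimensional time-difference electrical
impedance tomography (tdEIT): simulating boundary-voltage data on circular
finite-element phantoms and reconstructing conductivity-change images from
them. Its core is a **spectral-constraints (SC)** reconstruction that pools
measurements from several excitation frequencies into a single inverse
problem, something classical tdEIT cannot do, alongside the standard
single-frequency **damped least-squares (DLS)** baseline it is compared
against. It is aimed at EIT algorithm researchers who want a compact,
fully reproducible simulation-and-evaluation pipeline.

## The model

Tissue conductivity varies with frequency, so multi-frequency voltage sets
normally bring as many new unknowns as new equations. SC removes the
frequency dependence by modelling each mesh element *n* as a mixture of
*T* known tissues with volume fractions *f₍nj₎* ∈ [0, 1], Σⱼ f₍nj₎ = 1:

    σₙ(ωᵢ) = Σⱼ f₍nj₎ · ε^{tⱼ}(ωᵢ)        (σ(ωᵢ) = A(ωᵢ) F)

where ε^{tⱼ}(ωᵢ) are the tissues' known conductivity spectra. The
fractions are frequency-independent, so the linearised systems
J(ωᵢ)A(ωᵢ)ΔF = Δυ(ωᵢ) for all M frequencies stack into one tall system
solved by standard-form Tikhonov regularisation (L-curve-selected λ,
R = diag(S′ᵀS′)) under the box and unit-sum fraction constraints, with an
optional second damped Gauss–Newton step. The constraints bound each
element's conductivity inside the tissue-spectra span — a built-in
artifact suppressor — and, once iteration makes the background uneven,
the per-frequency Jacobians stop being proportional and the stacked
system gains genuinely independent equations (its SVD rank grows), which
single-frequency DLS can never achieve.

The package also ships the evaluation suite used to compare algorithms:
the region of perturbation (RP), position error (PE), shape deformation
(SD), image noise (IN, inverse CNR) and total error (TE = PE + SD + IN),
plus SVD rank/condition diagnostics of the inverted matrices.

## Worked example

Simulate a two-tissue scene — an ischaemic elliptical target 120 px from
the centre of a normal-brain disk — at 60 dB SNR, reconstruct with both
algorithms on a coarser inverse mesh, and score the images:

```r
library(sceit)

scene  <- make_two_tissue_scene(position_index = 2)
frames <- simulate_scene_frames(scene, snr_db = 60, base_seed = 1)

inv_mesh <- build_circular_mesh(300, 16, 512)
print(inv_mesh)
#> EIT disk mesh: 512 elements, 289 nodes, radius 300 px, 16 electrodes

sc  <- sc_reconstruct(frames$bg, frames$fg, scene$spectra, inv_mesh,
                      scene$protocol, num_steps = 2)
print(sc)
#> EIT reconstruction (SC), 2 step(s), lambda = 0.53, 0.53
#>   image: 512 elements x 3 frequency image(s); max |dsigma| = 0.01126 S/m

dls <- dls_reconstruct(frames$fg[, 2] - frames$bg[, 2], inv_mesh,
                       scene$protocol, sigma_ref = 0.155, num_steps = 2)

tgt <- eit_target(scene$target$center, scene$target$semi_axes)
compute_metrics(sc$delta_sigma[, 2], inv_mesh, tgt)
#> PE = 0.0362  SD = 0.1450  IN = 0.1874  TE = 0.3686  (RP: 26 elements)
compute_metrics(drop(dls$delta_sigma), inv_mesh, tgt)
#> PE = 0.0473  SD = 0.1450  IN = 0.2120  TE = 0.4043  (RP: 29 elements)

sapply(sc$iterations, `[[`, "rank")
#> [1]  76 227
mean_relative_contrast(scene$spectra)
#> [1] 24.04958
```

Each metric is an error, so lower is better: here SC beats DLS on
position error and image noise (and hence total error) on the same data.
The rank sequence 76 → 227 shows the second iteration unlocking
independent multi-frequency information. The 24.05% figure is the mean
relative conductivity contrast between the two tissues over the three
frequencies.

Full studies are one call each: `run_numerical_validation()` (5 target
positions × 2 SNR levels × both algorithms × 1–2 steps, with averaged
percent reductions of each metric) and `run_spectral_error_study()`
(reconstruction with randomly perturbed spectra at 1–10% error levels).
A thin command-line driver with `simulate` / `reconstruct` / `evaluate` /
`reproduce` subcommands is installed at `inst/cli/sceit.R`, and tissue
spectra tables ship under `inst/extdata/`. The methods vignette
(`vignettes/spectral-constraints-tdeit.Rmd`) documents the model,
algorithm, and every numerical choice.

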