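# svrsr — slice-to-volume registration and robust super-resolution MRI reconstruction

`svrsr` reconstructs an isotropic 3D volume from stacks of thick,
motion-scattered 2D MR slices — the situation of fetal brain MRI,
where ultrafast sequences freeze motion within each slice but the
head moves between slices, some slices are corrupted outright, and
every slice carries its own intensity scale and smooth bias field.

The method couples four estimators around one forward model
`Y* = M X` (sparse rows of `M` are discretized, rigidly oriented 3D
Gaussian PSFs; FWHM = slice thickness through-plane, 1.2 × voxel size
in-plane):

* **Super-resolution reconstruction** by iterative back-projection of
  the residuals `e_jk = y*_jk − Σ_i m_ijk x_i`, with edge-preserving
  regularization `R(X) = Σ φ((x_{i+d} − x_i)/(δ√|d|))`,
  `φ(t) = 2√(1+t²) − 2`, over the 26-neighborhood.
* **EM robust statistics**: voxel residuals follow a
  Gaussian-inlier/uniform-outlier mixture; posteriors
  `p_jk = G_σ(e)c / (G_σ(e)c + m(1−c))` redescend, so corrupted voxels
  are removed completely. Whole slices are classified by a
  two-Gaussian EM over `(Σ_j p_jk²)/N_k`. A Huber variant
  (`γ = 1.35·median|e|`) is included for comparison.
* **Intensity matching**: per-slice scales
  `s_k = Σ p e^{−b} y ŷ / Σ p (e^{−b} y)²` with `Π s_k = 1`, and
  differential bias fields from weighted Gaussian smoothing
  (σ_B = 12 mm) of `log(y*/ŷ)` with zero mean per slice.
* **Motion correction**: normalized-mutual-information rigid
  registration of stacks to a template and of each slice to the
  evolving volume, interleaved with reconstruction; the
  regularization weight decays from 0.08 δ² to 0.01 δ² across motion
  iterations.

An acquisition simulator reproduces the reference evaluation design
(3 mm slices, 1 mm in-plane, noise σ = 0.025 μ, 12 mm-smooth bias
fields, scales in [0.8, 1.2], displaced and ghost-corrupted outlier
slices, all ground truth recorded), and the evaluation module
implements NRMSE, PSNR, target registration error with the protocol's
exclusion rules, and leave-one-out scoring of real stacks.

## Worked example

```r
library(svrsr)

phantom <- make_phantom(48, 1, seed = 1)            # brain-like truth volume
spec    <- simulation_spec(n_stacks = 3, seed = 7)  # the corruption protocol
sim     <- simulate_acquisition(phantom, spec)
table(sim$truth$labels)
#>     clean corrupted displaced
#>        49         5         6

stacks <- transfer_mask(sim$stacks, phantom)
mc <- motion_correct(stacks,
                     registration_settings(motion_iterations = 3),
                     recon_settings(em_iterations = 5,
                                    em_iterations_final = 10),
                     grid = phantom$grid)

matched <- match_to_reference(mc$volume, phantom, register = FALSE)
round(c(nrmse = nrmse(matched, phantom), psnr = psnr(matched, phantom)), 3)
#>  nrmse   psnr
#>  0.172 19.429

d <- mc$recon$diagnostics
which(d$excluded & sim$truth$labels != "clean")   # outliers caught
#>  [1]  6 10 14 15 25 31 35 46 49 50 54
which(sim$truth$labels != "clean")                # ... which is all of them
#>  [1]  6 10 14 15 25 31 35 46 49 50 54
```

`nrmse` is the RMS intensity error over the head mask divided by the
reference mean (the reference design reports ≈ 0.10-0.14 at comparable
stack counts); `psnr` is `20·log10(MAX/RMSE)`. The diagnostics table
carries per-slice scale, inlier potential, slice posterior and the
hard exclusion flag (posterior < 0.5); corrupted and displaced slices
should end excluded while clean slices keep posteriors near 1.

## Command line

```sh
Rscript -e 'svrsr::svrsr_main()' simulate    --config sim.json --out simdir --seed 5
Rscript -e 'svrsr::svrsr_main()' reconstruct --stacks s1.nii.gz s2.nii.gz s3.nii.gz \
        --mask mask.nii.gz --out vol.nii.gz --report report.json
Rscript -e 'svrsr::svrsr_main()' evaluate    --recon vol.nii.gz --truth truth.nii.gz --out metrics.json
Rscript -e 'svrsr::svrsr_main()' bench       --config bench.json --out results.json
```

Every method constant (PSF factor, σ_B, λ schedule, EM iteration
counts, noise fraction, scale range) is a named, defaulted field of
the JSON configs.

## Documentation

`vignettes/svrsr-methods.Rmd` describes the model, every tunable
parameter with units and defaults, what the simulator does and does
not emulate, the numerical choices, and known limitations.
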