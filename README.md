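# hpepi

Susceptibility-distortion correction for blip-reversed echo planar
imaging (EPI) timecourses of hyperpolarized ¹³C metabolites.

## The problem

Hyperpolarized [1-¹³C]pyruvate imaging watches a bolus of injected
magnetization convert into lactate and bicarbonate over ~1 minute, with
single-shot EPI as the readout. EPI's low phase-encode (PE) bandwidth
turns local B0 offsets into geometric distortion: signal at a voxel with
offset ΔB0 Hz is displaced along PE by

    b = ΔB0 / pixel_bandwidth_PE   [voxels],

compressing and stretching anatomy near the heart, while transmitter
frequency errors translate each metabolite image bodily. Alternating the
sign of the PE blips between shots flips the sign of `b`, so a
blip-up/blip-down pair determines the displacement field without any
reference scan — essential when the ¹³C signal lives where no proton
reference is usable.

`hpepi` implements the full correction for 5D magnitude stacks
`[x, y, z, t, m]` (space × time × metabolite):

1. per-metabolite bulk-shift alignment of the two polarities
   (mutual-information search, sub-voxel Fourier phase-ramp shifts);
2. an SNR-weighted composite image per polarity, pooling all metabolites
   and timepoints with inverse-variance weights `1/σ²ₜₘ` after rescaling
   each metabolite to unit maximum;
3. displacement-field estimation by regularized least squares on the
   composite pair — both images are unwarped toward the midway frame
   (`±b`, Jacobian-modulated) and their squared disagreement plus a
   bending-energy penalty `λ‖Δb‖²` is minimized coarse-to-fine
   (subsampling 4/2/1, Gaussian blur FWHM 8/4/0 px, λ = 50/20/2) with
   Gauss–Newton and conjugate gradients;
4. unwarping of every frame by exact per-column inversion of the
   monotone displacement map;
5. residual alternating-translation registration per metabolite, giving
   maps `c` (up→down) and `d` (down→up);
6. merging through the geometric-mean interpolator: √c applied to the
   blip-up series, √d to the blip-down series (principal matrix square
   roots), interleaved in acquisition order;
7. evaluation by the odd/even-frame Jaccard overlap of thresholded
   temporally summed images (threshold 0.2 × max).

A synthetic phantom generator (`phantom_spec()` / `generate_study()`)
reproduces the study conditions — 32×16×12 matrix, 20 timepoints, three
metabolites with widely differing SNR, smooth Gaussian-bump field, bulk
frequency shifts, Rician noise — with full ground truth, so every stage
is testable without scanner data.

## Worked example

```r
library(hpepi)

spec   <- phantom_spec(seed = 1)                  # default blip-reversed study
study  <- generate_study(spec)                    # up/down stacks + ground truth
result <- correct_study(study$up, study$down,
                        pipeline_config(spec$params))
result
#> <correction_result>
#>   max |field| = 2.393 voxels
#>   metabolite jaccard_pre jaccard_post threshold
#>     pyruvate   0.2250000    0.8929426       0.2
#>  bicarbonate   0.4859526    0.6775925       0.2
#>      lactate   0.3552697    0.9360434       0.2

err <- result$field_solution$field$shift_voxels -
       study$truth$true_field$shift_voxels
sqrt(mean(err[study$truth$mask]^2))
#> [1] 0.1670336
```

Reading this: the simulated field peaks at 3 voxels of displacement and
the estimate recovers it to 0.17 voxels RMS inside the object. The
odd/even Jaccard overlap — odd and even frames alternate blip polarity,
so without distortion their temporal sums should coincide — rises for
every metabolite after correction (e.g. 0.23 → 0.89 for pyruvate);
uncorrected, the opposite distortions and bulk shifts push the two masks
apart.

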