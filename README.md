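# aedfuse

Autoencoder fusion of perimetry and OCT for glaucoma progression
monitoring, in R.

Glaucoma is followed with two instruments that disagree in scale, dimension
and noise: perimetry measures differential light sensitivity (dB) at the 52
usable points of the 24-2 visual-field grid, and optical coherence
tomography measures peripapillary retinal nerve fiber layer (RNFL)
thickness (μm) at 256 angular positions around the optic nerve head.
Perimetry carries the clinical progression criterion — an eye is called
*progressing* when the mean-deviation (MD) trend is worse than
−0.5 dB/year — but it is noisy; OCT is quiet but indirect and saturates in
advanced disease. `aedfuse` is for researchers in ophthalmic informatics
who want to combine the two while keeping the output readable as an
ordinary visual field.

## The model

An encoder maps the normalized input `x = (v, r, a)` (52-point field,
256-point RNFL profile, age; d = 309) to a 52-dimensional encoding
`z = f_θ(x)` — the **AE-fused field** — and a decoder reconstructs
`x' = g_φ(z)`. Training minimizes the convex combination

    L = (1 − λ) · L_rec + λ · L_enc
    L_rec = (1/N) Σ ‖x'_i − x_i‖²        (reconstruction loss)
    L_enc = (1/N) Σ ‖z_i − v_i‖²         (encoding loss)

The encoding loss is the interpretability device: it keeps each coordinate
of `z` a sensitivity estimate at a known grid location, so the fused field
can be trend-analyzed with the standard MD criterion, no new rules needed.
At `λ = 1` the fused field reproduces the measured field; at `λ = 0` it is
an unconstrained code; in between it absorbs structural information from
the RNFL profile. The package also implements the standard comparators: the
VF-only clinical method and a Bayesian linear regression (BLR) whose
posterior rate is the precision-weighted average of the functional MD slope
and a structural prior derived from mean-RNFL-thickness change.

Because no public paired longitudinal cohort exists, the package includes a
calibrated synthetic-cohort simulator (demographics, structure–function
coupling through a Garway-Heath-style sector map, RNFL floor effect,
heteroscedastic and global perimetric noise, lens-rim artifacts, reliability
indices), so everything trains and evaluates end to end with no external
data.

## Worked example

```r
library(aedfuse)

# a small synthetic clinic: 12 patients, ~2 eyes each, ~10 visits per eye
sim <- simulate_cohort(sim_config(n_patients = 12, seed = 42))
flt <- apply_reliability_filters(sim$cohort)
table(flt$log$reason)
#> oct-unreliable   rnfl-missing  vf-unreliable
#>              3              2              5

fit <- aedf(flt$cohort,
            config = aedf_config(lambda = 0.6, epochs = 120, patience = 20,
                                 seed = 1))
fit
#> Autoencoder data-fusion model
#>   input dx = 309 (dls+rnfl+age), encoding dz = 52
#>   encoder 309-256-128-52 | decoder mirrored
#>   lambda = 0.60; trained 120 epochs (best 115), val loss 0.41901

# fuse every visit and run the sliding-window progression benchmark
fused <- fuse_cohort(fit, flt$cohort)
rpt   <- evaluate_progression(flt$cohort, fused = fused, blr = TRUE)
subset(aggregate_report(rpt, "specificity"), abs(time - 2) < 1e-9)
#>    method time  mean     sem lower upper n
#> 3     blr    2 0.807 0.00997 0.788 0.827 5
#> 8   fused    2 0.636 0.01650 0.603 0.668 5
#> 13     vf    2 0.653 0.01672 0.620 0.686 5

# the Bayesian baseline on one eye: a steady RNFL prior tempers the call
lik  <- ols_slope(0:4, c(-2.0, -2.6, -3.1, -3.4, -4.1))
post <- posterior_slope(lik, list(mean = -0.15, variance = 0.01))
#> functional slope -0.50 dB/y, posterior -0.47 dB/y
```

The aggregate table reads: at the two-year horizon, specificity of the
progression call per method, averaged over the 4–8-year sliding windows
(mean ± SEM and the 95% interval). In this tiny demonstration the model is
trained on the same eyes it fuses; the real benchmark
(`evaluate_fusion()`) trains and evaluates with eye-grouped,
severity-stratified cross-validation so fused fields are always produced by
a model that never saw that eye.

`vignettes/fusing-vf-oct.Rmd` documents the model, the simulator and every
numerical convention; `inst/cli/aedfuse.R` exposes
`simulate` / `train` / `fuse` / `blr` / `evaluate-progression` subcommands
for shell use.

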