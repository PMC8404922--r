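# contrastgan

Contrast-aware MR image synthesis in R: a progressive-growing Wasserstein
GAN (gradient penalty) whose generator is conditioned on the MR acquisition
parameters — repetition time (TR), echo time (TE) and imaging orientation —
through a separately trained auxiliary classifier (AC) with adaptive
conditioning-loss weights. The package is for researchers who want to study
acquisition-conditioned generative models of MR contrast end to end on one
machine: it ships the data-curation pipeline for DICOM corpora, a
physics-based phantom generator standing in for gated clinical data, the
networks and losses, the training loops, and the evaluation harnesses
(conditioning-fidelity metrics, TR/TE interpolation grids, and a
bias-corrected visual Turing test scorer).

## The model

The critic `D` is trained on the Wasserstein objective with gradient
penalty,

    L = E[D(G(z, c))] - E[D(x)] + lambda_gp * E[(||grad_xhat D(xhat)|| - 1)^2],

with `lambda_gp = 10` and `xhat` interpolated per sample between paired real
and generated images. Conditions `c = (TR, TE, orientation)` are min-max
scaled / one-hot encoded and concatenated to the latent vector `z`. A
separate AC with three heads (orientation softmax; sigmoid regressions for
normalized TR and TE) is pretrained on

    L_AC = 1 * CCE(IOP) + 10 * MSE(TE) + 10 * MSE(TR),

and then guides the generator through the conditioning loss

    L_cond = gamma_IOP * CCE + gamma_TE * MSE(TE) + gamma_TR * MSE(TR),

whose weights follow the adaptive recurrence
`gamma_t = min(tau, max(0, gamma_{t-1} + r (L_fake - E_hat * L_real)))` with
`tau = 100`, `r = 0.01`, `E_hat = 1` and `gamma_0 = 0`. Both networks grow
progressively from 4x4, blending each new resolution stage in with a fade
weight; conditioning is inactive until the final resolution is reached.
Since no deep-learning framework is available in this R stack, the package
includes its own small layer engine (im2col convolutions over BLAS with
hand-written backward passes, verified against central differences in the
test suite).

## Worked example

Score a visual Turing test: 25 balanced 3x2 grids (75 real + 75 synthetic
images), two scripted raters replaying the reference confusion counts
through the same code path human answer sheets would use:

```r
library(contrastgan)

set.seed(1)
real <- matrix(runif(64 * 75, -1, 1), 64, 75)       # 8x8 toy images
syn  <- degrade_images(real, 8, seed = 2)           # blurred/noised copies
session <- build_turing_session(real, syn, n_grids = 25, seed = 3)
answers <- rbind(
  simulate_turing_answers(session, "expert1", 53, 53, seed = 4),
  simulate_turing_answers(session, "expert2", 36, 36, seed = 5))
score_turing_session(session, answers)
#> Rater expert1 : accuracy 71 % ( 70.67% raw )
#>            true
#> predicted   real synthetic
#>   real        53        22
#>   synthetic   22        53
#> Rater expert2 : accuracy 48 % ( 48.00% raw )
#>            true
#> predicted   real synthetic
#>   real        36        39
#>   synthetic   39        36
#> Inter-reader agreement (all raters correct): real = 27 , synthetic = 25
```

Expert 1 labeled 106 of 150 cells correctly (71 % after integer rounding);
expert 2 was at chance (48 %). The forced per-grid balance (3 real + 3
synthetic marks) is what removes the "everything looks synthetic" labeling
bias of free-response designs.

Curate a DICOM directory — here a generated fixture with 10 planted
violations per exclusion reason:

```r
dir <- file.path(tempdir(), "fixture")
make_curation_fixture(dir, n_series = 120, seed = 1)
res <- curate_directory(dir, curation_config(), split = FALSE)
str(res$report)
#> List of 5
#>  $ n_files      : int 360
#>  $ n_series     : int 120
#>  $ n_series_kept: int 80
#>  $ n_images_kept: int 240
#>  $ exclusions   :List of 6
#>   ..$ malformed     : int 0
#>   ..$ tr_range      : int 10
#>   ..$ te_max        : int 10
#>   ..$ fat_sat       : int 10
#>   ..$ field_strength: int 0
#>   ..$ manufacturer  : int 10
```

Exactly the 80 clean series survive: TR outside [1800, 5000] ms, TE above
50 ms, fat-saturated series, and series whose vendor cannot be resolved
(manufacturer attribute missing and no mappable coil name) are excluded.

Train the full desk-scale pipeline on spin-echo phantoms (about 7 minutes
for the AC, 12 for the GAN, single CPU):

```r
train <- make_phantom_dataset(5000, seed = 101)     # 32x32 labeled phantoms
test  <- make_phantom_dataset(1000, seed = 202)
acr <- pretrain_ac(train, epochs = 35, seed = 5,
                   lr_schedule = c(rep(1e-3, 22), rep(3e-4, 8),
                                   rep(1e-4, 5)))
conditioning_metrics(test$images, test$meta, acr$ac, condition_codec())
#> <conditioning_report> real_test (n = 1000): MAE(TR) 233.6 ms,
#>   MAE(TE) 1.77 ms, orientation 99.4%
```

The AC recovers TR to 233.6 ms (7 % of the 3200 ms conditioning range) and
TE to 1.77 ms (4.7 % of the 38 ms range) from image contrast alone — the
phantom's spin-echo law `S = PD (1 - exp(-TR/T1)) exp(-TE/T2)` is what makes
those parameters identifiable. `train_gan()` then runs the progressive
conditional GAN (demo profile: stages 4/8/16/32, ~22,000 images); across
the final stage's checkpoints the AC-measured conditioning loss on a fixed
evaluation batch fell from about 1.9 to 1.1 in the run recorded in the
history, with critic/generator updates exactly balanced.

A thin CLI over these functions is installed under
`system.file("cli", "mrcontrast.R", package = "contrastgan")` with
subcommands `curate`, `phantom`, `pretrain-ac`, `train`, `evaluate`,
`turing-build` and `turing-score`.

## Scope

The package demonstrates the method at desk scale on phantoms. The
256x256 clinical training run (gated DICOM knee corpus, tens of millions of
images on GPUs) is expressible through the same API (`default_schedule(256, "reference")`, `ac_backbone = "densenet121"`) but is not reproduced here;
reference values from that setting are quoted in the vignette for context
only.
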