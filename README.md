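# vnseg

Joint denoising and segmentation of stained melanoma tissue-section
images with a trainable **coupled variational network**, plus a
**stochastic scene generator** that synthesizes histology-like training
images with exact ground truth — so the entire train/predict/evaluate
loop runs on purely synthetic data, with no pathologist annotation.

## Who this is for

Computational-pathology researchers who want an interpretable,
small-parameter alternative to black-box segmentation networks for
tasks like marking immune cells interacting with tumor cells
(immunofluorescence), finding immune-cell-rich regions (H&E), or
detecting tumor nuclei in a visually similar microenvironment (H&E) —
and anyone who needs a scriptable generator of layered histology-like
scenes with pixel-exact masks.

## The model

The state is a pair (u, m): an RGB image u ∈ [0,1]^(H×W×3) and a soft
segmentation mask m ∈ [0,1]^(H×W), binarized at 1/2. Starting from the
noisy observation u₀ and an empty mask, the network unrolls N_t
projected gradient steps

    u_{t+1} = proj_[0,1]( u_t − ∇_u E_t(u_t, m_t) )
    m_{t+1} = proj_[0,1]( m_t − ∇_m E_t(u_t, m_t) )

of a per-stage coupled energy

    E_t(u, m) = Σ φ_t( K_t( φ_t^u(K_t^u u), φ_t^m(K_t^m m) ) )
                + (λ_t/2) ‖u − u₀‖²

with learned convolution kernel banks K_t^u (11×11×3), K_t^m (5×5) and
coupling kernels K_t (5×5×24), and learned Gaussian-RBF pointwise
nonlinearities (31 bases on [−1.2, 1.2]); the coupling nonlinearity is
parameterized through its derivative. Parameters are trained with
projected Adam on the loss Σ (1/6)‖u_T − g_u‖² + (1/2)‖m_T − g_m‖²,
under zero-mean and ℓ1-ball kernel constraints. The generator builds
scenes from declarative YAML scripts: layered ellipse geometry, Voronoi
and fast-marching domain decompositions, patch-mosaic textures,
multivariate-normal color noise, and rule-derived ground truth (e.g. an
immune cell is marked when the tumor-cell concentration in a radius-40
disk around it exceeds 0.3). See `vignette("vnseg-methods")` for the
full account.

## Worked example

```r
library(vnseg)

# one synthetic immunofluorescence scene with exact ground truth
cfg <- scenario_config(1)
sample <- generate_sample(cfg, sample_seed = 1)
print(sample)
#> <vn_sample> scenario 1, 300x300, seed 1
#>   shapes: hidden_cells=15, immune_cell=20, immune_nucleus=20,
#>           stroma=20, tumor_cell=25, tumor_nucleus=25
```

25 tumor cells, 20 immune cells and 20 stromal cells were placed
(the scene script's counts), each with its nucleus; `sample$u0` is the
noisy input, `sample$g_u` the clean target and `sample$g_m` the
rule-derived mask. The classification rule flips within one pixel-area
quantum of its configured threshold:

```r
classification_flip_point(40, 0.3)
#> [1] 0.3001592
```

The joint zero-mean/ℓ1 kernel projection is exact and fast:

```r
set.seed(0)
pk <- project_zero_mean_l1ball(rnorm(11 * 11 * 3))
sprintf("|mean| = %.2e, l1 = %.4f, iterations = %d",
        abs(mean(pk)), sum(abs(pk)), attr(pk, "iterations"))
#> "|mean| = 0.00e+00, l1 = 1.0000, iterations = 2"
```

Training a reduced network on small synthetic scenes (a 20-iteration
excerpt; the shipped end-to-end check trains 200 iterations and reaches
~96% held-out accuracy and > +2 dB PSNR over the input):

```r
arch <- vn_architecture(n_stages = 3, n_fu = 6, n_fm = 2,
                        k_u = 5, k_m = 5, k_c = 5, n_w = 15)
spec <- constraint_spec(zero_mean_image_kernels = FALSE)
params <- vn_init_params(arch, seed = 1, spec = spec)
small <- scenario_config(1, "small")
train_set <- generate_dataset(small, 16, master_seed = 11)
fit <- train_vn(params, train_set,
                train_config(iterations = 20, step_size = 2e-3,
                             batch_size = 8, master_seed = 5), spec)
tail(fit$log, 3)
#>    iteration loss accuracy  psnr
#> 18        18 3843    90.69 25.08
#> 19        19 3911    90.52 25.14
#> 20        20 3773    90.86 25.22
```

The log columns are the training diagnostics triple: summed squared
loss, batch segmentation accuracy (%) at threshold 1/2, and batch PSNR
(dB) of the reconstruction against the clean target.

A command-line interface over the same functions ships in
`inst/cli/vnseg.R`:

```sh
Rscript inst/cli/vnseg.R generate --scenario 1 --n 4 --seed 7 --out data/
Rscript inst/cli/vnseg.R train --scenario 1 --seed 1 --out model.rds
Rscript inst/cli/vnseg.R predict --checkpoint model.rds --input img.png --out pred
```

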