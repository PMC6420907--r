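#' Network architecture configuration
#'
#' Defines the shared shape of every stage of the unrolled scheme: channel
#' counts, kernel sizes and the RBF grid. Defaults follow the reference
#' configuration: 10 stages, 20 image-feature kernels of 11x11x3, 4 mask
#' kernels of 5x5x1, 24 coupling kernels of 5x5x24, and 31 Gaussian bases
#' equally spaced on the interval -1.2 to 1.2.
#'
#' @param n_stages number of unrolled projected-gradient steps.
#' @param n_fu number of image feature channels.
#' @param n_fm number of mask feature channels.
#' @param k_u,k_m,k_c spatial sizes (odd) of image, mask and coupling
#'   kernels.
#' @param n_w number of Gaussian bases per nonlinearity.
#' @param mu_range range of the equally spaced basis means.
#' @return an object of class `vn_arch`.
#' @export
vn_architecture <- function(n_stages = 10L, n_fu = 20L, n_fm = 4L,
                            k_u = 11L, k_m = 5L, k_c = 5L, n_w = 31L,
                            mu_range = c(-1.2, 1.2)) {
  stopifnot(n_stages >= 1L, n_fu >= 1L, n_fm >= 1L, n_w >= 2L,
            k_u %% 2L == 1L, k_m %% 2L == 1L, k_c %% 2L == 1L,
            length(mu_range) == 2L, mu_range[2] > mu_range[1])
  structure(list(n_stages = as.integer(n_stages), n_fu = as.integer(n_fu),
                 n_fm = as.integer(n_fm), n_f = as.integer(n_fu + n_fm),
                 k_u = as.integer(k_u), k_m = as.integer(k_m),
                 k_c = as.integer(k_c), n_w = as.integer(n_w),
                 mu_range = as.numeric(mu_range)),
            class = "vn_arch")
}

#' @export
print.vn_arch <- function(x, ...) {
  cat(sprintf(paste0("<vn_arch> %d stages | image: %d kernels %dx%dx3 | ",
                     "mask: %d kernels %dx%d | coupling: %d kernels %dx%dx%d",
                     " | %d bases on [%g, %g]\n"),
              x$n_stages, x$n_fu, x$k_u, x$k_u, x$n_fm, x$k_m, x$k_m,
              x$n_f, x$k_c, x$k_c, x$n_f, x$n_w, x$mu_range[1],
              x$mu_range[2]))
  invisible(x)
}

#' Per-stage parameter set
#'
#' Bundles the trainable tensors of one stage: the image kernel bank `K_u`
#' (`k_u x k_u x 3 x n_fu`), its function-parameterized RBF weights `w_u`,
#' the mask kernel bank `K_m` (`k_m x k_m x 1 x n_fm`) with weights `w_m`,
#' the coupling kernel bank `K_c` (`k_c x k_c x n_f x n_f`) whose RBF weights
#' `w_c` parameterize the derivative of the coupling nonlinearity directly,
#' and the nonnegative data-term weight `lambda`.
#'
#' @param K_u,w_u,K_m,w_m,K_c,w_c,lambda tensors as described above.
#' @param arch the [vn_architecture()] the shapes must match.
#' @return an object of class `vn_stage`.
#' @export
stage_params <- function(K_u, w_u, K_m, w_m, K_c, w_c, lambda, arch) {
  stopifnot(identical(dim(K_u), c(arch$k_u, arch$k_u, 3L, arch$n_fu)),
            identical(dim(K_m), c(arch$k_m, arch$k_m, 1L, arch$n_fm)),
            identical(dim(K_c), c(arch$k_c, arch$k_c, arch$n_f, arch$n_f)),
            identical(dim(w_u), c(arch$n_fu, arch$n_w)),
            identical(dim(w_m), c(arch$n_fm, arch$n_w)),
            identical(dim(w_c), c(arch$n_f, arch$n_w)),
            length(lambda) == 1L, lambda >= 0)
  structure(list(K_u = K_u, w_u = w_u, K_m = K_m, w_m = w_m,
                 K_c = K_c, w_c = w_c, lambda = as.numeric(lambda)),
            class = "vn_stage")
}

# internal: RBF objects for a stage under an architecture
.stage_nonlin <- function(stage, arch, which = c("u", "m", "c")) {
  which <- match.arg(which)
  w <- switch(which, u = stage$w_u, m = stage$w_m, c = stage$w_c)
  rbf_nonlinearity(w, arch$mu_range[1], arch$mu_range[2],
                   derivative_parameterized = (which == "c"))
}

#' Initialize network parameters
#'
#' Draws small random kernels (projected into the admissible set) and
#' near-linear RBF weights, reproducibly from a seed. The nonlinearities are
#' initialized so that each mixture approximates a gentle linear ramp, which
#' makes the initial unrolled scheme a mild contractive diffusion rather
#' than the identity, giving the optimizer a useful starting signal.
#'
#' @param arch a [vn_architecture()].
#' @param seed integer seed for the initialization draw.
#' @param spec constraint specification used to project the initial kernels;
#'   see [constraint_spec()].
#' @param ramp slope scale of the initial RBF mixtures.
#' @return an object of class `vn_params`: list with `arch` and `stages`.
#' @export
vn_init_params <- function(arch, seed = 0L, spec = constraint_spec(),
                           ramp = 0.02) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- seq(arch$mu_range[1], arch$mu_range[2], length.out = arch$n_w)
  # with equally spaced Gaussians of width = spacing,
  # sum_j mu_j rho_j(x) ~ x * sqrt(2*pi) for x inside the range
  lin <- ramp * matrix(mu, nrow = 1) / sqrt(2 * pi)
  rand_kern <- function(k, cin, cout, sd) {
    array(rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
  }
  stages <- lapply(seq_len(arch$n_stages), function(t) {
    stage_params(
      K_u = rand_kern(arch$k_u, 3L, arch$n_fu, 1 / (arch$k_u * sqrt(3))),
      w_u = lin[rep(1, arch$n_fu), , drop = FALSE] +
        matrix(rnorm(arch$n_fu * arch$n_w, sd = ramp / 20),
               arch$n_fu, arch$n_w),
      K_m = rand_kern(arch$k_m, 1L, arch$n_fm, 1 / arch$k_m),
      w_m = lin[rep(1, arch$n_fm), , drop = FALSE] +
        matrix(rnorm(arch$n_fm * arch$n_w, sd = ramp / 20),
               arch$n_fm, arch$n_w),
      K_c = rand_kern(arch$k_c, arch$n_f, arch$n_f,
                      1 / (arch$k_c * sqrt(arch$n_f))),
      w_c = lin[rep(1, arch$n_f), , drop = FALSE] +
        matrix(rnorm(arch$n_f * arch$n_w, sd = ramp / 20),
               arch$n_f, arch$n_w),
      lambda = 0.1, arch = arch)
  })
  project_parameters(structure(list(arch = arch, stages = stages),
                               class = "vn_params"), spec)
}

#' @export
print.vn_params <- function(x, ...) {
  print(x$arch)
  cat(sprintf("  %d trainable tensors, %d scalars total\n",
              7L * x$arch$n_stages, length(unlist(.param_tensors(x)))))
  invisible(x)
}

# internal: save/restore .Random.seed so seeded helpers do not disturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# internal: flat named list of every trainable tensor (stage-major order)
.param_tensors <- function(params) {
  out <- list()
  for (t in seq_along(params$stages)) {
    s <- params$stages[[t]]
    for (nm in c("K_u", "w_u", "K_m", "w_m", "K_c", "w_c", "lambda"))
      out[[sprintf("s%02d.%s", t, nm)]] <- s[[nm]]
  }
  out
}

# internal: rebuild a vn_params from a flat tensor list
.param_from_tensors <- function(tensors, arch) {
  n <- arch$n_stages
  stages <- lapply(seq_len(n), function(t) {
    g <- function(nm) tensors[[sprintf("s%02d.%s", t, nm)]]
    structure(list(K_u = g("K_u"), w_u = g("w_u"), K_m = g("K_m"),
                   w_m = g("w_m"), K_c = g("K_c"), w_c = g("w_c"),
                   lambda = as.numeric(g("lambda"))),
              class = "vn_stage")
  })
  structure(list(arch = arch, stages = stages), class = "vn_params")
}

#' Save or load a parameter checkpoint
#'
#' Checkpoints are single files carrying the architecture configuration and
#' every parameter tensor (R serialization, version 3). Round trips are
#' bit-exact.
#'
#' @param params a `vn_params` object.
#' @param path file path.
#' @return `load_checkpoint()` returns the `vn_params`.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "vn_params"))
  saveRDS(list(format = "vnseg-checkpoint", version = 1L,
               arch = unclass(params$arch),
               tensors = .param_tensors(params)),
          path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "vnseg-checkpoint"))
    stop("not a vnseg checkpoint: ", path)
  arch <- do.call(vn_architecture,
                  x$arch[c("n_stages", "n_fu", "n_fm", "k_u", "k_m", "k_c",
                           "n_w", "mu_range")])
  .param_from_tensors(x$tensors, arch)
}
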