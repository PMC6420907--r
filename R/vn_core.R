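#' Energy gradients of one stage
#'
#' Computes the chain-rule gradients of the coupled variational energy
#' with respect to the image `u` and the mask `m`:
#' the image and mask features are extracted by the stage's kernel banks,
#' passed through the function-parameterized nonlinearities, concatenated,
#' convolved with the coupling bank and fed to the derivative-parameterized
#' coupling nonlinearity; transposed convolutions propagate the result back
#' to image and mask space, and the image gradient adds the data-fidelity
#' pull `lambda * (u - u0)`.
#'
#' @param stage a [stage_params()] object.
#' @param u color image `H x W x 3`.
#' @param m segmentation mask `H x W`.
#' @param u0 the observed (noisy) image the data term anchors to.
#' @param arch the [vn_architecture()] of the stage.
#' @return list with `grad_u` (`H x W x 3`) and `grad_m` (`H x W`).
#' @export
energy_gradients <- function(stage, u, m, u0, arch) {
  c(.stage_forward(stage, u, m, u0, arch, keep = FALSE)[c("grad_u", "grad_m")])
}

# internal: full forward pass of one stage; keep = TRUE caches every
# intermediate needed by the reverse sweep in .stage_backward()
.stage_forward <- function(stage, u, m, u0, arch, keep = FALSE) {
  nl_u <- .stage_nonlin(stage, arch, "u")
  nl_m <- .stage_nonlin(stage, arch, "m")
  nl_c <- .stage_nonlin(stage, arch, "c")
  H <- dim(u)[1]; W <- dim(u)[2]; n <- H * W

  f_u <- conv_forward(stage$K_u, u)                       # H x W x n_fu
  f_m <- conv_forward(stage$K_m, m)                       # H x W x n_fm
  pu <- .cpp_rbf_mix01(matrix(f_u, n), nl_u$weights, nl_u$means, nl_u$width)
  pm <- .cpp_rbf_mix01(matrix(f_m, n), nl_m$weights, nl_m$means, nl_m$width)
  a  <- array(pu$value, dim = c(H, W, arch$n_fu))         # phi_u(f_u)
  b  <- array(pm$value, dim = c(H, W, arch$n_fm))         # phi_m(f_m)
  p_u <- array(pu$deriv, dim = c(H, W, arch$n_fu))        # phi_u'(f_u)
  p_m <- array(pm$deriv, dim = c(H, W, arch$n_fm))        # phi_m'(f_m)
  FF <- array(c(a, b), dim = c(H, W, arch$n_f))           # coupled features
  g  <- conv_forward(stage$K_c, FF)
  z  <- rbf_deriv(nl_c, g)                                # Dphi(g)
  y  <- conv_adjoint(stage$K_c, z)
  y_u <- y[, , seq_len(arch$n_fu), drop = FALSE]
  y_m <- y[, , arch$n_fu + seq_len(arch$n_fm), drop = FALSE]
  q_u <- p_u * y_u
  q_m <- p_m * y_m
  grad_u <- conv_adjoint(stage$K_u, q_u) + stage$lambda * (u - u0)
  grad_m <- conv_adjoint(stage$K_m, q_m)[, , 1L]
  out <- list(grad_u = grad_u, grad_m = grad_m)
  if (keep)
    out <- c(out, list(u = u, m = m, u0 = u0, f_u = f_u, f_m = f_m,
                       p_u = p_u, p_m = p_m, FF = FF, g = g, z = z,
                       y_u = y_u, y_m = y_m, q_u = q_u, q_m = q_m,
                       nl_u = nl_u, nl_m = nl_m, nl_c = nl_c))
  out
}

#' One projected gradient step
#'
#' Applies one stage of the scheme: gradient descent on the coupled energy
#' followed by the pointwise projection onto the admissible sets, i.e.
#' `u' = clip01(u - grad_u)`, `m' = clip01(m - grad_m)`.
#'
#' @inheritParams energy_gradients
#' @return list with updated `u` and `m`.
#' @export
vn_step <- function(stage, u, m, u0, arch) {
  gr <- energy_gradients(stage, u, m, u0, arch)
  list(u = clip01(u - gr$grad_u), m = clip01(m - gr$grad_m))
}

#' Run the unrolled network forward
#'
#' Applies [vn_step()] once per stage in order, starting from the noisy
#' image `u0` and an (typically all-zero) initial mask `m0`.
#'
#' @param params a `vn_params` object (see [vn_init_params()]).
#' @param u0 noisy input image `H x W x 3`, values in `[0, 1]`.
#' @param m0 initial segmentation mask `H x W`; defaults to all zeros.
#' @param record_trajectory if `TRUE`, also return all `n_stages + 1`
#'   intermediate states.
#' @return list with the final `u`, `m` and (optionally) `trajectory`, a
#'   list of `(u, m)` states from input to output.
#' @export
vn_forward <- function(params, u0, m0 = NULL, record_trajectory = FALSE) {
  stopifnot(inherits(params, "vn_params"))
  if (length(params$stages) == 0L) stop("network has no stages")
  u0 <- as_color_image(u0)
  if (is.null(m0)) m0 <- matrix(0, dim(u0)[1], dim(u0)[2])
  m0 <- as_seg_mask(m0)
  u <- u0; m <- m0
  traj <- if (record_trajectory) list(list(u = u, m = m))
  for (stage in params$stages) {
    st <- vn_step(stage, u, m, u0, params$arch)
    u <- st$u; m <- st$m
    if (record_trajectory) traj[[length(traj) + 1L]] <- list(u = u, m = m)
  }
  out <- list(u = u, m = m)
  if (record_trajectory) out$trajectory <- traj
  out
}
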