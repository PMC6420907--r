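# Reverse-mode differentiation through the unrolled projected-gradient
# scheme. The forward pass caches per-stage intermediates; the backward
# sweep applies the chain rule stage by stage. Clipping projections use the
# pass-through-inside / zero-outside subgradient (identity on the closed
# interval [0, 1] of the pre-clip value).

# forward pass keeping caches; returns final state + stage caches
.forward_with_cache <- function(params, u0, m0) {
  u <- u0; m <- m0
  caches <- vector("list", length(params$stages))
  for (t in seq_along(params$stages)) {
    cc <- .stage_forward(params$stages[[t]], u, m, u0, params$arch,
                         keep = TRUE)
    v_u <- u - cc$grad_u
    v_m <- m - cc$grad_m
    if (any(!is.finite(v_u)) || any(!is.finite(v_m)))
      stop("non-finite intermediate state in stage ", t)
    cc$pass_u <- (v_u >= 0) & (v_u <= 1)
    cc$pass_m <- (v_m >= 0) & (v_m <= 1)
    u <- clip01(v_u)
    m <- clip01(v_m)
    caches[[t]] <- cc
  }
  list(u = u, m = m, caches = caches)
}

# backward sweep of one stage: given cotangents of the stage outputs,
# return cotangents of the stage inputs plus parameter gradients
.stage_backward <- function(stage, arch, cc, du_next, dm_next) {
  n_fu <- arch$n_fu; n_fm <- arch$n_fm
  H <- dim(cc$u)[1]; W <- dim(cc$u)[2]; n <- H * W

  dv_u <- du_next * cc$pass_u
  dv_m <- dm_next * cc$pass_m
  du <- dv_u
  dm <- dv_m
  Gu <- -dv_u         # cotangent wrt grad_u
  Gm <- -dv_m         # cotangent wrt grad_m

  # grad_u = conv_adjoint(K_u, q_u) + lambda * (u - u0)
  dlambda <- sum(Gu * (cc$u - cc$u0))
  du <- du + stage$lambda * Gu
  qu_bar <- conv_forward(stage$K_u, Gu)
  dKu <- .conv_kernel_grad(Gu, cc$q_u, arch$k_u, arch$k_u)
  qm_bar <- conv_forward(stage$K_m, Gm)
  dKm <- .conv_kernel_grad(Gm, cc$q_m, arch$k_m, arch$k_m)

  # q = p * y
  pu_bar <- qu_bar * cc$y_u
  yu_bar <- qu_bar * cc$p_u
  pm_bar <- qm_bar * cc$y_m
  ym_bar <- qm_bar * cc$p_m

  # y = conv_adjoint(K_c, z)
  y_bar <- array(c(yu_bar, ym_bar), dim = c(H, W, arch$n_f))
  z_bar <- conv_forward(stage$K_c, y_bar)
  dKc <- .conv_kernel_grad(y_bar, cc$z, arch$k_c, arch$k_c)

  # z = Dphi(g), derivative-parameterized coupling nonlinearity
  bc <- .cpp_rbf_backward_direct(matrix(cc$g, n), cc$nl_c$weights,
                                 matrix(z_bar, n), cc$nl_c$means,
                                 cc$nl_c$width)
  g_bar <- array(bc$xgrad, dim = c(H, W, arch$n_f))
  dwc <- bc$wgrad

  # g = conv_forward(K_c, FF)
  FF_bar <- conv_adjoint(stage$K_c, g_bar)
  dKc <- dKc + .conv_kernel_grad(cc$FF, g_bar, arch$k_c, arch$k_c)

  a_bar <- FF_bar[, , seq_len(n_fu), drop = FALSE]
  b_bar <- FF_bar[, , n_fu + seq_len(n_fm), drop = FALSE]

  # image-feature nonlinearity: used as value a = phi_u(f_u) (cotangent
  # a_bar) and as derivative p_u = phi_u'(f_u) (cotangent pu_bar)
  bu <- .cpp_rbf_backward(matrix(cc$f_u, n), cc$nl_u$weights,
                          matrix(a_bar, n), matrix(pu_bar, n),
                          cc$nl_u$means, cc$nl_u$width)
  fu_bar <- array(bu$xgrad, dim = c(H, W, n_fu))
  dwu <- bu$wgrad
  bm <- .cpp_rbf_backward(matrix(cc$f_m, n), cc$nl_m$weights,
                          matrix(b_bar, n), matrix(pm_bar, n),
                          cc$nl_m$means, cc$nl_m$width)
  fm_bar <- array(bm$xgrad, dim = c(H, W, n_fm))
  dwm <- bm$wgrad

  # f_u = conv_forward(K_u, u), f_m = conv_forward(K_m, m)
  du <- du + conv_adjoint(stage$K_u, fu_bar)
  dKu <- dKu + .conv_kernel_grad(cc$u, fu_bar, arch$k_u, arch$k_u)
  dm <- dm + conv_adjoint(stage$K_m, fm_bar)[, , 1L]
  dKm <- dKm + .conv_kernel_grad(cc$m, fm_bar, arch$k_m, arch$k_m)

  list(du = du, dm = dm,
       grads = list(K_u = dKu, w_u = dwu, K_m = dKm, w_m = dwm,
                    K_c = dKc, w_c = dwc, lambda = dlambda))
}

#' Training loss
#'
#' Sum over samples of `(1/6) * ||u_T - g_u||^2 + (1/2) * ||m_T - g_m||^2`
#' (sums of squared entries, no per-pixel averaging); the 1/6 factor
#' compensates the three image channels against the single mask channel.
#'
#' @param outputs list of network outputs, each a list with `u` and `m`.
#' @param targets list of targets, each a list with `g_u` and `g_m`.
#' @return nonnegative scalar loss.
#' @export
compute_loss <- function(outputs, targets) {
  stopifnot(length(outputs) == length(targets))
  tot <- 0
  for (s in seq_along(outputs)) {
    if (!identical(dim(outputs[[s]]$u), dim(targets[[s]]$g_u)) ||
        !identical(dim(as_seg_mask(outputs[[s]]$m, strict = FALSE)),
                   dim(as_seg_mask(targets[[s]]$g_m, strict = FALSE))))
      stop("output/target shape mismatch at sample ", s)
    tot <- tot + sum((outputs[[s]]$u - targets[[s]]$g_u)^2) / 6 +
      sum((outputs[[s]]$m - targets[[s]]$g_m)^2) / 2
  }
  tot
}

#' Loss gradients through the unrolled network
#'
#' Reverse-mode gradient of [compute_loss()] composed with [vn_forward()]
#' with respect to every trainable tensor, accumulated over a batch of
#' training pairs.
#'
#' @param params a `vn_params` object.
#' @param batch list of training pairs (lists with `u0`, `m0`, `g_u`,
#'   `g_m`; `m0` may be omitted for the all-zero mask).
#' @return list with `loss`, `grads` (flat named tensor list matching the
#'   parameter layout) and `outputs` (per-sample final states).
#' @export
loss_gradients <- function(params, batch) {
  stopifnot(inherits(params, "vn_params"), length(batch) >= 1L)
  arch <- params$arch
  grads <- .param_tensors(params)
  for (nm in names(grads)) grads[[nm]][] <- 0
  loss <- 0
  outputs <- vector("list", length(batch))
  for (s in seq_along(batch)) {
    pair <- batch[[s]]
    u0 <- pair$u0
    m0 <- if (is.null(pair$m0)) matrix(0, dim(u0)[1], dim(u0)[2]) else pair$m0
    fw <- .forward_with_cache(params, u0, m0)
    outputs[[s]] <- list(u = fw$u, m = fw$m)
    loss <- loss + sum((fw$u - pair$g_u)^2) / 6 +
      sum((fw$m - pair$g_m)^2) / 2
    du <- (fw$u - pair$g_u) / 3
    dm <- fw$m - pair$g_m
    for (t in rev(seq_along(params$stages))) {
      bk <- .stage_backward(params$stages[[t]], arch, fw$caches[[t]], du, dm)
      du <- bk$du
      dm <- bk$dm
      for (nm in names(bk$grads)) {
        key <- sprintf("s%02d.%s", t, nm)
        grads[[key]] <- grads[[key]] + bk$grads[[nm]]
      }
    }
  }
  list(loss = loss, grads = grads, outputs = outputs)
}
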