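# Independent oracles and small fixtures shared across the suite.

# brute-force zero-padded cross-correlation, nested sums at every pixel
brute_conv <- function(kernels, input) {
  dk <- dim(kernels)
  H <- dim(input)[1]; W <- dim(input)[2]
  ch <- (dk[1] - 1) / 2; cw <- (dk[2] - 1) / 2
  out <- array(0, dim = c(H, W, dk[4]))
  for (o in seq_len(dk[4])) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(dk[1])) for (b in seq_len(dk[2]))
      for (c in seq_len(dk[3])) {
        ii <- i + a - 1 - ch; jj <- j + b - 1 - cw
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          acc <- acc + kernels[a, b, c, o] * input[ii, jj, c]
      }
    out[i, j, o] <- acc
  }
  out
}

# long-run Dykstra alternating projections onto {zero mean} * {l1 ball}:
# converges to the exact Euclidean projection
dykstra_oracle <- function(x, radius = 1, iterations = 10000L) {
  y <- as.numeric(x)
  p <- q <- numeric(length(y))
  for (it in seq_len(iterations)) {
    a <- (y + p) - mean(y + p)
    p <- y + p - a
    b <- as.numeric(project_l1_ball(a + q, radius))
    q <- a + q - b
    y <- b
  }
  y
}

# antiderivative of a derivative-parameterized Gaussian RBF mixture
# (closed form via the normal CDF), anchored at 0
rbf_antiderivative <- function(nonlin, x) {
  w <- nonlin$weights; mu <- nonlin$means; s <- nonlin$width
  d <- dim(x)
  xv <- as.numeric(x)
  F <- nrow(w)
  m <- matrix(xv, ncol = F)
  out <- matrix(0, nrow(m), F)
  for (f in seq_len(F)) for (j in seq_along(mu))
    out[, f] <- out[, f] + w[f, j] * s * sqrt(2 * pi) *
      (pnorm((m[, f] - mu[j]) / s) - pnorm(-mu[j] / s))
  array(out, dim = d)
}

# coupled energy reconstructed from a stage's parameters (the network only
# ever evaluates its gradients)
stage_energy <- function(stage, u, m, u0, arch) {
  nl_u <- vnseg:::.stage_nonlin(stage, arch, "u")
  nl_m <- vnseg:::.stage_nonlin(stage, arch, "m")
  nl_c <- vnseg:::.stage_nonlin(stage, arch, "c")
  a <- rbf_eval(nl_u, conv_forward(stage$K_u, u))
  b <- rbf_eval(nl_m, conv_forward(stage$K_m, m))
  FF <- array(c(a, b), dim = c(dim(u)[1], dim(u)[2], arch$n_f))
  g <- conv_forward(stage$K_c, FF)
  sum(rbf_antiderivative(nl_c, g)) + stage$lambda / 2 * sum((u - u0)^2)
}

# k-fold diamond (4-neighbor) dilation, the uniform-speed growth oracle
diamond_dilate <- function(mask, k) {
  H <- nrow(mask); W <- ncol(mask)
  for (step in seq_len(k)) {
    m2 <- mask
    m2[2:H, ] <- m2[2:H, ] | mask[1:(H - 1), ]
    m2[1:(H - 1), ] <- m2[1:(H - 1), ] | mask[2:H, ]
    m2[, 2:W] <- m2[, 2:W] | mask[, 1:(W - 1)]
    m2[, 1:(W - 1)] <- m2[, 1:(W - 1)] | mask[, 2:W]
    mask <- m2
  }
  mask
}

tiny_arch <- function(n_stages = 2L) {
  vn_architecture(n_stages = n_stages, n_fu = 2L, n_fm = 1L,
                  k_u = 3L, k_m = 3L, k_c = 3L, n_w = 5L)
}

tiny_pair <- function(seed = 1L, H = 8L, W = 8L) {
  set.seed(seed)
  list(u0 = array(runif(H * W * 3, 0.25, 0.75), c(H, W, 3L)),
       g_u = array(runif(H * W * 3, 0.25, 0.75), c(H, W, 3L)),
       g_m = matrix(rbinom(H * W, 1L, 0.3), H, W))
}

# relative error with an absolute floor, for gradient comparisons
rel_err <- function(a, b, floor = 1e-6) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}
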