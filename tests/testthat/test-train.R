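test_that("the loss weighs image and mask residuals 1/6 and 1/2", {
  H <- 4L; W <- 4L
  out <- list(list(u = array(0.5, c(H, W, 3)), m = matrix(0.5, H, W)))
  tgt <- list(list(g_u = array(0.5, c(H, W, 3)), g_m = matrix(0.5, H, W)))
  expect_identical(compute_loss(out, tgt), 0)
  # ||u - g||^2 = 6 and ||m - g||^2 = 2 gives loss 1 + 1 = 2
  out2 <- list(list(u = array(0.5 + sqrt(6 / 48), c(H, W, 3)),
                    m = matrix(0.5 + sqrt(2 / 16), H, W)))
  expect_equal(compute_loss(out2, tgt), 2)
  expect_error(compute_loss(out, list(list(g_u = array(0.5, c(3, 3, 3)),
                                           g_m = matrix(0.5, 3, 3)))),
               "shape")
})

test_that("loss gradients match central finite differences on a tiny net", {
  arch <- tiny_arch(2L)
  p <- vn_init_params(arch, seed = 2)
  pair <- tiny_pair(50)
  lg <- loss_gradients(p, list(pair))
  tensors <- vnseg:::.param_tensors(p)
  lossf <- function(tn) {
    f <- vn_forward(vnseg:::.param_from_tensors(tn, arch), pair$u0)
    sum((f$u - pair$g_u)^2) / 6 + sum((f$m - pair$g_m)^2) / 2
  }
  set.seed(51)
  h <- 1e-4
  for (nm in names(tensors)) {
    for (k in sample(length(tensors[[nm]]), min(5, length(tensors[[nm]])))) {
      tp <- tensors; tp[[nm]][k] <- tp[[nm]][k] + h
      tm <- tensors; tm[[nm]][k] <- tm[[nm]][k] - h
      fd <- (lossf(tp) - lossf(tm)) / (2 * h)
      an <- lg$grads[[nm]][k]
      if (abs(fd) + abs(an) > 1e-9)
        expect_lt(rel_err(fd, an, floor = 1e-5), 1e-4)
    }
  }
})

test_that("structurally zero gradients are exactly zero", {
  arch <- tiny_arch(2L)
  p <- vn_init_params(arch, seed = 7)
  pair <- tiny_pair(52)
  # zero coupling kernels at every stage: features cannot reach the loss
  z <- p
  for (t in seq_along(z$stages)) z$stages[[t]]$K_c[] <- 0
  lg <- loss_gradients(z, list(pair))
  for (t in 1:2) {
    pre <- sprintf("s%02d.", t)
    expect_true(all(lg$grads[[paste0(pre, "K_u")]] == 0))
    expect_true(all(lg$grads[[paste0(pre, "w_u")]] == 0))
    expect_true(all(lg$grads[[paste0(pre, "K_m")]] == 0))
    expect_true(all(lg$grads[[paste0(pre, "w_m")]] == 0))
  }
  # outputs equal to targets: stationary at zero loss
  out <- vn_forward(p, pair$u0)
  perfect <- list(u0 = pair$u0, g_u = out$u, g_m = out$m)
  lg2 <- loss_gradients(p, list(perfect))
  expect_equal(lg2$loss, 0)
  expect_true(all(vapply(lg2$grads, function(g) all(g == 0), logical(1))))
})

test_that("one Adam step from a fresh state equals the closed form", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 8)
  cfg <- train_config(iterations = 1, step_size = 1e-3, master_seed = 0,
                      batch_size = 1)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.999)
  st <- adam_init(p)
  grads <- vnseg:::.param_tensors(p)
  for (nm in names(grads)) grads[[nm]][] <- 0
  g <- 0.37
  grads[["s01.w_u"]][1, 2] <- g       # RBF weights are unconstrained
  upd <- adam_update(st, p, grads, cfg)
  # bias-corrected first step: displacement = -step * g / (|g| + eps)
  expect_equal(upd$params$stages[[1]]$w_u[1, 2],
               p$stages[[1]]$w_u[1, 2] - 1e-3 * g / (abs(g) + 1e-8),
               tolerance = 1e-12)
  # zero gradient, fresh state: parameters unchanged
  for (nm in names(grads)) grads[[nm]][] <- 0
  upd0 <- adam_update(adam_init(p), p, grads, cfg)
  expect_equal(vnseg:::.param_tensors(upd0$params),
               vnseg:::.param_tensors(p), tolerance = 1e-9)
})

test_that("mask accuracy and PSNR follow their closed forms", {
  m <- matrix(rbinom(300 * 300, 1, 0.4), 300, 300)
  expect_equal(mask_accuracy(m, m), 100)
  expect_equal(mask_accuracy(1 - m, m), 0)
  # 9,000 disagreeing pixels on 300x300 -> 90%
  m2 <- m
  m2[seq_len(9000)] <- 1 - m2[seq_len(9000)]
  expect_equal(mask_accuracy(m2, m), 90)
  # uniform absolute error 0.1: 20 dB
  u <- array(0.5, c(10, 10, 3))
  expect_equal(psnr(u + 0.1, u), 20)
  expect_equal(psnr(u, u), 100)            # documented cap
  set.seed(53)
  a <- array(runif(300), c(10, 10, 3)); b <- array(runif(300), c(10, 10, 3))
  expect_equal(psnr(a, b), 10 * log10(1 / mean((a - b)^2)))
  expect_error(psnr(a, array(0.5, c(9, 10, 3))), "shape")
})

test_that("training is seeded-deterministic and inert at step size zero", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 10)
  set.seed(54)
  ds <- lapply(1:4, function(i) {
    s <- tiny_pair(60 + i, 20L, 20L)
    s$m0 <- matrix(0, 20, 20)
    s
  })
  cfg <- train_config(iterations = 3, step_size = 1e-3, batch_size = 2,
                      master_seed = 99)
  f1 <- train_vn(p, ds, cfg)
  f2 <- train_vn(p, ds, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(vnseg:::.param_tensors(f1$params),
                   vnseg:::.param_tensors(f2$params))
  # step size 0 leaves the parameters where they started
  cfg0s <- train_config(iterations = 2, step_size = 0, batch_size = 2,
                        master_seed = 1)
  f0 <- train_vn(p, ds, cfg0s)
  expect_equal(vnseg:::.param_tensors(f0$params),
               vnseg:::.param_tensors(p), tolerance = 1e-12)
  # the per-iteration log carries the diagnostics triple
  expect_named(f1$log, c("iteration", "loss", "accuracy", "psnr"))
  tmp <- tempfile(fileext = ".tsv")
  write_training_log(f1$log, tmp)
  expect_equal(read_training_log(tmp), f1$log, tolerance = 1e-12)
  unlink(tmp)
})

test_that("projected Adam keeps the parameters feasible during training", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 11)
  ds <- lapply(1:2, function(i) tiny_pair(70 + i, 16L, 16L))
  spec <- constraint_spec()
  cfg <- train_config(iterations = 4, step_size = 0.05, batch_size = 2,
                      master_seed = 3)
  fit <- train_vn(p, ds, cfg, spec)
  for (st in fit$params$stages) {
    expect_gte(st$lambda, 0)
    for (o in seq_len(arch$n_f))
      expect_lte(sum(abs(st$K_c[, , , o])), 1 + 1e-6)
    for (o in seq_len(arch$n_fu)) {
      expect_lte(sum(abs(st$K_u[, , , o])), 1 + 1e-6)
      expect_lt(abs(mean(st$K_u[, , , o])), 1e-5)
    }
    for (o in seq_len(arch$n_fm)) {
      expect_lte(sum(abs(st$K_m[, , , o])), 1 + 1e-6)
      expect_lt(abs(mean(st$K_m[, , , o])), 1e-5)
    }
  }
})
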