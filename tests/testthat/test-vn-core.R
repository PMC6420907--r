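test_that("energy gradients reduce to the data term when coupling is off", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 1)
  st <- p$stages[[1]]
  st$K_c[] <- 0
  set.seed(30)
  u <- array(runif(8 * 8 * 3), c(8, 8, 3))
  u0 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  m <- matrix(runif(64), 8, 8)
  # zero coupling kernels and lambda = 0: both gradients vanish
  st$lambda <- 0
  gr <- energy_gradients(st, u, m, u0, arch)
  expect_true(all(gr$grad_u == 0))
  expect_true(all(gr$grad_m == 0))
  # lambda = 2: pure data-term pull on the image only
  st$lambda <- 2
  gr <- energy_gradients(st, u, m, u0, arch)
  expect_equal(gr$grad_u, 2 * (u - u0))
  expect_true(all(gr$grad_m == 0))
})

test_that("energy gradients match finite differences of the reconstructed
           energy", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 3)
  st <- p$stages[[1]]
  # give the stage meaningful weights so the coupling term is active
  set.seed(31)
  st$w_c <- matrix(rnorm(arch$n_f * arch$n_w, sd = 0.3), arch$n_f, arch$n_w)
  u <- array(runif(8 * 8 * 3, 0.2, 0.8), c(8, 8, 3))
  u0 <- array(runif(8 * 8 * 3, 0.2, 0.8), c(8, 8, 3))
  m <- matrix(runif(64, 0.2, 0.8), 8, 8)
  gr <- energy_gradients(st, u, m, u0, arch)
  h <- 1e-5
  for (k in sample(length(u), 12)) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    fd <- (stage_energy(st, up, m, u0, arch) -
             stage_energy(st, um, m, u0, arch)) / (2 * h)
    expect_lt(rel_err(fd, gr$grad_u[k], floor = 1e-4), 1e-4)
  }
  for (k in sample(length(m), 12)) {
    mp <- m; mp[k] <- mp[k] + h
    mm <- m; mm[k] <- mm[k] - h
    fd <- (stage_energy(st, u, mp, u0, arch) -
             stage_energy(st, u, mm, u0, arch)) / (2 * h)
    expect_lt(rel_err(fd, gr$grad_m[k], floor = 1e-4), 1e-4)
  }
})

test_that("vn_step clips the descent step into the unit box", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 1)
  st <- p$stages[[1]]
  st$K_c[] <- 0
  st$lambda <- 1
  set.seed(32)
  u <- array(runif(6 * 6 * 3), c(6, 6, 3))
  u0 <- array(runif(6 * 6 * 3), c(6, 6, 3))
  m <- matrix(runif(36), 6, 6)
  # lambda = 1 pulls the image exactly onto u0 (already feasible)
  out <- vn_step(st, u, m, u0, arch)
  expect_equal(out$u, u0)
  expect_equal(out$m, m)
  # a gradient pushing below 0 is clipped at 0
  st$lambda <- 10
  out <- vn_step(st, u, m, u0, arch)
  expect_true(all(out$u >= 0 & out$u <= 1))
  expect_true(any(u - 10 * (u - u0) < 0))  # clipping actually engaged
})

test_that("vn_forward composes vn_step stage by stage", {
  arch <- tiny_arch(3L)
  p <- vn_init_params(arch, seed = 4)
  set.seed(33)
  u0 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  m0 <- matrix(0, 8, 8)
  out <- vn_forward(p, u0, m0, record_trajectory = TRUE)
  expect_length(out$trajectory, arch$n_stages + 1L)
  # manual composition oracle
  u <- u0; m <- m0
  for (st in p$stages) {
    s <- vn_step(st, u, m, u0, arch)
    u <- s$u; m <- s$m
  }
  expect_identical(out$u, u)
  expect_identical(out$m, m)
  # all-zero parameters: the scheme is the identity
  z <- p
  for (t in seq_along(z$stages)) {
    z$stages[[t]]$K_u[] <- 0; z$stages[[t]]$w_u[] <- 0
    z$stages[[t]]$K_m[] <- 0; z$stages[[t]]$w_m[] <- 0
    z$stages[[t]]$K_c[] <- 0; z$stages[[t]]$w_c[] <- 0
    z$stages[[t]]$lambda <- 0
  }
  out0 <- vn_forward(z, u0, m0)
  expect_identical(out0$u, u0)
  expect_identical(out0$m, m0)
})

test_that("vn_forward outputs always stay in the unit box", {
  arch <- tiny_arch(2L)
  set.seed(34)
  for (i in 1:5) {
    p <- vn_init_params(arch, seed = 100 + i, ramp = 0.5)
    u0 <- array(runif(7 * 9 * 3), c(7, 9, 3))
    out <- vn_forward(p, u0)
    expect_true(all(out$u >= 0 & out$u <= 1))
    expect_true(all(out$m >= 0 & out$m <= 1))
  }
  expect_error(vn_forward(structure(list(arch = arch, stages = list()),
                                    class = "vn_params"),
                          array(0.5, c(4, 4, 3))), "stages")
})

test_that("checkpoints round-trip bit-exactly", {
  arch <- tiny_arch(2L)
  p <- vn_init_params(arch, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(p, path)
  q <- load_checkpoint(path)
  expect_identical(vnseg:::.param_tensors(p), vnseg:::.param_tensors(q))
  expect_identical(unclass(p$arch), unclass(q$arch))
  unlink(path)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "not a vnseg checkpoint")
  unlink(bad)
})
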