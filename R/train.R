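#' Training configuration
#'
#' Hyperparameters of the projected Adam loop. Defaults follow the
#' reference setting: 1500 iterations, step size 1e-4 (use 5e-5 for the
#' patch-textured H&E scenario), decay rates 0.9/0.999, batch size 8.
#'
#' @param iterations number of optimizer iterations.
#' @param step_size Adam step size.
#' @param beta1,beta2 exponential decay rates of the moment estimates.
#' @param batch_size minibatch size.
#' @param epsilon Adam denominator offset.
#' @param master_seed seed controlling minibatch sampling.
#' @return an object of class `vn_train_config`.
#' @export
train_config <- function(iterations = 1500L, step_size = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, batch_size = 8L,
                         epsilon = 1e-8, master_seed = 0L) {
  stopifnot(iterations >= 1L, step_size >= 0, batch_size >= 1L,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, epsilon > 0)
  structure(list(iterations = as.integer(iterations),
                 step_size = step_size, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size), epsilon = epsilon,
                 master_seed = as.integer(master_seed)),
            class = "vn_train_config")
}

#' Adam optimizer state
#'
#' First/second moment accumulators (one per trainable tensor) and the step
#' counter, all initialized at zero.
#'
#' @param params a `vn_params` object.
#' @return an object of class `vn_adam_state`.
#' @export
adam_init <- function(params) {
  tensors <- .param_tensors(params)
  zero <- lapply(tensors, function(x) { x[] <- 0; x })
  structure(list(m = zero, v = zero, step = 0L), class = "vn_adam_state")
}

#' One projected Adam update
#'
#' Standard bias-corrected Adam step on every trainable tensor, followed
#' immediately by the projection onto the admissible parameter set.
#'
#' @param state a [adam_init()] state.
#' @param params a `vn_params` object.
#' @param grads flat named tensor list, as returned by [loss_gradients()].
#' @param config a [train_config()].
#' @param spec a [constraint_spec()].
#' @return list with updated `state` and `params`.
#' @export
adam_update <- function(state, params, grads, config,
                        spec = constraint_spec()) {
  stopifnot(inherits(state, "vn_adam_state"), inherits(params, "vn_params"))
  tensors <- .param_tensors(params)
  state$step <- state$step + 1L
  t <- state$step
  c1 <- 1 - config$beta1^t
  c2 <- 1 - config$beta2^t
  for (nm in names(tensors)) {
    g <- grads[[nm]]
    state$m[[nm]] <- config$beta1 * state$m[[nm]] + (1 - config$beta1) * g
    state$v[[nm]] <- config$beta2 * state$v[[nm]] + (1 - config$beta2) * g^2
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    tensors[[nm]] <- tensors[[nm]] -
      config$step_size * mhat / (sqrt(vhat) + config$epsilon)
  }
  params <- project_parameters(.param_from_tensors(tensors, params$arch),
                               spec)
  list(state = state, params = params)
}

#' Segmentation accuracy
#'
#' Percentage of pixels whose thresholded (at 1/2) predicted mask agrees
#' with the thresholded ground truth.
#'
#' @param predicted,truth masks of equal size, values in `[0, 1]`.
#' @return accuracy in percent.
#' @export
mask_accuracy <- function(predicted, truth) {
  predicted <- as_seg_mask(predicted, strict = FALSE)
  truth <- as_seg_mask(truth, strict = FALSE)
  if (!identical(dim(predicted), dim(truth))) stop("mask shape mismatch")
  100 * mean(binarize_mask(predicted) == binarize_mask(truth))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(1 / MSE)` in decibels with peak intensity 1 and the MSE
#' averaged over all pixels and channels. Identical images are reported at
#' the documented cap of 100 dB.
#'
#' @param reconstructed,target images of equal shape, values in `[0, 1]`.
#' @param cap value returned when the MSE is (numerically) zero.
#' @return PSNR in dB.
#' @export
psnr <- function(reconstructed, target, cap = 100) {
  if (!identical(dim(reconstructed), dim(target)))
    stop("image shape mismatch")
  mse <- mean((reconstructed - target)^2)
  if (mse <= 0) return(cap)
  min(cap, 10 * log10(1 / mse))
}

#' Train the coupled variational network
#'
#' Projected Adam on the training loss: per iteration, a seeded uniform
#' minibatch is drawn without replacement, gradients are backpropagated
#' through all unrolled stages, the Adam update is applied and the
#' parameters are projected back onto the admissible set. The returned log
#' records the loss, the batch segmentation accuracy and the batch PSNR per
#' iteration (the diagnostics triple); runs are bit-reproducible from
#' `config$master_seed`.
#'
#' @param params initial `vn_params`.
#' @param dataset list of training pairs (`u0`, `m0`, `g_u`, `g_m`).
#' @param config a [train_config()].
#' @param spec a [constraint_spec()].
#' @param verbose print progress every `verbose` iterations (0 = silent).
#' @return list with trained `params`, the final Adam `state` and `log`, a
#'   data.frame with columns iteration, loss, accuracy, psnr.
#' @export
train_vn <- function(params, dataset, config = train_config(),
                     spec = constraint_spec(), verbose = 0L) {
  stopifnot(length(dataset) >= config$batch_size)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$master_seed)
  state <- adam_init(params)
  log <- data.frame(iteration = seq_len(config$iterations), loss = NA_real_,
                    accuracy = NA_real_, psnr = NA_real_)
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(length(dataset), config$batch_size)
    batch <- dataset[idx]
    lg <- loss_gradients(params, batch)
    upd <- adam_update(state, params, lg$grads, config, spec)
    state <- upd$state
    params <- upd$params
    log$loss[it] <- lg$loss
    log$accuracy[it] <- mean(vapply(seq_along(batch), function(s)
      mask_accuracy(lg$outputs[[s]]$m, batch[[s]]$g_m), numeric(1)))
    log$psnr[it] <- mean(vapply(seq_along(batch), function(s)
      psnr(lg$outputs[[s]]$u, batch[[s]]$g_u), numeric(1)))
    if (verbose > 0L && it %% verbose == 0L)
      message(sprintf("iter %4d  loss %.3f  acc %.2f%%  psnr %.2f dB",
                      it, log$loss[it], log$accuracy[it], log$psnr[it]))
  }
  list(params = params, state = state, log = log)
}

#' Evaluate a trained network on held-out pairs
#'
#' Runs the forward scheme on each pair and reports per-sample mask
#' accuracy, PSNR of the reconstruction and PSNR of the noisy input, plus
#' the accuracy of the all-zero-mask baseline.
#'
#' @param params trained `vn_params`.
#' @param pairs list of training pairs.
#' @return data.frame with one row per pair.
#' @export
evaluate_vn <- function(params, pairs) {
  rows <- lapply(seq_along(pairs), function(s) {
    p <- pairs[[s]]
    out <- vn_forward(params, p$u0, p$m0)
    data.frame(sample = s,
               accuracy = mask_accuracy(out$m, p$g_m),
               baseline_accuracy = mask_accuracy(0 * p$g_m, p$g_m),
               psnr = psnr(out$u, p$g_u),
               psnr_input = psnr(p$u0, p$g_u))
  })
  do.call(rbind, rows)
}

#' Write or read a training log
#'
#' Tab-separated text table with columns iteration, loss, accuracy (%),
#' psnr (dB).
#'
#' @param log data.frame as returned by [train_vn()].
#' @param path file path.
#' @return `read_training_log()` returns the data.frame.
#' @export
write_training_log <- function(log, path) {
  write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_training_log
#' @export
read_training_log <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
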