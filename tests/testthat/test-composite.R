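test_that("background noise scale is estimated robustly per frame", {
  p <- acq_params()
  ms <- p$matrix_size
  set.seed(31)
  # pure Rician noise frame of known sigma
  noise <- sqrt(rnorm(prod(ms), sd = 0.1)^2 + rnorm(prod(ms), sd = 0.1)^2)
  stack <- metabolite_stack(array(noise, c(ms, 1, 3)), +1, p)
  est <- estimate_noise_sigma(stack, background = 0.25)
  expect_equal(est$sigma[1, 1] * max(noise), 0.1, tolerance = 0.1)
  # noise-free frame floors at 1e-6; scale invariance
  obj <- make_phantom_object(p)$intensity
  clean <- metabolite_stack(array(rep(obj, 3), c(ms, 1, 3)), +1, p)
  est_c <- estimate_noise_sigma(clean)
  expect_equal(as.vector(est_c$sigma), rep(1e-6, 3))
  scaled <- metabolite_stack(clean$data * 10, +1, p)
  expect_equal(estimate_noise_sigma(scaled)$sigma, est_c$sigma,
               tolerance = 1e-12)
  # all-zero frame gets infinite sigma (zero weight), with a message
  z <- clean$data; z[, , , 1, 2] <- 0
  expect_message(est_z <- estimate_noise_sigma(metabolite_stack(z, +1, p)),
                 "all-zero")
  expect_equal(est_z$sigma[1, 2], Inf)
})

test_that("inverse-variance weighting normalizes and excludes dead frames", {
  p <- acq_params(metabolites = "pyruvate")
  ms <- p$matrix_size
  obj <- make_phantom_object(p)$intensity
  # identical frames with equal sigmas reproduce the frame exactly
  stack <- metabolite_stack(array(rep(obj, 4), c(ms, 4, 1)), +1, p)
  noise <- structure(list(sigma = matrix(0.1, 4, 1), method = "fixed"),
                     class = "noise_estimate")
  cm <- snr_weighted_mean(stack, noise)
  expect_equal(cm$image, obj / max(obj), tolerance = 1e-12)
  expect_equal(sum(cm$weights), 1, tolerance = 1e-12)
  # hand-computed two-frame weighting: sigma (1, 2) -> weights (0.8, 0.2)
  st2 <- metabolite_stack(array(rep(obj, 2), c(ms, 2, 1)), +1, p)
  n2 <- structure(list(sigma = matrix(c(1, 2), 2, 1), method = "fixed"),
                  class = "noise_estimate")
  expect_equal(as.vector(snr_weighted_mean(st2, n2)$weights), c(0.8, 0.2))
  # a metabolite with infinite sigma everywhere contributes nothing
  p3 <- acq_params()
  st3 <- metabolite_stack(array(rep(obj, 6), c(ms, 2, 3)), +1, p3)
  sig <- matrix(0.1, 2, 3); sig[, 2] <- Inf
  n3 <- structure(list(sigma = sig, method = "fixed"), class = "noise_estimate")
  expect_warning(c3 <- snr_weighted_mean(st3, n3), "dropped")
  expect_equal(c3$image, obj / max(obj), tolerance = 1e-12)
  expect_equal(c3$weights[, 2], c(0, 0))
})

test_that("composite pairs localize the field and resist dead frames", {
  st <- quiet_study(seed = 6, bulk_shift_voxels = c(0, 0, 0))
  expect_error(build_composite_pair(st$up, st$up), "polarit")
  pair <- suppressMessages(build_composite_pair(st$up, st$down))
  # up/down composites differ most near the bump
  d <- abs(pair$f_up / max(pair$f_up) - pair$f_down / max(pair$f_down))
  peak <- which(d == max(d), arr.ind = TRUE)[1, ]
  bump <- which(st$truth$b0_hz == max(st$truth$b0_hz), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((peak[1:2] - bump[1:2])^2)), 6)
  # dropping a zero-SNR pre-bolus frame barely changes the composite
  trunc_up <- metabolite_stack(st$up$data[, , , -1, , drop = FALSE], +1,
                               st$up$params)
  trunc_down <- metabolite_stack(st$down$data[, , , -1, , drop = FALSE], -1,
                                 st$down$params)
  pair2 <- suppressMessages(build_composite_pair(trunc_up, trunc_down))
  rel <- sqrt(mean((pair2$f_up - pair$f_up)^2)) / max(pair$f_up)
  expect_lt(rel, 0.01)
  # composite SNR beats the best single frame
  mask <- st$truth$mask
  bgm <- !mask
  snr_of <- function(img) mean(img[mask]) / stats::sd(img[bgm])
  best_frame <- max(apply(st$up$data[, , , , 1], 4,
                          function(fr) snr_of(fr)))
  expect_gt(snr_of(pair$f_up), best_frame)
  # zero-field noise-free pair agrees up to scale
  st0 <- quiet_study(seed = 6, noise_sigma = 0,
                     field_model = list(type = "zero", amplitude_hz = 0),
                     bulk_shift_voxels = c(0, 0, 0))
  p0 <- suppressMessages(build_composite_pair(st0$up, st0$down))
  expect_lt(max(abs(p0$f_up / max(p0$f_up) - p0$f_down / max(p0$f_down))),
            1e-10)
})
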