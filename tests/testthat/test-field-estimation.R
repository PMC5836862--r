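test_that("gaussian blur conserves mass and composes in quadrature", {
  x <- smooth_test_volume()
  expect_identical(gaussian_blur(x, 0), x)
  # compactly supported content far from the boundary
  set.seed(17)
  y <- array(0, c(48, 48, 40))
  y[21:27, 21:27, 17:23] <- abs(rnorm(7 * 7 * 7))
  expect_equal(mean(gaussian_blur(y, 4)), mean(y), tolerance = 1e-9)
  # impulse response samples the kernel, peaked at the impulse
  d <- array(0, c(15, 15, 1)); d[8, 8, 1] <- 1
  bd <- gaussian_blur(d, 3)
  expect_equal(which.max(bd), which.max(d))
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  expect_equal(bd[8, 8, 1] / bd[9, 8, 1], exp(0.5 / sigma^2), tolerance = 1e-6)
  # blur(f) twice == blur(f * sqrt(2)) once, away from boundary effects
  two <- gaussian_blur(gaussian_blur(y, 3), 3)
  one <- gaussian_blur(y, 3 * sqrt(2))
  expect_lt(sqrt(mean((two - one)^2)), 1e-6)
  expect_error(gaussian_blur(x, -1), ">= 0")
})

test_that("block-mean subsampling averages blocks exactly", {
  x <- smooth_test_volume()
  expect_identical(subsample(x, 1), x)
  cst <- array(3, c(8, 8, 4))
  expect_true(all(subsample(cst, 2) == 3))
  chk <- array(0, c(4, 4, 1))
  chk[] <- (slice.index(chk, 1) + slice.index(chk, 2)) %% 2
  expect_true(all(subsample(chk, 2) == 0.5))
  expect_error(subsample(x, 0), ">= 1")
})

test_that("the objective scores agreement and rewards the true field", {
  st <- quiet_study(seed = 8, noise_sigma = 0, bulk_shift_voxels = c(0, 0, 0))
  pair <- suppressMessages(build_composite_pair(st$up, st$down))
  fu <- pair$f_up / max(pair$f_up); fd <- pair$f_down / max(pair$f_down)
  zero <- array(0, dim(fu))
  expect_equal(as.numeric(field_objective(zero, fu, fu, lambda = 1)), 0)
  c0 <- field_objective(zero, fu, fd, lambda = 5)
  expect_equal(as.numeric(c0), sum((fu - fd)^2))
  expect_equal(attr(c0, "penalty_value"), 0)
  ctrue <- field_objective(st$truth$true_field, fu, fd, lambda = 0)
  expect_lt(as.numeric(ctrue), as.numeric(field_objective(zero, fu, fd, 0)))
})

test_that("field estimation recovers phantom fields and respects symmetry", {
  st <- quiet_study(seed = 8, noise_sigma = 0, bulk_shift_voxels = c(0, 0, 0))
  pair <- suppressMessages(build_composite_pair(st$up, st$down))
  sol <- estimate_field(pair)
  truth <- st$truth
  err <- sol$field$shift_voxels - truth$true_field$shift_voxels
  expect_lt(sqrt(mean(err[truth$mask]^2)), 0.25)
  peak_true <- which.max(truth$true_field$shift_voxels)
  expect_lt(abs(sol$field$shift_voxels[peak_true] -
                  truth$true_field$shift_voxels[peak_true]), 0.75)
  # cost trace is non-increasing within every level
  for (tr in sol$cost_trace) expect_true(all(diff(tr) <= 1e-9))
  # swapping the composites negates the field
  sol_sw <- estimate_field(list(f_up = pair$f_down, f_down = pair$f_up,
                                pe_axis = pair$pe_axis))
  expect_lt(sqrt(mean((sol$field$shift_voxels +
                         sol_sw$field$shift_voxels)^2)), 0.1)
  # identical composites give (essentially) no field
  sol_id <- estimate_field(list(f_up = pair$f_up, f_down = pair$f_up,
                                pe_axis = pair$pe_axis))
  expect_lt(max(abs(sol_id$field$shift_voxels)), 0.05)
  # infinite regularization forces the field to zero
  sol_reg <- estimate_field(pair, estimation_schedule(lambdas = c(1e6, 1e6, 1e6)))
  expect_lt(max(abs(sol_reg$field$shift_voxels)), 0.05)
})

test_that("schedules are validated", {
  expect_error(estimation_schedule(subsample_factors = c(1, 2, 4)),
               "non-increasing")
  expect_error(estimation_schedule(lambdas = c(1, 2)), "equal length")
  expect_error(estimation_schedule(lambdas = c(0, 1, 1)), "positive")
})
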