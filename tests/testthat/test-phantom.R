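test_that("gamma_variate is a normalized bolus curve", {
  expect_equal(gamma_variate(2, t0 = 2, alpha = 3, beta = 2.5), 0)
  expect_equal(gamma_variate(0, t0 = 2, alpha = 3, beta = 2.5), 0)
  # peak of 1 at t0 + alpha * beta
  expect_equal(gamma_variate(2 + 7.5, t0 = 2, alpha = 3, beta = 2.5), 1)
  # closed form ((t / (alpha beta))^alpha exp(alpha - t / beta))
  expect_equal(gamma_variate(3, 0, alpha = 2, beta = 3),
               (3 / 6)^2 * exp(2 - 1))
  tt <- seq(0, 30, by = 0.1)
  v <- gamma_variate(tt, 2, 3, 2.5)
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
  expect_error(gamma_variate(1, 0, -1, 2), "positive")
  expect_error(gamma_variate(1, 0, 2, 0), "positive")
})

test_that("phantom object is deterministic with a signal-free lumen", {
  p <- acq_params()
  o1 <- make_phantom_object(p, seed = 4)
  o2 <- make_phantom_object(p, seed = 4)
  expect_identical(o1$intensity, o2$intensity)
  expect_false(identical(o1$intensity, make_phantom_object(p, seed = 5)$intensity))
  expect_true(all(o1$intensity >= 0 & o1$intensity <= 1))
  expect_identical(o1$mask, o1$intensity > 0)
  g <- o1$geometry
  zmid <- round(mean(g$z_range))
  expect_equal(o1$intensity[round(g$heart_center[1]), round(g$heart_center[2]),
                            zmid], 0)
  # voxel count close to the analytic ellipsoid-minus-lumen volume
  v_ell <- 4 / 3 * pi * prod(g$chest_semiaxes)
  v_lumen <- pi * g$r_inner^2 * (diff(g$z_range) + 1)
  expect_equal(sum(o1$mask), v_ell - v_lumen, tolerance = 0.10)
  expect_error(make_phantom_object(acq_params(matrix_size = c(16, 3, 6),
                                              fov_mm = c(32, 6, 24))),
               "degenerate")
})

test_that("generated studies follow the kinetics and the field", {
  # zero field / shift / noise: polarities differ only by the half-frame
  # kinetic offset
  st <- quiet_study(seed = 2, noise_sigma = 0,
                    field_model = list(type = "zero", amplitude_hz = 0),
                    bulk_shift_voxels = c(0, 0, 0))
  k_up <- st$truth$kinetics_up; k_down <- st$truth$kinetics_down
  t <- 10; m <- 1
  expect_equal(st$up$data[, , , t, m] / k_up[t, m],
               st$down$data[, , , t, m] / k_down[t, m], tolerance = 1e-12)
  # determinism
  st2 <- quiet_study(seed = 2, noise_sigma = 0,
                     field_model = list(type = "zero", amplitude_hz = 0),
                     bulk_shift_voxels = c(0, 0, 0))
  expect_identical(st$up$data, st2$up$data)
  # uniform 2-voxel field translates the polarities apart by 4 voxels
  stu <- quiet_study(seed = 2, noise_sigma = 0,
                     field_model = list(type = "uniform", amplitude_hz = 30),
                     bulk_shift_voxels = c(0, 0, 0))
  ku <- stu$truth$kinetics_up[10, 1]; kd <- stu$truth$kinetics_down[10, 1]
  up <- stu$up$data[, , , 10, 1] / ku
  down <- stu$down$data[, , , 10, 1] / kd
  expect_equal(up[, 1:12, ], down[, 5:16, ], tolerance = 1e-10)
  # frame energy is exactly proportional to the kinetic curve (noise-free)
  e <- apply(st$up$data[, , , , 1], 4, sum)
  nz <- k_up[, 1] > 0.01
  ratio <- e[nz] / k_up[nz, 1]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
})

test_that("Rician noise produces the expected background floor", {
  st <- quiet_study(seed = 9)
  # pre-bolus frames (t = 1) are pure noise at sigma = 1
  bg <- c(st$up$data[, , , 1, 1], st$up$data[, , , 1, 2],
          st$up$data[, , , 1, 3])
  expect_gte(length(bg), 1e4)
  expect_equal(mean(bg), sqrt(pi / 2), tolerance = 0.05)
})

test_that("field amplitudes beyond a quarter of the PE axis are rejected", {
  expect_error(phantom_spec(field_model = list(type = "uniform",
                                               amplitude_hz = 90)),
               "out of bounds")
})
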