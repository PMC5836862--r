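test_that("displacement_from_field divides the B0 map by the PE bandwidth", {
  p <- small_params()
  ms <- p$matrix_size
  expect_equal(displacement_from_field(array(0, ms), p)$shift_voxels,
               array(0, ms))
  f <- displacement_from_field(array(30, ms), p)
  expect_true(all(f$shift_voxels == 2))
  # Gaussian bump: elementwise division oracle
  x <- slice.index(array(0, ms), 1)
  b0 <- 45 * exp(-0.5 * ((x - 8) / 3)^2)
  f2 <- displacement_from_field(b0, p)
  expect_equal(f2$shift_voxels, b0 / 15)
  expect_equal(which.max(f2$shift_voxels), which.max(b0))
  expect_equal(max(f2$shift_voxels), 3)
  # errors name the offending axis
  expect_error(displacement_from_field(array(0, c(16, 8, 5)), p), "axis 3")
  bad <- array(0, ms); bad[2, 2, 2] <- NA
  expect_error(displacement_from_field(bad, p), "finite")
})

test_that("distortion matrix reproduces identity and unit index shifts", {
  K0 <- build_distortion_matrix(rep(0, 8), +1)
  expect_equal(K0$entries, diag(8))
  K1 <- build_distortion_matrix(rep(1, 8), +1, jacobian = TRUE)
  # row i reads true position i + 1; last row falls off the field of view
  expect_equal(K1$entries[1:7, ], diag(8)[2:8, ])
  expect_equal(K1$entries[8, ], rep(0, 8))
  expect_error(build_distortion_matrix(rep(9, 8), +1), "unphysical")
  expect_error(build_distortion_matrix(0.5, +1), ">= 2")
})

test_that("jacobian modulation conserves the mass of compressed profiles", {
  n <- 16
  ramp <- (seq_len(n) - 1) / (n - 1)       # linear shift 0 -> 1
  K <- build_distortion_matrix(ramp, +1, jacobian = TRUE)
  out <- as.vector(K$entries %*% rep(2, n))
  # away from the edges the compressed continuous profile integrates to
  # 2 * (1 + slope) per voxel
  a <- 1 / (n - 1)
  expect_equal(sum(out[2:(n - 1)]), 2 * (1 + a) * (n - 2), tolerance = 1e-6)
  # bump vanishing at the column ends (and with |d shift/dx| < 1, so the
  # displacement map stays monotone): constant-profile mass is conserved
  nn <- 32
  bump <- 2.5 * exp(-0.5 * ((seq_len(nn) - 16.5) / 2.2)^2)
  Kb <- build_distortion_matrix(bump, +1, jacobian = TRUE)
  outb <- as.vector(Kb$entries %*% rep(1, nn))
  expect_equal(sum(outb), nn, tolerance = 1e-6)
})

test_that("fast per-column distortion matches the dense matrix oracle", {
  set.seed(11)
  for (n in c(8, 16, 64)) {
    shift <- 2.5 * exp(-0.5 * ((seq_len(n) - n / 2) / (n / 6))^2) +
      0.3 * sin(seq_len(n) / 3)
    col <- abs(rnorm(n))
    for (pol in c(1, -1)) for (jac in c(TRUE, FALSE)) {
      K <- build_distortion_matrix(shift, pol, jac)
      fast <- hpepi:::.distort_mat(matrix(col), matrix(shift), pol, jac,
                                   hpepi:::.diff_matrix(n))
      expect_lt(max(abs(K$entries %*% col - fast)), 1e-10)
    }
  }
})

test_that("apply_distortion honours identity, translation and polarity", {
  p <- small_params()
  ms <- p$matrix_size
  set.seed(7)
  arr <- array(abs(rnorm(prod(c(ms, 2, 3)))), c(ms, 2, 3))
  up <- metabolite_stack(arr, +1, p)
  # zero field is the identity
  zf <- displacement_field(array(0, ms), p$pe_axis)
  expect_equal(apply_distortion(up, zf)$data, arr, tolerance = 1e-12)
  # uniform integer shift is a translation along PE (polarity-signed)
  uf <- displacement_field(array(2, ms), p$pe_axis)
  du <- apply_distortion(up, uf, jacobian = TRUE)
  expect_equal(du$data[, 1:6, , , ], arr[, 3:8, , , ])
  down <- metabolite_stack(arr, -1, p)
  dd <- apply_distortion(down, uf)
  expect_equal(dd$data[, 3:8, , , ], arr[, 1:6, , , ])
  # polarity antisymmetry: field b at +1 == field -b at -1
  x <- slice.index(array(0, ms), 2)
  bf <- displacement_field(1.5 * exp(-0.5 * ((x - 4.5) / 1.5)^2), p$pe_axis)
  nf <- displacement_field(-bf$shift_voxels, p$pe_axis)
  expect_equal(apply_distortion(up, bf)$data,
               apply_distortion(metabolite_stack(arr, -1, p), nf)$data)
  expect_error(apply_distortion(up, displacement_field(array(0, c(4, 4, 4)))),
               "shape")
})
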