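test_that("matrix square roots take the principal branch", {
  expect_equal(unclass(matrix_sqrt(diag(4))), diag(4))
  expect_equal(unclass(matrix_sqrt(diag(c(4, 9, 1, 1)))), diag(c(2, 3, 1, 1)))
  set.seed(41)
  for (i in 1:5) {
    L <- matrix(rnorm(9), 3)
    A <- diag(4)
    A[1:3, 1:3] <- crossprod(L) + diag(3) * 0.5
    A[1:3, 4] <- rnorm(3)
    S <- matrix_sqrt(A)
    expect_lt(max(abs(unclass(S) %*% unclass(S) - A)), 1e-10)
    # eigendecomposition oracle for the principal root
    e <- eigen(A)
    So <- Re(e$vectors %*% diag(sqrt(as.complex(e$values))) %*% solve(e$vectors))
    expect_lt(max(abs(unclass(S) - So)), 1e-8)
    expect_true(all(Re(eigen(unclass(S), only.values = TRUE)$values) >= 0))
  }
  neg <- diag(c(-1, 1, 1, 1))
  expect_error(matrix_sqrt(neg), "negative real axis")
})

test_that("unwarping inverts the forward distortion", {
  p <- acq_params()
  ms <- p$matrix_size
  # adequately sampled (smooth) object at the default geometry and the
  # default 3-voxel bump field
  vol <- gaussian_blur(make_phantom_object(p, seed = 3)$intensity, 4)
  field <- displacement_from_field(hpepi:::.phantom_b0(phantom_spec(seed = 3)), p)
  stack <- metabolite_stack(array(vol, c(ms, 1, 3)), +1, p)
  zf <- displacement_field(array(0, ms), p$pe_axis)
  expect_equal(unwarp_stack(apply_distortion(stack, zf), zf)$data, stack$data)
  interior <- array(FALSE, ms)
  interior[, 3:(ms[2] - 2), ] <- TRUE
  for (pol in c(1, -1)) {
    s <- metabolite_stack(stack$data, pol, p)
    round_trip <- unwarp_stack(apply_distortion(s, field), field)
    expect_equal(round_trip$polarity, 0)
    err <- (round_trip$data[, , , 1, 1] - vol)[interior]
    expect_lt(sqrt(mean(err^2)), 0.01 * max(vol))
  }
  # sharp-edged content still round-trips to within interpolation error
  sharp <- metabolite_stack(array(make_phantom_object(p, seed = 3)$intensity,
                                  c(ms, 1, 3)), +1, p)
  rt_sharp <- unwarp_stack(apply_distortion(sharp, field), field)
  err_sharp <- (rt_sharp$data[, , , 1, 1] - sharp$data[, , , 1, 1])[interior]
  expect_lt(sqrt(mean(err_sharp^2)), 0.08)
  # unwarping both polarities with the shared field shrinks their residual
  up_d <- apply_distortion(metabolite_stack(stack$data, +1, p), field)
  down_d <- apply_distortion(metabolite_stack(stack$data, -1, p), field)
  before <- sqrt(mean((up_d$data - down_d$data)^2))
  after <- sqrt(mean((unwarp_stack(up_d, field)$data -
                        unwarp_stack(down_d, field)$data)^2))
  expect_lt(after, before / 4)
})

test_that("residual translations are registered and inverse-consistent", {
  x <- smooth_test_volume(c(24, 16, 6))
  id <- affine_register(x, x)
  expect_lt(max(abs(unclass(id)[1:3, 4])), 0.05)
  moved <- fourier_shift(x, 2, 1)
  tr <- affine_register(fixed = x, moving = moved)
  expect_equal(unclass(tr)[1, 4], -2, tolerance = 0.1)
  back <- affine_register(fixed = moved, moving = x)
  comp <- unclass(tr) %*% unclass(back)
  expect_lt(max(abs(comp[1:3, 4])), 0.2)
  expect_warning(flat <- affine_register(x, array(0, dim(x))), "flat")
  expect_true(attr(flat, "flat"))
})

test_that("geometric-mean merging meets in the middle and keeps order", {
  p <- small_params()
  ms <- p$matrix_size
  obj <- make_phantom_object(p, seed = 5)$intensity
  arr <- array(rep(obj, 3 * 4), c(ms, 4, 3))
  up <- metabolite_stack(arr, 0, p)
  down <- metabolite_stack(arr * 0.9, 0, p)
  ident <- lapply(1:3, function(i) homogeneous_transform(diag(4)))
  merged <- geometric_mean_merge(up, down, list(c = ident, d = ident))
  expect_equal(dim(merged$data)[4], 8)
  expect_equal(merged$data[, , , c(1, 3, 5, 7), ], arr)
  expect_equal(merged$data[, , , c(2, 4, 6, 8), ], arr * 0.9)
  # opposite 2-voxel translations meet at the midpoint: build a blip-down
  # series whose content sits 2 voxels from the blip-up series
  sh_arr <- arr
  for (t in 1:4) for (m in 1:3)
    sh_arr[, , , t, m] <- fourier_shift(arr[, , , t, m], 2, 1)
  down <- metabolite_stack(pmax(sh_arr, 0) * 0.9, 0, p)
  tp <- lapply(1:3, function(i) translation_transform(c(2, 0, 0)))
  tm <- lapply(1:3, function(i) translation_transform(c(-2, 0, 0)))
  m2 <- geometric_mean_merge(up, down, list(c = tp, d = tm))
  odd <- apply(m2$data[, , , c(1, 3, 5, 7), 1], 1:3, sum)
  even <- apply(m2$data[, , , c(2, 4, 6, 8), 1], 1:3, sum)
  res <- affine_register(fixed = even, moving = odd)
  expect_lt(max(abs(unclass(res)[1:3, 4])), 0.1)
  # sqrt fallback: a reflection in the linear part has no principal root
  refl <- homogeneous_transform(diag(c(-1, 1, 1, 1)))
  bad <- lapply(1:3, function(i) refl)
  suppressWarnings(
    expect_warning(geometric_mean_merge(up, down, list(c = bad, d = bad)),
                   "half-translation"))
  # literal mode applies the composed interpolator to one series only
  lit <- geometric_mean_merge(up, down, list(c = tp, d = tm), mode = "literal")
  expect_equal(lit$data[, , , 1, ], arr[, , , 1, ])
})

test_that("exact inverse pairs compose the interpolator to identity", {
  set.seed(43)
  for (i in 1:5) {
    L <- matrix(rnorm(9), 3)
    C <- diag(4)
    C[1:3, 1:3] <- crossprod(L) + diag(3) * 0.5
    C[1:3, 4] <- rnorm(3)
    D <- solve(C)
    E <- unclass(matrix_sqrt(C)) %*% unclass(matrix_sqrt(D))
    expect_lt(max(abs(E - diag(4))), 1e-8)
  }
})
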