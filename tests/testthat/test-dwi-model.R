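# small synthetic volume set: 3 shells, one b0 each, a few directions
toy_dwi <- function(nx = 4, b0 = list(s1 = 1, s2 = 1, s3 = 1)) {
  gs <- c(nx, nx, nx)
  dirs6 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                 c(0, 1, 1) / sqrt(2))
  bv <- c(0, rep(300, 6), 0, rep(1000, 6), 0, rep(2000, 6))
  dm <- rbind(0, dirs6, 0, dirs6, 0, dirs6)
  sh <- rep(1:3, each = 7)
  scheme <- acquisition_scheme(bv, dm, sh)
  base <- array(runif(prod(gs), 50, 150), dim = gs)
  data <- array(0, dim = c(gs, length(bv)))
  for (j in seq_along(bv)) {
    scale <- unlist(b0)[sh[j]]
    data[, , , j] <- scale * base * exp(-bv[j] * 0.7e-3)
  }
  dwi_volume_set(data, scheme, voxel_size = 2)
}

test_that("calibration is the identity when all shell b0s agree", {
  set.seed(1)
  dwi <- toy_dwi()
  cal <- calibrate_shells(dwi)
  expect_equal(cal$dwi$data, dwi$data, tolerance = 1e-14)
  expect_false(any(cal$qc_undefined))
})

test_that("a doubled shell b0 halves that shell's volumes", {
  set.seed(2)
  dwi <- toy_dwi(b0 = list(s1 = 1, s2 = 2, s3 = 1))
  # overall mean b0 averages shells 2 and 3: (2 + 1) / 2 = 1.5 x base
  cal <- calibrate_shells(dwi)
  tab <- dwi$scheme$table
  for (j in which(tab$shell == 2))
    expect_equal(cal$dwi$data[, , , j], dwi$data[, , , j] * 1.5 / 2,
                 tolerance = 1e-12)
  for (j in which(tab$shell == 1))
    expect_equal(cal$dwi$data[, , , j], dwi$data[, , , j] * 1.5,
                 tolerance = 1e-12)
})

test_that("phantom shell offsets are removed and calibration is idempotent", {
  ph <- build_phantom(default_phantom_spec())
  scheme <- default_acquisition_scheme(shell_scales = c(1.0, 1.1, 0.9))
  dwi <- simulate_dwi(ph, scheme, noise_sd = 0)
  cal <- calibrate_shells(dwi)
  tab <- scheme$table
  b0s <- which(tab$bval == 0)
  mean_b0 <- cal$mean_b0
  ok <- !cal$qc_undefined
  expect_gt(sum(ok), 0)
  for (j in b0s) {
    rel <- abs(cal$dwi$data[, , , j][ok] - mean_b0[ok]) / mean_b0[ok]
    expect_lt(max(rel), 1e-10)
  }
  cal2 <- calibrate_shells(cal$dwi)
  rel2 <- max(abs(cal2$dwi$data - cal$dwi$data) /
                pmax(abs(cal$dwi$data), 1e-300))
  expect_lt(rel2, 1e-12)
})

test_that("voxels with undefined calibration are flagged and passed through", {
  set.seed(3)
  dwi <- toy_dwi()
  dwi$data[1, 1, 1, ] <- 0  # zero mean b0 at this voxel
  cal <- calibrate_shells(dwi)
  expect_true(cal$qc_undefined[1, 1, 1])
  expect_identical(cal$dwi$data[1, 1, 1, ], dwi$data[1, 1, 1, ])
  expect_false(any(cal$qc_undefined[-1, , ]))
})

test_that("tensor fit recovers isotropic and degenerate tensors", {
  scheme <- default_acquisition_scheme(shell_scales = c(1, 1, 1))
  tab <- scheme$table
  gs <- c(2, 2, 2)
  d_iso <- 0.9e-3
  lam <- 1.6e-3
  D_deg <- diag(c(lam, 0, 0))
  data <- array(100, dim = c(gs, nrow(tab)))
  for (j in seq_len(nrow(tab))) {
    g <- c(tab$gx[j], tab$gy[j], tab$gz[j])
    data[1, 1, 1, j] <- 400 * exp(-tab$bval[j] * d_iso)
    data[2, 1, 1, j] <- oracle_tensor_signal(400, tab$bval[j], g, D_deg)
  }
  tf <- fit_tensor(dwi_volume_set(data, scheme, 2))
  expect_lt(abs(tf$fa[1, 1, 1]), 1e-9)
  expect_equal(tf$md[1, 1, 1], d_iso, tolerance = 1e-9)
  # eigenvalues (lambda, 0, 0): fully anisotropic limit
  expect_equal(tf$fa[2, 1, 1], 1, tolerance = 1e-9)
})

test_that("noise-free signals from known tensors are recovered to 1e-8", {
  scheme <- default_acquisition_scheme(shell_scales = c(1, 1, 1))
  tab <- scheme$table
  set.seed(42)
  gs <- c(3, 2, 2)
  tensors <- replicate(prod(gs), {
    A <- matrix(rnorm(9, sd = 0.5), 3)
    D <- crossprod(A) * 1e-3 / 3 + diag(3) * 0.2e-3
    D
  }, simplify = FALSE)
  data <- array(0, dim = c(gs, nrow(tab)))
  for (v in seq_along(tensors)) {
    ijk <- arrayInd(v, gs)
    for (j in seq_len(nrow(tab))) {
      g <- c(tab$gx[j], tab$gy[j], tab$gz[j])
      data[ijk[1], ijk[2], ijk[3], j] <-
        oracle_tensor_signal(800, tab$bval[j], g, tensors[[v]])
    }
  }
  tf <- fit_tensor(dwi_volume_set(data, scheme, 2))
  for (v in seq_along(tensors)) {
    ijk <- arrayInd(v, gs)
    fitted <- tensor_matrix_from_fit(tf, ijk)
    expect_equal(fitted, tensors[[v]], tolerance = 1e-8)
    ref <- oracle_fa_md(tensors[[v]])
    expect_equal(tf$fa[ijk[1], ijk[2], ijk[3]], ref$fa, tolerance = 1e-8)
    expect_equal(tf$md[ijk[1], ijk[2], ijk[3]], ref$md, tolerance = 1e-8)
  }
  expect_true(all(tf$fa[tf$fit_ok] >= 0 & tf$fa[tf$fit_ok] <= 1))
})

test_that("FA is invariant to a global positive rescaling of the signals", {
  ph <- build_phantom(default_phantom_spec())
  scheme <- default_acquisition_scheme(shell_scales = c(1, 1, 1))
  dwi <- simulate_dwi(ph, scheme, noise_sd = 0)
  m <- array(FALSE, dim = ph$spec$grid_shape)
  m[which(ph$wm_mask)[seq(1, 60, by = 7)]] <- TRUE
  tf1 <- fit_tensor(dwi, mask = m)
  dwi$data <- dwi$data * 3.7
  tf2 <- fit_tensor(dwi, mask = m)
  expect_equal(tf1$fa[m], tf2$fa[m], tolerance = 1e-10)
})

test_that("rank-deficient gradient schemes are rejected with named components", {
  bv <- c(0, rep(1000, 7))
  dm <- rbind(0, matrix(rep(c(0, 0, 1), 7), ncol = 3, byrow = TRUE))
  scheme <- acquisition_scheme(bv, dm, rep(1, 8))
  data <- array(100, dim = c(2, 2, 2, 8))
  expect_error(fit_tensor(dwi_volume_set(data, scheme, 2)),
               "rank-deficient")
})

test_that("peak extraction returns principal directions above the floor", {
  spec <- phantom_spec(
    grid_shape = c(12, 12, 12), voxel_size = 2,
    bundles = list(bundle_spec("v", "left", rbind(c(5, 13, 3), c(5, 13, 21)),
                               radius = 2.2, volume_fraction = 1.0)))
  ph <- build_phantom(spec)
  dwi <- simulate_dwi(ph, default_acquisition_scheme(c(1, 1, 1)), noise_sd = 0)
  tf <- fit_tensor(dwi)
  field <- extract_peaks(tf, amplitude_floor = 0.1)
  validate_orientation_field(field)
  n3 <- prod(spec$grid_shape)
  vox <- which(ph$bundle_masks$v)
  # angular error below 1 degree (up to sign)
  for (v in vox[c(1, 10, 20)]) {
    d <- field$directions[v + n3 * (0 + 3 * (0:2))]
    ang <- acos(pmin(1, abs(d[3]))) * 180 / pi
    expect_lt(ang, 1)
    expect_gt(field$amplitudes[v], 0.1)
  }
  # isotropic voxels carry no population
  iso <- which(ph$csf_mask)[1:5]
  expect_true(all(field$amplitudes[iso] == 0))
})
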