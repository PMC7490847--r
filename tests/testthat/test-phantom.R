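test_that("bundle rasterization carries tangent directions and amplitudes", {
  spec <- phantom_spec(
    grid_shape = c(16, 16, 16), voxel_size = 2,
    bundles = list(bundle_spec("v", "left", rbind(c(9, 17, 3), c(9, 17, 29)),
                               radius = 2.5, volume_fraction = 0.6)))
  ph <- build_phantom(spec)
  vox <- which(ph$bundle_masks$v)
  expect_gt(length(vox), 0)
  n3 <- prod(spec$grid_shape)
  # exactly one population with direction (0, 0, 1)
  expect_true(all(ph$field$amplitudes[vox] == 0.6))
  expect_true(all(ph$field$amplitudes[vox + n3] == 0))
  expect_true(all(ph$field$directions[vox + n3 * (0 + 3 * 2)] == 1))
  expect_true(all(ph$field$directions[vox + n3 * (0 + 3 * 0)] == 0))
  # wm/gm/csf partition the grid
  expect_true(all(ph$wm_mask + ph$gm_mask + ph$csf_mask == 1))
})

test_that("crossing voxels carry two orthogonal populations", {
  ph <- build_phantom(default_phantom_spec())
  cross <- ph$bundle_masks$cst_left & ph$bundle_masks$crossing_left
  expect_gt(sum(cross), 0)
  n3 <- prod(ph$spec$grid_shape)
  vox <- which(cross)
  a1 <- ph$field$amplitudes[vox]
  a2 <- ph$field$amplitudes[vox + n3]
  expect_true(all(a1 > 0 & a2 > 0))
  expect_true(all(ph$field$amplitudes[vox + 2 * n3] == 0))
  dots <- sapply(vox, function(v) {
    d1 <- ph$field$directions[v + n3 * (0 + 3 * (0:2))]
    d2 <- ph$field$directions[v + n3 * (1 + 3 * (0:2))]
    sum(d1 * d2)
  })
  expect_true(all(abs(dots) < 1e-12))
})

test_that("a full-severity bundle-targeted lesion zeroes that bundle's amplitudes", {
  spec <- default_phantom_spec(lesions = list(
    lesion_spec(c(25, 41, 41), 6.2, severity = 1.0,
                bundle = "crossing_left", visible = FALSE)))
  ph <- build_phantom(spec)
  cross <- ph$bundle_masks$cst_left & ph$bundle_masks$crossing_left
  n3 <- prod(spec$grid_shape)
  vox <- which(cross)
  # population 2 is the crossing bundle in shared voxels
  expect_true(all(ph$field$amplitudes[vox + n3] == 0))
  # the vertical population is untouched
  expect_true(all(ph$field$amplitudes[vox] == 0.25))
})

test_that("invalid phantom specifications are rejected", {
  cl <- rbind(c(9, 17, 3), c(9, 17, 29))
  expect_error(bundle_spec("b", "left", cl, radius = 2.5,
                           axial_diffusivity = 1e-4,
                           radial_diffusivity = 2e-4), "axial")
  expect_error(lesion_spec(c(0, 0, 0), 2, severity = 1.5), "severity")
  # centerline on the wrong side of the midline
  expect_error(phantom_spec(
    grid_shape = c(16, 16, 16), voxel_size = 2,
    bundles = list(bundle_spec("b", "right", cl, 2.5))), "midline")
  # overlapping volume fractions above 1
  over <- phantom_spec(
    grid_shape = c(16, 16, 16), voxel_size = 2,
    bundles = list(
      bundle_spec("a", "left", cl, 2.5, volume_fraction = 0.7),
      bundle_spec("b", "left", rbind(c(3, 17, 13), c(15, 17, 13)), 2.5,
                  volume_fraction = 0.7)))
  expect_error(build_phantom(over), "volume fractions")
})

test_that("no bundle population is placed on or across the midline", {
  ph <- build_phantom(default_phantom_spec())
  hemi <- hemisphere_labels(ph$spec$grid_shape)
  any_pop <- rowSums(matrix(ph$field$amplitudes,
                            ncol = 3)) > 0
  expect_true(all(hemi[any_pop] != 0))
  # and each bundle stays in its own hemisphere
  expect_true(all(hemi[ph$bundle_masks$cst_left] == -1L))
  expect_true(all(hemi[ph$bundle_masks$cst_right] == 1L))
})

test_that("simulated signals match closed forms and honour shell scales", {
  spec <- phantom_spec(
    grid_shape = c(12, 12, 12), voxel_size = 2,
    bundles = list(bundle_spec("v", "left", rbind(c(5, 13, 3), c(5, 13, 21)),
                               radius = 2.2, volume_fraction = 1.0,
                               axial_diffusivity = 1.7e-3,
                               radial_diffusivity = 0.3e-3)),
    background_iso_diffusivity = 0.8e-3)
  ph <- build_phantom(spec)
  scheme <- default_acquisition_scheme(shell_scales = c(1.0, 1.1, 0.9))
  dwi <- simulate_dwi(ph, scheme, s0 = 500, noise_sd = 0)
  tab <- scheme$table

  # b0 volumes: signal = shell_scale * s0 everywhere
  for (j in which(tab$bval == 0)) {
    sc <- scheme$shell_scales[as.character(tab$shell[j])]
    expect_equal(max(abs(dwi$data[, , , j] - sc * 500)), 0, tolerance = 1e-12)
  }

  # pure isotropic voxel: s0 * exp(-b d)
  iso_vox <- which(ph$csf_mask)[1]
  ijk <- arrayInd(iso_vox, spec$grid_shape)
  for (j in c(2, 10, 80)) {
    sc <- scheme$shell_scales[as.character(tab$shell[j])]
    expect_equal(dwi$data[ijk[1], ijk[2], ijk[3], j],
                 unname(sc) * 500 * exp(-tab$bval[j] * 3.0e-3),
                 tolerance = 1e-12)
  }

  # single-tensor voxel vs independent closed-form oracle
  D <- oracle_axisym_tensor(c(0, 0, 1), 1.7e-3, 0.3e-3)
  bvox <- which(ph$bundle_masks$v)[5]
  ijk <- arrayInd(bvox, spec$grid_shape)
  for (j in seq(2, nrow(tab), by = 17)) {
    g <- c(tab$gx[j], tab$gy[j], tab$gz[j])
    sc <- unname(scheme$shell_scales[as.character(tab$shell[j])])
    expect_equal(dwi$data[ijk[1], ijk[2], ijk[3], j],
                 sc * oracle_tensor_signal(500, tab$bval[j], g, D),
                 tolerance = 1e-12)
  }

  expect_error(simulate_dwi(ph, scheme, s0 = -1), "s0")
  expect_error(simulate_dwi(ph, scheme, noise_sd = -1), "noise_sd")
})

test_that("signal is non-increasing in b along the fibre axis", {
  ph <- build_phantom(default_phantom_spec())
  # axis-aligned scheme with all three shells sampling (0,0,1)
  bv <- c(0, 300, 0, 1000, 0, 2000)
  dirs <- rbind(0, c(0, 0, 1), 0, c(0, 0, 1), 0, c(0, 0, 1))
  scheme <- acquisition_scheme(bv, dirs, c(1, 1, 2, 2, 3, 3))
  dwi <- simulate_dwi(ph, scheme, noise_sd = 0)
  vox <- which(ph$bundle_masks$cst_left)[10]
  ijk <- arrayInd(vox, ph$spec$grid_shape)
  s <- dwi$data[ijk[1], ijk[2], ijk[3], c(1, 2, 4, 6)]
  expect_true(all(diff(s) < 0))
})

test_that("phantom and noise generation are seed-reproducible", {
  ph <- build_phantom(default_phantom_spec())
  sch <- acquisition_scheme(c(0, 1000, 1000), rbind(0, c(1, 0, 0), c(0, 0, 1)),
                            c(1, 1, 1))
  d1 <- simulate_dwi(ph, sch, noise_sd = 20, rng_seed = 11)
  d2 <- simulate_dwi(ph, sch, noise_sd = 20, rng_seed = 11)
  d3 <- simulate_dwi(ph, sch, noise_sd = 20, rng_seed = 12)
  expect_identical(d1$data, d2$data)
  expect_false(identical(d1$data, d3$data))
})

test_that("make_cohort honours group sizes, cutoffs and determinism", {
  cs <- cohort_spec(n_per_group = c(HC = 2, FMS = 2, NFMS = 2), rng_seed = 5)
  co <- make_cohort(cs)
  expect_length(co, 6)
  groups <- vapply(co, `[[`, "", "group")
  expect_identical(groups, c("HC", "HC", "FMS", "FMS", "NFMS", "NFMS"))
  fsmc <- vapply(co, function(s) s$record$fsmc_motor, 0)
  expect_true(all(fsmc[groups == "FMS"] >= 27))
  expect_true(all(fsmc[groups == "NFMS"] < 27))
  expect_true(all(classify_fatigue(fsmc[groups != "HC"]) ==
                    groups[groups != "HC"]))

  co2 <- make_cohort(cs)
  expect_identical(co, co2)

  # zero damage variance and no focal lesions: identical FMS phantoms
  cs0 <- cohort_spec(n_per_group = c(HC = 2, FMS = 3, NFMS = 2),
                     damage_mean = list(HC = c(0, 0), FMS = c(0.8, 0),
                                        NFMS = c(0, 0.8)),
                     damage_sd = 0, lesion_rate = 0, rng_seed = 2)
  co0 <- make_cohort(cs0)
  fms <- co0[vapply(co0, `[[`, "", "group") == "FMS"]
  amps <- lapply(fms, function(s) build_phantom(s$spec)$field$amplitudes)
  expect_identical(amps[[1]], amps[[2]])
  expect_identical(amps[[1]], amps[[3]])
})
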