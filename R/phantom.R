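#' Bundle specification
#'
#' Describes one fibre bundle of a synthetic two-hemisphere phantom: a tube
#' of given radius around a polyline centerline, carrying a single fibre
#' population with axially symmetric tensor diffusivities.
#'
#' @param name Bundle name (unique within a phantom).
#' @param hemisphere `"left"` or `"right"`; all centerline points must lie
#'   strictly on that side of the mid-sagittal voxel plane.
#' @param centerline Numeric matrix (n x 3) of world-mm points.
#' @param radius Tube radius in mm.
#' @param axial_diffusivity,radial_diffusivity Compartment diffusivities in
#'   mm^2/s; axial must be >= radial > 0.
#' @param volume_fraction Fraction of the voxel signal carried by this
#'   bundle, in (0, 1]. Within a voxel, population amplitude equals the
#'   volume fraction (before lesion scaling).
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, hemisphere, centerline, radius,
                        axial_diffusivity = 1.9e-3,
                        radial_diffusivity = 0.2e-3,
                        volume_fraction = 0.5) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("centerline must be an n x 3 matrix with n >= 2")
  if (!(radius > 0)) stop("radius must be positive")
  if (!(axial_diffusivity >= radial_diffusivity && radial_diffusivity > 0))
    stop("need axial_diffusivity >= radial_diffusivity > 0")
  if (!(volume_fraction > 0 && volume_fraction <= 1))
    stop("volume_fraction must lie in (0, 1]")
  structure(list(name = name, hemisphere = hemisphere,
                 centerline = centerline, radius = radius,
                 axial_diffusivity = axial_diffusivity,
                 radial_diffusivity = radial_diffusivity,
                 volume_fraction = volume_fraction),
            class = "bundle_spec")
}

#' Lesion specification
#'
#' A spherical region in which fibre amplitudes are reduced by `severity`
#' and replaced by an isotropic compartment.  A lesion may target a single
#' named bundle (emulating tract-specific axonal degeneration) or all
#' populations.  Visible lesions enter the binary lesion mask used for NAWM
#' exclusion and lesion-load accounting; invisible lesions model diffuse
#' damage in normal-appearing tissue.
#'
#' @param center World-mm coordinates (length 3).
#' @param radius Sphere radius in mm.
#' @param severity Fraction of the local fibre amplitude removed, in [0, 1].
#' @param bundle Optional bundle name; `NULL` scales every population.
#' @param visible Logical; whether the lesion appears in the lesion mask.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, severity, bundle = NULL,
                        visible = TRUE) {
  if (length(center) != 3L) stop("center must have length 3")
  if (!(radius > 0)) stop("radius must be positive")
  if (!(severity >= 0 && severity <= 1)) stop("severity must lie in [0, 1]")
  structure(list(center = as.numeric(center), radius = radius,
                 severity = severity, bundle = bundle,
                 visible = isTRUE(visible)),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' @param grid_shape Voxel counts per axis (all >= 8).  The mid-sagittal
#'   plane is the single voxel column at x index `grid_shape[1] %/% 2`
#'   (0-based).
#' @param voxel_size Voxel edge lengths in mm.
#' @param bundles List of [bundle_spec()] objects.
#' @param lesions List of [lesion_spec()] objects.
#' @param background_iso_diffusivity Isotropic diffusivity (mm^2/s) of the
#'   non-fibre tissue compartment.
#' @param csf_diffusivity Isotropic diffusivity of CSF voxels.
#' @param rng_seed Integer seed recorded with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         voxel_size = c(2, 2, 2),
                         bundles = list(), lesions = list(),
                         background_iso_diffusivity = 0.6e-3,
                         csf_diffusivity = 3.0e-3,
                         rng_seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must have three entries, all >= 8")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  stopifnot(all(vapply(bundles, inherits, TRUE, "bundle_spec")),
            all(vapply(lesions, inherits, TRUE, "lesion_spec")))
  spec <- structure(list(grid_shape = grid_shape,
                         voxel_size = as.numeric(voxel_size),
                         bundles = bundles, lesions = lesions,
                         background_iso_diffusivity = background_iso_diffusivity,
                         csf_diffusivity = csf_diffusivity,
                         rng_seed = rng_seed),
                    class = "phantom_spec")
  mid <- midline_index(grid_shape)
  for (b in bundles) {
    x <- b$centerline[, 1]
    lim <- c(mid * spec$voxel_size[1], (mid + 1) * spec$voxel_size[1])
    ok <- if (b$hemisphere == "left") all(x < lim[1]) else all(x > lim[2])
    if (!ok)
      stop(sprintf("bundle '%s' centerline crosses onto the %s of the midline",
                   b$name, "wrong side"))
  }
  spec
}

# 0-based x index of the mid-sagittal voxel column
midline_index <- function(grid_shape) as.integer(grid_shape[1] %/% 2L)

#' Hemisphere labels for a grid
#'
#' Integer array with -1 on the left of the mid-sagittal voxel column, 0 on
#' the column itself and +1 on the right.  The labels partition the grid.
#'
#' @param grid_shape Voxel counts per axis.
#' @return Integer array of dimension `grid_shape`.
#' @export
hemisphere_labels <- function(grid_shape) {
  mid <- midline_index(grid_shape)
  ix <- seq_len(grid_shape[1]) - 1L
  lab <- ifelse(ix < mid, -1L, ifelse(ix == mid, 0L, 1L))
  array(rep(lab, times = grid_shape[2] * grid_shape[3]), dim = grid_shape)
}

# voxel centres along one axis, world mm (0-based voxel i at (i + 0.5) * vs)
axis_centres <- function(n, vs) (seq_len(n) - 0.5) * vs

# minimum distance from every voxel centre to a polyline; returns an array
dist_to_polyline <- function(grid_shape, voxel_size, centerline) {
  cx <- axis_centres(grid_shape[1], voxel_size[1])
  cy <- axis_centres(grid_shape[2], voxel_size[2])
  cz <- axis_centres(grid_shape[3], voxel_size[3])
  px <- array(rep(cx, times = grid_shape[2] * grid_shape[3]), dim = grid_shape)
  py <- array(rep(rep(cy, each = grid_shape[1]), times = grid_shape[3]),
              dim = grid_shape)
  pz <- array(rep(cz, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
  d2 <- array(Inf, dim = grid_shape)
  tangent_ix <- array(1L, dim = grid_shape)
  for (s in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[s, ]; b <- centerline[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dd <- (px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2 +
      (pz - a[3] - t * ab[3])^2
    upd <- dd < d2
    d2[upd] <- dd[upd]
    tangent_ix[upd] <- s
  }
  list(dist = sqrt(d2), segment = tangent_ix)
}

#' Construct an orientation field
#'
#' Low-level constructor for a per-voxel fibre population field: up to three
#' populations per voxel, each a unit direction with a non-negative
#' amplitude.
#'
#' @param grid_shape,voxel_size Grid geometry.
#' @param amplitudes Array `(nx, ny, nz, 3)` of population amplitudes.
#' @param directions Array `(nx, ny, nz, 3, 3)`; last index is the xyz
#'   component.
#' @param wm_mask Logical array of white-matter voxels.
#' @param ad,rd Optional per-population diffusivity arrays (needed only for
#'   signal simulation).
#' @param iso_diffusivity Scalar or array of the isotropic compartment
#'   diffusivity.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(grid_shape, voxel_size, amplitudes, directions,
                              wm_mask, ad = NULL, rd = NULL,
                              iso_diffusivity = 0.6e-3) {
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  f <- structure(list(grid_shape = grid_shape,
                      voxel_size = as.numeric(voxel_size),
                      amplitudes = amplitudes, directions = directions,
                      wm_mask = wm_mask,
                      hemi = hemisphere_labels(grid_shape),
                      ad = ad, rd = rd,
                      iso_diffusivity = iso_diffusivity),
                 class = "orientation_field")
  validate_orientation_field(f)
  f
}

#' Validate an orientation field
#'
#' Checks the structural invariants: array shapes, at most three
#' populations, non-negative amplitudes, unit-norm directions wherever the
#' amplitude is positive, and hemisphere labels partitioning the grid.
#'
#' @param field An `orientation_field`.
#' @return The field, invisibly; errors on violation.
#' @export
validate_orientation_field <- function(field) {
  gs <- field$grid_shape
  if (!identical(dim(field$amplitudes), c(gs, 3L)))
    stop("amplitudes must have dimension (nx, ny, nz, 3)")
  if (!identical(dim(field$directions), c(gs, 3L, 3L)))
    stop("directions must have dimension (nx, ny, nz, 3, 3)")
  if (any(field$amplitudes < 0)) stop("amplitudes must be non-negative")
  nrm2 <- field$directions[, , , , 1]^2 + field$directions[, , , , 2]^2 +
    field$directions[, , , , 3]^2
  live <- field$amplitudes > 0
  if (any(abs(sqrt(nrm2[live]) - 1) >= 1e-9))
    stop("directions with positive amplitude must have unit norm")
  if (!all(field$hemi %in% c(-1L, 0L, 1L)))
    stop("hemisphere labels must be -1, 0 or 1")
  invisible(field)
}

#' Build a synthetic two-hemisphere phantom
#'
#' Rasterizes the bundle tubes of a [phantom_spec()] into an orientation
#' field, applies lesions, and derives tissue masks.  Voxels within a
#' bundle's radius carry that bundle's tangent direction with amplitude
#' equal to its volume fraction; overlapping bundles contribute one
#' population each (their volume fractions must not sum above 1).  Lesions
#' multiply the targeted amplitudes by `1 - severity`.  No population is
#' ever placed on the mid-sagittal plane or the contralateral side.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `field`
#'   (an `orientation_field`), `wm_mask`, `gm_mask`, `csf_mask`,
#'   `lesion_mask`, per-bundle masks in `bundle_masks`, and the `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vs <- spec$voxel_size
  hemi <- hemisphere_labels(gs)
  nb <- length(spec$bundles)
  if (nb == 0L) stop("phantom needs at least one bundle")

  amp <- array(0, dim = c(gs, 3L))
  dirs <- array(0, dim = c(gs, 3L, 3L))
  ad <- array(0, dim = c(gs, 3L))
  rd <- array(0, dim = c(gs, 3L))
  npop <- array(0L, dim = gs)
  vf_sum <- array(0, dim = gs)
  bundle_masks <- vector("list", nb)
  names(bundle_masks) <- vapply(spec$bundles, `[[`, "", "name")
  pop_bundle <- array(0L, dim = c(gs, 3L))  # which bundle owns population p

  for (bi in seq_len(nb)) {
    b <- spec$bundles[[bi]]
    dp <- dist_to_polyline(gs, vs, b$centerline)
    side <- if (b$hemisphere == "left") -1L else 1L
    inside <- dp$dist <= b$radius & hemi == side
    bundle_masks[[bi]] <- inside
    if (!any(inside)) next
    if (any(npop[inside] >= 3L))
      stop("more than 3 bundle populations in one voxel")
    vf_sum[inside] <- vf_sum[inside] + b$volume_fraction
    if (any(vf_sum > 1 + 1e-12))
      stop(sprintf("summed volume fractions exceed 1 where bundle '%s' overlaps others",
                   b$name))
    # per-segment unit tangents
    tang <- diff(b$centerline)
    tang <- tang / sqrt(rowSums(tang^2))
    idx <- which(inside)
    slot <- npop[idx] + 1L
    n3 <- prod(gs)
    amp[idx + n3 * (slot - 1L)] <- b$volume_fraction
    ad[idx + n3 * (slot - 1L)] <- b$axial_diffusivity
    rd[idx + n3 * (slot - 1L)] <- b$radial_diffusivity
    pop_bundle[idx + n3 * (slot - 1L)] <- bi
    seg <- dp$segment[idx]
    for (c in 1:3)
      dirs[idx + n3 * ((slot - 1L) + 3L * (c - 1L))] <- tang[seg, c]
    npop[idx] <- npop[idx] + 1L
  }

  wm <- npop > 0L
  lesion_mask <- array(FALSE, dim = gs)
  bnames <- names(bundle_masks)
  for (les in spec$lesions) {
    cl <- matrix(rep(les$center, 2), nrow = 2, byrow = TRUE)
    cl[2, 1] <- cl[2, 1] + 1e-9
    d <- dist_to_polyline(gs, vs, cl)$dist
    sphere <- d <= les$radius & wm
    if (!any(sphere)) next
    if (is.null(les$bundle)) {
      target <- rep(TRUE, 3L)
      sel <- which(sphere)
      for (p in 1:3) {
        pidx <- sel + prod(gs) * (p - 1L)
        amp[pidx] <- amp[pidx] * (1 - les$severity)
      }
      if (les$visible) lesion_mask <- lesion_mask | sphere
    } else {
      bi <- match(les$bundle, bnames)
      if (is.na(bi)) stop(sprintf("lesion targets unknown bundle '%s'", les$bundle))
      sel <- which(sphere)
      for (p in 1:3) {
        pidx <- sel + prod(gs) * (p - 1L)
        hit <- pop_bundle[pidx] == bi
        amp[pidx[hit]] <- amp[pidx[hit]] * (1 - les$severity)
      }
      if (les$visible) lesion_mask <- lesion_mask | (sphere & bundle_masks[[bi]])
    }
  }

  iso <- array(spec$background_iso_diffusivity, dim = gs)
  # grey matter: one-voxel 6-neighbour shell around WM; CSF: everything else
  gm <- dilate6(wm) & !wm
  csf <- !wm & !gm
  iso[csf] <- spec$csf_diffusivity

  field <- orientation_field(gs, vs, amp, dirs, wm, ad = ad, rd = rd,
                             iso_diffusivity = iso)
  structure(list(field = field, wm_mask = wm, gm_mask = gm, csf_mask = csf,
                 lesion_mask = lesion_mask, bundle_masks = bundle_masks,
                 spec = spec),
            class = "phantom")
}

# 6-connected binary dilation
dilate6 <- function(m) {
  d <- m
  n <- dim(m)
  d[-1, , ] <- d[-1, , ] | m[-n[1], , ]
  d[-n[1], , ] <- d[-n[1], , ] | m[-1, , ]
  d[, -1, ] <- d[, -1, ] | m[, -n[2], ]
  d[, -n[2], ] <- d[, -n[2], ] | m[, -1, ]
  d[, , -1] <- d[, , -1] | m[, , -n[3]]
  d[, , -n[3]] <- d[, , -n[3]] | m[, , -1]
  d
}

#' Default crossing-fibre phantom specification
#'
#' The reference geometry used throughout the package: a 40x40x40 grid at
#' 2 mm isotropic resolution holding, per hemisphere, a vertical
#' corticospinal-tract-like bundle spanning most of the z extent and a
#' shorter horizontal bundle crossing it orthogonally at mid-height
#' (emulating association fibres such as the superior longitudinal
#' fascicle).  The crossing bundle carries the larger volume fraction, so
#' that in crossing voxels the association population dominates the fibre
#' orientation distribution.
#'
#' @param lesions Optional list of [lesion_spec()] objects.
#' @param rng_seed Seed recorded with the spec.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(lesions = list(), rng_seed = NULL) {
  vcl <- function(x) rbind(c(x, 41, 9), c(x, 41, 71))
  hcl <- function(x1, x2) rbind(c(x1, 41, 41), c(x2, 41, 41))
  bundles <- list(
    bundle_spec("cst_left", "left", vcl(25), radius = 3.2,
                volume_fraction = 0.25),
    bundle_spec("crossing_left", "left", hcl(23, 27), radius = 3.2,
                volume_fraction = 0.75),
    bundle_spec("cst_right", "right", vcl(57), radius = 3.2,
                volume_fraction = 0.25),
    bundle_spec("crossing_right", "right", hcl(55, 59), radius = 3.2,
                volume_fraction = 0.75))
  phantom_spec(bundles = bundles, lesions = lesions, rng_seed = rng_seed)
}

#' Synthetic tract-probability map for a bundle
#'
#' Produces a smooth probability map emulating a probabilistic tract atlas:
#' `p = exp(-d^2 / (2 sigma^2))` with `d` the distance to the bundle
#' centerline, clipped to the bundle's hemisphere.  With the default
#' `sigma = radius / 2`, probability exceeds 10% out to roughly the bundle
#' radius.
#'
#' @param spec A [phantom_spec()].
#' @param bundle Name of the bundle.
#' @param sigma Gaussian width in mm; defaults to half the bundle radius.
#' @return Probability array in [0, 1].
#' @export
tract_probability_map <- function(spec, bundle, sigma = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  bi <- match(bundle, vapply(spec$bundles, `[[`, "", "name"))
  if (is.na(bi)) stop(sprintf("unknown bundle '%s'", bundle))
  b <- spec$bundles[[bi]]
  if (is.null(sigma)) sigma <- b$radius / 2
  d <- dist_to_polyline(spec$grid_shape, spec$voxel_size, b$centerline)$dist
  p <- exp(-d^2 / (2 * sigma^2))
  side <- if (b$hemisphere == "left") -1L else 1L
  p[hemisphere_labels(spec$grid_shape) != side] <- 0
  p
}

#' Simulate multi-shell diffusion-weighted signals
#'
#' Forward multi-tensor mixture: per voxel the signal for gradient `g` at
#' b-value `b` is
#' `shell_scale * s0 * (sum_k a_k exp(-b g' D_k g) + f_iso exp(-b d_iso))`
#' with `f_iso = 1 - sum_k a_k` and axially symmetric population tensors.
#' Optional Rician noise is applied as the magnitude of the signal plus
#' complex Gaussian noise.
#'
#' @param phantom A `phantom` (or an `orientation_field` carrying `ad`/`rd`).
#' @param scheme An [acquisition_scheme()].
#' @param s0 Baseline signal amplitude.
#' @param noise_sd Rician noise sigma, in signal units (0 = noise-free).
#' @param rng_seed Optional seed for the noise draw.
#' @return An object of class `dwi_volume_set`.
#' @export
simulate_dwi <- function(phantom, scheme, s0 = 1000, noise_sd = 0,
                         rng_seed = NULL) {
  field <- if (inherits(phantom, "phantom")) phantom$field else phantom
  stopifnot(inherits(field, "orientation_field"),
            inherits(scheme, "acquisition_scheme"))
  if (is.null(field$ad) || is.null(field$rd))
    stop("field carries no per-population diffusivities; simulate from a built phantom")
  if (s0 < 0) stop("s0 must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  gs <- field$grid_shape
  tab <- scheme$table
  nvol <- nrow(tab)
  iso_frac <- pmax(0, 1 - rowSumsPop(field$amplitudes))
  iso_d <- field$iso_diffusivity
  if (length(iso_d) == 1L) iso_d <- array(iso_d, dim = gs)

  data <- array(0, dim = c(gs, nvol))
  n3 <- prod(gs)
  for (j in seq_len(nvol)) {
    b <- tab$bval[j]
    g <- c(tab$gx[j], tab$gy[j], tab$gz[j])
    sig <- iso_frac * exp(-b * iso_d)
    for (p in 1:3) {
      a <- field$amplitudes[, , , p]
      if (!any(a > 0)) next
      dotg <- field$directions[, , , p, 1] * g[1] +
        field$directions[, , , p, 2] * g[2] +
        field$directions[, , , p, 3] * g[3]
      adc <- field$rd[, , , p] + (field$ad[, , , p] - field$rd[, , , p]) * dotg^2
      sig <- sig + a * exp(-b * adc)
    }
    scale <- scheme$shell_scales[as.character(tab$shell[j])]
    data[, , , j] <- scale * s0 * sig
  }
  if (noise_sd > 0) {
    n1 <- array(rnorm(length(data), 0, noise_sd), dim = dim(data))
    n2 <- array(rnorm(length(data), 0, noise_sd), dim = dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  dwi_volume_set(data, scheme, field$voxel_size)
}

rowSumsPop <- function(a) a[, , , 1] + a[, , , 2] + a[, , , 3]

#' Cohort specification
#'
#' Group structure for synthetic cohorts.  Each patient group receives
#' crossing-bundle damage drawn around a per-hemisphere group mean
#' (modelling diffuse degeneration of fibres crossing the corticospinal
#' tract), plus a random number of focal visible lesions whose left/right
#' placement varies between subjects.
#'
#' @param n_per_group Named integer vector with entries `HC`, `FMS`, `NFMS`
#'   (each >= 2).
#' @param damage_mean Named list of length-2 numeric vectors
#'   `c(left, right)` of mean crossing-bundle damage severity per group.
#' @param damage_sd Between-subject standard deviation of the severity
#'   (draws are clipped to [0, 1]).
#' @param lesion_rate Poisson mean of the focal-lesion count per patient
#'   (healthy controls receive none).
#' @param lesion_radius,lesion_severity Focal lesion geometry.
#' @param rng_seed Integer seed; the whole cohort is a deterministic
#'   function of the spec and this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 12L, FMS = 15L, NFMS = 12L),
                        damage_mean = list(HC = c(0, 0),
                                           FMS = c(0.85, 0.10),
                                           NFMS = c(0.10, 0.85)),
                        damage_sd = 0.10,
                        lesion_rate = 3,
                        lesion_radius = 1.2,
                        lesion_severity = 0.95,
                        rng_seed = 1L) {
  stopifnot(all(c("HC", "FMS", "NFMS") %in% names(n_per_group)),
            all(n_per_group >= 2L),
            all(unlist(damage_mean) >= 0), all(unlist(damage_mean) <= 1),
            damage_sd >= 0)
  structure(list(n_per_group = n_per_group, damage_mean = damage_mean,
                 damage_sd = damage_sd, lesion_rate = lesion_rate,
                 lesion_radius = lesion_radius,
                 lesion_severity = lesion_severity, rng_seed = rng_seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject phantom variants and covariate records from a
#' [cohort_spec()].  Crossing-bundle damage severities are sampled per
#' hemisphere around the group mean; motor-fatigue questionnaire scores
#' (FSMC motor subscale, range 10-50) are generated to increase with
#' left-hemisphere crossing damage and are consistent with the clinical
#' cutoff: fatigued (FMS) subjects score >= 27, non-fatigued (NFMS)
#' subjects below.  Patients additionally receive focal visible lesions
#' placed at random along the bundles, with subject-specific left/right
#' imbalance.
#'
#' @param cspec A [cohort_spec()].
#' @param pspec Base [phantom_spec()]; must contain bundles named
#'   `cst_left`, `cst_right`, `crossing_left`, `crossing_right` (as
#'   produced by [default_phantom_spec()]).
#' @return A list of subjects; each has `id`, `group`, `spec` (the phantom
#'   variant), `damage` (left/right severities), `tracking_seed`, and a
#'   one-row data frame `record` of covariates.
#' @export
make_cohort <- function(cspec, pspec = default_phantom_spec()) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(pspec, "phantom_spec"))
  set.seed(cspec$rng_seed)
  bn <- vapply(pspec$bundles, `[[`, "", "name")
  need <- c("cst_left", "cst_right", "crossing_left", "crossing_right")
  if (!all(need %in% bn))
    stop("base phantom must contain cst and crossing bundles per hemisphere")
  cross_centre <- list(
    left = colMeans(pspec$bundles[[match("crossing_left", bn)]]$centerline),
    right = colMeans(pspec$bundles[[match("crossing_right", bn)]]$centerline))
  cross_b <- pspec$bundles[[match("crossing_left", bn)]]
  half_len <- sqrt(sum((cross_b$centerline[nrow(cross_b$centerline), ] -
                          cross_b$centerline[1, ])^2)) / 2
  cross_radius <- half_len + cross_b$radius + 1

  subjects <- list()
  sid <- 0L
  for (grp in c("HC", "FMS", "NFMS")) {
    for (q in seq_len(cspec$n_per_group[[grp]])) {
      sid <- sid + 1L
      mu <- cspec$damage_mean[[grp]]
      sev <- pmin(pmax(rnorm(2, mu, cspec$damage_sd), 0), 1)
      lesions <- list()
      if (sev[1] > 0)
        lesions <- c(lesions, list(lesion_spec(cross_centre$left, cross_radius,
                                               sev[1], bundle = "crossing_left",
                                               visible = FALSE)))
      if (sev[2] > 0)
        lesions <- c(lesions, list(lesion_spec(cross_centre$right, cross_radius,
                                               sev[2], bundle = "crossing_right",
                                               visible = FALSE)))
      n_les_left <- 0L; n_les_right <- 0L
      if (grp != "HC" && cspec$lesion_rate > 0) {
        n_les <- max(1L, rpois(1, cspec$lesion_rate))
        p_left <- stats::rbeta(1, 2, 2)
        for (l in seq_len(n_les)) {
          side <- if (runif(1) < p_left) "left" else "right"
          if (side == "left") n_les_left <- n_les_left + 1L
          else n_les_right <- n_les_right + 1L
          host <- pspec$bundles[[match(paste0(sample(c("cst_", "crossing_"), 1),
                                              side), bn)]]
          t <- runif(1)
          a <- host$centerline[1, ]; b <- host$centerline[nrow(host$centerline), ]
          centre <- a + t * (b - a)
          lesions <- c(lesions, list(lesion_spec(centre, cspec$lesion_radius,
                                                 cspec$lesion_severity)))
        }
      }
      age <- round(runif(1, 22, 55), 1)
      sex <- sample(c("F", "M"), 1, prob = c(0.65, 0.35))
      fsmc_raw <- 12 + 30 * sev[1] + rnorm(1, 0, 3)
      fsmc <- switch(grp,
                     HC = round(runif(1, 10, 17)),
                     FMS = round(min(max(fsmc_raw, 27), 50)),
                     NFMS = round(min(max(fsmc_raw, 10), 26)))
      spec_s <- phantom_spec(pspec$grid_shape, pspec$voxel_size,
                             bundles = pspec$bundles, lesions = lesions,
                             background_iso_diffusivity =
                               pspec$background_iso_diffusivity,
                             csf_diffusivity = pspec$csf_diffusivity,
                             rng_seed = pspec$rng_seed)
      record <- data.frame(
        id = sprintf("S%03d", sid), group = grp,
        fsmc_motor = fsmc,
        fsmc_cognitive = round(min(max(fsmc_raw + rnorm(1, 0, 4), 10), 50)),
        fsmc_total = NA_real_,
        bdi = round(pmin(pmax(rnorm(1, if (grp == "HC") 3 else 8, 3), 0), 28)),
        edss = if (grp == "HC") 0 else round(runif(1, 0, 3.5) * 2) / 2,
        age = age, sex = sex,
        n_lesions_left = n_les_left, n_lesions_right = n_les_right,
        stringsAsFactors = FALSE)
      record$fsmc_total <- record$fsmc_motor + record$fsmc_cognitive
      subjects[[sid]] <- list(id = record$id, group = grp, spec = spec_s,
                              damage = c(left = sev[1], right = sev[2]),
                              tracking_seed = sample.int(2^30, 1),
                              record = record)
    }
  }
  subjects
}
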