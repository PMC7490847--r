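#' Tracking parameters
#'
#' Parameters of the probabilistic streamline tracker.  Defaults mirror
#' common probabilistic-tracker defaults: 300 seeds per white-matter voxel,
#' step size half the voxel edge, 45 degrees maximum turn per step, an FOD
#' amplitude threshold of 0.1, and streamline lengths between 4 and 250 mm.
#' Direction sampling is von Mises-Fisher around the selected population
#' direction with concentration `dispersion_kappa`; `Inf` gives the
#' deterministic mode used by enumeration oracles.
#'
#' @param seeds_per_voxel Streamlines launched per white-matter voxel.
#' @param step_size Step length in mm (`NULL`: half the smallest voxel
#'   edge, resolved at tracking time).
#' @param max_turn_angle Maximum angle (degrees) between consecutive steps.
#' @param amplitude_threshold Minimum local maximum population amplitude for
#'   propagation to continue.
#' @param dispersion_kappa von Mises-Fisher concentration (> 0, may be
#'   `Inf`).
#' @param min_length,max_length Retained streamline length bounds in mm.
#' @param rng_seed Optional seed applied before tracking.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(seeds_per_voxel = 300L, step_size = NULL,
                            max_turn_angle = 45, amplitude_threshold = 0.1,
                            dispersion_kappa = 30, min_length = 4,
                            max_length = 250, rng_seed = NULL) {
  if (seeds_per_voxel < 1L) stop("seeds_per_voxel must be >= 1")
  if (!(max_turn_angle > 0 && max_turn_angle < 90))
    stop("max_turn_angle must lie in (0, 90)")
  if (amplitude_threshold < 0) stop("amplitude_threshold must be >= 0")
  if (!(dispersion_kappa > 0)) stop("dispersion_kappa must be positive")
  if (min_length < 0 || max_length <= 0 || max_length < min_length)
    stop("need 0 <= min_length <= max_length")
  structure(list(seeds_per_voxel = as.integer(seeds_per_voxel),
                 step_size = step_size, max_turn_angle = max_turn_angle,
                 amplitude_threshold = amplitude_threshold,
                 dispersion_kappa = dispersion_kappa,
                 min_length = min_length, max_length = max_length,
                 rng_seed = rng_seed),
            class = "tracking_params")
}

resolve_step <- function(params, voxel_size) {
  step <- params$step_size %||% (0.5 * min(voxel_size))
  if (!(step > 0 && step <= min(voxel_size)))
    stop("step_size must lie in (0, min(voxel_size)]")
  step
}

hemi_code <- function(hemisphere) {
  switch(match.arg(hemisphere, c("left", "right")), left = -1L, right = 1L)
}

term_levels <- c("amplitude", "curvature", "mask_exit", "max_length",
                 "midline_excluded")

track_core <- function(field, hemisphere, params, wm_mask, keep) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(params, "tracking_params"))
  wm_mask <- wm_mask %||% field$wm_mask
  code <- hemi_code(hemisphere)
  if (!any(wm_mask & field$hemi == code))
    stop(sprintf("white-matter mask is empty in the %s hemisphere", hemisphere))
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  step <- resolve_step(params, field$voxel_size)
  .track_cpp(field$amplitudes, field$directions,
             array(as.integer(wm_mask), dim = field$grid_shape),
             field$hemi, field$grid_shape, field$voxel_size,
             code, params$seeds_per_voxel, step, params$max_turn_angle,
             params$amplitude_threshold, params$dispersion_kappa,
             params$min_length, params$max_length, keep)
}

#' Track streamlines in one hemisphere
#'
#' Launches `seeds_per_voxel` streamlines from every white-matter voxel of
#' the chosen hemisphere (seed points uniform within the voxel) and
#' propagates each bidirectionally.  At every step the next direction is a
#' von Mises-Fisher draw centred on the amplitude-weighted nearest
#' population direction (weights are amplitude times `|cos|` of the angle
#' to the incoming direction; ties break to the lowest population index),
#' sign-aligned with the incoming direction.  Steps terminate on a local
#' maximum amplitude below threshold, a turn sharper than
#' `max_turn_angle`, exit from the white-matter mask, or exceeding
#' `max_length`.  Any streamline that touches the mid-sagittal plane or the
#' contralateral hemisphere is discarded in full; retained streamlines
#' shorter than `min_length` are also discarded.
#'
#' @param field An `orientation_field`.
#' @param hemisphere `"left"` or `"right"`.
#' @param params A [tracking_params()].
#' @param wm_mask Optional override of the field's white-matter mask.
#' @return A list of class `streamline_set`: `points` (one n x 3 matrix per
#'   streamline, world mm), `seed_voxel` (0-based linear indices),
#'   `terminations` (two-column character matrix), and the launch
#'   bookkeeping (`n_launched`, `n_retained`, `n_midline_excluded`,
#'   `n_below_min_length`).
#' @export
track_unilateral <- function(field, hemisphere, params = tracking_params(),
                             wm_mask = NULL) {
  res <- track_core(field, hemisphere, params, wm_mask, keep = TRUE)
  npts <- res$n_points
  idx <- rep(seq_along(npts), npts)
  pts <- split.data.frame(res$points, idx)
  structure(list(
    points = unname(lapply(pts, as.matrix)),
    seed_voxel = res$seed_voxel,
    terminations = cbind(first = term_levels[res$term_first],
                         last = term_levels[res$term_last]),
    n_launched = res$n_launched, n_retained = res$n_retained,
    n_midline_excluded = res$n_midline_excluded,
    n_below_min_length = res$n_below_min_length,
    counts = res$counts,
    hemisphere = hemisphere, params = params,
    grid_shape = field$grid_shape, voxel_size = field$voxel_size,
    step_size = resolve_step(params, field$voxel_size)),
    class = "streamline_set")
}

#' Count streamline visits into an anatomical connectivity map
#'
#' Each voxel's count is the number of distinct streamlines whose path
#' intersects it: a streamline increments a voxel at most once, and
#' segments are supersampled at half the step spacing so no traversed voxel
#' is missed.
#'
#' @param streamlines A `streamline_set` from [track_unilateral()], or a
#'   bare list of n x 3 point matrices.
#' @param grid_shape,voxel_size Grid geometry (taken from the
#'   `streamline_set` when available).
#' @param hemisphere Tracked hemisphere label stored in the result.
#' @return An object of class `acm_map` with integer `counts` and the
#'   launch bookkeeping.
#' @export
compute_acm <- function(streamlines, grid_shape = NULL, voxel_size = NULL,
                        hemisphere = NULL) {
  if (inherits(streamlines, "streamline_set")) {
    grid_shape <- grid_shape %||% streamlines$grid_shape
    voxel_size <- voxel_size %||% streamlines$voxel_size
    hemisphere <- hemisphere %||% streamlines$hemisphere
    pts <- streamlines$points
    book <- streamlines[c("n_launched", "n_retained", "n_midline_excluded",
                          "n_below_min_length")]
    params <- streamlines$params
    spacing <- streamlines$step_size
  } else {
    pts <- streamlines
    if (is.null(grid_shape) || is.null(voxel_size))
      stop("grid_shape and voxel_size are required for bare streamline lists")
    book <- list(n_launched = length(pts), n_retained = length(pts),
                 n_midline_excluded = 0, n_below_min_length = 0)
    params <- NULL
    spacing <- 0.5 * min(voxel_size)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(pts)) {
    allpts <- do.call(rbind, pts)
    counts <- .count_visits_cpp(allpts, vapply(pts, nrow, 0L),
                                as.integer(grid_shape),
                                as.numeric(voxel_size), spacing)
  } else {
    counts <- array(0L, dim = grid_shape)
  }
  acm_map(counts, hemisphere, book, params)
}

acm_map <- function(counts, hemisphere, book, params) {
  structure(c(list(counts = counts, hemisphere = hemisphere, params = params),
              book),
            class = "acm_map")
}

#' Track one hemisphere and count visits in one pass
#'
#' Equivalent to [track_unilateral()] followed by [compute_acm()], without
#' materialising streamline coordinates; this is the form used for
#' full-size runs.
#'
#' @inheritParams track_unilateral
#' @return An `acm_map`.
#' @export
track_acm <- function(field, hemisphere, params = tracking_params(),
                      wm_mask = NULL) {
  res <- track_core(field, hemisphere, params, wm_mask, keep = FALSE)
  acm_map(res$counts, hemisphere,
          res[c("n_launched", "n_retained", "n_midline_excluded",
                "n_below_min_length")],
          params)
}

#' Gaussian smoothing of a 3-D map
#'
#' Separable Gaussian convolution with the kernel width given as full width
#' at half maximum in mm (`sigma = fwhm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxels).  `fwhm = 0` is the identity.  Borders use
#' renormalised (truncated) kernels so constant images are preserved.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm Full width at half maximum, mm.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Smoothed array of the same dimension.
#' @export
smooth_map <- function(x, fwhm_mm, voxel_size = c(2, 2, 2)) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(x)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- x * 1.0
  for (ax in 1:3) {
    sig <- sigma_mm / voxel_size[ax]
    r <- max(1L, ceiling(4 * sig))
    k <- exp(-((-r:r)^2) / (2 * sig^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1-D convolution along one axis with edge renormalisation
convolve_axis <- function(x, k, ax) {
  d <- dim(x)
  r <- (length(k) - 1L) %/% 2L
  perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  n <- dp[1]
  acc <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src <- (1:n) + o
    ok <- src >= 1 & src <= n
    acc[ok, ] <- acc[ok, ] + w * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  acc <- acc / wsum
  aperm(array(acc, dim = dp), order(perm))
}

#' Write an ACM map as NIfTI with a JSON sidecar
#'
#' @param acm An `acm_map`.
#' @param prefix Output prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json` (parameters and launch bookkeeping).
#' @param voxel_size Voxel edge lengths in mm.
#' @return The prefix, invisibly.
#' @export
write_acm <- function(acm, prefix, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(acm, "acm_map"))
  write_map_nifti(acm$counts, paste0(prefix, ".nii.gz"), voxel_size)
  meta <- list(hemisphere = acm$hemisphere,
               n_launched = acm$n_launched, n_retained = acm$n_retained,
               n_midline_excluded = acm$n_midline_excluded,
               n_below_min_length = acm$n_below_min_length,
               params = acm$params[!vapply(acm$params, is.null, TRUE)])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Write streamlines as a plain-text polyline table
#'
#' One row per point with a streamline index, for visual QC in external
#' viewers.
#'
#' @param streamlines A `streamline_set` from [track_unilateral()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_streamlines_tsv <- function(streamlines, path) {
  stopifnot(inherits(streamlines, "streamline_set"))
  n <- vapply(streamlines$points, nrow, 0L)
  df <- data.frame(streamline = rep(seq_along(n), n),
                   do.call(rbind, streamlines$points))
  names(df)[2:4] <- c("x_mm", "y_mm", "z_mm")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
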