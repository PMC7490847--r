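#' Acquisition scheme
#'
#' A multi-shell gradient table.  Every entry has a b-value, a unit gradient
#' direction (zero vector for b0 volumes) and a shell id; each shell must
#' contain at least one b0 volume.  Per-shell scale factors emulate the
#' TE/TR-driven intensity offsets between shells that shell calibration is
#' designed to remove.
#'
#' @param bvals Numeric vector of b-values (s/mm^2); 0 marks b0 volumes.
#' @param directions Matrix (n x 3); rows for b > 0 must have unit norm.
#' @param shells Integer vector assigning each entry to a shell.
#' @param shell_scales Named numeric vector (> 0) of per-shell intensity
#'   scale factors; names are shell ids.
#' @return An object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvals, directions, shells,
                               shell_scales = NULL) {
  directions <- as.matrix(directions)
  n <- length(bvals)
  stopifnot(nrow(directions) == n, length(shells) == n)
  nrm <- sqrt(rowSums(directions^2))
  if (any(bvals > 0 & abs(nrm - 1) > 1e-8))
    stop("diffusion-weighted directions must have unit norm")
  if (any(bvals == 0 & nrm > 1e-12))
    stop("b0 entries must have zero direction")
  shells <- as.integer(shells)
  if (is.null(shell_scales)) {
    shell_scales <- setNames(rep(1, length(unique(shells))),
                             as.character(sort(unique(shells))))
  }
  if (any(shell_scales <= 0)) stop("shell scale factors must be positive")
  for (s in unique(shells))
    if (!any(bvals == 0 & shells == s))
      stop(sprintf("shell %d contains no b0 volume", s))
  tab <- data.frame(bval = as.numeric(bvals), gx = directions[, 1],
                    gy = directions[, 2], gz = directions[, 3],
                    shell = shells)
  structure(list(table = tab, shell_scales = shell_scales),
            class = "acquisition_scheme")
}

# deterministic quasi-uniform unit directions (spherical Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default three-shell acquisition scheme
#'
#' Shells of 6 directions at b = 300, 62 at b = 1000 and 62 at
#' b = 2000 s/mm^2, each preceded by one b0 volume.  Default per-shell
#' scale factors (1.0, 1.1, 0.9) mimic inter-shell intensity offsets.
#'
#' @param shell_scales Per-shell intensity scales for shells 1..3.
#' @return An [acquisition_scheme()].
#' @export
default_acquisition_scheme <- function(shell_scales = c(1.0, 1.1, 0.9)) {
  shells_def <- list(list(b = 300, n = 6), list(b = 1000, n = 62),
                     list(b = 2000, n = 62))
  bv <- numeric(0); dm <- NULL; sh <- integer(0)
  for (s in seq_along(shells_def)) {
    d <- fibonacci_directions(shells_def[[s]]$n)
    bv <- c(bv, 0, rep(shells_def[[s]]$b, nrow(d)))
    dm <- rbind(dm, c(0, 0, 0), d)
    sh <- c(sh, rep(s, nrow(d) + 1L))
  }
  acquisition_scheme(bv, dm, sh,
                     shell_scales = setNames(shell_scales, as.character(1:3)))
}

#' DWI volume set
#'
#' 4-D signal data with its acquisition scheme.
#'
#' @param data 4-D array `(nx, ny, nz, nvol)` of non-negative signals.
#' @param scheme The [acquisition_scheme()]; entry count must match the
#'   fourth dimension.
#' @param voxel_size Voxel edge lengths in mm.
#' @return An object of class `dwi_volume_set`.
#' @export
dwi_volume_set <- function(data, scheme, voxel_size = c(2, 2, 2)) {
  stopifnot(length(dim(data)) == 4L, inherits(scheme, "acquisition_scheme"))
  if (dim(data)[4] != nrow(scheme$table))
    stop("volume count must equal the scheme entry count")
  if (any(data < 0)) stop("signals must be non-negative")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(data = data, scheme = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_volume_set")
}

nifti_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  structure(a, dimnames = NULL)
}

#' Write a DWI volume set as NIfTI plus FSL-style bval/bvec files
#'
#' @param dwi A [dwi_volume_set()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval` and `<prefix>.bvec`.
#' @return The prefix, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume_set"))
  img <- RNifti::asNifti(dwi$data, pixdim = c(dwi$voxel_size, 1))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  tab <- dwi$scheme$table
  writeLines(paste(format(tab$bval, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- rbind(tab$gx, tab$gy, tab$gz)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read a DWI volume set from NIfTI plus bval/bvec files
#'
#' Shell ids are assigned by grouping unique non-zero b-values (after
#' rounding to the nearest 50 s/mm^2); each b0 is attached to the shell of
#' the following diffusion-weighted block, or the first shell.
#'
#' @param prefix Path prefix as used by [write_dwi()].
#' @return A [dwi_volume_set()].
#' @export
read_dwi <- function(prefix) {
  nii <- paste0(prefix, ".nii.gz")
  if (!file.exists(nii)) nii <- paste0(prefix, ".nii")
  if (!file.exists(nii)) stop(sprintf("no NIfTI image found for '%s'", prefix))
  bvalf <- paste0(prefix, ".bval")
  bvecf <- paste0(prefix, ".bvec")
  if (!file.exists(bvalf)) stop(sprintf("missing bval file '%s'", bvalf))
  if (!file.exists(bvecf)) stop(sprintf("missing bvec file '%s'", bvecf))
  img <- RNifti::readNifti(nii)
  bvals <- scan(bvalf, quiet = TRUE)
  bvec <- as.matrix(read.table(bvecf))
  if (nrow(bvec) != 3L) stop("bvec file must have three rows")
  dirs <- t(bvec)
  nrm <- sqrt(rowSums(dirs^2))
  dw <- bvals > 0 & nrm > 0
  dirs[dw, ] <- dirs[dw, ] / nrm[dw]
  bshell <- round(bvals / 50) * 50
  ushell <- sort(unique(bshell[bshell > 0]))
  shells <- integer(length(bvals))
  shells[bshell > 0] <- match(bshell[bshell > 0], ushell)
  # attach each b0 to the next diffusion-weighted entry's shell
  for (i in which(bshell == 0)) {
    nxt <- which(bshell > 0 & seq_along(bshell) > i)
    shells[i] <- if (length(nxt)) shells[nxt[1]] else 1L
  }
  vs <- attr(img, "pixdim")[1:3] %||% c(2, 2, 2)
  dwi_volume_set(array(as.numeric(img), dim = dim(img)),
                 acquisition_scheme(bvals, dirs, shells),
                 voxel_size = vs)
}

#' Write a binary mask (or count/metric map) as NIfTI
#'
#' @param x 3-D array; logical masks are written as uint8.
#' @param path Output file path.
#' @param voxel_size Voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(x, path, voxel_size = c(2, 2, 2)) {
  dt <- if (is.logical(x)) "uint8" else if (is.integer(x)) "int32" else "double"
  img <- RNifti::asNifti(x * 1, pixdim = c(voxel_size, 1), datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom specification as a YAML config
#'
#' @param spec A [phantom_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  ser <- list(
    grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
    background_iso_diffusivity = spec$background_iso_diffusivity,
    csf_diffusivity = spec$csf_diffusivity,
    rng_seed = spec$rng_seed,
    bundles = lapply(spec$bundles, function(b)
      list(name = b$name, hemisphere = b$hemisphere,
           centerline = apply(b$centerline, 1, as.list),
           radius = b$radius, axial_diffusivity = b$axial_diffusivity,
           radial_diffusivity = b$radial_diffusivity,
           volume_fraction = b$volume_fraction)),
    lesions = lapply(spec$lesions, function(l)
      list(center = as.list(l$center), radius = l$radius,
           severity = l$severity, bundle = l$bundle, visible = l$visible)))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a phantom specification from a YAML config
#'
#' @param path File written by [write_phantom_spec()].
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  bundles <- lapply(y$bundles, function(b)
    bundle_spec(b$name, b$hemisphere,
                do.call(rbind, lapply(b$centerline, unlist)),
                b$radius, b$axial_diffusivity, b$radial_diffusivity,
                b$volume_fraction))
  lesions <- lapply(y$lesions, function(l)
    lesion_spec(unlist(l$center), l$radius, l$severity,
                bundle = l$bundle, visible = l$visible))
  phantom_spec(y$grid_shape, y$voxel_size, bundles, lesions,
               y$background_iso_diffusivity, y$csf_diffusivity, y$rng_seed)
}
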