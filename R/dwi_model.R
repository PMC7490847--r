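#' Calibrate shell intensities against the b0
#'
#' Removes inter-shell intensity offsets (different TE/TR settings per
#' shell) in three steps: (1) an overall mean b0 image is formed by
#' voxel-wise averaging the b0 images of the calibration shells (by
#' default the b = 1000 and b = 2000 s/mm^2 shells); (2) each shell's b0 is
#' divided voxel-wise by the overall mean b0, giving a shell-specific
#' calibration image; (3) every volume in the shell is divided voxel-wise
#' by that calibration image.  After calibration each shell's b0 equals the
#' overall mean b0 wherever the calibration image is finite and non-zero.
#'
#' Voxels where the overall mean b0 is zero have no defined calibration;
#' they are flagged in the returned QC mask and passed through unchanged.
#' The operation is idempotent.
#'
#' @param dwi A [dwi_volume_set()]; every shell must contain a b0 volume.
#' @param calibration_bvalues Nominal b-values of the shells averaged into
#'   the overall mean b0.
#' @return A list with `dwi` (calibrated volume set), `mean_b0`,
#'   and `qc_undefined` (logical array of voxels left unchanged).
#' @export
calibrate_shells <- function(dwi, calibration_bvalues = c(1000, 2000)) {
  stopifnot(inherits(dwi, "dwi_volume_set"))
  tab <- dwi$scheme$table
  shells <- sort(unique(tab$shell))
  gs <- dim(dwi$data)[1:3]

  shell_b0 <- lapply(shells, function(s) {
    j <- which(tab$shell == s & tab$bval == 0)
    if (!length(j)) stop(sprintf("shell %d has no b0 volume", s))
    if (length(j) == 1L) dwi$data[, , , j]
    else apply(dwi$data[, , , j, drop = FALSE], 1:3, mean)
  })
  names(shell_b0) <- as.character(shells)

  # nominal (maximum) b-value identifies the calibration shells
  nominal <- vapply(shells, function(s) max(tab$bval[tab$shell == s]), 0)
  cal <- shells[nominal %in% calibration_bvalues]
  if (!length(cal))
    stop("no shell matches the requested calibration b-values")
  mean_b0 <- Reduce(`+`, shell_b0[as.character(cal)]) / length(cal)

  undefined <- mean_b0 == 0
  out <- dwi$data
  for (s in shells) {
    calib <- shell_b0[[as.character(s)]] / mean_b0
    bad <- undefined | !is.finite(calib) | calib == 0
    calib[bad] <- 1
    undefined <- undefined | bad
    for (j in which(tab$shell == s))
      out[, , , j] <- out[, , , j] / calib
  }
  list(dwi = dwi_volume_set(out, dwi$scheme, dwi$voxel_size),
       mean_b0 = mean_b0, qc_undefined = undefined)
}

# log-linear diffusion tensor design matrix: columns
# (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(tab) {
  b <- tab$bval
  cbind(1, -b * tab$gx^2, -b * tab$gy^2, -b * tab$gz^2,
        -2 * b * tab$gx * tab$gy, -2 * b * tab$gx * tab$gz,
        -2 * b * tab$gy * tab$gz)
}

tensor_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Fit the diffusion tensor model
#'
#' Weighted-least-squares fit of the log signal per voxel: an ordinary
#' least-squares pass provides predicted signals whose squares serve as WLS
#' weights (two reweighted iterations).  Fractional anisotropy and mean
#' diffusivity are computed from the tensor eigenvalues:
#' `MD = mean(lambda)` and
#' `FA = sqrt(3/2 * sum((lambda - MD)^2) / sum(lambda^2))`, clipped
#' to [0, 1].  Voxels with non-positive signals have those volumes excluded
#' (not clamped); a voxel with fewer than 7 usable volumes, or a
#' non-positive fitted MD, is marked `fit_ok = FALSE`.
#'
#' @param dwi A [dwi_volume_set()] with at least 7 volumes spanning at
#'   least 6 non-collinear gradient directions.
#' @param mask Optional logical array restricting the fit.
#' @return An object of class `tensor_fit`: arrays `tensor`
#'   `(nx, ny, nz, 6)` (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `fa`, `md`,
#'   `fit_ok`, principal eigenvector `evec1` `(nx, ny, nz, 3)` and
#'   eigenvalues `evals` `(nx, ny, nz, 3)`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume_set"))
  tab <- dwi$scheme$table
  X <- tensor_design(tab)
  if (nrow(X) < 7L) stop("need at least 7 volumes to fit the tensor")
  qrX <- qr(X)
  if (qrX$rank < 7L) {
    bad <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    comp <- c("lnS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")[bad]
    stop(sprintf(
      "rank-deficient gradient design: cannot estimate %s; add non-collinear directions",
      paste(comp, collapse = ", ")))
  }
  gs <- dim(dwi$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = gs)
  nvol <- nrow(X)
  vox <- which(mask)
  n3 <- prod(gs)

  tensor <- array(NA_real_, dim = c(gs, 6L))
  fa <- array(NA_real_, dim = gs)
  md <- array(NA_real_, dim = gs)
  fit_ok <- array(FALSE, dim = gs)
  evec1 <- array(NA_real_, dim = c(gs, 3L))
  evals <- array(NA_real_, dim = c(gs, 3L))

  sig <- matrix(dwi$data, nrow = n3)[vox, , drop = FALSE]
  for (q in seq_along(vox)) {
    s <- sig[q, ]
    use <- s > 0
    if (sum(use) < 7L) next
    Xu <- X[use, , drop = FALSE]
    y <- log(s[use])
    beta <- tryCatch(qr.coef(qr(Xu), y), error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) next
    for (it in 1:2) {
      w <- exp(Xu %*% beta)^2
      beta2 <- tryCatch(lm.wfit(Xu, y, w = as.numeric(w))$coefficients,
                        error = function(e) NULL)
      if (is.null(beta2) || anyNA(beta2)) break
      beta <- beta2
    }
    D <- tensor_matrix(beta[2:7])
    ev <- eigen(D, symmetric = TRUE)
    lam <- ev$values
    mdv <- mean(lam)
    if (!is.finite(mdv) || mdv <= 0) next
    ss <- sum(lam^2)
    fav <- if (ss > 0) sqrt(1.5 * sum((lam - mdv)^2) / ss) else 0
    v <- vox[q]
    tensor[v + n3 * (0:5)] <- beta[2:7]
    md[v] <- mdv
    fa[v] <- min(max(fav, 0), 1)
    vec <- ev$vectors[, 1]
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    evec1[v + n3 * (0:2)] <- vec
    evals[v + n3 * (0:2)] <- lam
    fit_ok[v] <- TRUE
  }
  structure(list(tensor = tensor, fa = fa, md = md, fit_ok = fit_ok,
                 evec1 = evec1, evals = evals, grid_shape = gs,
                 voxel_size = dwi$voxel_size),
            class = "tensor_fit")
}

#' Extract per-voxel orientation peaks from a tensor fit
#'
#' Produces a single-population orientation field: the principal
#' eigenvector with amplitude equal to the fractional anisotropy.
#' Populations below `amplitude_floor` are dropped (isotropic voxels carry
#' no peak).  This is the default orientation source for data-driven runs;
#' trackers may alternatively consume a phantom's ground-truth multi-peak
#' field directly.
#'
#' @param tf A [fit_tensor()] result.
#' @param amplitude_floor Minimum FA for a peak to be retained.
#' @param wm_mask Optional white-matter mask for the output field; defaults
#'   to the voxels with a retained peak.
#' @return An `orientation_field` with at most one population per voxel.
#' @export
extract_peaks <- function(tf, amplitude_floor = 0.1, wm_mask = NULL) {
  stopifnot(inherits(tf, "tensor_fit"))
  gs <- tf$grid_shape
  amp <- array(0, dim = c(gs, 3L))
  dirs <- array(0, dim = c(gs, 3L, 3L))
  keep <- which(tf$fit_ok & !is.na(tf$fa) & tf$fa >= amplitude_floor)
  n3 <- prod(gs)
  amp[keep] <- tf$fa[keep]
  for (c in 1:3)
    dirs[keep + n3 * (0L + 3L * (c - 1L))] <- tf$evec1[keep + n3 * (c - 1L)]
  ad <- array(0, dim = c(gs, 3L))
  rd <- array(0, dim = c(gs, 3L))
  ad[keep] <- tf$evals[keep]
  rd[keep] <- (tf$evals[keep + n3] + tf$evals[keep + 2L * n3]) / 2
  if (is.null(wm_mask)) {
    wm_mask <- array(FALSE, dim = gs)
    wm_mask[keep] <- TRUE
  }
  orientation_field(gs, tf$voxel_size, amp, dirs, wm_mask,
                    ad = ad, rd = rd)
}
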