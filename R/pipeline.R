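#' Fractional anisotropy of the voxel-wise effective tensor
#'
#' Analytic FA/MD of the signal-fraction-weighted sum of the population
#' tensors and the isotropic compartment.  For single-compartment voxels
#' this equals the tensor-fit FA; for mixtures it is the small-b limit and
#' serves as a fast noise-free stand-in for masking when signal simulation
#' is skipped.
#'
#' @param phantom A `phantom` from [build_phantom()].
#' @return List with arrays `fa` and `md`.
#' @export
effective_tensor_fa <- function(phantom) {
  field <- phantom$field
  gs <- field$grid_shape
  n3 <- prod(gs)
  iso_frac <- pmax(0, 1 - rowSumsPop(field$amplitudes))
  iso_d <- field$iso_diffusivity
  if (length(iso_d) == 1L) iso_d <- array(iso_d, dim = gs)
  # effective tensor: D = sum_k a_k [(ad-rd) d d' + rd I] + f_iso d_iso I
  comp <- array(0, dim = c(gs, 6L))  # Dxx Dyy Dzz Dxy Dxz Dyz
  base <- iso_frac * iso_d
  for (c in 1:3) comp[, , , c] <- base
  for (p in 1:3) {
    a <- field$amplitudes[, , , p]
    if (!any(a > 0)) next
    dd <- field$ad[, , , p] - field$rd[, , , p]
    dx <- field$directions[, , , p, 1]
    dy <- field$directions[, , , p, 2]
    dz <- field$directions[, , , p, 3]
    comp[, , , 1] <- comp[, , , 1] + a * (dd * dx * dx + field$rd[, , , p])
    comp[, , , 2] <- comp[, , , 2] + a * (dd * dy * dy + field$rd[, , , p])
    comp[, , , 3] <- comp[, , , 3] + a * (dd * dz * dz + field$rd[, , , p])
    comp[, , , 4] <- comp[, , , 4] + a * dd * dx * dy
    comp[, , , 5] <- comp[, , , 5] + a * dd * dx * dz
    comp[, , , 6] <- comp[, , , 6] + a * dd * dy * dz
  }
  fa <- array(0, dim = gs)
  md <- array(0, dim = gs)
  for (v in which(phantom$wm_mask | phantom$gm_mask | phantom$csf_mask)) {
    lam <- eigen(tensor_matrix(comp[v + n3 * (0:5)]), symmetric = TRUE,
                 only.values = TRUE)$values
    md[v] <- mean(lam)
    ss <- sum(lam^2)
    fa[v] <- if (ss > 0) min(1, sqrt(1.5 * sum((lam - md[v])^2) / ss)) else 0
  }
  list(fa = fa, md = md)
}

#' Run the full single-subject analysis
#'
#' Builds the subject's phantom, (optionally) simulates the multi-shell
#' acquisition, calibrates shells and fits the diffusion tensor, tracks
#' both hemispheres on the ground-truth orientation field, and summarises
#' ACM, FA and MD over CST-NAWM and non-CST-NAWM with lateralization
#' indices and the slice-wise ACM-LI profile.
#'
#' @param subject One element of a [make_cohort()] result (or a list with
#'   `spec`, `id`, `record`, `tracking_seed`).
#' @param tracking A [tracking_params()].
#' @param scheme Acquisition scheme used when `simulate = TRUE`.
#' @param s0,noise_sd Signal amplitude and Rician noise sigma for the
#'   simulated acquisition.
#' @param simulate When `TRUE`, FA/MD come from calibrated simulated
#'   signals via [fit_tensor()]; otherwise from [effective_tensor_fa()].
#' @return List with the extended one-row `record`, both `acm_map`s, the
#'   FA/MD arrays, masks and the subject's `slice_li_profile`.
#' @export
run_subject_pipeline <- function(subject, tracking = tracking_params(),
                                 scheme = default_acquisition_scheme(),
                                 s0 = 1000, noise_sd = 25, simulate = TRUE) {
  spec <- subject$spec
  ph <- build_phantom(spec)
  if (simulate) {
    dwi <- simulate_dwi(ph, scheme, s0 = s0, noise_sd = noise_sd,
                        rng_seed = subject$tracking_seed %||% NULL)
    cal <- calibrate_shells(dwi)
    tf <- fit_tensor(cal$dwi, mask = ph$wm_mask)
    fa <- tf$fa
    md <- tf$md
    fa[is.na(fa)] <- 0
    md[is.na(md)] <- 0
  } else {
    eff <- effective_tensor_fa(ph)
    fa <- eff$fa
    md <- eff$md
  }

  tr <- tracking
  tr$rng_seed <- subject$tracking_seed %||% tracking$rng_seed
  acm_l <- track_acm(ph$field, "left", tr)
  tr$rng_seed <- if (!is.null(tr$rng_seed)) tr$rng_seed + 1L else NULL
  acm_r <- track_acm(ph$field, "right", tr)
  acm <- acm_l$counts + acm_r$counts

  nawm <- make_nawm_mask(ph$wm_mask, ph$lesion_mask, fa)
  hemi <- hemisphere_labels(spec$grid_shape)
  p_l <- tract_probability_map(spec, "cst_left")
  p_r <- tract_probability_map(spec, "cst_right")
  cst_l <- make_cst_mask(p_l)$left
  cst_r <- make_cst_mask(p_r)$right

  masks <- list(
    cst_nawm_left = roi_mask(nawm$mask & cst_l$mask, "CST-NAWM", "left"),
    cst_nawm_right = roi_mask(nawm$mask & cst_r$mask, "CST-NAWM", "right"),
    noncst_nawm_left = roi_mask(nawm$mask & !cst_l$mask & hemi == -1L,
                                "non-CST-NAWM", "left"),
    noncst_nawm_right = roi_mask(nawm$mask & !cst_r$mask & hemi == 1L,
                                 "non-CST-NAWM", "right"),
    nawm_left = roi_mask(nawm$mask & hemi == -1L, "NAWM", "left"),
    nawm_right = roi_mask(nawm$mask & hemi == 1L, "NAWM", "right"))

  mval <- function(map, m) mean(map[m$mask])
  rec <- subject$record
  rec$total_acm <- sum(acm_l$counts) + sum(acm_r$counts)
  for (metric in c("acm", "fa", "md")) {
    map <- switch(metric, acm = acm, fa = fa, md = md)
    for (roi in c("cst_nawm", "noncst_nawm", "nawm"))
      for (side in c("left", "right"))
        rec[[paste(metric, roi, side, sep = "_")]] <-
          mval(map, masks[[paste(roi, side, sep = "_")]])
    rec[[paste0("li_", metric, "_cst_nawm")]] <-
      lateralization_index(rec[[paste0(metric, "_cst_nawm_left")]],
                           rec[[paste0(metric, "_cst_nawm_right")]])
    rec[[paste0("li_", metric, "_nawm")]] <-
      lateralization_index(rec[[paste0(metric, "_nawm_left")]],
                           rec[[paste0(metric, "_nawm_right")]])
  }
  vvol <- prod(spec$voxel_size) / 1000  # mL per voxel
  rec$lesion_volume_left <- sum(ph$lesion_mask & hemi == -1L) * vvol
  rec$lesion_volume_right <- sum(ph$lesion_mask & hemi == 1L) * vvol
  rec$li_lesion_load <-
    if (rec$lesion_volume_left + rec$lesion_volume_right > 0)
      lateralization_index(rec$lesion_volume_left, rec$lesion_volume_right)
    else NA_real_

  profile <- slice_li_profile(acm, acm, masks$cst_nawm_left,
                              masks$cst_nawm_right)
  list(record = rec, acm_left = acm_l, acm_right = acm_r, fa = fa, md = md,
       masks = masks, lesion_mask = ph$lesion_mask, profile = profile)
}

#' Run the cohort-level analysis
#'
#' Generates a cohort with [make_cohort()], runs every subject through
#' [run_subject_pipeline()], and returns the stacked covariate/ROI table,
#' the slice-wise ACM-LI profile matrix and the lesion frequency map.
#'
#' @param cspec A [cohort_spec()].
#' @param pspec Base [phantom_spec()].
#' @param tracking A [tracking_params()] (per-subject seeds are drawn by
#'   [make_cohort()]).
#' @param ... Passed to [run_subject_pipeline()].
#' @return A list of class `cohort_result`: `records` (data frame, one row
#'   per subject), `profiles` (subjects x slices LI matrix),
#'   `lesion_frequency` and `groups`.
#' @export
run_cohort_pipeline <- function(cspec, pspec = default_phantom_spec(),
                                tracking = tracking_params(), ...) {
  subjects <- make_cohort(cspec, pspec)
  records <- NULL
  profiles <- NULL
  lesions <- list()
  for (s in subjects) {
    res <- run_subject_pipeline(s, tracking = tracking, ...)
    records <- rbind(records, res$record)
    profiles <- rbind(profiles, res$profile$li)
    lesions[[length(lesions) + 1L]] <- res$lesion_mask
  }
  rownames(profiles) <- records$id
  structure(list(records = records, profiles = profiles,
                 lesion_frequency = lesion_frequency_map(lesions),
                 groups = records$group),
            class = "cohort_result")
}

#' Headline group statistics for a cohort result
#'
#' Reproduces the study's analysis layout on a synthetic cohort: the
#' repeated-measures group ANCOVA on CST-NAWM ACM (covariates age, sex and
#' total ACM count), the covariate-adjusted correlation between the
#' CST-NAWM ACM lateralization index and the FSMC motor score within
#' patients, the correlation between the whole-NAWM ACM lateralization and
#' the lesion-load lateralization within patients, and the slice-wise
#' FMS-vs-NFMS comparison.
#'
#' @param cohort A `cohort_result`.
#' @return List with `ancova`, `cor_li_fsmc`, `cor_li_lesion`,
#'   `slice_tests` and the group-mean ACM-LI values `li_by_group`.
#' @export
cohort_analysis <- function(cohort) {
  rec <- cohort$records
  pat <- rec[rec$group %in% c("FMS", "NFMS"), ]
  anc <- group_ancova(rec, "acm_cst_nawm_left", "acm_cst_nawm_right")
  covs <- pat[, c("age", "sex", "total_acm")]
  cor_fsmc <- adjusted_correlation(pat$li_acm_cst_nawm, pat$fsmc_motor, covs)
  cor_les <- adjusted_correlation(pat$li_acm_nawm, pat$li_lesion_load, covs)
  keep <- cohort$groups %in% c("FMS", "NFMS")
  slice <- suppressWarnings(
    slice_group_test(cohort$profiles[keep, , drop = FALSE],
                     droplevels(factor(cohort$groups[keep],
                                       levels = c("NFMS", "FMS")))))
  li_by_group <- tapply(rec$li_acm_cst_nawm, rec$group, mean)
  list(ancova = anc, cor_li_fsmc = cor_fsmc, cor_li_lesion = cor_les,
       slice_tests = slice, li_by_group = li_by_group)
}
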