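#' Normal-appearing white matter mask
#'
#' NAWM is the white-matter segmentation with visible lesions removed and,
#' to limit partial-volume contamination at tissue boundaries, all voxels
#' with FA below 0.3 removed as well.  The FA rule is "remove if FA < 0.3",
#' so a voxel at exactly 0.3 is kept.
#'
#' @param wm_mask Logical white-matter array.
#' @param lesion_mask Logical lesion array on the same grid.
#' @param fa_map FA array on the same grid.
#' @param fa_floor Removal threshold (default 0.3).
#' @return A list of class `roi_mask` (`mask`, `name`, `hemisphere`).
#' @export
make_nawm_mask <- function(wm_mask, lesion_mask, fa_map, fa_floor = 0.3) {
  if (!identical(dim(wm_mask), dim(lesion_mask)) ||
      !identical(dim(wm_mask), dim(fa_map)))
    stop("wm_mask, lesion_mask and fa_map must share one grid")
  fa <- fa_map
  fa[is.na(fa)] <- 0
  roi_mask(wm_mask & !lesion_mask & !(fa < fa_floor), "NAWM", "both")
}

roi_mask <- function(mask, name, hemisphere) {
  structure(list(mask = mask, name = name, hemisphere = hemisphere),
            class = "roi_mask")
}

#' Corticospinal-tract mask from a tract-probability map
#'
#' Voxels with a probability strictly above `prob_floor` (default 10%) of
#' belonging to the tract are included, then split into left and right
#' masks by the hemisphere labels (midline voxels belong to neither).
#'
#' @param probability_map Array of probabilities in [0, 1].
#' @param prob_floor Inclusion threshold (strict `>`).
#' @param name ROI name stem.
#' @return A list with `roi_mask` objects `left`, `right` and `both`.  An
#'   empty mask triggers a warning.
#' @export
make_cst_mask <- function(probability_map, prob_floor = 0.10, name = "CST") {
  if (any(probability_map < 0 | probability_map > 1))
    stop("probabilities must lie in [0, 1]")
  m <- probability_map > prob_floor
  hemi <- hemisphere_labels(dim(probability_map))
  out <- list(left = roi_mask(m & hemi == -1L, paste0(name, "_left"), "left"),
              right = roi_mask(m & hemi == 1L, paste0(name, "_right"), "right"),
              both = roi_mask(m & hemi != 0L, name, "both"))
  if (!any(out$both$mask))
    warning(sprintf("'%s' mask is empty at probability floor %g", name,
                    prob_floor))
  out
}

#' Mean of a metric map over ROI masks
#'
#' @param metric_map Numeric array.
#' @param masks A single `roi_mask` or a list of them.
#' @return Data frame with columns `roi`, `hemisphere`, `n_voxels`, `mean`.
#' @export
roi_means <- function(metric_map, masks) {
  if (inherits(masks, "roi_mask")) masks <- list(masks)
  rows <- lapply(masks, function(m) {
    stopifnot(inherits(m, "roi_mask"))
    if (!identical(dim(m$mask), dim(metric_map)))
      stop(sprintf("mask '%s' is not on the metric grid", m$name))
    n <- sum(m$mask)
    if (n == 0L) stop(sprintf("ROI mask '%s' is empty", m$name))
    data.frame(roi = m$name, hemisphere = m$hemisphere, n_voxels = n,
               mean = mean(metric_map[m$mask]))
  })
  do.call(rbind, rows)
}

#' Lateralization index
#'
#' `LI = 100 * (left - right) / (left + right)`: values from 1 to 100
#' reflect higher values in the left hemisphere, -1 to -100 higher values
#' in the right.  Defined for non-negative inputs with a positive sum.
#'
#' @param left,right Non-negative hemisphere summary values (vectorised).
#' @return The lateralization index in [-100, 100].
#' @export
lateralization_index <- function(left, right) {
  if (any(left < 0 | right < 0)) stop("inputs must be non-negative")
  if (any(left + right == 0))
    stop("lateralization index undefined: left + right = 0")
  100 * (left - right) / (left + right)
}

#' Slice-wise lateralization profile
#'
#' For each axial (z) slice, the lateralization index of the mean metric
#' over the left and right ROI restricted to that slice.  Slices where
#' either side of the ROI is empty (or both means are zero) are marked
#' undefined and carry `NA`.
#'
#' @param metric_left,metric_right Metric arrays for the two unilateral
#'   runs (may be the same array when one map covers both hemispheres).
#' @param roi_left,roi_right `roi_mask` objects for the paired ROIs.
#' @return Data frame of class `slice_li_profile`: `slice` (1-based z
#'   index), `left_mean`, `right_mean`, `li`, `defined`.
#' @export
slice_li_profile <- function(metric_left, metric_right, roi_left, roi_right) {
  stopifnot(inherits(roi_left, "roi_mask"), inherits(roi_right, "roi_mask"))
  gs <- dim(metric_left)
  nz <- gs[3]
  out <- data.frame(slice = seq_len(nz), left_mean = NA_real_,
                    right_mean = NA_real_, li = NA_real_, defined = FALSE)
  for (z in seq_len(nz)) {
    ml <- roi_left$mask[, , z]
    mr <- roi_right$mask[, , z]
    if (!any(ml) || !any(mr)) next
    lv <- mean(metric_left[, , z][ml])
    rv <- mean(metric_right[, , z][mr])
    out$left_mean[z] <- lv
    out$right_mean[z] <- rv
    if (lv + rv > 0) {
      out$li[z] <- lateralization_index(lv, rv)
      out$defined[z] <- TRUE
    }
  }
  class(out) <- c("slice_li_profile", class(out))
  out
}

#' Lesion frequency map
#'
#' Voxel-wise sum of binary lesion masks across subjects.
#'
#' @param lesion_masks List of logical (or 0/1) arrays on one grid.
#' @return Integer count array; maximum is the number of subjects.
#' @export
lesion_frequency_map <- function(lesion_masks) {
  stopifnot(length(lesion_masks) >= 1L)
  d <- dim(lesion_masks[[1]])
  acc <- array(0L, dim = d)
  for (m in lesion_masks) {
    if (!identical(dim(m), d)) stop("lesion masks must share one grid")
    v <- as.array(m)
    if (!all(v %in% c(0, 1, FALSE, TRUE)))
      stop("lesion masks must be binary")
    acc <- acc + as.integer(v)
  }
  acc
}

#' Write ROI summaries as a tidy TSV
#'
#' @param df Data frame (e.g. stacked [roi_means()] results with subject
#'   and metric columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
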