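#' Classify motor fatigue from the FSMC motor subscale
#'
#' The FSMC motor subscale (10 items scored 1-5) ranges from 10 to 50; a
#' score of 27 or above classifies a patient as motor-fatigued (FMS),
#' below as non-fatigued (NFMS).
#'
#' @param fsmc_motor Numeric score(s) in [10, 50].
#' @return Character vector of `"FMS"` / `"NFMS"`.
#' @export
classify_fatigue <- function(fsmc_motor) {
  if (any(fsmc_motor < 10 | fsmc_motor > 50))
    stop("FSMC motor scores must lie within the instrument range [10, 50]")
  ifelse(fsmc_motor >= 27, "FMS", "NFMS")
}

#' Repeated-measures group ANCOVA on paired hemisphere measures
#'
#' Left and right ROI measures form the within-subject factor `side`;
#' `group` is the between-subject factor, with age, sex and (for
#' connectivity measures) the total individual ACM count as covariates.
#' The model is fitted as a linear mixed model on long-format data with a
#' random subject intercept; omnibus F tests use Satterthwaite degrees of
#' freedom (type III).  Conditional on a significant omnibus group effect
#' (or side-by-group interaction), pairwise group contrasts are computed on
#' the adjusted means and reported as F tests.
#'
#' @param records Data frame with one row per subject, containing `id`,
#'   `group`, the two dependent columns and the covariates.
#' @param value_left,value_right Names of the left/right dependent columns.
#' @param covariates Character vector of covariate column names.
#' @param alpha Significance level gating the post-hoc contrasts.
#' @return A list of class `group_ancova`: `anova` (data frame of effects,
#'   F and p), `posthoc_group`, `posthoc_interaction` (data frames or
#'   `NULL`), and the fitted `model`.
#' @export
group_ancova <- function(records, value_left, value_right,
                         covariates = c("age", "sex", "total_acm"),
                         alpha = 0.05) {
  stopifnot(all(c("id", "group", value_left, value_right) %in% names(records)))
  covariates <- intersect(covariates, names(records))
  if (length(unique(records$group)) < 2L) stop("need at least two groups")
  if (any(table(records$group) < 2L)) stop("each group needs n >= 2")

  long <- rbind(
    data.frame(records[c("id", "group", covariates)], side = "left",
               value = records[[value_left]]),
    data.frame(records[c("id", "group", covariates)], side = "right",
               value = records[[value_right]]))
  long$group <- factor(long$group)
  long$side <- factor(long$side)
  for (cv in covariates)
    if (is.numeric(long[[cv]])) {
      long[[cv]] <- long[[cv]] - mean(long[[cv]])
      s <- sd(long[[cv]])
      if (s > 0) long[[cv]] <- long[[cv]] / s  # F tests are scale-invariant
    }

  rhs <- paste(c("group * side", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("value ~", rhs, "+ (1 | id)"))

  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), long)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("collinear design; aliased columns: %s",
                 paste(aliased, collapse = ", ")))
  }

  fit <- lmerTest::lmer(fml, data = long,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
  an <- stats::anova(fit, type = 3)
  an_df <- data.frame(effect = rownames(an), F = an$`F value`,
                      df1 = an$NumDF, df2 = an$DenDF,
                      p = an$`Pr(>F)`, row.names = NULL)

  posthoc_group <- NULL
  posthoc_inter <- NULL
  p_group <- an_df$p[an_df$effect == "group"]
  p_inter <- an_df$p[an_df$effect == "group:side"]
  if (length(p_group) && !is.na(p_group) && p_group < alpha) {
    em <- emmeans::emmeans(fit, "group")
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "none"))
    posthoc_group <- data.frame(contrast = ct$contrast,
                                F = ct$t.ratio^2, df1 = 1, df2 = ct$df,
                                p = ct$p.value)
  }
  if (length(p_inter) && !is.na(p_inter) && p_inter < alpha) {
    em <- emmeans::emmeans(fit, "group", by = "side")
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "none"))
    posthoc_inter <- data.frame(side = ct$side, contrast = ct$contrast,
                                F = ct$t.ratio^2, df1 = 1, df2 = ct$df,
                                p = ct$p.value)
  }
  structure(list(anova = an_df, posthoc_group = posthoc_group,
                 posthoc_interaction = posthoc_inter, model = fit),
            class = "group_ancova")
}

#' Covariate-adjusted Pearson correlation
#'
#' Partial correlation by residualisation: both variables are regressed on
#' the covariates (with intercept) and the residuals are correlated.  The
#' p value uses the t transform with `n - k - 2` degrees of freedom for `k`
#' covariate columns.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates (factors
#'   are expanded to dummies).
#' @return List with `r`, `p` (two-sided), `df`, `n`.
#' @export
adjusted_correlation <- function(x, y, covariates = NULL) {
  ok <- complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    Z <- stats::model.matrix(~ ., covariates)
    k <- ncol(Z) - 1L
    if (n <= k + 2L) stop("need n > number of covariates + 2")
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero-variance residuals; correlation undefined")
  r <- cor(x, y)
  df <- n - k - 2L
  tval <- r * sqrt(df) / sqrt(max(1e-300, 1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df), df = df, n = n)
}

#' TFCE parameters
#'
#' Defaults are the de facto standard: height exponent `H = 2`, extent
#' exponent `E = 0.5`, 26-neighbour connectivity, and a threshold
#' increment of 1/100 of the map maximum (set `dh` to fix it).
#'
#' @param H,E Height and extent exponents (> 0).
#' @param dh Threshold increment; `NULL` uses `max(stat)/100` per map.
#' @param connectivity 6, 18 or 26.
#' @param n_permutations Number of permutations for [permutation_test()].
#' @param alpha Significance level.
#' @param rng_seed Optional seed for the permutation draw.
#' @return An object of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26,
                        n_permutations = 5000L, alpha = 0.05,
                        rng_seed = NULL) {
  stopifnot(H > 0, E > 0, is.null(dh) || dh > 0,
            connectivity %in% c(6, 18, 26), n_permutations >= 1)
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 rng_seed = rng_seed),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates cluster support across all thresholds:
#' `TFCE(v) = sum_{h = dh, 2dh, ... <= stat(v)} e(h, v)^E * h^H * dh`,
#' where `e(h, v)` is the voxel count of the connected component containing
#' `v` in the supra-threshold image `{stat >= h}`.  Voxels with
#' non-positive statistic map to 0.
#'
#' @param stat_map Finite 3-D statistic array.
#' @param params A [tfce_params()].
#' @return TFCE array of the same dimension.
#' @export
tfce_transform <- function(stat_map, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  if (any(!is.finite(stat_map))) stop("stat_map must be finite")
  .tfce_cpp(as.numeric(stat_map), as.integer(dim(stat_map)),
            params$H, params$E, params$dh %||% -1, params$connectivity)
}

#' Voxel-wise two-sample permutation test with TFCE
#'
#' Computes the observed pooled-variance two-sample t map (second group
#' minus first), applies TFCE, and builds a null distribution of the
#' maximum TFCE statistic by relabelling group membership
#' `n_permutations` times -- or exhaustively when fewer distinct
#' labelings exist.  Family-wise-error-corrected p values use the plus-one
#' estimator `p(v) = (1 + #{perm max >= TFCE_obs(v)}) / (1 + n_used)`, so
#' p values are never zero and are bounded below by `1/(n_used + 1)`.
#'
#' @param maps 4-D array `(nx, ny, nz, n_subjects)` of subject maps, or a
#'   matrix (voxels x subjects) with `grid_shape` supplied.
#' @param groups Two-level factor (or character) of group labels; the t
#'   contrast is level 2 minus level 1.
#' @param params A [tfce_params()].
#' @param grid_shape Required when `maps` is a matrix.
#' @return An object of class `permutation_result`: `t_obs`, `tfce_obs`,
#'   `null_max`, `fwe_p`, `n_permutations_used`, `exhaustive`.
#' @export
permutation_test <- function(maps, groups, params = tfce_params(),
                             grid_shape = NULL) {
  stopifnot(inherits(params, "tfce_params"))
  if (length(dim(maps)) == 4L) {
    grid_shape <- dim(maps)[1:3]
    data <- matrix(maps, ncol = dim(maps)[4])
  } else {
    if (is.null(grid_shape)) stop("grid_shape required for matrix input")
    data <- as.matrix(maps)
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  n <- length(groups)
  g <- as.integer(groups) - 1L  # 0 / 1
  n1 <- sum(g)

  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= params$n_permutations
  if (exhaustive) {
    combos <- combn(n, n1)
    perms <- matrix(0L, ncol(combos), n)
    for (i in seq_len(ncol(combos))) perms[i, combos[, i]] <- 1L
    # put the observed labelling first; the rest form the null
    obs_row <- which(apply(perms, 1, function(r) all(r == g)))
    perms <- rbind(g, perms[-obs_row, , drop = FALSE])
  } else {
    perms <- rbind(g, t(replicate(params$n_permutations, sample(g))))
  }
  res <- .perm_tfce_cpp(data, perms, as.integer(grid_shape),
                        params$H, params$E, params$dh %||% -1,
                        params$connectivity)
  n_used <- nrow(perms) - 1L
  fwe <- array(NA_real_, dim = grid_shape)
  tf <- as.numeric(res$tfce_obs)
  fwe[] <- vapply(tf, function(v) (1 + sum(res$null_max >= v)) / (1 + n_used),
                  0)
  structure(list(t_obs = res$t_obs, tfce_obs = res$tfce_obs,
                 null_max = as.numeric(res$null_max), fwe_p = fwe,
                 n_permutations_used = n_used, exhaustive = exhaustive,
                 params = params),
            class = "permutation_result")
}

#' Slice-wise two-sample group comparison of lateralization profiles
#'
#' Per axial slice, a two-sample t test (Welch) of the subject
#' lateralization indices between two groups; slices undefined in any
#' subject, or with degenerate variance in both groups, are skipped with a
#' warning.  P values are uncorrected by design.
#'
#' @param profiles Matrix (subjects x slices) of LI values (`NA` =
#'   undefined), e.g. stacked `li` columns of [slice_li_profile()] results.
#' @param groups Two-level factor of length `nrow(profiles)`.
#' @param alpha Flagging threshold (uncorrected).
#' @return Data frame: `slice`, `mean_1`, `mean_2`, `t`, `p`, `flagged`.
#' @export
slice_group_test <- function(profiles, groups, alpha = 0.05) {
  profiles <- as.matrix(profiles)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, nrow(profiles) == length(groups))
  lev <- levels(groups)
  out <- data.frame(slice = seq_len(ncol(profiles)), mean_1 = NA_real_,
                    mean_2 = NA_real_, t = NA_real_, p = NA_real_,
                    flagged = FALSE)
  skipped <- 0L
  for (z in seq_len(ncol(profiles))) {
    v <- profiles[, z]
    ok <- !is.na(v)
    if (sum(ok & groups == lev[1]) < 2L || sum(ok & groups == lev[2]) < 2L) {
      skipped <- skipped + 1L
      next
    }
    a <- v[ok & groups == lev[1]]
    b <- v[ok & groups == lev[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      skipped <- skipped + 1L
      next
    }
    tt <- t.test(b, a)
    out$mean_1[z] <- mean(a)
    out$mean_2[z] <- mean(b)
    out$t[z] <- unname(tt$statistic)
    out$p[z] <- tt$p.value
    out$flagged[z] <- tt$p.value < alpha
  }
  if (skipped > 0L)
    warning(sprintf("%d slice(s) skipped (undefined or degenerate)", skipped))
  out
}
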