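sim_records <- function(n = 20, shift_left = 0, u_sd = 1, e_sd = 0.5) {
  id <- sprintf("s%03d", seq_len(2 * n))
  grp <- rep(c("A", "B"), each = n)
  u <- rnorm(2 * n, 0, u_sd)
  left <- u + rnorm(2 * n, 0, e_sd)
  right <- u + rnorm(2 * n, 0, e_sd)
  left[grp == "B"] <- left[grp == "B"] + shift_left
  data.frame(id = id, group = grp, left = left, right = right,
             age = rnorm(2 * n, 40, 10),
             sex = sample(c("F", "M"), 2 * n, replace = TRUE),
             total_acm = rnorm(2 * n, 1e5, 1e4),
             stringsAsFactors = FALSE)
}

test_that("the fatigue cutoff is applied at 27 inclusive", {
  expect_identical(classify_fatigue(27), "FMS")
  expect_identical(classify_fatigue(26), "NFMS")
  expect_identical(classify_fatigue(10), "NFMS")
  expect_identical(classify_fatigue(c(50, 26.5)), c("FMS", "NFMS"))
  expect_error(classify_fatigue(9), "range")
  expect_error(classify_fatigue(51), "range")
})

test_that("cloned groups produce a null group effect", {
  set.seed(5)
  rec <- sim_records(n = 10)
  rec$group <- "A"
  clone <- rec
  clone$group <- "B"
  clone$id <- paste0(clone$id, "c")
  res <- group_ancova(rbind(rec, clone), "left", "right")
  g <- res$anova[res$anova$effect == "group", ]
  expect_lt(g$F, 1e-10)
  expect_gt(g$p, 0.999)
})

test_that("a planted side-by-group interaction is detected with high power", {
  set.seed(77)
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    # d = 1.5 on the measure scale (sd = sqrt(1 + 0.25))
    rec <- sim_records(n = 20, shift_left = 1.5 * sqrt(1.25))
    res <- group_ancova(rec, "left", "right")
    p <- res$anova$p[res$anova$effect == "group:side"]
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("mixed-model F statistics match hand-coded projection oracles", {
  # In a balanced design with subject-constant covariates, the
  # between-subject F equals OLS on subject means and the interaction F
  # equals OLS on left-right differences; both oracles are computed from
  # explicit projection matrices.
  proj_F <- function(y, X_full, drop_cols) {
    H <- function(X) X %*% solve(t(X) %*% X) %*% t(X)
    X0 <- X_full[, -drop_cols, drop = FALSE]
    r1 <- y - H(X_full) %*% y
    r0 <- y - H(X0) %*% y
    q <- length(drop_cols)
    df <- length(y) - ncol(X_full)
    ((sum(r0^2) - sum(r1^2)) / q) / (sum(r1^2) / df)
  }
  set.seed(11)
  rec <- sim_records(n = 12, shift_left = 0.8)
  res <- group_ancova(rec, "left", "right")
  an <- res$anova

  sexn <- as.numeric(factor(rec$sex)) - 1
  scale2 <- function(x) as.numeric(scale(x))
  Xb <- cbind(1, grpB = rec$group == "B", age = scale2(rec$age),
              sex = sexn - mean(sexn), acm = scale2(rec$total_acm))
  m <- (rec$left + rec$right) / 2
  F_group <- proj_F(m, Xb, drop_cols = 2)
  d <- rec$left - rec$right
  F_inter <- proj_F(d, Xb[, 1:2], drop_cols = 2)
  expect_equal(an$F[an$effect == "group"], F_group, tolerance = 1e-6)
  expect_equal(an$F[an$effect == "group:side"], F_inter, tolerance = 1e-6)
})

test_that("collinear covariates are reported by name", {
  set.seed(6)
  rec <- sim_records(n = 6)
  rec$dup <- rec$age
  expect_error(group_ancova(rec, "left", "right",
                            covariates = c("age", "dup")), "aliased")
})

test_that("adjusted correlations residualise as an explicit oracle does", {
  expect_equal(adjusted_correlation(1:10, 1:10)$r, 1)
  set.seed(14)
  x <- rnorm(10); z <- rnorm(10); y <- 0.5 * z + rnorm(10)
  res <- adjusted_correlation(x, y, data.frame(z = z))
  expect_equal(res$r, oracle_partial_cor(x, y, cbind(z)), tolerance = 1e-10)
  # y equal to a covariate leaves no adjusted association
  set.seed(15)
  z2 <- rnorm(500)
  x2 <- rnorm(500)
  res2 <- adjusted_correlation(x2, z2 + rnorm(500, 0, 1e-8),
                               data.frame(z = z2))
  expect_lt(abs(res2$r), 0.1)
  expect_error(adjusted_correlation(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("TFCE handles trivial maps in closed form", {
  z <- array(0, dim = c(5, 5, 5))
  expect_true(all(tfce_transform(z) == 0))
  zn <- z; zn[2, 2, 2] <- -3
  expect_true(all(tfce_transform(zn) == 0))
  # single isolated voxel: e(h) = 1, TFCE = sum h^H dh
  h0 <- 2.5
  one <- z; one[3, 3, 3] <- h0
  p <- tfce_params(H = 2, E = 0.5, dh = 0.1)
  got <- tfce_transform(one, p)
  hs <- seq(0.1, h0, by = 0.1)
  expect_equal(got[3, 3, 3], sum(hs^2 * 0.1), tolerance = 1e-9)
  expect_equal(sum(got > 0), 1)
})

test_that("TFCE matches the per-threshold connected-component brute force", {
  set.seed(19)
  for (conn in c(6, 26)) {
    stat <- array(rnorm(216, 0.5, 1), dim = c(6, 6, 6))
    got <- tfce_transform(stat, tfce_params(connectivity = conn))
    ref <- oracle_tfce(stat, H = 2, E = 0.5, connectivity = conn)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("TFCE is monotone in single-voxel increases", {
  set.seed(23)
  for (r in 1:5) {
    stat <- array(rnorm(125, 0.3, 1), dim = c(5, 5, 5))
    v <- sample(125, 1)
    hi <- stat
    hi[v] <- hi[v] + runif(1, 0.1, 2)
    p <- tfce_params(dh = 0.05)
    expect_gte(tfce_transform(hi, p)[v], tfce_transform(stat, p)[v])
  }
})

test_that("exhaustive permutation p values match full enumeration", {
  set.seed(31)
  gs <- c(4, 4, 2)
  n <- 7
  g <- c(0, 0, 0, 1, 1, 1, 1)
  data <- matrix(rnorm(prod(gs) * n), ncol = n)
  data[1:6, g == 1] <- data[1:6, g == 1] + 1.5
  res <- permutation_test(data, factor(g), tfce_params(n_permutations = 500),
                          grid_shape = gs)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations_used, choose(7, 4) - 1)

  # independent enumeration with naive t maps and brute-force TFCE
  combos <- combn(7, 4)
  tf_obs <- oracle_tfce(array(oracle_tmap(data, g), dim = gs))
  null_max <- c()
  for (i in seq_len(ncol(combos))) {
    gi <- integer(7); gi[combos[, i]] <- 1L
    if (all(gi == g)) next
    tfi <- oracle_tfce(array(oracle_tmap(data, gi), dim = gs))
    null_max <- c(null_max, max(tfi))
  }
  ref_p <- array(vapply(tf_obs, function(v)
    (1 + sum(null_max >= v)) / (1 + length(null_max)), 0), dim = gs)
  expect_equal(res$fwe_p, ref_p, tolerance = 1e-12)
  expect_equal(res$tfce_obs, tf_obs, tolerance = 1e-9)
  expect_true(all(res$fwe_p >= 1 / (1 + res$n_permutations_used)))
})

test_that("permutation p values are scale invariant and never zero", {
  set.seed(37)
  gs <- c(4, 4, 3)
  n <- 12
  g <- rep(0:1, each = 6)
  data <- matrix(rnorm(prod(gs) * n), ncol = n)
  p1 <- permutation_test(data, factor(g),
                         tfce_params(n_permutations = 200, rng_seed = 3),
                         grid_shape = gs)
  p2 <- permutation_test(data * 100, factor(g),
                         tfce_params(n_permutations = 200, rng_seed = 3),
                         grid_shape = gs)
  expect_equal(p1$fwe_p, p2$fwe_p, tolerance = 1e-12)
  expect_true(all(p1$fwe_p > 0))
  # observed t map equals the naive oracle
  expect_equal(as.numeric(p1$t_obs), oracle_tmap(data, g), tolerance = 1e-10)
})

test_that("a planted cluster effect is detected by the permutation test", {
  set.seed(41)
  gs <- c(6, 6, 4)
  n <- 30
  g <- rep(0:1, each = 15)
  hits <- 0L
  for (r in 1:20) {
    data <- matrix(rnorm(prod(gs) * n), ncol = n)
    clust <- c(1, 2, 7, 8, 37, 38, 43, 44)  # 8-voxel block
    data[clust, g == 1] <- data[clust, g == 1] + 2
    res <- permutation_test(data, factor(g),
                            tfce_params(n_permutations = 200, rng_seed = r),
                            grid_shape = gs)
    if (min(res$fwe_p) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.8)
})

test_that("slice-wise group tests flag planted shifts and skip degenerate slices", {
  set.seed(43)
  n <- 24
  grp <- rep(c("A", "B"), each = n / 2)
  prof <- matrix(rnorm(n * 30), n, 30)
  prof[grp == "B", 10:20] <- prof[grp == "B", 10:20] + 2
  res <- slice_group_test(prof, grp)
  expect_true(all(res$flagged[10:20]))
  expect_lt(mean(res$flagged[-(10:20)]), 0.3)

  prof2 <- matrix(rnorm(n * 4), n, 4)
  prof2[, 2] <- 5  # zero variance in both groups
  expect_warning(res2 <- slice_group_test(prof2, grp), "skipped")
  expect_true(is.na(res2$p[2]))

  # identical groups: flagging stays at the nominal rate
  set.seed(44)
  flags <- 0L; total <- 0L
  for (r in 1:100) {
    pr <- matrix(rnorm(20 * 15), 20, 15)
    rs <- slice_group_test(pr, rep(c("A", "B"), each = 10))
    flags <- flags + sum(rs$flagged)
    total <- total + sum(!is.na(rs$p))
  }
  expect_gte(flags, qbinom(0.025, total, 0.05))
  expect_lte(flags, qbinom(0.975, total, 0.05))
})
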