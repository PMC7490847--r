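# Independent oracles and small fixture builders.  Everything here is
# deliberately naive (loops, explicit formulas) and shares no code with the
# package internals it checks.

# ---- closed-form single-tensor signal -------------------------------------

# S = s0 * exp(-b g' D g) evaluated with an explicit matrix product
oracle_tensor_signal <- function(s0, b, g, D) {
  s0 * exp(-b * as.numeric(t(g) %*% D %*% g))
}

oracle_axisym_tensor <- function(dir, ad, rd) {
  dir <- dir / sqrt(sum(dir^2))
  (ad - rd) * outer(dir, dir) + rd * diag(3)
}

# ---- FA / MD from eigenvalues ---------------------------------------------

oracle_fa_md <- function(D) {
  lam <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  md <- mean(lam)
  list(fa = sqrt(1.5 * sum((lam - md)^2) / sum(lam^2)), md = md)
}

# ---- single-fibre column field for tracking oracles -----------------------

# grid (nx, ny, nz) with a single 1x1xnz WM column at (ix, iy) (1-based),
# fibres along +z with the given amplitude
column_field <- function(nx = 8, ny = 8, nz = 8, ix = 3, iy = 5,
                         amplitude = 0.8, voxel_size = 2) {
  gs <- c(nx, ny, nz)
  amp <- array(0, dim = c(gs, 3))
  dirs <- array(0, dim = c(gs, 3, 3))
  wm <- array(FALSE, dim = gs)
  wm[ix, iy, ] <- TRUE
  amp[ix, iy, , 1] <- amplitude
  dirs[ix, iy, , 1, 3] <- 1
  orientation_field(gs, voxel_size, amp, dirs, wm)
}

# Exhaustive path-enumeration oracle for the deterministic straight-column
# case: marches a straight line in +/- z from a dense grid of seed
# positions inside every column voxel and records the voxel-visitation set.
# Returns the expected count per column voxel for `spv` seeds per voxel
# (errors if different seed positions ever visit different voxel sets).
oracle_column_counts <- function(nz, spv, voxel_size = 2, step = 1,
                                 positions = c(0.1, 0.35, 0.6, 0.9)) {
  visits <- NULL
  for (k in seq_len(nz) - 1L) {
    for (fz in positions) {
      z <- (k + fz) * voxel_size
      pts <- z
      zz <- z
      while (zz + step < nz * voxel_size) { zz <- zz + step; pts <- c(pts, zz) }
      zz <- z
      while (zz - step >= 0) { zz <- zz - step; pts <- c(pts, zz) }
      vis <- sort(unique(floor(pts / voxel_size)))
      if (is.null(visits)) visits <- vis
      else if (!identical(visits, vis))
        stop("oracle: seed positions disagree on visited voxels")
    }
  }
  # every streamline from every seed voxel visits `visits`
  counts <- integer(nz)
  counts[visits + 1L] <- as.integer(nz * spv)
  counts
}

# ---- brute-force TFCE -----------------------------------------------------

# connected-component labelling by breadth-first search
oracle_label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, dim = d)
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (lab[v[1], v[2], v[3]] > 0L) next
    cur <- cur + 1L
    stack <- matrix(v, 1, 3)
    lab[v[1], v[2], v[3]] <- cur
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack <- rbind(stack, q, deparse.level = 0)
        }
      }
    }
  }
  lab
}

oracle_tfce <- function(stat, H = 2, E = 0.5, dh = NULL, connectivity = 26) {
  out <- array(0, dim = dim(stat))
  hmax <- max(stat)
  if (hmax <= 0) return(out)
  if (is.null(dh)) dh <- hmax / 100
  nh <- floor(hmax / dh + 1e-10)
  for (m in seq_len(nh)) {
    h <- m * dh
    supra <- stat >= h
    lab <- oracle_label_components(supra, connectivity)
    sizes <- tabulate(lab)
    idx <- which(supra)
    out[idx] <- out[idx] + sizes[lab[idx]]^E * h^H * dh
  }
  out
}

# ---- pooled two-sample t map (naive) --------------------------------------

oracle_tmap <- function(data, groups) {
  g1 <- groups == levels(factor(groups))[2]
  apply(data, 1, function(x) {
    a <- x[!g1]; b <- x[g1]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    if (se == 0) 0 else (mean(b) - mean(a)) / se
  })
}

# ---- misc -----------------------------------------------------------------

# naive mean over a mask by explicit loop
oracle_masked_mean <- function(map, mask) {
  tot <- 0; n <- 0
  for (v in seq_along(map)) if (mask[v]) { tot <- tot + map[v]; n <- n + 1 }
  tot / n
}

# partial correlation via explicit normal equations
oracle_partial_cor <- function(x, y, Z) {
  Z <- cbind(1, as.matrix(Z))
  rx <- x - Z %*% solve(t(Z) %*% Z, t(Z) %*% x)
  ry <- y - Z %*% solve(t(Z) %*% Z, t(Z) %*% y)
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# small deterministic tracking parameter set used across tests
det_params <- function(spv = 10, seed = 1)
  tracking_params(seeds_per_voxel = spv, dispersion_kappa = Inf,
                  rng_seed = seed)

# fitted tensor as a 3x3 matrix at a 1-based (i, j, k) voxel
tensor_matrix_from_fit <- function(tf, ijk) {
  gs <- tf$grid_shape
  n3 <- prod(gs)
  v <- ijk[1] + (ijk[2] - 1) * gs[1] + (ijk[3] - 1) * gs[1] * gs[2]
  d6 <- tf$tensor[v + n3 * (0:5)]
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}
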