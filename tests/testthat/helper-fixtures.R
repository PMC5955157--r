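# Shared fixtures: tiny images, random masks, and independent oracles
# (brute-force flood fill, triple-loop overlap counts, Mann-Whitney split
# enumeration) used to cross-check the package's implementations.

toy_grid <- function(shape = c(3, 3, 3), spacing = c(4, 4, 4),
                     origin = c(0, 0, 0)) {
  volume_grid(shape, spacing, origin)
}

# 3x3x3: center voxel 10, its six face neighbors 6, everything else 1
toy_center_image <- function(spacing = c(4, 4, 4)) {
  a <- array(1, c(3, 3, 3))
  a[2, 2, 2] <- 10
  a[1, 2, 2] <- a[3, 2, 2] <- a[2, 1, 2] <- a[2, 3, 2] <-
    a[2, 2, 1] <- a[2, 2, 3] <- 6
  suv_image(a, toy_grid(spacing = spacing))
}

rand_pet <- function(shape = c(8, 8, 8), seed = 1, spacing = c(4, 4, 4)) {
  set.seed(seed)
  g <- volume_grid(shape, spacing, origin = -spacing * (shape - 1) / 2)
  suv_image(array(runif(prod(shape), 0, 10), shape), g)
}

rand_mask <- function(grid, p = 0.3, seed = 1, nonempty = TRUE) {
  set.seed(seed)
  m <- array(runif(prod(grid$shape)) < p, grid$shape)
  if (nonempty && !any(m)) m[1, 1, 1] <- TRUE
  binary_mask(m, grid)
}

quiet_phantom <- function(..., seed = 1) {
  generate_patient(phantom_config(..., noise_sd = 0, anat_noise_sd = 0,
                                  seed = seed))
}

# independent overlap oracle: explicit triple loop over voxels
oracle_overlap <- function(a, b) {
  d <- dim(a$membership)
  ni <- na <- nb <- 0L
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    ai <- a$membership[i, j, k]; bi <- b$membership[i, j, k]
    na <- na + ai; nb <- nb + bi; ni <- ni + (ai && bi)
  }
  list(n_i = na, n_r = nb, n_intersection = ni,
       dice = 2 * ni / (na + nb), jaccard = ni / (na + nb - ni),
       of = ni / min(na, nb), vci = ni / na, vcr = ni / nb)
}

# independent 26-connectivity flood fill: explicit stack-based DFS
oracle_flood_26 <- function(cand, seed_idx) {
  d <- dim(cand)
  comp <- array(FALSE, d)
  stack <- list(seed_idx)
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > d)) next
      if (cand[w[1], w[2], w[3]] && !comp[w[1], w[2], w[3]]) {
        comp[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
  }
  comp
}

# Mann-Whitney two-sided p by exhaustive enumeration of group splits
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# voxels of a mask with at least one 6-neighbor outside the mask
count_surface_voxels <- function(mask) {
  m <- mask$membership
  d <- dim(m)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  sum(m) - sum(core)
}
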