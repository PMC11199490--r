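# Shared oracles and fixtures, all generated in code.

# O(n * m) brute-force squared Euclidean distance (voxel units) from every
# voxel of a grid to the nearest TRUE voxel of `target`; independent of the
# package's separable transform.
brute_edt2 <- function(target) {
  dims <- dim(target)
  idx <- which(target)
  stopifnot(length(idx) > 0)
  co <- cbind((idx - 1) %% dims[1],
              ((idx - 1) %/% dims[1]) %% dims[2],
              (idx - 1) %/% (dims[1] * dims[2]))
  n <- prod(dims)
  gz <- (seq_len(n) - 1) %% dims[1]
  gy <- ((seq_len(n) - 1) %/% dims[1]) %% dims[2]
  gx <- (seq_len(n) - 1) %/% (dims[1] * dims[2])
  best <- rep(Inf, n)
  for (t in seq_len(nrow(co))) {
    best <- pmin(best, (gz - co[t, 1])^2 + (gy - co[t, 2])^2 + (gx - co[t, 3])^2)
  }
  array(best, dims)
}

# Hochberg step-up adjusted p-values by the textbook recursion.
brute_hochberg <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ps <- p[o]
  adj <- numeric(m)
  adj[1] <- min(1, ps[1])
  for (i in seq_len(m)[-1]) adj[i] <- min(adj[i - 1], i * ps[i])
  out <- numeric(m)
  out[o] <- adj
  out
}

# BH rejection set at level alpha straight from the max-k definition.
brute_bh_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) / m * alpha)
  if (!length(ks)) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

# small fast phantom configuration for segmentation-level tests
small_phantom_config <- function(seed = 1L, n_lacunae = 30L, n_canals = 2L,
                                 noise = 0, ...) {
  phantom_config(shape_voxels = c(64L, 96L, 96L),
                 cortex = list(outer_radius_um = 55, inner_radius_um = 24),
                 canals = list(count = n_canals, radius_um = 4,
                               orientation_jitter_deg = 3),
                 lacunae = list(target_count = n_lacunae,
                                volume_median_um3 = 160,
                                sigma_log = 0.45,
                                truncation = c(100, 500),
                                axis_ratio_range = list(mid = c(0.4, 0.7),
                                                        short = c(0.3, 0.5)),
                                volume_scale = 1, endosteal_volume_scale = 1),
                 noise_sigma_frac = noise, seed = seed, ...)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Paint an ellipsoid void (semi-axes um, axis-aligned) into a baseline
# array; returns the modified array. Voxel centres at (index-1)*spacing.
paint_void <- function(arr, center_um, semi_um, spacing, value = 0.1) {
  dims <- dim(arr)
  z <- (seq_len(dims[1]) - 1) * spacing
  y <- (seq_len(dims[2]) - 1) * spacing
  x <- (seq_len(dims[3]) - 1) * spacing
  zz <- array(rep(z, times = dims[2] * dims[3]), dims)
  yy <- aperm(array(rep(y, times = dims[1] * dims[3]), c(dims[2], dims[1], dims[3])), c(2, 1, 3))
  xx <- aperm(array(rep(x, times = dims[1] * dims[2]), c(dims[3], dims[2], dims[1])), c(3, 2, 1))
  inside <- ((zz - center_um[1]) / semi_um[1])^2 +
    ((yy - center_um[2]) / semi_um[2])^2 +
    ((xx - center_um[3]) / semi_um[3])^2 <= 1
  arr[inside] <- value
  arr
}

simulate_nested <- function(n_bones = 4, n_lac = 30, effect = 0,
                            sd_bone = 5, sd_lac = 10, seed = 1) {
  set.seed(seed)
  grp <- rep(c("a", "b"), each = n_bones)
  bones <- paste0(grp, rep(seq_len(n_bones), 2))
  do.call(rbind, lapply(seq_along(bones), function(i) {
    data.frame(cohort = grp[i], sample_id = bones[i],
               y = 100 + (grp[i] == "b") * effect + rnorm(1, 0, sd_bone) +
                 rnorm(n_lac, 0, sd_lac))
  }))
}

make_annulus_mask <- function(R_um = 130, r_um = 65, h_um = 130, sp = 1.3) {
  nxy <- ceiling(2 * R_um / sp) + 9
  nz <- round(h_um / sp)
  c_um <- (nxy - 1) / 2 * sp
  xy <- (seq_len(nxy) - 1) * sp
  rr <- sqrt(outer((xy - c_um)^2, (xy - c_um)^2, "+"))
  ring <- rr <= R_um & rr > r_um
  arr <- aperm(array(ring, c(nxy, nxy, nz)), c(3, 1, 2))
  volume3d(arr + 0L, sp, "binary")
}
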