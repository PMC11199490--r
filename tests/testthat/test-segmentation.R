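# A hand-built synthetic slab with planted voids of known size/shape
# (independent of the phantom generator).
make_slab <- function(dims = c(40, 60, 90), sp = 1.3,
                      baseline = 1, background = 0.1) {
  arr <- array(baseline, dims)
  volume3d(arr, sp, "attenuation")
}

test_that("bone segmentation recovers the phantom cortex", {
  cfg <- small_phantom_config(seed = 2L, n_lacunae = 25L, n_canals = 2L, noise = 0)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  expect_gte(dice(bone$data > 0, ph$truth$bone_mask$data > 0), 0.99)

  cfg5 <- small_phantom_config(seed = 2L, n_lacunae = 25L, n_canals = 2L, noise = 0.05)
  ph5 <- generate_phantom(cfg5)
  bone5 <- segment_bone(ph5$attenuation)
  expect_gte(dice(bone5$data > 0, ph5$truth$bone_mask$data > 0), 0.98)

  flat <- volume3d(array(0.1, c(16, 16, 16)), 1.3, "attenuation")
  expect_error(segment_bone(flat, segmentation_params(bone_threshold = 0.5)),
               "no bone detected")
})

test_that("the size, shape and edge filters remove the planted artifacts", {
  sp <- 1.3
  vol <- make_slab()
  r60 <- (3 * 60 / (4 * pi))^(1 / 3)    # sphere of 60 um^3 (below range)
  r800 <- (3 * 800 / (4 * pi))^(1 / 3)  # 800 um^3 (above range)
  r300 <- (3 * 300 / (4 * pi))^(1 / 3)  # admissible control
  a <- vol$data
  a <- paint_void(a, c(26, 15, 15) * sp, rep(r60, 3), sp)
  a <- paint_void(a, c(26, 40, 40) * sp, rep(r800, 3), sp)
  a <- paint_void(a, c(26, 15, 70) * sp, rep(r300, 3), sp)
  # rod: 3.4 x 3.4 x 96 um extents, ~580 um^3, aspect ratio ~ 0.035 --
  # wide enough to survive the median-filter overlap check, so the shape
  # filter is what removes it
  a <- paint_void(a, c(20, 10, 44) * sp, c(1.7, 1.7, 48), sp)
  a <- paint_void(a, c(0.5, 28, 15) * sp, rep(r300, 3), sp)     # touches z = 1
  vol$data <- a
  params <- segmentation_params(bone_threshold = 0.5)
  bone <- volume3d(array(1L, dim(a)), sp, "binary")
  res <- segment_lacunae(vol, bone, params)
  expect_equal(nrow(res$table), 1L)
  expect_true(abs(res$table$volume_um3 - 300) < 60)
  counts <- res$qc$counts
  expect_equal(unname(counts["candidates"]),
               unname(counts["retained"] + counts["removed_size"] +
                        counts["removed_overlap"] + counts["removed_edge"] +
                        counts["removed_aspect"] + counts["removed_manual"]))
  expect_gte(counts[["removed_size"]], 2)   # 60 and 800 um^3 voids
  expect_gte(counts[["removed_edge"]], 1)   # z-edge void
  expect_gte(counts[["removed_aspect"]], 1) # the rod
  rej <- res$qc$rejected
  expect_true(any(rej$aspect_removed & rej$aspect_ratio < 0.05))
})

test_that("a noise-free phantom yields one row per planted lacuna with faithful volumes", {
  cfg <- small_phantom_config(seed = 6L, n_lacunae = 50L, n_canals = 0L, noise = 0)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  res <- segment_lacunae(ph$attenuation, bone)
  expect_equal(nrow(res$table), 50L)
  # match segmented components to truth by voxel overlap
  seg <- res$labels$data; tru <- ph$truth$lacuna_labels$data
  sel <- seg > 0 & tru > 0
  pairs <- unique(data.frame(seg = seg[sel], tru = tru[sel]))
  expect_equal(nrow(pairs), 50L)  # one-to-one
  m <- merge(merge(pairs, res$table, by.x = "seg", by.y = "id"),
             ph$truth$lacuna_params, by.x = "tru", by.y = "id")
  # per-lacuna volume error bounded by a one-voxel surface shell
  # (ellipsoid surface area ~ 4*pi*(abc)^(2/3) within a few percent)
  shell_um3 <- 4 * pi * (m$semi_a_um.y * m$semi_b_um.y * m$semi_c_um.y)^(2 / 3) *
    cfg$spacing_um
  rel <- abs(m$volume_um3 - m$analytic_volume_um3)
  expect_true(all(rel <= shell_um3))
  expect_lt(abs(mean(m$volume_um3 / m$analytic_volume_um3) - 1), 0.05)
})

test_that("every retained lacuna re-passes all filter predicates independently", {
  cfg <- small_phantom_config(seed = 8L, n_lacunae = 30L, n_canals = 1L, noise = 0.05)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  params <- segmentation_params()
  res <- segment_lacunae(ph$attenuation, bone, params)
  thr <- res$qc$threshold
  ref <- perilacunar:::median_filter3(ph$attenuation$data,
                                      params$smoothing_kernel_k) < thr
  labels <- res$labels$data
  dims <- dim(labels)
  sp <- cfg$spacing_um
  for (id in res$table$id) {
    idx <- which(labels == id)
    v <- length(idx) * sp^3
    expect_true(v >= 65 && v <= 700)
    expect_true(any(ref[idx]))
    zyx <- perilacunar:::lin_to_zyx(idx, dims)
    expect_false(any(zyx[, "z"] %in% c(1L, dims[1])))
    shp <- perilacunar:::component_shape(
      cbind((zyx[, "x"] - 1) * sp, (zyx[, "y"] - 1) * sp, (zyx[, "z"] - 1) * sp), sp)
    expect_gte(shp$aspect_ratio, 0.05)
  }
})

test_that("the retained set is invariant to the order of filters 3-6", {
  # filters are pure predicates on the fixed component set, so the package
  # evaluates them independently; verify against an explicit re-ordered
  # sequential application on several random phantoms
  for (seed in 1:8) {
    cfg <- small_phantom_config(seed = seed, n_lacunae = 15L, n_canals = 1L,
                                noise = 0.05)
    ph <- generate_phantom(cfg)
    bone <- segment_bone(ph$attenuation)
    params <- segmentation_params()
    res <- segment_lacunae(ph$attenuation, bone, params)
    thr <- res$qc$threshold
    void <- ph$attenuation$data < thr
    labels <- perilacunar:::label_components(void, 26L)
    dims <- dim(labels)
    sp <- cfg$spacing_um
    ref <- perilacunar:::median_filter3(ph$attenuation$data, 3L) < thr
    counts <- tabulate(labels[labels > 0L])
    # apply the predicates in a permuted order: aspect, edge, overlap, size
    ids <- which(counts > 0)
    keep <- logical(length(ids))
    for (k in seq_along(ids)) {
      idx <- which(labels == ids[k])
      v <- counts[ids[k]] * sp^3
      if (v < 30 || v > 1500) { keep[k] <- FALSE; next }  # cheap pre-cut only
      zyx <- perilacunar:::lin_to_zyx(idx, dims)
      shp <- perilacunar:::component_shape(
        cbind((zyx[, "x"] - 1) * sp, (zyx[, "y"] - 1) * sp, (zyx[, "z"] - 1) * sp), sp)
      keep[k] <- shp$aspect_ratio >= 0.05 &&
        !any(zyx[, "z"] %in% c(1L, dims[1])) &&
        any(ref[idx]) &&
        v >= 65 && v <= 700
    }
    expect_setequal(ids[keep], res$table$id)
  }
})

test_that("canal segmentation recovers planted cylinders and drops small pores", {
  cfg <- small_phantom_config(seed = 12L, n_lacunae = 0L, n_canals = 2L, noise = 0)
  cfg$canals$orientation_jitter_deg <- 0
  cfg$canals$radius_um <- 8
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  canals <- segment_canals(ph$attenuation, bone)
  expect_equal(max(canals$data), 2L)
  sp <- cfg$spacing_um
  analytic <- pi * cfg$canals$radius_um^2 * (dim(ph$attenuation$data)[1] * sp)
  for (cid in 1:2) {
    v <- sum(canals$data == cid) * sp^3
    expect_lt(abs(v - analytic) / analytic, 0.10)
  }
  # an intracortical pore of 500 um^3 is below the canal volume floor
  vol <- ph$attenuation
  r500 <- (3 * 500 / (4 * pi))^(1 / 3)
  ctr_idx <- which(ph$truth$bone_mask$data > 0 & ph$truth$canal_labels$data == 0)
  zyx <- perilacunar:::lin_to_zyx(ctr_idx, dim(vol$data))
  pick <- which(zyx[, "z"] == 32)[1]
  # place it mid-cortex, away from the canals
  dists <- sqrt((zyx[, "y"] - dim(vol$data)[2] / 2)^2 +
                  (zyx[, "x"] - dim(vol$data)[3] / 2)^2)
  ring <- which(zyx[, "z"] == 32 & abs(dists * sp - 40) < 2)
  ctr <- (zyx[ring[1], c("z", "y", "x")] - 1) * sp
  vol$data <- paint_void(vol$data, ctr, rep(r500, 3), sp)
  canals2 <- segment_canals(vol, bone)
  expect_equal(max(canals2$data), 2L)  # still only the two true canals

  cfg0 <- small_phantom_config(seed = 12L, n_lacunae = 0L, n_canals = 0L, noise = 0)
  ph0 <- generate_phantom(cfg0)
  c0 <- segment_canals(ph0$attenuation, segment_bone(ph0$attenuation))
  expect_identical(sum(c0$data), 0L)
})

test_that("surface identification separates endosteum and periosteum", {
  cfg <- small_phantom_config(seed = 13L, n_lacunae = 10L, n_canals = 1L, noise = 0)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  surf <- suppressWarnings(identify_surfaces(bone))
  expect_gte(dice(surf$endosteum_mask$data > 0, ph$truth$endosteum_mask$data > 0), 0.95)
  expect_gte(dice(surf$periosteum_mask$data > 0, ph$truth$periosteum_mask$data > 0), 0.95)
  # ideal annulus: every endosteal voxel radially inside every periosteal one
  dims <- dim(bone$data)
  cy <- (dims[2] - 1) / 2; cx <- (dims[3] - 1) / 2
  rad <- function(mask) {
    idx <- which(mask > 0)
    zyx <- perilacunar:::lin_to_zyx(idx, dims)
    sqrt((zyx[, "y"] - 1 - cy)^2 + (zyx[, "x"] - 1 - cx)^2)
  }
  expect_lt(max(rad(surf$endosteum_mask$data)), min(rad(surf$periosteum_mask$data)))

  solid <- volume3d(array(0.1, c(20, 40, 40)), 1.3, "attenuation")
  solid$data[, 10:30, 10:30] <- 1
  sb <- segment_bone(solid, segmentation_params(bone_threshold = 0.5))
  expect_warning(s2 <- identify_surfaces(sb), "no enclosed cavity")
  expect_identical(sum(s2$endosteum_mask$data), 0L)
})

test_that("retained lacuna counts are stable under small threshold perturbations", {
  cfg <- small_phantom_config(seed = 14L, n_lacunae = 40L, n_canals = 1L, noise = 0)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  base_thr <- attr(bone, "threshold")
  n <- sapply(c(0.95, 1, 1.05), function(f) {
    p <- segmentation_params(bone_threshold = base_thr * f)
    nrow(segment_lacunae(ph$attenuation, bone, p)$table)
  })
  expect_lt(max(abs(n - n[2]) / n[2]), 0.05)
})

test_that("canal and lacuna label sets are voxel-disjoint", {
  cfg <- small_phantom_config(seed = 15L, n_lacunae = 20L, n_canals = 2L, noise = 0.05)
  ph <- generate_phantom(cfg)
  bone <- segment_bone(ph$attenuation)
  lac <- segment_lacunae(ph$attenuation, bone)
  can <- segment_canals(ph$attenuation, bone)
  expect_identical(sum(lac$labels$data > 0 & can$data > 0), 0L)
})
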