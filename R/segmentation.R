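#' Segmentation parameters
#'
#' Parameters of the bone / lacuna / canal segmentation cascade. Defaults
#' follow the SRuCT protocol this pipeline reproduces: lacunar volumes
#' restricted to 65-700 um^3, a k = 3 median-filtered reference
#' segmentation for the noise (overlap) filter, aspect ratio >= 0.05 to
#' exclude rod-like artifacts, two k = 3 median passes and a 750 um^3
#' minimum volume for canals, and 26-connected components throughout.
#'
#' @param bone_threshold `"auto"` (between-class-variance maximization) or
#'   an explicit numeric threshold; voxels below it are void/background.
#' @param closing_radius_vox Ball radius (voxels) of the morphological
#'   closing applied to the bone mask.
#' @param lacuna_volume_bounds_um3 Admissible lacunar volume range, um^3.
#' @param smoothing_kernel_k Median kernel for the reference segmentation.
#' @param aspect_ratio_min Minimum shortest/longest principal-extent ratio.
#' @param canal_median_passes,canal_median_k Median filtering of the canal
#'   segmentation input.
#' @param canal_volume_min_um3 Minimum canal component volume, um^3.
#' @param connectivity Voxel connectivity: 6, 18 or 26.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(bone_threshold = "auto",
                                closing_radius_vox = 1,
                                lacuna_volume_bounds_um3 = c(65, 700),
                                smoothing_kernel_k = 3L,
                                aspect_ratio_min = 0.05,
                                canal_median_passes = 2L,
                                canal_median_k = 3L,
                                canal_volume_min_um3 = 750,
                                connectivity = 26L) {
  b <- lacuna_volume_bounds_um3
  if (!(length(b) == 2L && b[1] < b[2])) stop("lacuna volume bounds must be ordered")
  if (smoothing_kernel_k %% 2L != 1L || canal_median_k %% 2L != 1L)
    stop("median kernel sizes must be odd")
  if (!(aspect_ratio_min > 0 && aspect_ratio_min <= 1))
    stop("aspect_ratio_min must lie in (0, 1]")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(bone_threshold = bone_threshold,
                 closing_radius_vox = closing_radius_vox,
                 lacuna_volume_bounds_um3 = b,
                 smoothing_kernel_k = as.integer(smoothing_kernel_k),
                 aspect_ratio_min = aspect_ratio_min,
                 canal_median_passes = as.integer(canal_median_passes),
                 canal_median_k = as.integer(canal_median_k),
                 canal_volume_min_um3 = canal_volume_min_um3,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

resolve_threshold <- function(vol_data, params) {
  if (identical(params$bone_threshold, "auto")) otsu_threshold(as.vector(vol_data))
  else as.numeric(params$bone_threshold)
}

#' Segment the cortical bone mask
#'
#' Thresholds the attenuation volume (automatic between-class-variance
#' threshold or an explicit value), applies a morphological closing with a
#' Euclidean ball, and keeps the largest connected component.
#'
#' @param vol Attenuation [volume3d()].
#' @param params A [segmentation_params()].
#' @return Binary [volume3d()] with attributes `threshold` (value used).
#' @export
segment_bone <- function(vol, params = segmentation_params()) {
  stopifnot_volume(vol)
  thr <- resolve_threshold(vol$data, params)
  mask <- vol$data >= thr
  if (!any(mask))
    stop(sprintf("segment_bone: no bone detected at threshold %.4g", thr))
  mask <- close_ball(mask, params$closing_radius_vox)
  labs <- label_components(mask, params$connectivity)
  if (max(labs) == 0L)
    stop(sprintf("segment_bone: no bone detected at threshold %.4g", thr))
  counts <- tabulate(labs[labs > 0L])
  keep <- which.max(counts)
  out <- volume3d(array(as.integer(labs == keep), dim(mask)), vol$spacing_um, "binary")
  attr(out, "threshold") <- thr
  out
}

lin_to_zyx <- function(idx, dims) {
  nz <- dims[1]; ny <- dims[2]
  i0 <- idx - 1L
  z <- i0 %% nz
  y <- (i0 %/% nz) %% ny
  x <- i0 %/% (nz * ny)
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

#' Segment osteocyte lacunae
#'
#' The five-filter cascade: (1) threshold voids; (2) 26-connected
#' components; (3) volume filter (65-700 um^3 by default); (4) overlap
#' filter against a reference segmentation from a k = 3 median-filtered
#' image (a component must share at least one voxel); (5) removal of
#' components touching the first or last z-slice (incomplete lacunae);
#' (6) aspect-ratio filter (>= 0.05) excluding rod-like artifacts. Volume
#' is voxel count times spacing^3. The manual corrections of interactive
#' workflows are replaced by an optional reproducible exclusion list of
#' component ids.
#'
#' @param vol Attenuation [volume3d()].
#' @param bone_mask Binary [volume3d()] from [segment_bone()].
#' @param params A [segmentation_params()].
#' @param exclude_ids Optional integer vector of component ids to drop
#'   after the cascade (reproducible stand-in for manual correction).
#' @param prefiltered Optional cached median-filtered image (k =
#'   `smoothing_kernel_k`) to avoid refiltering when several stages share
#'   it.
#' @return List: `labels` ([volume3d()], retained components keep their
#'   original component ids), `table` (one row per retained lacuna: id,
#'   volume, centroid, principal semi-axes descending, aspect ratio,
#'   voxel count), `qc` (filter ledger counts and the rejected-candidate
#'   table with removal flags).
#' @export
segment_lacunae <- function(vol, bone_mask, params = segmentation_params(),
                            exclude_ids = NULL, prefiltered = NULL) {
  stopifnot_volume(vol); stopifnot_volume(bone_mask)
  if (!any(bone_mask$data > 0)) stop("segment_lacunae: bone_mask is empty")
  sp <- vol$spacing_um
  thr <- resolve_threshold(vol$data, params)
  void <- vol$data < thr
  labels <- label_components(void, params$connectivity)
  dims <- dim(labels)
  all_idx <- which(labels > 0L)
  labs <- labels[all_idx]
  counts <- tabulate(labs)
  n_cand <- length(counts)
  vol_um3 <- counts * sp^3
  b <- params$lacuna_volume_bounds_um3
  pass_size <- vol_um3 >= b[1] & vol_um3 <= b[2]

  # reference segmentation for the noise/overlap filter
  if (is.null(prefiltered))
    prefiltered <- median_filter3(vol$data, params$smoothing_kernel_k)
  ref <- prefiltered < thr

  keep_vox <- pass_size[labs]
  idx <- all_idx[keep_vox]
  labs2 <- labs[keep_vox]
  zyx <- lin_to_zyx(idx, dims)
  groups <- split(seq_along(labs2), labs2)
  ids_size <- as.integer(names(groups))

  overlap_ok <- vapply(groups, function(g) any(ref[idx[g]]), logical(1))
  edge_ok <- vapply(groups, function(g) {
    zz <- zyx[g, "z"]; !(any(zz == 1L) || any(zz == dims[1]))
  }, logical(1))
  shape_list <- lapply(groups, function(g) {
    component_shape(cbind((zyx[g, "x"] - 1) * sp, (zyx[g, "y"] - 1) * sp,
                          (zyx[g, "z"] - 1) * sp), sp)
  })
  aspect <- vapply(shape_list, function(s) s$aspect_ratio, numeric(1))
  aspect_ok <- aspect >= params$aspect_ratio_min

  # sequential attribution for the QC ledger (spec order of the cascade)
  removed_size <- sum(!pass_size)
  fail_overlap <- !overlap_ok
  fail_edge <- overlap_ok & !edge_ok
  fail_aspect <- overlap_ok & edge_ok & !aspect_ok
  retained_mask <- overlap_ok & edge_ok & aspect_ok
  retained_ids <- ids_size[retained_mask]
  manual_removed <- intersect(retained_ids, exclude_ids %||% integer())
  retained_ids <- setdiff(retained_ids, manual_removed)

  mk_row <- function(id) {
    g <- groups[[as.character(id)]]
    shp <- shape_list[[as.character(id)]]
    data.frame(id = id,
               volume_um3 = counts[id] * sp^3,
               centroid_z_um = mean((zyx[g, "z"] - 1) * sp),
               centroid_y_um = mean((zyx[g, "y"] - 1) * sp),
               centroid_x_um = mean((zyx[g, "x"] - 1) * sp),
               semi_a_um = shp$semi_axes_um[1],
               semi_b_um = shp$semi_axes_um[2],
               semi_c_um = shp$semi_axes_um[3],
               aspect_ratio = shp$aspect_ratio,
               voxel_count = counts[id])
  }
  table <- if (length(retained_ids)) {
    do.call(rbind, lapply(retained_ids, mk_row))
  } else {
    data.frame(id = integer(), volume_um3 = numeric(),
               centroid_z_um = numeric(), centroid_y_um = numeric(),
               centroid_x_um = numeric(), semi_a_um = numeric(),
               semi_b_um = numeric(), semi_c_um = numeric(),
               aspect_ratio = numeric(), voxel_count = integer())
  }

  rejected <- data.frame(id = ids_size,
                         volume_um3 = counts[ids_size] * sp^3,
                         aspect_ratio = unname(aspect),
                         size_removed = rep(FALSE, length(ids_size)),
                         overlap_removed = unname(fail_overlap),
                         edge_removed = unname(fail_edge),
                         aspect_removed = unname(fail_aspect))
  rejected <- rejected[!retained_mask, , drop = FALSE]

  out_labels <- labels
  out_labels[!(labels %in% retained_ids)] <- 0L

  qc <- list(counts = c(candidates = n_cand,
                        removed_size = removed_size,
                        removed_overlap = sum(fail_overlap),
                        removed_edge = sum(fail_edge),
                        removed_aspect = sum(fail_aspect),
                        removed_manual = length(manual_removed),
                        retained = length(retained_ids)),
             threshold = thr,
             rejected = rejected)
  list(labels = volume3d(out_labels, sp, "labels"), table = table, qc = qc)
}

#' Segment intracortical vascular canals
#'
#' Two sequential median filters (k = 3), void thresholding, removal of
#' components connected to the exterior or medullary background, and a
#' minimum-volume filter (750 um^3).
#'
#' @param vol Attenuation [volume3d()].
#' @param bone_mask Binary [volume3d()] from [segment_bone()].
#' @param params A [segmentation_params()].
#' @param surfaces Optional result of [identify_surfaces()] (recomputed
#'   from `bone_mask` when omitted).
#' @param prefiltered Optional cached single-pass median-filtered image
#'   reused as the first of the two passes.
#' @return Label [volume3d()], canals renumbered 1..n.
#' @export
segment_canals <- function(vol, bone_mask, params = segmentation_params(),
                           surfaces = NULL, prefiltered = NULL) {
  stopifnot_volume(vol); stopifnot_volume(bone_mask)
  if (!any(bone_mask$data > 0)) stop("segment_canals: bone_mask is empty")
  sp <- vol$spacing_um
  thr <- resolve_threshold(vol$data, params)
  f <- vol$data
  passes <- params$canal_median_passes
  if (!is.null(prefiltered) && passes >= 1L) {
    f <- prefiltered
    passes <- passes - 1L
  }
  for (i in seq_len(passes))
    f <- median_filter3(f, params$canal_median_k)
  void <- f < thr
  labels <- label_components(void, params$connectivity)
  if (is.null(surfaces))
    surfaces <- suppressWarnings(identify_surfaces(bone_mask, params))
  background <- surfaces$exterior_mask$data > 0 | surfaces$medullary_mask$data > 0
  bg_ids <- unique(labels[background & labels > 0L])
  counts <- tabulate(labels[labels > 0L])
  min_vox <- params$canal_volume_min_um3 / sp^3
  keep_ids <- setdiff(which(counts >= min_vox), bg_ids)
  out <- array(0L, dim(labels))
  if (length(keep_ids)) {
    remap <- integer(length(counts))
    remap[keep_ids] <- seq_along(keep_ids)
    sel <- labels > 0L & labels %in% keep_ids
    out[sel] <- remap[labels[sel]]
  }
  volume3d(out, sp, "labels")
}

#' Identify the endosteal and periosteal bone surfaces
#'
#' Classifies the background of a bone mask: the component touching the
#' volume's lateral (x/y) border is the exterior; enclosed components are
#' medullary candidates, of which the largest is taken as the medullary
#' cavity (smaller enclosed components are intracortical pores). The
#' periosteum is the set of bone voxels 26-adjacent to the exterior, the
#' endosteum the set 26-adjacent to the medullary cavity. With no enclosed
#' cavity the endosteum is empty and a warning is raised.
#'
#' @param bone_mask Binary [volume3d()].
#' @param params A [segmentation_params()] (connectivity).
#' @return List of binary [volume3d()]: `endosteum_mask`,
#'   `periosteum_mask`, `medullary_mask`, `exterior_mask`.
#' @export
identify_surfaces <- function(bone_mask, params = segmentation_params()) {
  stopifnot_volume(bone_mask)
  sp <- bone_mask$spacing_um
  bone <- bone_mask$data > 0
  dims <- dim(bone)
  comp <- label_components(!bone, params$connectivity)
  border <- array(FALSE, dims)
  border[, 1, ] <- TRUE; border[, dims[2], ] <- TRUE
  border[, , 1] <- TRUE; border[, , dims[3]] <- TRUE
  ext_ids <- unique(comp[border & comp > 0L])
  counts <- tabulate(comp[comp > 0L])
  enclosed_ids <- setdiff(which(counts > 0), ext_ids)
  exterior <- array(comp > 0L & (comp %in% ext_ids), dims)
  if (!length(enclosed_ids)) {
    warning("identify_surfaces: bone mask has no enclosed cavity; endosteum is empty")
    medullary <- array(FALSE, dims)
  } else {
    if (length(enclosed_ids) > 1L)
      warning(sprintf("identify_surfaces: %d enclosed cavities; largest taken as medullary, others treated as intracortical pores",
                      length(enclosed_ids)))
    med_id <- enclosed_ids[which.max(counts[enclosed_ids])]
    medullary <- array(comp == med_id, dims)
  }
  adj <- function(m) {
    if (!any(m)) return(array(FALSE, dims))
    array(cpp_dilate26(m, dims), dims) & bone
  }
  list(endosteum_mask = volume3d(adj(medullary) + 0L, sp, "binary"),
       periosteum_mask = volume3d(adj(exterior) + 0L, sp, "binary"),
       medullary_mask = volume3d(medullary + 0L, sp, "binary"),
       exterior_mask = volume3d(exterior + 0L, sp, "binary"))
}
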