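#' Euclidean distance map to a target surface
#'
#' Exact Euclidean distance transform of the complement of a target mask:
#' every voxel receives its distance in micrometres to the nearest target
#' voxel (zero on the target itself). Distances are voxel-centre to
#' voxel-centre.
#'
#' @param target_mask Binary [volume3d()] (non-empty).
#' @param name Surface name used in the empty-target error message.
#' @return A [volume3d()] of kind `"distance"`.
#' @export
distance_map <- function(target_mask, name = "target") {
  stopifnot_volume(target_mask)
  if (!any(target_mask$data > 0))
    stop(sprintf("distance_map: surface '%s' is empty", name))
  d <- edt(target_mask$data, target_mask$spacing_um)$distance_um
  volume3d(d, target_mask$spacing_um, "distance")
}

#' Assign lacunae to their nearest vascular surface
#'
#' For every lacuna, the minimum over its voxels of the distance maps to
#' the endosteum, the canals and the periosteum; the lacuna is assigned to
#' the surface attaining the smallest of the three (argmin), with the
#' documented tie-break priority endosteum > canals > periosteum. The
#' distance to the combined vasculature equals the minimum of the three by
#' construction and is stored alongside.
#'
#' If the canal mask is missing/empty, `d_canal_um` is `NA` and assignment
#' runs over the two cortical surfaces with a warning.
#'
#' @param table Lacuna table from [segment_lacunae()].
#' @param lacuna_labels Label [volume3d()] matching `table$id`.
#' @param endosteum_mask,periosteum_mask Binary [volume3d()] surfaces.
#' @param canal_mask Binary or label [volume3d()] of canals, or `NULL`.
#' @param mode `"surface"` (minimum over the lacuna's voxels; default) or
#'   `"centroid"` (distance at the voxel nearest the centroid), provided
#'   for sensitivity analysis.
#' @return `table` with columns `d_endosteum_um`, `d_canal_um`,
#'   `d_periosteum_um`, `d_vasculature_um`, `assigned_surface` appended.
#' @export
assign_lacunae <- function(table, lacuna_labels, endosteum_mask,
                           periosteum_mask, canal_mask = NULL,
                           mode = c("surface", "centroid")) {
  mode <- match.arg(mode)
  stopifnot_volume(lacuna_labels)
  if (nrow(table) == 0) {
    table$d_endosteum_um <- numeric(0); table$d_canal_um <- numeric(0)
    table$d_periosteum_um <- numeric(0); table$d_vasculature_um <- numeric(0)
    table$assigned_surface <- character(0)
    return(table)
  }
  have_canals <- !is.null(canal_mask) && any(canal_mask$data > 0)
  if (!have_canals)
    warning("assign_lacunae: no canal mask; assigning over endosteum and periosteum only")
  d_endo <- distance_map(endosteum_mask, "endosteum")$data
  d_peri <- distance_map(periosteum_mask, "periosteum")$data
  d_can <- if (have_canals) distance_map(volume3d((canal_mask$data > 0) + 0L,
                                                  canal_mask$spacing_um, "binary"),
                                         "canals")$data else NULL

  labels <- lacuna_labels$data
  idx <- which(labels > 0L)
  labs <- labels[idx]
  if (mode == "centroid") {
    dims <- dim(labels)
    zyx <- lin_to_zyx(idx, dims)
    sp <- lacuna_labels$spacing_um
    groups <- split(seq_along(labs), labs)
    pick <- vapply(groups, function(g) {
      cz <- mean(zyx[g, "z"]); cy <- mean(zyx[g, "y"]); cx <- mean(zyx[g, "x"])
      g[which.min((zyx[g, "z"] - cz)^2 + (zyx[g, "y"] - cy)^2 + (zyx[g, "x"] - cx)^2)]
    }, numeric(1))
    idx <- idx[pick]; labs <- as.integer(names(groups))
    min_by <- function(d) d[idx]
    ids <- labs
  } else {
    min_by <- function(d) {
      as.numeric(tapply(d[idx], labs, min))
    }
    ids <- as.integer(names(tapply(idx, labs, length)))
  }
  de <- min_by(d_endo); dp <- min_by(d_peri)
  dc <- if (have_canals) min_by(d_can) else rep(NA_real_, length(de))
  dmat <- cbind(endosteum = de, canals = dc, periosteum = dp)
  surf <- apply(dmat, 1, function(r) {
    r[is.na(r)] <- Inf
    c("endosteum", "canals", "periosteum")[which.min(r)]  # ties -> priority order
  })
  dv <- pmin(de, dp, if (have_canals) dc else Inf)
  res <- data.frame(id = ids, d_endosteum_um = de, d_canal_um = dc,
                    d_periosteum_um = dp, d_vasculature_um = dv,
                    assigned_surface = surf)
  merge(table, res, by = "id", sort = TRUE)
}

#' Pooled volume quartiles
#'
#' Pools lacunar volumes across all samples and cohorts, computes the
#' 25/50/75th percentile boundaries, and labels every lacuna Q1-Q4 using
#' half-open bins `[q_k, q_{k+1})` with the last bin closed (tied values
#' always share a bin). Also reports each cohort's proportion per quartile.
#'
#' @param table Pooled lacuna table with columns `volume_um3` and
#'   (optionally) `cohort`.
#' @return List: `table` with a `volume_quartile` factor column appended,
#'   `boundaries` (the three percentile values), `proportions` (cohort x
#'   quartile proportion table, when a cohort column is present).
#' @export
volume_quartiles <- function(table) {
  if (nrow(table) < 4)
    stop("volume_quartiles: fewer than 4 lacunae in the pooled table")
  q <- stats::quantile(table$volume_um3, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bin <- findInterval(table$volume_um3, q)  # 0..3
  table$volume_quartile <- factor(paste0("Q", bin + 1L),
                                  levels = paste0("Q", 1:4))
  props <- NULL
  if (!is.null(table$cohort)) {
    tab <- table(table$cohort, table$volume_quartile)
    props <- prop.table(tab, margin = 1)
  }
  list(table = table, boundaries = q, proportions = props)
}

#' Mean minimum distances by cohort and volume quartile
#'
#' Cell means of the per-lacuna minimum distances for each cohort x
#' quartile cell, with per-bone nesting preserved: per-bone cell means are
#' emitted alongside, and the cohort-level mean is the mean of bone means
#' (bones are the experimental unit). Empty cells are reported as `NA`,
#' never zero.
#'
#' @param table Lacuna table with `cohort`, `sample_id`, `volume_quartile`
#'   and the distance columns from [assign_lacunae()].
#' @param value Name of the distance column to summarize.
#' @return List: `per_bone` (sample-level cell means) and `per_cohort`
#'   (cohort x quartile mean of bone means, long format).
#' @export
mean_min_distance_by_quartile <- function(table, value = "d_vasculature_um") {
  stopifnot(all(c("cohort", "sample_id", "volume_quartile", value) %in% names(table)))
  dt <- data.table::as.data.table(table)
  per_bone <- dt[, list(mean_distance_um = mean(.SD[[1]], na.rm = TRUE),
                        n_lacunae = .N),
                 by = c("cohort", "sample_id", "volume_quartile"),
                 .SDcols = value]
  grid <- data.table::CJ(cohort = unique(dt$cohort),
                         volume_quartile = levels(factor(dt$volume_quartile)))
  per_cohort <- per_bone[, list(mean_distance_um = mean(mean_distance_um),
                                n_bones = .N),
                         by = c("cohort", "volume_quartile")]
  per_cohort <- merge(grid, per_cohort,
                      by = c("cohort", "volume_quartile"), all.x = TRUE)
  list(per_bone = as.data.frame(per_bone),
       per_cohort = as.data.frame(per_cohort))
}
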