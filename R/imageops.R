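# Low-level voxel-grid operations shared by the segmentation, spatial and
# mineral stages. These wrap the compiled cores in src/.

#' Exact Euclidean distance transform
#'
#' Distance (in micrometres) from every voxel to the nearest `TRUE` voxel of
#' `target`, computed with the separable lower-envelope algorithm (exact,
#' O(n)). Optionally also returns the feature transform: the linear index of
#' a nearest target voxel per voxel.
#'
#' @param target Logical/0-1 3-D array or binary [volume3d()].
#' @param spacing_um Voxel spacing; taken from the volume if one is given.
#' @param feature If `TRUE`, also return the nearest-site index array.
#' @return `list(distance_um = <3-D array>, site = <int array or NULL>)`.
#' @export
edt <- function(target, spacing_um = NULL, feature = FALSE) {
  if (is_volume3d(target)) {
    spacing_um <- spacing_um %||% target$spacing_um
    target <- target$data
  }
  if (is.null(spacing_um)) stop("edt: spacing_um required")
  m <- target > 0
  res <- cpp_edt3(m, dim(m))
  list(distance_um = sqrt(res$dist2) * spacing_um,
       site = if (feature) res$site else NULL)
}

# Between-class-variance-maximising (Otsu) threshold on a numeric vector.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(pmax(findInterval(x, seq(r[1], r[2], length.out = n_bins + 1L),
                                       rightmost.closed = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins * diff(r) + r[1]
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Binary dilation/erosion/closing by a Euclidean ball of radius r (voxels),
# implemented through the exact EDT. Voxels beyond the volume border count
# as background, so erosion shrinks at the border (documented convention).
dilate_ball <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  d2 <- cpp_edt3(mask > 0, dim(mask))$dist2
  array(d2 <= r_vox^2, dim(mask))
}

erode_ball <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  d2 <- cpp_edt3(!(mask > 0), dim(mask))$dist2
  array(d2 > r_vox^2, dim(mask))
}

close_ball <- function(mask, r_vox) {
  erode_ball(dilate_ball(mask, r_vox), r_vox)
}

# 3-D connected components; connectivity 6, 18 or 26.
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  cpp_label3(mask > 0, dim(mask), as.integer(connectivity))
}

# k x k x k median filter, replicated borders.
median_filter3 <- function(x, k = 3L) {
  if (k %% 2L != 1L) stop("median filter kernel size k must be odd")
  cpp_median3(as.numeric(x) + array(0, dim(x)), dim(x), as.integer(k))
}

# Voxel-coordinate covariance shape statistics for one labeled component.
# Extents are 4*sqrt(eigenvalue) of the coordinate covariance plus the
# cube-voxel self-term spacing^2/12 on the diagonal, in um; the aspect
# ratio is shortest/longest extent.
component_shape <- function(coords_um, spacing_um) {
  n <- nrow(coords_um)
  cv <- stats::cov(coords_um) * (n - 1) / n
  if (n == 1L) cv <- matrix(0, 3, 3)
  cv <- cv + diag(spacing_um^2 / 12, 3)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  extents <- 4 * sqrt(ev)
  list(semi_axes_um = extents / 2,
       aspect_ratio = extents[3] / extents[1])
}
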