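#' 3-D scalar volume with voxel spacing
#'
#' The common currency of the pipeline: a 3-D array (axis order
#' slice/row/column, i.e. z, y, x) plus the isotropic voxel edge length in
#' micrometres and a tag describing what the values mean.
#'
#' @param data 3-D numeric, integer or logical array.
#' @param spacing_um Isotropic voxel edge length in micrometres (> 0). The
#'   SRuCT scans this pipeline was designed around use 1.3 um.
#' @param value_kind One of `"attenuation"`, `"tmd"`, `"binary"`,
#'   `"labels"`, `"distance"`.
#' @return An object of class `volume3d`: a list with elements `data`,
#'   `spacing_um`, `value_kind`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing_um = 1.3, "attenuation")
#' dim(v$data)
#' @export
volume3d <- function(data, spacing_um,
                     value_kind = c("attenuation", "tmd", "binary",
                                    "labels", "distance")) {
  value_kind <- match.arg(value_kind)
  if (length(dim(data)) != 3L)
    stop("volume3d: `data` must have exactly 3 axes")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L ||
      !is.finite(spacing_um) || spacing_um <= 0)
    stop("volume3d: `spacing_um` must be a single positive number")
  if (value_kind == "binary") {
    if (is.logical(data)) {
      storage.mode(data) <- "integer"
    } else if (!all(data %in% c(0, 1))) {
      stop("volume3d: binary volume must contain only 0/1")
    }
  }
  if (value_kind == "labels" && any(data < 0, na.rm = TRUE))
    stop("volume3d: label volume must be non-negative integers")
  structure(list(data = data, spacing_um = spacing_um,
                 value_kind = value_kind),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x), %.4g um/voxel, kind=%s\n",
              d[1], d[2], d[3], x$spacing_um, x$value_kind))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

stopifnot_volume <- function(x, name = deparse(substitute(x))) {
  if (!is_volume3d(x)) stop(sprintf("`%s` must be a volume3d object", name))
  invisible(x)
}

#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice; spacing, value kind and any extra metadata go
#' to `<path>.json` so geometry is never inferred from file names. Label and
#' binary volumes are stored losslessly as 16-bit integers (error if a label
#' exceeds 65535); float volumes are stored as 32-bit floats.
#'
#' @param vol A [volume3d()].
#' @param path Output TIFF path.
#' @param extra Named list merged into the sidecar (e.g. seed, config echo).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, extra = list()) {
  stopifnot_volume(vol)
  d <- dim(vol$data)
  pages <- vector("list", d[1])
  int_kind <- vol$value_kind %in% c("binary", "labels")
  if (int_kind && max(vol$data) > 65535)
    stop("write_volume: label values exceed 16-bit range")
  # TIFF samples live in [0,1]; float volumes are affinely normalized and
  # the range recorded in the sidecar
  rng <- if (int_kind) c(0, 65535) else range(vol$data)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  for (z in seq_len(d[1])) {
    sl <- matrix(as.numeric(vol$data[z, , ]), d[2], d[3])
    pages[[z]] <- (sl - rng[1]) / diff(rng)
  }
  if (int_kind) {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  sidecar <- c(list(spacing_um = vol$spacing_um, value_kind = vol$value_kind,
                    dim_zyx = d, value_range = rng), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; `<path>.json` must exist (spacing is required
#'   metadata and is never silently assumed).
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop(sprintf("read_volume: sidecar %s not found; voxel spacing is required metadata", sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$spacing_um))
    stop("read_volume: sidecar lacks spacing_um")
  pages <- tiff::readTIFF(path, all = TRUE)
  d1 <- length(pages)
  d2 <- nrow(pages[[1]]); d3 <- ncol(pages[[1]])
  arr <- array(0, c(d1, d2, d3))
  for (z in seq_len(d1)) arr[z, , ] <- pages[[z]]
  kind <- sc$value_kind %||% "attenuation"
  rng <- sc$value_range %||% c(0, 1)
  if (kind %in% c("binary", "labels")) {
    arr <- array(as.integer(round(arr * 65535)), dim(arr))
  } else {
    arr <- arr * (rng[2] - rng[1]) + rng[1]
  }
  volume3d(arr, sc$spacing_um, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read tables with a declared schema
#'
#' Thin CSV wrappers that check for required columns on read, so schema
#' mismatches fail loudly with the missing column names.
#'
#' @param x Data frame to write.
#' @param path CSV path.
#' @param required Character vector of columns that must be present.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, required = character()) {
  x <- as.data.frame(data.table::fread(path))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("read_table: %s is missing required columns: %s",
                 path, paste(missing, collapse = ", ")))
  x
}
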