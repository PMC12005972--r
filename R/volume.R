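#' 3D labeled nucleus volume
#'
#' A light container for an integer-labeled segmentation volume: a 3D array
#' with dimensions ordered (x, y, z) and the physical voxel size in
#' micrometres per axis. Label 0 is background; labels need not be consecutive
#' after filtering. Physical coordinates map to voxels by the floor
#' convention: a point at `x` micrometres lies in 0-based voxel
#' `floor(x / voxel_size["x"])`.
#'
#' @param data Integer 3D array (x, y, z) of labels, 0 = background.
#' @param voxel_size_um Numeric length-3 vector, micrometres per voxel along
#'   (x, y, z); anisotropy is respected by all geometric operations.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, voxel_size_um = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array", call. = FALSE)
  if (any(data < 0, na.rm = TRUE)) stop("labels must be non-negative", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    stop("'voxel_size_um' must be 3 positive numbers (x, y, z)", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, voxel_size_um = voxel_size_um),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume: %d x %d x %d voxels (x,y,z), voxel %s um, %d labels\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_um, digits = 3), collapse = " x "),
              length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

# 0-based voxel index per axis for physical coordinates (floor convention)
voxel_index <- function(coords_um, voxel_size_um) {
  sweep(coords_um, 2L, voxel_size_um, function(a, b) floor(a / b))
}

#' Per-label volumes and centroids
#'
#' Volumes in cubic micrometres and intensity-free centroids (mean voxel
#' centre position, micrometres) computed from the undilated volume.
#'
#' @param labels A [label_volume()].
#' @return `label_volumes_um3()`: named numeric vector; `label_centroids_um()`:
#'   matrix with columns x, y, z and one row per label.
#' @export
label_volumes_um3 <- function(labels) {
  a <- labels$data
  counts <- table(a[a > 0L])
  v <- as.numeric(counts) * prod(labels$voxel_size_um)
  names(v) <- names(counts)
  v
}

#' @rdname label_volumes_um3
#' @export
label_centroids_um <- function(labels) {
  a <- labels$data
  idx <- which(a > 0L)
  lab <- a[idx]
  d <- dim(a)
  ix <- (idx - 1L) %% d[1]
  iy <- ((idx - 1L) %/% d[1]) %% d[2]
  iz <- (idx - 1L) %/% (d[1] * d[2])
  vs <- labels$voxel_size_um
  # voxel centre = (index + 0.5) * voxel size
  cx <- tapply((ix + 0.5) * vs[1], lab, mean)
  cy <- tapply((iy + 0.5) * vs[2], lab, mean)
  cz <- tapply((iz + 0.5) * vs[3], lab, mean)
  out <- cbind(x = as.numeric(cx), y = as.numeric(cy), z = as.numeric(cz))
  rownames(out) <- names(cx)
  out
}

#' Write / read a label volume as multi-page TIFF with a JSON sidecar
#'
#' Pages are z-slices (rows = y, columns = x), stored as 16-bit unsigned
#' integers; the voxel size is written to `<path>.json`. Round-trips
#' losslessly for label values up to 65535.
#'
#' @param labels A [label_volume()].
#' @param path Output TIFF path.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns the volume.
#' @export
write_label_volume <- function(labels, path) {
  a <- labels$data
  if (max(a) > 65535L) stop("labels exceed 16-bit TIFF range", call. = FALSE)
  pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = labels$voxel_size_um,
         axes = "pages=z, rows=y, cols=x"),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])                      # rows = y, cols = x
  a <- array(0L, dim = c(d[2], d[1], length(pages)))
  for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
  sidecar <- paste0(path, ".json")
  vs <- if (file.exists(sidecar)) {
    as.numeric(jsonlite::read_json(sidecar, simplifyVector = TRUE)$voxel_size_um)
  } else c(1, 1, 1)
  label_volume(a, vs)
}
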