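#' Volumetric containers
#'
#' An `image_volume` is a 3-D scalar lattice (CT numbers in HU or dose in Gy)
#' with voxel spacing and origin in mm; a `binary_mask` is a boolean lattice
#' sharing the grid of its parent volume. Voxel values sit at voxel centers;
#' the voxel at index (i, j, k) (1-based) is centered at
#' `origin + (c(i, j, k) - 1) * spacing` in mm.
#'
#' @param data 3-D array (numeric for volumes, logical for masks).
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin numeric length-3, mm coordinate of the first voxel center.
#' @param units `"HU"` or `"Gy"` for volumes.
#' @return An object of class `image_volume` or `binary_mask`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0), units = c("HU", "Gy")) {
  units <- match.arg(units)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image_volume requires a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (any(!is.finite(data))) stop("image_volume values must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 units = units),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("binary_mask requires a 3-D array")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume [%s]> %s voxels, spacing %s mm, range [%.6g, %.6g]\n",
              x$units, paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Physical volume of a mask in cm^3
#' @param mask a `binary_mask`
#' @return voxel count times voxel volume, cm^3
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

## ---- low-level lattice operations (shared by segmentation & phantoms) ----

# Shift a 3-D array by whole voxels, filling vacated cells with `fill`.
shift3d <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  xs <- sx - dx; ys <- sy - dy; zs <- sz - dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okz <- zs >= 1 & zs <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[xs[okx], ys[oky], zs[okz]]
  out
}

# Separable 3x3(x3) binary dilation: box structuring element.
dilate_box <- function(a, along = c(TRUE, TRUE, TRUE)) {
  out <- a
  if (along[1]) out <- out | shift3d(out, 1, 0, 0) | shift3d(out, -1, 0, 0)
  if (along[2]) out <- out | shift3d(out, 0, 1, 0) | shift3d(out, 0, -1, 0)
  if (along[3]) out <- out | shift3d(out, 0, 0, 1) | shift3d(out, 0, 0, -1)
  out
}

# Plus-shaped (4/6-neighborhood) dilation; in-plane only when axial = TRUE.
dilate_plus <- function(a, axial = FALSE) {
  out <- a | shift3d(a, 1, 0, 0) | shift3d(a, -1, 0, 0) |
    shift3d(a, 0, 1, 0) | shift3d(a, 0, -1, 0)
  if (!axial) out <- out | shift3d(a, 0, 0, 1) | shift3d(a, 0, 0, -1)
  out
}

# Geodesic flood fill: grow `seed` inside `domain` until stable.
# connectivity "box" = 26-neighborhood, "plus" = 6, "plus-axial" = in-plane 4.
flood_fill <- function(seed, domain, connectivity = c("box", "plus", "plus-axial")) {
  connectivity <- match.arg(connectivity)
  cur <- seed & domain
  repeat {
    nxt <- switch(connectivity,
                  "box" = dilate_box(cur),
                  "plus" = dilate_plus(cur),
                  "plus-axial" = dilate_plus(cur, axial = TRUE))
    nxt <- nxt & domain
    if (sum(nxt) == sum(cur)) return(nxt)
    cur <- nxt
  }
}

# Largest 26-connected component of a logical array.
largest_component <- function(a) {
  remaining <- a
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(a))
    seed[which(remaining)[1L]] <- TRUE
    comp <- flood_fill(seed, remaining, "box")
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) a else best
}

# Fill internal cavities slice by slice (axial planes): background connected
# to the in-plane border stays background, the rest becomes foreground.
# Background uses the 4-neighborhood, the complement of 8-connected foreground.
fill_holes_axial <- function(a) {
  d <- dim(a)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  outside <- flood_fill(border & !a, !a, "plus-axial")
  a | (!a & !outside)
}

# In-plane (axial) moving-window mean filter with constant padding.
# `window` is the odd side length in voxels.
mean_filter_axial <- function(a, window, pad) {
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and >= 1")
  if (window == 1L) return(a)
  h <- (window - 1L) / 2L
  d <- dim(a)
  acc <- array(0, d)
  for (s in -h:h) acc <- acc + shift3d(a, s, 0, 0, fill = pad)
  acc2 <- array(0, d)
  for (s in -h:h) acc2 <- acc2 + shift3d(acc, 0, s, 0, fill = pad * window)
  acc2 / (window * window)
}
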