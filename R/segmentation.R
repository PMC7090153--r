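#' Spherical structuring element on an anisotropic grid
#'
#' Rasterizes a sphere of physical radius `r` mm as voxel offsets on a grid
#' with the given spacing: offsets (dx, dy, dz) with half-widths
#' `floor(r / spacing)` whose mm displacement lies within the sphere. Always
#' contains the center and is symmetric under axis reflection, so erosion by
#' it preserves the physical thickness on anisotropic grids (e.g. 3 mm on
#' 2.5 mm slices).
#'
#' @param r radius in mm (>= 0)
#' @param spacing voxel spacing in mm per axis
#' @return integer matrix with one offset (dx, dy, dz) per row
#' @export
structuring_element <- function(r, spacing) {
  if (r < 0) stop("structuring element radius must be >= 0")
  hw <- floor(r / spacing)
  g <- expand.grid(dx = -hw[1]:hw[1], dy = -hw[2]:hw[2], dz = -hw[3]:hw[3])
  mm2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[mm2 <= r^2 + 1e-9, , drop = FALSE])
}

#' Morphological erosion by a physical radius
#'
#' Erodes a binary mask by a sphere of radius `r` mm rasterized on the mask's
#' own (possibly anisotropic) grid. Because voxel centers of the background
#' sit on average half a voxel beyond the continuous boundary, the element is
#' rasterized at the boundary-corrected radius `r + mean(spacing) / 2`; this
#' keeps the *physical* erosion depth at `r` (a voxel is removed when a
#' background voxel center lies within the corrected radius, i.e. when the
#' true boundary is within about `r`). Voxels outside the array count as
#' background. `r = 0` returns the mask unchanged.
#'
#' @param mask a `binary_mask`
#' @param r erosion radius in mm
#' @return eroded `binary_mask` (always a subset of `mask`)
#' @export
erode_mask <- function(mask, r) {
  stopifnot(inherits(mask, "binary_mask"))
  if (r < 0) stop("erosion radius must be >= 0")
  if (r == 0) return(mask)
  # ties at exactly r + h/2 are excluded: they correspond to boundary
  # distance r itself, which erosion by an open ball keeps
  se <- structuring_element(r + mean(mask$spacing) / 2 - 1e-6, mask$spacing)
  out <- mask$data
  for (i in seq_len(nrow(se))) {
    if (all(se[i, ] == 0L)) next
    out <- out & shift3d(mask$data, se[i, 1], se[i, 2], se[i, 3], fill = FALSE)
  }
  binary_mask(out, mask$spacing, mask$origin)
}

#' Corrected body contour from a CT-like volume
#'
#' Recovers the body structure Omega from a HU volume: an in-plane
#' moving-window mean filter suppresses thin treatment-couch structures and
#' partial-volume bridges, voxels above the HU threshold are kept, the
#' largest 26-connected 3-D component is retained (dropping the couch), and
#' internal cavities (lungs, airways) are filled per axial slice.
#'
#' The moving window acts as a robustness filter, not as the contour: thin
#' couch slabs average toward air and drop below the threshold, while the
#' body core stays above it. The largest 26-connected component of the
#' *smoothed* thresholded volume seeds the body, and the contour is then
#' recovered at full resolution as the thresholded voxels 26-connected to
#' that seed — so the couch (disconnected from the body) is excluded without
#' eroding the true body boundary. The window size and threshold are not
#' canonical; both are exposed.
#'
#' @param ct an `image_volume` with HU units
#' @param threshold HU threshold separating tissue from air
#' @param window odd in-plane window side length, voxels
#' @return the body mask Omega as a `binary_mask`
#' @export
correct_body_contour <- function(ct, threshold = -250, window = 5L) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$units != "HU") stop("body contour correction expects a HU volume")
  raw_fg <- ct$data > threshold
  if (!any(raw_fg)) stop("no body found: no voxel above threshold")
  smoothed <- mean_filter_axial(ct$data, as.integer(window), pad = -1000)
  seed_fg <- smoothed > threshold & raw_fg
  if (!any(seed_fg)) stop("no body found: no voxel above threshold after smoothing")
  seed <- largest_component(seed_fg)
  body <- flood_fill(seed, raw_fg, "box")
  body <- fill_holes_axial(body)
  binary_mask(body, ct$spacing, ct$origin)
}

#' Skin structure by erosion of the body contour
#'
#' The skin of thickness `r` is the set difference between the body Omega and
#' its erosion by a spherical element of radius `r` mm:
#' `skin_r = Omega \ (Omega erode B[r])`. The default 3 mm approximates the
#' mean epidermis/dermis thickness. Skin and eroded core partition Omega.
#'
#' @param omega body `binary_mask`
#' @param r skin thickness in mm (default 3)
#' @return the skin shell as a `binary_mask`
#' @export
extract_skin <- function(omega, r = 3) {
  stopifnot(inherits(omega, "binary_mask"))
  if (!any(omega$data)) stop("empty body mask")
  core <- erode_mask(omega, r)
  binary_mask(omega$data & !core$data, omega$spacing, omega$origin)
}
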