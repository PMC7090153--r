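#' Body surface area by the Du Bois formula
#'
#' BSA = 0.007184 m^2 * W^0.425 * H^0.725 with W in kg and H in cm. The
#' value is carried in cm^2 (1 m^2 = 1e4 cm^2).
#'
#' @param weight_kg body weight, kg (> 0)
#' @param height_cm body height, cm (> 0)
#' @return a `bsa` object with fields `cm2`, `m2`, `weight_kg`, `height_cm`
#' @export
compute_bsa <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive")
  m2 <- 0.007184 * weight_kg^0.425 * height_cm^0.725
  structure(list(cm2 = m2 * 1e4, m2 = m2,
                 weight_kg = weight_kg, height_cm = height_cm),
            class = "bsa")
}

#' Dose-surface histogram container
#'
#' Cumulative area receiving more than each dose edge. `edges` are uniform
#' dose bin edges in Gy starting at 0; `area` is the area above each edge,
#' in cm^2 (`flavor = "absolute"`) or percent of BSA (`flavor = "relative"`).
#' The value at 0 Gy is the total (in-scan) surface.
#'
#' @param edges dose edges, Gy
#' @param area cumulative area per edge
#' @param flavor `"absolute"` or `"relative"`
#' @param bsa_cm2 BSA used for normalization (relative flavor)
#' @param total_cm2 total surface in cm^2 (kept through normalization)
#' @return a `dsh` object
#' @export
dsh <- function(edges, area, flavor = c("absolute", "relative"),
                bsa_cm2 = NA_real_, total_cm2 = NA_real_) {
  flavor <- match.arg(flavor)
  if (length(edges) != length(area)) stop("edges and area lengths differ")
  if (any(area < -1e-9)) stop("DSH areas must be non-negative")
  if (any(diff(area) > 1e-9)) stop("cumulative DSH must be non-increasing")
  structure(list(edges = as.numeric(edges), area = pmax(as.numeric(area), 0),
                 flavor = flavor, bsa_cm2 = bsa_cm2, total_cm2 = total_cm2),
            class = "dsh")
}

#' @export
print.dsh <- function(x, ...) {
  unit <- if (x$flavor == "absolute") "cm2" else "% BSA"
  cat(sprintf("<dsh [%s]> %d edges to %.5g Gy, total %.6g %s\n",
              x$flavor, length(x$edges), max(x$edges), x$area[1], unit))
  invisible(x)
}

#' Resample a dose volume onto a target grid
#'
#' Trilinear interpolation of the dose at the target voxel centers; points
#' outside the source extent are set to 0 Gy and counted in a warning.
#'
#' @param dose an `image_volume` in Gy
#' @param target an `image_volume` or `binary_mask` defining the output grid
#' @return an `image_volume` in Gy on the target grid
#' @export
resample_dose <- function(dose, target) {
  stopifnot(inherits(dose, "image_volume"))
  sd <- dim(dose$data); ssp <- dose$spacing; sor <- dose$origin
  td <- dim(target$data); tsp <- target$spacing; tor <- target$origin
  src_hi <- sor + (sd - 1) * ssp
  tgt_hi <- tor + (td - 1) * tsp
  if (any(tor > src_hi) || any(tgt_hi < sor))
    stop("disjoint physical extents")
  g <- grid_coords(td, tsp, tor)
  px <- rep(g$x, times = td[2] * td[3])
  py <- rep(rep(g$y, each = td[1]), times = td[3])
  pz <- rep(g$z, each = td[1] * td[2])
  val <- trilinear_at(dose, px, py, pz, outside = 0)
  n_out <- attr(val, "n_outside")
  if (n_out > 0)
    warning(sprintf("%d target voxels outside the dose grid set to 0 Gy", n_out))
  out <- image_volume(array(as.numeric(val), td), tsp, tor, units = "Gy")
  out
}

# Trilinear interpolation of an image_volume at physical points (mm).
# Points outside the grid take `outside`; their count is attached.
trilinear_at <- function(vol, px, py, pz, outside = 0) {
  d <- dim(vol$data); sp <- vol$spacing; or <- vol$origin
  fx <- (px - or[1]) / sp[1]
  fy <- (py - or[2]) / sp[2]
  fz <- (pz - or[3]) / sp[3]
  out_of_grid <- fx < 0 | fx > d[1] - 1 | fy < 0 | fy > d[2] - 1 |
    fz < 0 | fz > d[3] - 1
  fx <- pmin(pmax(fx, 0), d[1] - 1)
  fy <- pmin(pmax(fy, 0), d[2] - 1)
  fz <- pmin(pmax(fz, 0), d[3] - 1)
  i0 <- pmin(floor(fx), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz), d[3] - 2); k0 <- pmax(k0, 0)
  if (d[1] < 2) i0 <- rep(0, length(fx))
  if (d[2] < 2) j0 <- rep(0, length(fy))
  if (d[3] < 2) k0 <- rep(0, length(fz))
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  at <- function(i, j, k) vol$data[cbind(pmin(i, d[1] - 1) + 1,
                                         pmin(j, d[2] - 1) + 1,
                                         pmin(k, d[3] - 1) + 1)]
  v <- (1 - tx) * (1 - ty) * (1 - tz) * at(i0, j0, k0) +
    tx * (1 - ty) * (1 - tz) * at(i0 + 1, j0, k0) +
    (1 - tx) * ty * (1 - tz) * at(i0, j0 + 1, k0) +
    tx * ty * (1 - tz) * at(i0 + 1, j0 + 1, k0) +
    (1 - tx) * (1 - ty) * tz * at(i0, j0, k0 + 1) +
    tx * (1 - ty) * tz * at(i0 + 1, j0, k0 + 1) +
    (1 - tx) * ty * tz * at(i0, j0 + 1, k0 + 1) +
    tx * ty * tz * at(i0 + 1, j0 + 1, k0 + 1)
  v[out_of_grid] <- outside
  attr(v, "n_outside") <- sum(out_of_grid)
  v
}

#' Cumulative dose-volume histogram
#'
#' Volume (cm^3) of the mask receiving more than each dose edge; the value
#' at the 0 Gy edge is the full mask volume.
#'
#' @param dose `image_volume` in Gy, on the mask grid
#' @param mask `binary_mask`
#' @param bin_width dose bin width in Gy
#' @return list with `edges` (Gy) and `volume` (cm^3)
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  stopifnot(inherits(dose, "image_volume"), inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("empty mask")
  if (bin_width <= 0) stop("bin width must be positive")
  if (!same_grid(dose, mask)) stop("dose and mask grids differ")
  dv <- dose$data[mask$data]
  vox_cm3 <- prod(mask$spacing) / 1000
  edges <- seq(0, max(dv, 0) + bin_width, by = bin_width)
  list(edges = edges, volume = cum_above(dv, rep(vox_cm3, length(dv)), edges))
}

# Weighted cumulative histogram: out[k] = sum of w where v > edges[k]
# (strict), except out[1] = total weight (the 0-edge holds everything).
cum_above <- function(v, w, edges) {
  K <- length(edges)
  i <- findInterval(v, edges, left.open = TRUE)  # largest i: edges[i] < v
  bs <- numeric(K)
  agg <- rowsum(w, i)
  pos <- as.integer(rownames(agg))
  keep <- pos >= 1L
  bs[pos[keep]] <- agg[keep]
  out <- rev(cumsum(rev(bs)))
  out[1] <- sum(w)
  out
}

# Separable 3x3x3 box mean of a numeric array (constant 0 padding).
box_mean3 <- function(a) {
  for (ax in 1:3) {
    sh <- function(s) { d <- c(0L, 0L, 0L); d[ax] <- s
      shift3d(a, d[1], d[2], d[3], fill = 0) }
    a <- (sh(-1L) + a + sh(1L)) / 3
  }
  a
}

# Exposed boundary faces of a mask with normal-corrected areas. A plain sum
# of exposed voxel-face areas converges to the integral of the L1 norm of
# the surface normal (3/2 of the true area for a sphere), so each face is
# weighted by |n_axis| of the local unit normal estimated from the gradient
# of a box-smoothed indicator; the weighted total converges to the true
# area. Returns per-face corrected areas (cm^2) and, when a dose volume is
# supplied, the dose trilinearly sampled at each face center.
boundary_faces <- function(mask, dose = NULL) {
  d <- dim(mask$data); sp <- mask$spacing; or <- mask$origin
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2]) / 100  # cm^2
  sm <- box_mean3(box_mean3(array(as.numeric(mask$data), d)))
  gx <- (shift3d(sm, -1, 0, 0, 0) - shift3d(sm, 1, 0, 0, 0)) / (2 * sp[1])
  gy <- (shift3d(sm, 0, -1, 0, 0) - shift3d(sm, 0, 1, 0, 0)) / (2 * sp[2])
  gz <- (shift3d(sm, 0, 0, -1, 0) - shift3d(sm, 0, 0, 1, 0)) / (2 * sp[3])
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  areas <- numeric(0); doses <- numeric(0)
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    sh <- c(0L, 0L, 0L); sh[axis] <- -s
    nb <- shift3d(mask$data, sh[1], sh[2], sh[3], fill = FALSE)
    exposed <- which(mask$data & !nb, arr.ind = TRUE)
    if (nrow(exposed) == 0L) next
    g_axis <- switch(axis, gx, gy, gz)[exposed]
    w <- ifelse(gn[exposed] > 1e-12, abs(g_axis) / gn[exposed], 1)
    areas <- c(areas, face_area[axis] * w)
    if (!is.null(dose)) {
      ctr <- sweep(sweep(exposed - 1, 2, sp, "*"), 2, or, "+")
      ctr[, axis] <- ctr[, axis] + s * sp[axis] / 2
      doses <- c(doses, as.numeric(trilinear_at(dose, ctr[, 1], ctr[, 2], ctr[, 3])))
    }
  }
  list(area_cm2 = areas, dose_gy = if (is.null(dose)) NULL else doses)
}

#' Absolute dose-surface histogram
#'
#' The DSH is the thin-shell limit of the skin DVH: the area of the body
#' surface receiving more than each dose level. Two estimators are provided:
#'
#' * `"face"` (default): sums exposed voxel-face areas on the boundary of
#'   Omega, each face carrying the dose trilinearly sampled at its center.
#'   Deterministic and free of tuning parameters.
#' * `"shell"`: computes the DVH of the skin shell `skin_r` for r = 1, 2, 3
#'   voxel units, divides by the thickness, and extrapolates linearly to
#'   r -> 0. Retained as an independent estimator for cross-checks.
#'
#' @param dose `image_volume` in Gy on the body grid
#' @param omega body `binary_mask`
#' @param method `"face"` or `"shell"`
#' @param bin_width dose bin width, Gy
#' @return an absolute-flavor `dsh`
#' @export
compute_dsh <- function(dose, omega, method = c("face", "shell"),
                        bin_width = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(dose, "image_volume"), inherits(omega, "binary_mask"))
  if (!any(omega$data)) stop("empty body mask")
  if (!same_grid(dose, omega)) stop("dose and mask grids differ")
  if (method == "face") {
    bf <- boundary_faces(omega, dose)
    edges <- seq(0, max(bf$dose_gy, 0) + bin_width, by = bin_width)
    area <- cum_above(bf$dose_gy, bf$area_cm2, edges)
    dsh(edges, area, "absolute", total_cm2 = sum(bf$area_cm2))
  } else {
    # Thin-shell limit via the slope at zero thickness: shell volumes
    # vol_x(r) above each dose level are computed for r = 1, 2, 3 voxel
    # units with partial-volume weighting from the Euclidean distance to
    # the boundary, a quadratic is put through the three points per dose
    # bin, and the DSH is its derivative dvol/dr at r -> 0 (vol(0) = 0, so
    # lim vol(r)/r = dvol/dr|0; the half-voxel boundary offset is absorbed
    # by the quadratic's constant term).
    h <- mean(omega$spacing)
    s <- max(omega$spacing)
    rs <- s * (1:3)
    D <- edt_band(omega, dmax = max(rs) + 2 * h)
    db <- D[omega$data] - h / 2
    dv <- dose$data[omega$data]
    vox_cm3 <- prod(omega$spacing) / 1000
    edges <- seq(0, max(dv, 0) + bin_width, by = bin_width)
    vols <- vapply(rs, function(r) {
      w <- pmin(pmax((r - db) / h + 0.5, 0), 1)
      cum_above(dv, w * vox_cm3, edges)
    }, numeric(length(edges)))
    area <- (-5 * vols[, 1] + 8 * vols[, 2] - 3 * vols[, 3]) / (2 * s / 10)
    area <- rev(cummax(rev(pmax(area, 0))))
    dsh(edges, area, "absolute", total_cm2 = area[1])
  }
}

# Euclidean distance from every voxel to the nearest background voxel
# center, exact up to `dmax` (Inf beyond): scan lattice offsets in order of
# increasing physical length; the first background hit is the minimum.
edt_band <- function(mask, dmax) {
  d <- dim(mask$data)
  sp <- mask$spacing
  hw <- ceiling(dmax / sp)
  g <- expand.grid(dx = -hw[1]:hw[1], dy = -hw[2]:hw[2], dz = -hw[3]:hw[3])
  dist_o <- sqrt((g$dx * sp[1])^2 + (g$dy * sp[2])^2 + (g$dz * sp[3])^2)
  keep <- dist_o <= dmax
  g <- g[keep, ]; dist_o <- dist_o[keep]
  ord <- order(dist_o)
  g <- g[ord, ]; dist_o <- dist_o[ord]
  bg <- !mask$data
  D <- array(Inf, d)
  for (i in seq_len(nrow(g))) {
    hit <- shift3d(bg, g$dx[i], g$dy[i], g$dz[i], fill = TRUE)
    new <- hit & !is.finite(D)
    if (any(new)) D[new] <- dist_o[i]
  }
  D
}

#' Normalize an absolute DSH by body surface area
#'
#' Expresses each cumulative area as a percentage of the patient's BSA.
#'
#' @param x absolute-flavor `dsh`
#' @param bsa a `bsa` object or BSA in cm^2
#' @return relative-flavor `dsh`
#' @export
normalize_dsh <- function(x, bsa) {
  stopifnot(inherits(x, "dsh"))
  if (x$flavor != "absolute") stop("normalize_dsh expects an absolute DSH")
  bsa_cm2 <- if (inherits(bsa, "bsa")) bsa$cm2 else as.numeric(bsa)
  if (bsa_cm2 <= 0) stop("BSA must be positive")
  dsh(x$edges, x$area / bsa_cm2 * 100, "relative",
      bsa_cm2 = bsa_cm2, total_cm2 = x$total_cm2)
}

# Linear interpolation of a cumulative DSH at arbitrary dose values.
dsh_at <- function(x, dose_gy) {
  stats::approx(x$edges, x$area, xout = dose_gy, yleft = x$area[1],
                yright = 0, rule = 2, ties = "ordered")$y *
    ifelse(dose_gy > max(x$edges), 0, 1)
}

#' DSH metrics: S_x, D_x, near-maximum and mean dose
#'
#' From a relative DSH, extracts the relative surface receiving more than x
#' Gy (`S_x`, 1 Gy steps), the minimum dose to the hottest x% of BSA
#' (`D_x`, 5% steps), the near-maximum dose `D_2%`, and the surface-weighted
#' mean dose over the in-scan skin. Values between stored edges are linearly
#' interpolated.
#'
#' @param x relative-flavor `dsh`
#' @return list with `S` (named, % BSA), `D` (named, Gy), `D2pct` (Gy),
#'   `Dmean` (Gy)
#' @export
extract_metrics <- function(x) {
  stopifnot(inherits(x, "dsh"))
  if (x$flavor != "relative") stop("extract_metrics expects a relative DSH")
  if (length(x$edges) == 0L || x$area[1] <= 0) stop("empty histogram")
  dmax <- max(x$edges[x$area > 0], 0)
  sx_dose <- seq_len(max(ceiling(dmax), 1))
  S <- dsh_at(x, sx_dose)
  names(S) <- paste0("S_", sx_dose)
  # inverse lookup: smallest dose with cumulative area <= target % of BSA
  dx_pct <- seq(5, 95, by = 5)
  D <- vapply(dx_pct, function(p) inv_dsh(x, p), numeric(1))
  names(D) <- paste0("D_", dx_pct)
  D2 <- inv_dsh(x, 2)
  # mean over the in-scan skin: integral of the cumulative curve / total
  Dmean <- sum(diff(x$edges) * (utils::head(x$area, -1) + utils::tail(x$area, -1)) / 2) /
    x$area[1]
  list(S = S, D = D, D2pct = D2, Dmean = Dmean)
}

#' Read an S_x value from extracted metrics
#'
#' `S_x` beyond the curve's maximum dose is 0 by definition (no surface
#' receives more); this accessor returns that instead of a missing entry.
#'
#' @param metrics output of [extract_metrics()]
#' @param x dose level, Gy
#' @return S_x in % of BSA
#' @export
s_metric <- function(metrics, x) {
  v <- metrics$S[paste0("S_", x)]
  if (is.na(v)) 0 else unname(v)
}

# Minimum dose received by the hottest p% of BSA (0 if p exceeds the curve).
inv_dsh <- function(x, p) {
  if (p >= x$area[1]) return(0)
  idx <- which(x$area <= p)[1]
  if (is.na(idx)) return(max(x$edges))
  if (idx == 1L) return(x$edges[1])
  a0 <- x$area[idx - 1]; a1 <- x$area[idx]
  e0 <- x$edges[idx - 1]; e1 <- x$edges[idx]
  if (a0 == a1) return(e1)
  e0 + (a0 - p) / (a0 - a1) * (e1 - e0)
}
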