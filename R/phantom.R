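#' Phantom specification
#'
#' Describes a synthetic CT-like phantom: grid geometry, a simple body model
#' (sphere or elliptic cylinder along z), tissue/air HU, and an optional
#' treatment-couch slab touching neither the body nor the grid edge. The
#' default 2.0 x 2.0 x 2.5 mm spacing matches a typical RT dose grid.
#'
#' @param shape integer length-3, grid size in voxels
#' @param spacing mm per axis
#' @param body `"sphere"` or `"cylinder"`
#' @param semi_axes mm; for a sphere the first element is the radius, for a
#'   cylinder the in-plane semi-axes (a, b) and half-length along z
#' @param center mm, body center (default grid center)
#' @param couch add a couch slab below the body?
#' @param couch_hu,tissue_hu,air_hu Hounsfield values
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(shape = c(96L, 96L, 64L),
                         spacing = c(2.0, 2.0, 2.5),
                         body = c("cylinder", "sphere"),
                         semi_axes = c(150, 100, 70),
                         center = NULL,
                         couch = FALSE,
                         couch_hu = 300, tissue_hu = 40, air_hu = -1000) {
  body <- match.arg(body)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  extent <- (shape - 1) * spacing
  if (is.null(center)) center <- extent / 2
  semi <- if (body == "sphere") rep(semi_axes[1], 3) else semi_axes
  # body must fit inside the grid with at least one voxel of air margin
  if (any(center - semi < spacing) || any(center + semi > extent - spacing))
    stop("body does not fit inside the grid with an air margin")
  structure(list(shape = shape, spacing = spacing, body = body,
                 semi_axes = semi_axes, center = center, couch = couch,
                 couch_hu = couch_hu, tissue_hu = tissue_hu, air_hu = air_hu),
            class = "phantom_spec")
}

# Voxel-center coordinate grids (mm) for a phantom grid.
grid_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
}

#' Build a phantom HU volume and its ground-truth body mask
#'
#' @param spec a `phantom_spec`
#' @return list with `ct` (an `image_volume`, HU) and `truth` (a
#'   `binary_mask` of the body, excluding the couch)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- grid_coords(spec$shape, spec$spacing)
  dx <- (g$x - spec$center[1])
  dy <- (g$y - spec$center[2])
  dz <- (g$z - spec$center[3])
  if (spec$body == "sphere") {
    r <- spec$semi_axes[1]
    q <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    inside <- q <= r^2
  } else {
    a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; hl <- spec$semi_axes[3]
    inplane <- outer((dx / a)^2, (dy / b)^2, "+") <= 1
    inside <- outer(inplane, abs(dz) <= hl, "&")
  }
  hu <- array(spec$air_hu, spec$shape)
  hu[inside] <- spec$tissue_hu
  if (spec$couch) {
    # 2-voxel-thick slab spanning x, below the body with >= 1 voxel air gap
    ylo_mm <- spec$center[2] - (if (spec$body == "sphere") spec$semi_axes[1] else spec$semi_axes[2])
    jbody <- min(which(g$y >= ylo_mm))
    jc <- jbody - 3L
    if (jc < 2L) stop("no room for couch slab")
    hu[3:(spec$shape[1] - 2L), (jc - 1L):jc, ] <- spec$couch_hu
  }
  list(ct = image_volume(hu, spec$spacing, units = "HU"),
       truth = binary_mask(inside, spec$spacing))
}

#' Beam specification for the analytic dose model
#'
#' Dose fields are built from per-beam depth-dose profiles applied along
#' straight rays through the body — a deliberately simple stand-in for a
#' treatment planning system that reproduces only the surface-dose structure
#' the downstream DSH analysis depends on. Photon-like beams have a
#' sub-surface build-up (low skin dose) and an attenuated exit; proton-like
#' beams have a flat entrance plateau at a fraction of the peak and no exit
#' dose beyond the distal fall-off.
#'
#' @param modality `"photon"` or `"proton"`
#' @param n_beams number of equidistant coplanar axial beams (photon default
#'   8, proton default 3)
#' @param prescribed_dose Gy at the target center
#' @param angles radians in the axial plane; default equidistant
#' @param buildup_mm photon build-up depth
#' @param surface_frac photon surface dose as a fraction of the build-up peak
#' @param mu_mm photon exponential attenuation per mm beyond build-up
#' @param entrance_frac proton entrance plateau as a fraction of peak
#' @param sobp_margin_mm proton peak plateau half-width around the target
#' @param falloff_mm proton distal fall-off length
#' @param field_halfwidth_mm longitudinal (z) field half-width around the
#'   target; dose falls off linearly over `penumbra_mm` beyond it
#' @param field_inplane_halfwidth_mm lateral (in-plane, perpendicular to the
#'   beam axis) field half-width
#' @param penumbra_mm penumbra length, both directions
#' @return a `beam_spec` list
#' @export
beam_spec <- function(modality = c("photon", "proton"),
                      n_beams = NULL,
                      prescribed_dose = 74,
                      angles = NULL,
                      buildup_mm = 15, surface_frac = 0.22, mu_mm = 0.0065,
                      entrance_frac = 0.88, sobp_margin_mm = 25, falloff_mm = 5,
                      field_halfwidth_mm = 35, field_inplane_halfwidth_mm = 45,
                      penumbra_mm = 8) {
  modality <- match.arg(modality)
  if (is.null(n_beams)) n_beams <- if (modality == "photon") 8L else 3L
  n_beams <- as.integer(n_beams)
  if (n_beams < 1L) stop("at least one beam is required")
  if (prescribed_dose <= 0) stop("prescribed dose must be positive")
  if (is.null(angles)) {
    # photons: equidistant coplanar axial beams; protons: a posterior field
    # plus two posterior-oblique fields (typical three-field arrangement)
    angles <- if (modality == "photon" || n_beams != 3L) {
      seq(0, 2 * pi, length.out = n_beams + 1L)[seq_len(n_beams)]
    } else {
      c(pi, 2 * pi / 3, 4 * pi / 3)
    }
  }
  structure(list(modality = modality, n_beams = n_beams,
                 prescribed_dose = prescribed_dose, angles = angles,
                 buildup_mm = buildup_mm, surface_frac = surface_frac,
                 mu_mm = mu_mm, entrance_frac = entrance_frac,
                 sobp_margin_mm = sobp_margin_mm, falloff_mm = falloff_mm,
                 field_halfwidth_mm = field_halfwidth_mm,
                 field_inplane_halfwidth_mm = field_inplane_halfwidth_mm,
                 penumbra_mm = penumbra_mm),
            class = "beam_spec")
}

# Radiological depth of every voxel along direction u (unit vector, axial
# plane): march upstream in steps of h mm and count path length inside the
# body. Vectorized over all voxels.
beam_depth <- function(body, u, step_frac = 1.0) {
  d <- dim(body$data)
  sp <- body$spacing
  h <- min(sp) * step_frac
  g <- grid_coords(d, sp, body$origin)
  px <- rep(g$x, times = d[2] * d[3])
  py <- rep(rep(g$y, each = d[1]), times = d[3])
  pz <- rep(g$z, each = d[1] * d[2])
  nmax <- ceiling(sqrt(sum(((d - 1) * sp)^2)) / h)
  depth <- numeric(length(px))
  for (k in seq_len(nmax)) {
    qx <- px - k * h * u[1]
    qy <- py - k * h * u[2]
    qz <- pz - k * h * u[3]
    i <- round((qx - body$origin[1]) / sp[1]) + 1
    j <- round((qy - body$origin[2]) / sp[2]) + 1
    l <- round((qz - body$origin[3]) / sp[3]) + 1
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & l >= 1 & l <= d[3]
    if (!any(ok)) break
    inside <- logical(length(px))
    inside[ok] <- body$data[cbind(i[ok], j[ok], l[ok])]
    depth <- depth + h * inside
  }
  array(depth, d)
}

photon_profile <- function(z, buildup_mm, surface_frac, mu_mm) {
  ifelse(z < buildup_mm,
         surface_frac + (1 - surface_frac) * z / buildup_mm,
         exp(-mu_mm * (z - buildup_mm)))
}

proton_profile <- function(z, z_peak, entrance_frac, sobp_margin_mm, falloff_mm) {
  lo <- z_peak - sobp_margin_mm
  hi <- z_peak + sobp_margin_mm
  out <- numeric(length(z))
  out[z < lo] <- entrance_frac
  out[z >= lo & z <= hi] <- 1
  tail <- z > hi & z < hi + falloff_mm
  out[tail] <- 1 - (z[tail] - hi) / falloff_mm
  out
}

#' Analytic multi-beam dose field on a phantom
#'
#' Applies the per-beam depth-dose profile of `spec` along each beam
#' direction and scales the sum so that the dose at the body center equals
#' the prescription. Dose is defined on the whole grid (air near the surface
#' carries the entrance dose of the profile at zero depth).
#'
#' @param spec a `beam_spec`
#' @param body body `binary_mask`
#' @return an `image_volume` in Gy on the body grid
#' @export
make_dose <- function(spec, body) {
  stopifnot(inherits(spec, "beam_spec"), inherits(body, "binary_mask"))
  if (!any(body$data)) stop("body mask is empty")
  if (spec$n_beams < 1L) stop("at least one beam is required")
  d <- dim(body$data)
  sp <- body$spacing
  g <- grid_coords(d, sp, body$origin)
  idx <- which(body$data, arr.ind = TRUE)
  cm <- c(mean(g$x[idx[, 1]]), mean(g$y[idx[, 2]]), mean(g$z[idx[, 3]]))
  ci <- round((cm - body$origin) / sp) + 1
  # longitudinal field factor: flat over the field, linear penumbra beyond
  zoff <- abs(g$z - cm[3])
  fz <- pmin(pmax((spec$field_halfwidth_mm + spec$penumbra_mm - zoff) /
                    spec$penumbra_mm, 0), 1)
  fz_vol <- array(rep(fz, each = d[1] * d[2]), d)
  # in-plane lateral offset from the beam axis, per beam
  xo <- g$x - cm[1]
  yo <- g$y - cm[2]
  total <- array(0, d)
  for (ang in spec$angles) {
    u <- c(cos(ang), sin(ang), 0)
    depth <- beam_depth(body, u)
    zc <- depth[ci[1], ci[2], ci[3]]
    f <- if (spec$modality == "photon") {
      photon_profile(depth, spec$buildup_mm, spec$surface_frac, spec$mu_mm)
    } else {
      proton_profile(depth, zc, spec$entrance_frac, spec$sobp_margin_mm,
                     spec$falloff_mm)
    }
    lat <- abs(outer(xo, yo, function(a, b) -a * sin(ang) + b * cos(ang)))
    fxy <- pmin(pmax((spec$field_inplane_halfwidth_mm + spec$penumbra_mm - lat) /
                       spec$penumbra_mm, 0), 1)
    fxy_vol <- array(rep(fxy, times = d[3]), d)
    total <- total + array(f, d) * fz_vol * fxy_vol
  }
  sc <- spec$prescribed_dose / total[ci[1], ci[2], ci[3]]
  image_volume(total * sc, sp, body$origin, units = "Gy")
}
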