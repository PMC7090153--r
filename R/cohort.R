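#' Cohort specification for the synthetic study population
#'
#' Describes the simulated cohort: its size, the treatment-modality mix, the
#' covariate distributions (matched to the study population medians and
#' ranges), the generating NTCP model and the target severe-dermatitis event
#' rate. Defaults emulate a 166-patient thoracic cohort with a 15/166 (~9%)
#' grade-3 event rate.
#'
#' @param n number of patients (>= 2)
#' @param target_event_rate generating mean NTCP, in (0, 1)
#' @param imrt_fraction share of photon (IMRT) patients; the rest are
#'   proton (PSPT)
#' @param seed master seed; per-patient substreams are derived from it
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n = 166L, target_event_rate = 15 / 166,
                        imrt_fraction = 103 / 166, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("cohort size must be >= 2")
  if (target_event_rate <= 0 || target_event_rate >= 1)
    stop("event rate must be in (0, 1)")
  structure(list(n = n, target_event_rate = target_event_rate,
                 imrt_fraction = imrt_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-patient substream seed derived from a master seed (Knuth-style hash,
# kept inside the 32-bit signed range).
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 2654435) %% 2147483647)
}

#' Relative-DSH calibration template
#'
#' A monotone cumulative curve through the study-population medians of the
#' S_x metrics (combined over both endpoint groups, weighted 151:15), with
#' the in-scan total surface `s0_pct` (% of BSA) at 0 Gy. The template is the
#' center of the parametric DSH generator; per-patient curves are scaled and
#' dose-stretched around it.
#'
#' `s0_pct` is the fraction of body surface inside the scanned thorax
#' region. Its default is calibrated (see
#' [calibrate_surface_fraction()]) so that the generating LKB model
#' reproduces the target event rate.
#'
#' @param s0_pct total in-scan surface at 0 Gy, % of BSA
#' @return list with `dose` (Gy) and `area` (% BSA) template nodes
#' @export
dsh_template <- function(s0_pct = 21.3) {
  # the unirradiated (out-of-field) surface drops away below ~1 Gy; beyond
  # that the curve follows the S_x medians
  dose <- c(0, 1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50)
  area <- c(s0_pct, 4.0, 2.90, 1.95, 1.39, 0.863, 0.545, 0.345, 0.136, 0.045,
            0.001, 0)
  if (any(diff(area) > 0)) stop("template must be non-increasing in dose")
  list(dose = dose, area = area)
}

# Evaluate a template (linear interpolation, 0 beyond the last node).
template_at <- function(tpl, d) {
  stats::approx(tpl$dose, tpl$area, xout = d, rule = 2, ties = "ordered")$y *
    ifelse(d > max(tpl$dose), 0, 1)
}

#' Sample parametric relative DSH curves
#'
#' Fast fixture path: draws per-patient relative DSHs around the calibration
#' template with a lognormal amplitude scale, a lognormal dose-axis stretch
#' (max-dose jitter) and a lognormal jitter of the in-scan surface. All
#' randomness is drawn from per-patient substreams of `seed`, so cohorts are
#' reproducible patient by patient.
#'
#' @param n number of curves
#' @param seed master seed
#' @param template output of [dsh_template()]
#' @param scale global amplitude multiplier (0 collapses all curves to zero)
#' @param amp_sdlog lognormal sd of the per-patient amplitude
#' @param stretch_sdlog lognormal sd of the per-patient dose stretch
#' @param s0_sdlog lognormal sd of the in-scan surface jitter
#' @param shape_sdlog lognormal sd of the per-patient curvature exponent
#'   applied to the template area (changes the relative weight of mid vs
#'   high dose surface, independently of amplitude and stretch)
#' @param bin_width stored dose bin width, Gy
#' @param max_dose last stored dose edge, Gy
#' @return list of relative-flavor `dsh` objects; per-patient draw values
#'   are attached as attributes `amp`, `stretch`, `s0`, `shape`
#' @export
sample_dsh_curves <- function(n, seed = 1L, template = dsh_template(),
                              scale = 1, amp_sdlog = 0.35,
                              stretch_sdlog = 0.18, s0_sdlog = 0.10,
                              shape_sdlog = 0.15,
                              bin_width = 0.1, max_dose = 80) {
  if (any(diff(template$area) > 0)) stop("template must be non-increasing in dose")
  edges <- seq(0, max_dose, by = bin_width)
  amp <- numeric(n); str <- numeric(n); s0 <- numeric(n); shp <- numeric(n)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    amp[i] <- stats::rlnorm(1, 0, amp_sdlog)
    str[i] <- stats::rlnorm(1, 0, stretch_sdlog)
    s0[i] <- template$area[1] * stats::rlnorm(1, 0, s0_sdlog)
    shp[i] <- stats::rlnorm(1, 0, shape_sdlog)
    a <- pmin(s0[i],
              amp[i] * template_at(template, edges / str[i])^shp[i])
    a[1] <- s0[i]
    a <- rev(cummax(rev(a)))          # guard monotonicity at the join
    curves[[i]] <- dsh(edges, a * scale, "relative")
  }
  attr(curves, "amp") <- amp
  attr(curves, "stretch") <- str
  attr(curves, "s0") <- s0
  attr(curves, "shape") <- shp
  curves
}

#' Calibrate the in-scan surface fraction to a target event rate
#'
#' The only free scalar of the DSH generator not pinned by the
#' study-population S_x medians is the total in-scan surface at 0 Gy. It is
#' fixed by requiring that the stated generating LKB model reproduce the
#' target severe-dermatitis rate on the generated curve population: larger
#' in-scan surface dilutes the surface weights, lowers the gEUD and the
#' event rate. Solved by bisection on a fixed large Monte-Carlo population.
#'
#' @param lkb generating parameters, list with `td50`, `m`, `n`
#' @param target_rate desired mean NTCP
#' @param n_mc Monte-Carlo population size
#' @param seed seed for the calibration population
#' @param interval search interval for `s0_pct`
#' @param ... further arguments passed to [sample_dsh_curves()]
#' @return the calibrated `s0_pct` (% of BSA)
#' @export
calibrate_surface_fraction <- function(lkb = list(td50 = 9.5, m = 0.24, n = 0.62),
                                       target_rate = 15 / 166, n_mc = 4000,
                                       seed = 761L, interval = c(5, 80), ...) {
  rate_at <- function(s0) {
    curves <- sample_dsh_curves(n_mc, seed = seed,
                                template = dsh_template(s0), ...)
    mean(lkb_ntcp(vapply(curves, function(cv) geud(cv, lkb$n), numeric(1)),
                  lkb$td50, lkb$m))
  }
  stats::uniroot(function(s0) rate_at(s0) - target_rate, interval,
                 tol = 0.01)$root
}

# Rejection sampler for a truncated normal.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Rejection sampler for a range-truncated lognormal given median.
rtrunclnorm <- function(n, median, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 8, log(median), sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample patient covariates
#'
#' Draws the non-dosimetric covariates from range-truncated lognormal or
#' normal distributions matched to the study-population medians and ranges
#' (weight, height, age, GTV volume) and categorical mixes (gender, tumor
#' localization, modality, prescribed dose, smoking). Only location, scale
#' and range are matched; the study reports no higher moments.
#'
#' @param spec a `cohort_spec`
#' @return data.frame with one row per patient
#' @export
sample_covariates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed + 1000L, i))
    weight <- rtrunclnorm(1, 79.5, 0.17, 47, 132)
    height <- rtruncnorm(1, 175.5, 4.0, 162, 181)
    age <- rtruncnorm(1, 65, 9.5, 30, 85)
    gtv <- rtrunclnorm(1, 77, 1.05, 1.9, 690)
    modality <- if (stats::runif(1) < spec$imrt_fraction) "IMRT" else "PSPT"
    rows[[i]] <- data.frame(
      id = i,
      weight_kg = weight, height_cm = height, age_yr = age, gtv_cm3 = gtv,
      gender = sample(c("M", "F"), 1, prob = c(0.56, 0.44)),
      side = sample(c("right", "left"), 1, prob = c(0.64, 0.36)),
      lobe = sample(c("upper", "lower", "middle"), 1,
                    prob = c(0.63, 0.32, 0.05)),
      modality = modality,
      prescribed_gy = sample(c(66, 74), 1, prob = c(0.39, 0.61)),
      smoking = sample(c("yes", "no"), 1, prob = c(0.92, 0.08)),
      bsa_m2 = NA_real_)
  }
  out <- do.call(rbind, rows)
  out$bsa_m2 <- compute_bsa(out$weight_kg, out$height_cm)$m2
  out
}

#' Simulate binary toxicity outcomes from per-patient NTCP values
#'
#' `outcome_i ~ Bernoulli(ntcp_i)`, one substream per patient.
#'
#' @param ntcp per-patient complication probabilities in \[0, 1\]
#' @param seed master seed
#' @return integer 0/1 vector
#' @export
simulate_outcomes <- function(ntcp, seed = 1L) {
  if (any(ntcp < 0 | ntcp > 1 | !is.finite(ntcp)))
    stop("NTCP values must lie in [0, 1]")
  out <- integer(length(ntcp))
  for (i in seq_along(ntcp)) {
    set.seed(derive_seed(seed + 2000L, i))
    out[i] <- as.integer(stats::runif(1) < ntcp[i])
  }
  out
}

#' Endpoint-stratified S_20Gy sampler
#'
#' Draws S_20Gy values (% of BSA) from range-truncated normal distributions
#' matched to the study groups: patients without severe dermatitis (median
#' 0.8, range 0.0-2.2) and with it (median 1.5, range 0.7-2.4).
#'
#' @param n0 number of event-free patients
#' @param n1 number of event patients
#' @param seed seed
#' @return list with `s20` values and integer `y` labels (0/1)
#' @export
sample_s20_strata <- function(n0 = 151L, n1 = 15L, seed = 1L) {
  set.seed(seed)
  s0 <- rtruncnorm(n0, 0.8, 0.52, 0, 2.2)
  s1 <- rtruncnorm(n1, 1.5, 0.45, 0.7, 2.4)
  list(s20 = c(s0, s1), y = c(rep(0L, n0), rep(1L, n1)))
}

#' Marginal S_20Gy sampler for logistic-model simulations
#'
#' Mixture of the two endpoint strata with the study prevalence, used as
#' the covariate population when outcomes are then re-simulated from a
#' stated logistic model.
#'
#' @param n cohort size
#' @param seed seed
#' @param prevalence mixture weight of the event stratum
#' @return numeric S_20Gy values, % of BSA
#' @export
sample_s20_mixture <- function(n, seed = 1L, prevalence = 15 / 166) {
  set.seed(seed)
  k <- stats::rbinom(1, n, prevalence)
  g <- sample_s20_strata(n - k, k, seed = derive_seed(seed, 7L))
  sample(g$s20)  # shuffle so order carries no label information
}
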