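#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain. Serializes losslessly to
#' JSON via [write_config()] / [read_config()].
#'
#' @param n_patients cohort size
#' @param path `"parametric"` (fast DSH generator) or `"volumetric"`
#'   (phantom -> segmentation -> DSH)
#' @param skin_mm skin thickness for segmentation, mm
#' @param hu_threshold body-contour HU threshold
#' @param hu_window in-plane moving-window side, voxels
#' @param dsh_method `"face"` or `"shell"`
#' @param bin_width DSH bin width, Gy
#' @param p_enter,p_remove stepwise thresholds
#' @param p_screen univariable screening threshold
#' @param rs_threshold collinearity cut on |Spearman Rs|
#' @param calibration_bins equal-count calibration bins
#' @param n_boot AUC bootstrap replicates
#' @param seed master seed
#' @param run_loo run leave-one-out validation
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_patients = 40L, path = c("parametric", "volumetric"),
                            skin_mm = 3, hu_threshold = -250, hu_window = 5L,
                            dsh_method = c("face", "shell"), bin_width = 0.1,
                            p_enter = 0.05, p_remove = 0.10, p_screen = 0.1,
                            rs_threshold = 0.75, calibration_bins = 5L,
                            n_boot = 2000L, seed = 1L, run_loo = FALSE) {
  cfg <- list(n_patients = as.integer(n_patients), path = match.arg(path),
              skin_mm = skin_mm, hu_threshold = hu_threshold,
              hu_window = as.integer(hu_window),
              dsh_method = match.arg(dsh_method), bin_width = bin_width,
              p_enter = p_enter, p_remove = p_remove, p_screen = p_screen,
              rs_threshold = rs_threshold,
              calibration_bins = as.integer(calibration_bins),
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              run_loo = isTRUE(run_loo))
  stopifnot(cfg$n_patients >= 2L, cfg$skin_mm >= 0, cfg$bin_width > 0,
            cfg$hu_window %% 2L == 1L, cfg$calibration_bins >= 2L)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @param path_json file path for the JSON round-trip helpers
#' @export
write_config <- function(config, path_json) {
  jsonlite::write_json(unclass(config), path_json, auto_unbox = TRUE,
                       digits = NA)
  invisible(path_json)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path_json) {
  raw <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Write / read per-patient DSH curves as TSV
#'
#' Long format with columns `patient_id`, `dose_gy`, `area` (cm^2 for
#' absolute curves, % of BSA for relative ones) and a `flavor` column.
#'
#' @param curves list of `dsh` objects
#' @param path output TSV path
#' @export
write_dsh_tsv <- function(curves, path) {
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    data.frame(patient_id = i, dose_gy = cv$edges, area = cv$area,
               flavor = cv$flavor)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dsh_tsv
#' @export
read_dsh_tsv <- function(path) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$patient_id), function(g) {
    dsh(g$dose_gy, g$area, flavor = g$flavor[1])
  })
}

#' Write / read volumes and masks as NIfTI
#'
#' Lossless interchange for HU/dose volumes and binary masks (stored as
#' 0/1), with voxel spacing carried in the NIfTI pixdim. Requires the
#' suggested RNifti package.
#'
#' @param vol an `image_volume` or `binary_mask`
#' @param path output `.nii` / `.nii.gz` path
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI I/O requires the RNifti package")
  data <- if (inherits(vol, "binary_mask")) vol$data * 1L else vol$data
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param units units tag for the volume read back (`"HU"`, `"Gy"` or
#'   `"mask"`)
#' @export
read_volume_nifti <- function(path, units = c("HU", "Gy", "mask")) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI I/O requires the RNifti package")
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img))
  if (units == "mask") binary_mask(arr > 0.5, spacing)
  else image_volume(arr, spacing, units = units)
}

# Stable md5 fingerprint of an R object (for the pipeline manifest).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort (covariates, DSH curves — parametric or through the
#' phantom/segmentation/DSH chain — and simulated outcomes from the stated
#' generating logistic model on S_20Gy), computes the DSH metrics, the
#' univariable table, both NTCP model fits and their validation reports,
#' and a manifest with the configuration hash and a hash of all outputs
#' (bitwise reproducibility check).
#'
#' @param config a `pipeline_config`
#' @return a `study_bundle` list
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(n = config$n_patients, seed = config$seed)
  cov <- sample_covariates(spec)
  curves <- if (config$path == "parametric") {
    sample_dsh_curves(spec$n, seed = spec$seed, bin_width = config$bin_width)
  } else {
    volumetric_curves(cov, config)
  }
  metrics <- lapply(curves, function(cv) {
    tryCatch(extract_metrics(cv),
             error = function(e) stop("stage 'dsh' failed: ", conditionMessage(e)))
  })
  s20 <- vapply(metrics, s_metric, numeric(1), 20)
  gen <- list(intercept = -6.34, slope = log(31.4))
  p_gen <- stats::plogis(gen$intercept + gen$slope * s20)
  y <- simulate_outcomes(p_gen, seed = spec$seed)
  # small cohorts: keep the downstream fits defined (>= 2 per class)
  if (sum(y) < 2L) y[order(p_gen, decreasing = TRUE)[1:2]] <- 1L
  if (sum(1L - y) < 2L) y[order(p_gen)[1:2]] <- 0L
  vars <- data.frame(age_yr = cov$age_yr, gtv_cm3 = cov$gtv_cm3,
                     weight_kg = cov$weight_kg, height_cm = cov$height_cm,
                     bsa_m2 = cov$bsa_m2,
                     S_5 = vapply(metrics, s_metric, numeric(1), 5),
                     S_10 = vapply(metrics, s_metric, numeric(1), 10),
                     S_20 = s20,
                     S_30 = vapply(metrics, s_metric, numeric(1), 30),
                     gender = cov$gender, modality = cov$modality,
                     smoking = cov$smoking)
  screen <- univariable_screen(vars, y, p_enter = config$p_screen)
  kept <- collinearity_filter(screen, vars, threshold = config$rs_threshold)
  logistic <- fit_logistic_ntcp(vars, y, candidates = kept,
                                p_enter = config$p_enter,
                                p_remove = config$p_remove)
  lkb <- fit_lkb(curves, y)
  pred_log <- predict(logistic, vars)
  pred_lkb <- predict(lkb, curves)
  reports <- list(
    logistic = validation_report(pred_log, y, config$calibration_bins,
                                 config$n_boot, seed = config$seed),
    lkb = validation_report(pred_lkb, y, config$calibration_bins,
                            config$n_boot, seed = config$seed))
  loo <- NULL
  if (config$run_loo) {
    loo <- loo_predict(
      fit_fun = function(train) {
        sc <- univariable_screen(vars[train, ], y[train],
                                 p_enter = config$p_screen)
        kp <- collinearity_filter(sc, vars[train, ],
                                  threshold = config$rs_threshold)
        fit_logistic_ntcp(vars[train, ], y[train], candidates = kp,
                          p_enter = config$p_enter, p_remove = config$p_remove)
      },
      predict_fun = function(fit, i) predict(fit, vars[i, , drop = FALSE]),
      n = spec$n, y = y)
  }
  out <- list(covariates = cov, curves = curves, metrics = metrics,
              outcomes = y, screen = screen, kept = kept,
              logistic = logistic, lkb = lkb, reports = reports, loo = loo)
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("skinNTCP")),
    config = unclass(config),
    config_hash = object_hash(unclass(config)),
    seed = config$seed,
    n_events = sum(y),
    output_hash = object_hash(list(cov, lapply(curves, `[[`, "area"), y,
                                   stats::coef(logistic$model),
                                   c(lkb$td50, lkb$m, lkb$n))))
  class(out) <- "study_bundle"
  out
}

# Volumetric fixture path: per-patient phantom scaled by anthropometry,
# modality-specific beams, segmentation and face-estimator DSH.
volumetric_curves <- function(cov, config) {
  lapply(seq_len(nrow(cov)), function(i) {
    scale_wh <- (cov$weight_kg[i] / 79.5)^(1 / 3)
    spec <- phantom_spec(shape = c(48L, 48L, 32L), spacing = c(4, 4, 5),
                         semi_axes = c(70, 50, 40) * scale_wh,
                         couch = TRUE)
    ph <- make_phantom(spec)
    omega <- tryCatch(
      correct_body_contour(ph$ct, config$hu_threshold, config$hu_window),
      error = function(e) stop("stage 'segment' failed for patient ", i,
                               ": ", conditionMessage(e)))
    beams <- beam_spec(if (cov$modality[i] == "IMRT") "photon" else "proton",
                       prescribed_dose = cov$prescribed_gy[i])
    dose <- make_dose(beams, omega)
    abs_dsh <- tryCatch(
      compute_dsh(dose, omega, method = config$dsh_method,
                  bin_width = config$bin_width),
      error = function(e) stop("stage 'dsh' failed for patient ", i, ": ",
                               conditionMessage(e)))
    normalize_dsh(abs_dsh, compute_bsa(cov$weight_kg[i], cov$height_cm[i]))
  })
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> n = %d, events = %d\n",
              length(x$outcomes), sum(x$outcomes)))
  print(x$logistic)
  print(x$lkb)
  invisible(x)
}
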