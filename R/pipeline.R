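# End-to-end orchestration: simulate a study, estimate the field from the
# single centric k-space, correct the distortion, and evaluate against the
# simulated truth; plus the ablation harness that switches the proposed
# steps on one by one.

#' Build a run configuration
#'
#' A serializable bundle of everything one run needs.  `load(dump(c))`
#' round-trips through YAML.
#'
#' @param shape matrix shape (default `c(64, 64, 8)`)
#' @param field_amplitude_hz peak |off-resonance| of the simulated truth
#'   field (default 40 Hz)
#' @param smoothness field bump width in voxels (default 8)
#' @param partial_fourier,total_readout_time,trajectory acquisition
#'   settings, see [acq_params()]
#' @param noise_sd relative k-space noise SD (default 0 = noiseless)
#' @param seed integer seed for the simulators
#' @param n_iterations estimation passes (default 3)
#' @param use_lsr combine corrected halves by least-squares restoration
#' @param out_dir optional output directory; when given, NIfTI artifacts
#'   and a JSON report are written there
#' @return an object of class `"run_config"`
#' @export
run_config <- function(shape = c(64L, 64L, 8L), field_amplitude_hz = 40,
                       smoothness = 8, partial_fourier = 0.75,
                       total_readout_time = 0.032,
                       trajectory = "centric_1shot", noise_sd = 0,
                       seed = 1L, n_iterations = 3L, use_lsr = TRUE,
                       out_dir = NULL) {
  structure(list(shape = as.integer(shape),
                 field_amplitude_hz = field_amplitude_hz,
                 smoothness = smoothness,
                 partial_fourier = partial_fourier,
                 total_readout_time = total_readout_time,
                 trajectory = trajectory, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations),
                 use_lsr = use_lsr, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path
#' @param config a `run_config`
#' @export
config_write <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
config_read <- function(path) {
  x <- yaml::read_yaml(path)
  x$shape <- as.integer(unlist(x$shape))
  do.call(run_config, x)
}

# Simulate one complete study from a config.
simulate_study <- function(config) {
  params <- acq_params(config$shape,
                       partial_fourier = config$partial_fourier,
                       total_readout_time = config$total_readout_time,
                       trajectory = config$trajectory)
  phantom <- make_phantom(config$shape, seed = config$seed)
  truth <- make_field_map(config$shape, config$field_amplitude_hz,
                          config$smoothness, seed = config$seed + 1000L)
  k <- simulate_cenepi_kspace(phantom, truth, params,
                              noise_sd = config$noise_sd,
                              seed = config$seed + 2000L)
  list(params = params, phantom = phantom, truth = truth, k = k)
}

#' Run the full simulate / estimate / correct / evaluate pipeline
#'
#' Simulates a phantom study from the configuration, estimates the field
#' map from the single centric k-space, corrects the distortion, and
#' evaluates Dice / Hausdorff / field-map agreement against the simulated
#' truth.  Deterministic per seed.  When `config$out_dir` is set, NIfTI
#' artifacts and a JSON report are written there.
#'
#' @param config a [run_config()]
#' @param topup_opts a [topup_options()]
#' @return report list with the estimated field, masks and metrics
#' @export
run_pipeline <- function(config, topup_opts = topup_options()) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_study(config)
  fit <- estimate_field_cenepi(
    study$k, topup_opts,
    estimation_control(n_iterations = config$n_iterations))
  corrected <- correct_cenepi(study$k, fit$field, use_lsr = config$use_lsr)
  distorted <- Mod(ifftc(study$k$data))

  truth_mask <- otsu_mask(Mod(study$phantom))
  corr_mask <- otsu_mask(corrected$magnitude)
  dist_mask <- otsu_mask(distorted)
  metrics <- list(
    dice_corrected = dice(corr_mask, truth_mask),
    dice_distorted = dice(dist_mask, truth_mask),
    hausdorff_corrected = hausdorff(corr_mask, truth_mask),
    hausdorff_distorted = hausdorff(dist_mask, truth_mask),
    field_r_inmask = fieldmap_correlation(fit$field, study$truth, truth_mask),
    field_rmse_voxels = fieldmap_rmse_voxels(fit$field, study$truth,
                                             truth_mask, study$params),
    n_estimations = fit$n_estimations)
  report <- list(config = unclass(config), metrics = metrics)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fieldmap_write(fit$field, study$params,
                   file.path(config$out_dir, "field"))
    image_write(corrected$magnitude, file.path(config$out_dir, "corrected"))
    image_write(distorted, file.path(config$out_dir, "distorted"))
    kspace_write(study$k, file.path(config$out_dir, "kspace"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(report, list(field = fit$field, truth = study$truth,
                 mask_up = fit$mask_up, mask_down = fit$mask_down,
                 truth_mask = truth_mask, corrected = corrected,
                 distorted = distorted, params = study$params))
}

# The named ablation variants, in the order the steps were added.
ablation_controls <- function(n_iterations = 3L) {
  list(
    pocs_only = estimation_control(uniformity = FALSE),
    uc_by_dilation_masking = estimation_control(n_iterations = 1L,
                                                masking = "dilation",
                                                final_sigma = "constant"),
    uc_by_iterative_masking = estimation_control(n_iterations = n_iterations,
                                                 final_sigma = "constant"),
    location_dependent_uc = estimation_control(n_iterations = n_iterations,
                                               final_sigma =
                                                 "location_dependent"))
}

#' Ablation sweep over the proposed estimation steps
#'
#' Re-estimates the field with each variant — POCS only, uniformity
#' correction with dilation masking, iterative masking with a constant
#' smoothing width, and the full location-dependent correction — and
#' additionally compares least-squares restoration against complex
#' averaging at the correction stage.  Returns one metrics block per
#' variant.
#'
#' @param config a [run_config()]
#' @param topup_opts a [topup_options()]
#' @return list with per-variant field metrics and the correction-stage
#'   comparison (`mse_lsr`, `mse_avg` against the truth-registered phantom)
#' @export
run_ablation <- function(config, topup_opts = topup_options()) {
  study <- simulate_study(config)
  truth_mask <- otsu_mask(Mod(study$phantom))
  variants <- ablation_controls(config$n_iterations)
  out <- lapply(names(variants), function(nm) {
    fit <- estimate_field_cenepi(study$k, topup_opts, variants[[nm]])
    list(variant = nm,
         field_rmse_voxels = fieldmap_rmse_voxels(fit$field, study$truth,
                                                  truth_mask, study$params),
         field_r_inmask = fieldmap_correlation(fit$field, study$truth,
                                               truth_mask),
         n_estimations = fit$n_estimations)
  })
  names(out) <- names(variants)
  ref <- Mod(study$phantom)
  for (m in c(TRUE, FALSE)) {
    corr <- correct_cenepi(study$k, study$truth, use_lsr = m)
    mse <- mean((corr$magnitude[truth_mask] - ref[truth_mask])^2)
    out[[if (m) "mse_lsr" else "mse_avg"]] <- mse
  }
  out
}
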