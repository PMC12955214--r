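#' Specification for a synthetic tuning-curve dataset
#'
#' Defaults emulate the measured velocity-tuning experiment: seven drum
#' velocities spanning ~30-700 deg/s at 60 degrees spatial wavelength, a
#' ground-truth time constant of 41 ms, and an interommatidial /
#' acceptance angle of 17.8 / 17.7 degrees.
#'
#' @param tau_true Ground-truth EMD time constant, seconds (> 0).
#' @param wavelengths Spatial wavelengths, degrees (non-empty, positive).
#' @param velocities Drum angular velocities, deg/s (non-empty).
#' @param io_angle Interommatidial angle, degrees.
#' @param acceptance_angle Acceptance angle, degrees.
#' @param noise_sd SD of the zero-mean Gaussian noise added to each
#'   normalized response (>= 0).
#' @param n_replicates Number of replicate curves (animals / experiments).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_tuning_spec`.
#' @export
synthetic_tuning_spec <- function(tau_true = 0.041, wavelengths = 60,
                                  velocities = c(30, 60, 120, 210, 300,
                                                 420, 700),
                                  io_angle = 17.8, acceptance_angle = 17.7,
                                  noise_sd = 0.05, n_replicates = 20,
                                  seed = 1) {
  stop_field(tau_true > 0, "tau_true", "must be positive")
  if (length(wavelengths) == 0 || length(velocities) == 0) {
    stop("invalid `wavelengths`/`velocities`: must be non-empty",
         call. = FALSE)
  }
  stop_field(all(wavelengths > 0), "wavelengths", "must be positive")
  stop_field(noise_sd >= 0, "noise_sd", "must be >= 0")
  stop_field(n_replicates >= 1, "n_replicates", "must be >= 1")
  structure(list(tau_true = tau_true, wavelengths = wavelengths,
                 velocities = velocities, io_angle = io_angle,
                 acceptance_angle = acceptance_angle, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "synthetic_tuning_spec")
}

#' Generate synthetic normalized tuning-curve data
#'
#' For every replicate and (wavelength, velocity) condition the closed-form
#' EMD response at the ground-truth parameters is evaluated, zero-mean
#' Gaussian noise of `noise_sd` is added, and each replicate's
#' per-wavelength curve is renormalized to its own maximum magnitude —
#' mirroring the per-experiment normalization applied to measured
#' responses.
#'
#' @param spec A [synthetic_tuning_spec()].
#' @return data.frame of class `tuning_dataset` with columns `replicate`,
#'   `wavelength`, `velocity`, `response` (normalized); attribute `truth`
#'   (list: `tau_true`, `io_angle`, `acceptance_angle`).
#' @export
generate_tuning_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tuning_spec"))
  params <- emd_params(spec$tau_true, spec$io_angle, spec$acceptance_angle)
  grid <- expand.grid(velocity = spec$velocities,
                      wavelength = spec$wavelengths)
  clean <- emd_response(params, grid$wavelength, grid$velocity)
  # noise is specified on the normalized-response scale
  for (g in split(seq_len(nrow(grid)), grid$wavelength)) {
    clean[g] <- normalize_to_max(clean[g])
  }
  with_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_replicates), function(rep_i) {
      r <- clean + stats::rnorm(nrow(grid), 0, spec$noise_sd)
      d <- data.frame(replicate = rep_i, wavelength = grid$wavelength,
                      velocity = grid$velocity, response = r)
      for (g in split(seq_len(nrow(d)), d$wavelength)) {
        d$response[g] <- normalize_to_max(d$response[g])
      }
      d
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(tau_true = spec$tau_true,
                               io_angle = spec$io_angle,
                               acceptance_angle = spec$acceptance_angle)
    class(out) <- c("tuning_dataset", "data.frame")
    out
  })
}

#' Condition-wise means of a tuning dataset
#'
#' Averages the per-replicate normalized responses into the per-condition
#' tuning curve consumed by [grid_fit_tau()].
#'
#' @param dataset A [generate_tuning_dataset()] result (or any data.frame
#'   with `wavelength`, `velocity`, `response`).
#' @return A `tuning_curve` data.frame (see [assemble_tuning_curve()]).
#' @export
tuning_means <- function(dataset) {
  d <- data.frame(wavelength = dataset$wavelength,
                  velocity = dataset$velocity,
                  normalized = dataset$response)
  assemble_tuning_curve(d)
}
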