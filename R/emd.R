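#' Parameters of the correlation-type elementary motion detector
#'
#' Bundles the three parameters that determine the steady-state grating
#' response of a Reichardt-type elementary motion detector (EMD): the
#' temporal low-pass filter time constant, the interommatidial angle
#' (angular spacing of the two sampling stations), and the ommatidial
#' acceptance angle (angular width of each station's field of view).
#'
#' @param tau Low-pass filter time constant in seconds (> 0).
#' @param io_angle Interommatidial angle in degrees (> 0).
#' @param acceptance_angle Acceptance angle in degrees (> 0).
#' @return An object of class `emd_params`.
#' @examples
#' emd_params(tau = 0.045, io_angle = 17.8, acceptance_angle = 17.7)
#' @export
emd_params <- function(tau, io_angle, acceptance_angle) {
  stop_field(is.numeric(tau) && length(tau) == 1 && tau > 0,
             "tau", "must be a single positive number (seconds)")
  stop_field(is.numeric(io_angle) && io_angle > 0,
             "io_angle", "must be positive (degrees)")
  stop_field(is.numeric(acceptance_angle) && acceptance_angle > 0,
             "acceptance_angle", "must be positive (degrees)")
  structure(list(tau = tau, io_angle = io_angle,
                 acceptance_angle = acceptance_angle),
            class = "emd_params")
}

#' Steady-state EMD response to a moving grating
#'
#' Closed-form steady-state response of a correlation-type EMD to a
#' sinusoidal grating of spatial wavelength `wavelength` (degrees) drifting
#' at angular velocity `velocity` (deg/s). With `x = 2*pi*tau*velocity /
#' wavelength` the response factorizes as
#'
#' `R = (1 + x^2)^(-1/2) * sin(atan(x)) * sin(2*pi*io/wavelength) *
#'      (1 + (rho/wavelength)^2)^(-1/2)`
#'
#' whose four factors are, in order, the first-order low-pass filter term,
#' the temporal-frequency term, the interference term (which produces
#' spatial-aliasing zeros at `wavelength = 2*io/k`), and the optics term.
#' `sin(atan(x))` is evaluated as `x / sqrt(1 + x^2)`, which is identical
#' and stable for large `|x|`.
#'
#' The response is odd in `velocity` (direction selectivity) and bounded by
#' 1 in magnitude. Its temporal-frequency tuning peaks at
#' `f_opt = 1 / (2*pi*tau)` regardless of wavelength.
#'
#' @param params An [emd_params()] object.
#' @param wavelength Grating spatial wavelength(s), degrees (> 0).
#' @param velocity Grating angular velocity(ies), deg/s (signed).
#' @param terms If `TRUE`, return a data.frame with the four factors and
#'   the product; otherwise a numeric vector of responses.
#' @return Numeric vector (or data.frame when `terms = TRUE`), recycled over
#'   `wavelength` and `velocity`.
#' @examples
#' p <- emd_params(0.04547, 17.8, 17.7)
#' emd_response(p, wavelength = 60, velocity = 210)
#' @export
emd_response <- function(params, wavelength, velocity, terms = FALSE) {
  stopifnot(inherits(params, "emd_params"))
  if (any(wavelength <= 0)) {
    stop("`wavelength` must be positive (degrees)")
  }
  n <- max(length(wavelength), length(velocity))
  lam <- rep_len(wavelength, n)
  v <- rep_len(velocity, n)
  x <- 2 * pi * params$tau * v / lam
  lowpass <- 1 / sqrt(1 + x^2)
  temporal <- x / sqrt(1 + x^2)      # sin(atan(x))
  interference <- sin(2 * pi * params$io_angle / lam)
  optics <- 1 / sqrt(1 + (params$acceptance_angle / lam)^2)
  r <- lowpass * temporal * interference * optics
  if (terms) {
    data.frame(wavelength = lam, velocity = v,
               lowpass = lowpass, temporal = temporal,
               interference = interference, optics = optics,
               response = r)
  } else {
    r
  }
}

#' Temporal-frequency tuning curve of the EMD
#'
#' Evaluates the EMD response across a grid of temporal frequencies at a
#' fixed spatial wavelength (velocity = frequency * wavelength) and
#' normalizes the curve to its own maximum. Because the wavelength-dependent
#' interference and optics factors are constant along the curve, the
#' normalized curve is independent of wavelength and peaks at
#' `f_opt = 1 / (2*pi*tau)`.
#'
#' @param params An [emd_params()] object.
#' @param wavelength Spatial wavelength, degrees.
#' @param frequencies Positive temporal-frequency grid, Hz.
#' @return data.frame with columns `frequency`, `response`, `normalized`;
#'   attribute `f_peak` holds the grid argmax frequency.
#' @export
temporal_tuning_curve <- function(params, wavelength, frequencies) {
  stop_field(length(frequencies) >= 1 && all(frequencies > 0),
             "frequencies", "must be a positive grid (Hz)")
  r <- emd_response(params, wavelength, frequencies * wavelength)
  peak <- r[which.max(r)]
  out <- data.frame(frequency = frequencies, response = r,
                    normalized = r / peak)
  attr(out, "f_peak") <- frequencies[which.max(r)]
  out
}

#' Optimal temporal frequency of a first-order low-pass EMD
#'
#' The product of the low-pass and temporal-frequency factors is
#' `x / (1 + x^2)`, maximal at `x = 1`, i.e. at temporal frequency
#' `f_opt = 1 / (2*pi*tau)`.
#'
#' @param tau Time constant, seconds (> 0).
#' @return Optimal temporal frequency, Hz.
#' @seealso [tau_from_fopt()] for the inverse.
#' @export
optimal_frequency <- function(tau) {
  stop_field(all(tau > 0), "tau", "must be positive")
  1 / (2 * pi * tau)
}

#' @rdname optimal_frequency
#' @param f_opt Optimal temporal frequency, Hz (> 0).
#' @return `tau_from_fopt`: the implied time constant in seconds.
#' @export
tau_from_fopt <- function(f_opt) {
  stop_field(all(f_opt > 0), "f_opt", "must be positive")
  1 / (2 * pi * f_opt)
}

#' Wavelength-sensitivity curve of the EMD
#'
#' Evaluates the EMD response over a grid of spatial wavelengths at a fixed
#' temporal frequency (velocity = frequency * wavelength per grid point).
#' Below twice the interommatidial angle the interference term oscillates
#' and changes sign (spatial aliasing, zeros at `wavelength = 2*io/k`);
#' these sign changes are reported as-is. The analytic wavelength of
#' maximal interference-term response, `lambda_max = 4 * io_angle`, is
#' attached alongside the grid argmax.
#'
#' @param params An [emd_params()] object.
#' @param frequency Temporal frequency, Hz (> 0).
#' @param wavelengths Positive wavelength grid, degrees.
#' @return data.frame with columns `wavelength`, `velocity`, `response`;
#'   attributes `lambda_max_analytic` (= 4 * io_angle, degrees) and
#'   `lambda_max_grid` (grid argmax of the interference term).
#' @export
wavelength_sensitivity <- function(params, frequency, wavelengths) {
  stop_field(length(frequency) == 1 && frequency > 0,
             "frequency", "must be a single positive number (Hz)")
  stop_field(all(wavelengths > 0), "wavelengths", "must be positive")
  v <- frequency * wavelengths
  r <- emd_response(params, wavelengths, v)
  interference <- sin(2 * pi * params$io_angle / wavelengths)
  out <- data.frame(wavelength = wavelengths, velocity = v, response = r)
  attr(out, "lambda_max_analytic") <- 4 * params$io_angle
  attr(out, "lambda_max_grid") <- wavelengths[which.max(interference)]
  out
}
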