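#' Time-constant search grid
#'
#' Defaults: 10 ms to 70 ms in 1.2 ms steps, endpoints inclusive (51
#' values); `endpoint = "exclusive"` drops the upper endpoint (50 values).
#'
#' @param tau_min,tau_max Grid bounds, seconds.
#' @param step Grid step, seconds.
#' @param endpoint `"inclusive"` (default) or `"exclusive"`.
#' @return Numeric vector of time constants, seconds.
#' @export
tau_grid <- function(tau_min = 0.010, tau_max = 0.070, step = 0.0012,
                     endpoint = c("inclusive", "exclusive")) {
  endpoint <- match.arg(endpoint)
  stop_field(tau_min < tau_max, "tau_min", "must be below tau_max")
  stop_field(step > 0, "step", "must be positive")
  g <- seq(tau_min, tau_max + step / 2, by = step)
  g <- g[g <= tau_max + 1e-12]
  if (endpoint == "exclusive" && abs(g[length(g)] - tau_max) < 1e-12) {
    g <- g[-length(g)]
  }
  g
}

#' Least-squares error between two normalized tuning curves
#'
#' @param model_curve,data_curve Numeric vectors of equal length (>= 2),
#'   each normalized to its own maximum.
#' @param method `"sum"` (default): sum of squared differences over
#'   conditions; `"mean"`: mean squared difference.
#' @return Non-negative scalar.
#' @export
lse <- function(model_curve, data_curve, method = c("sum", "mean")) {
  method <- match.arg(method)
  stop_field(length(model_curve) == length(data_curve),
             "model_curve/data_curve", "must have equal length")
  stop_field(length(model_curve) >= 2, "model_curve",
             "need at least two conditions")
  d2 <- (model_curve - data_curve)^2
  if (method == "sum") sum(d2) else mean(d2)
}

# Normalize a response vector by its maximum magnitude (sign-preserving).
normalize_to_max <- function(x) {
  m <- max(abs(x))
  if (!is.finite(m) || m == 0) return(x)
  x / m
}

#' Grid-search least-squares fit of the EMD time constant
#'
#' For every time constant on the grid, the EMD model is evaluated at the
#' data's (wavelength, velocity) conditions, each wavelength's model curve
#' is normalized to its own maximum magnitude, and the least-squares error
#' against the (already normalized) measured curve is accumulated. The fit
#' reports the full LSE profile, the minimizing time constant (ties broken
#' toward the smaller value), and the contiguous grid band around the
#' minimum within `band_tolerance` of the minimum LSE — the sensitivity
#' band of the fit.
#'
#' @param data data.frame with columns `wavelength`, `velocity` and `mean`
#'   (mean normalized response per condition), e.g. an
#'   [assemble_tuning_curve()] result. One wavelength by default; multiple
#'   wavelengths are pooled when `pool_wavelengths = TRUE`.
#' @param io_angle Interommatidial angle, degrees.
#' @param acceptance_angle Acceptance angle, degrees.
#' @param grid Time-constant grid from [tau_grid()].
#' @param band_tolerance LSE increase defining the flat band (default
#'   0.008).
#' @param lse_method Passed to [lse()].
#' @param pool_wavelengths Allow several wavelengths in `data`.
#' @return An object of class `tau_fit`: list with `grid`, `lse`,
#'   `tau_best`, `lse_min`, `flat_band` (c(low, high), seconds),
#'   `identifiable` (FALSE when the data curve is constant), `n_conditions`,
#'   `lse_method`.
#' @export
grid_fit_tau <- function(data, io_angle, acceptance_angle,
                         grid = tau_grid(), band_tolerance = 0.008,
                         lse_method = c("sum", "mean"),
                         pool_wavelengths = FALSE) {
  lse_method <- match.arg(lse_method)
  need <- c("wavelength", "velocity", "mean")
  stop_field(all(need %in% names(data)), "data",
             paste("must contain columns", paste(need, collapse = ", ")))
  data <- data[is.finite(data$mean), ]
  stop_field(nrow(data) >= 2, "data",
             "need at least two conditions with finite means")
  n_lam <- length(unique(data$wavelength))
  if (n_lam > 1 && !pool_wavelengths) {
    stop("`data` spans several wavelengths; set `pool_wavelengths = TRUE` ",
         "or fit per wavelength")
  }
  identifiable <- stats::sd(data$mean) > 0
  lam_groups <- split(seq_len(nrow(data)), data$wavelength)
  profile <- vapply(grid, function(tau) {
    p <- emd_params(tau, io_angle, acceptance_angle)
    model <- emd_response(p, data$wavelength, data$velocity)
    for (g in lam_groups) model[g] <- normalize_to_max(model[g])
    lse(model, data$mean, lse_method)
  }, numeric(1))
  best <- which(profile <= min(profile) + 0)
  best <- best[1]  # ties toward smaller tau (grid is increasing)
  within <- profile <= profile[best] + band_tolerance
  lo <- best
  while (lo > 1 && within[lo - 1]) lo <- lo - 1
  hi <- best
  while (hi < length(grid) && within[hi + 1]) hi <- hi + 1
  structure(list(grid = grid, lse = profile,
                 tau_best = grid[best], lse_min = profile[best],
                 flat_band = c(grid[lo], grid[hi]),
                 identifiable = identifiable,
                 n_conditions = nrow(data), lse_method = lse_method),
            class = "tau_fit")
}

#' Structured fit report
#'
#' @param fit A `tau_fit` from [grid_fit_tau()].
#' @return list with the grid, LSE profile, best time constant (s and ms),
#'   flat band, and the implied optimal temporal frequency
#'   `f_opt = 1 / (2 * pi * tau_best)` (Hz).
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "tau_fit"))
  stop_field(length(fit$grid) >= 1 && length(fit$lse) == length(fit$grid),
             "fit", "empty or inconsistent fit")
  list(grid = fit$grid, lse = fit$lse,
       tau_best = fit$tau_best, tau_best_ms = 1000 * fit$tau_best,
       lse_min = fit$lse_min, flat_band = fit$flat_band,
       identifiable = fit$identifiable,
       implied_f_opt = optimal_frequency(fit$tau_best),
       lse_method = fit$lse_method, n_conditions = fit$n_conditions)
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf(
    "EMD time-constant grid fit: tau = %.1f ms (LSE = %.4g, %s over %d conditions)\n",
    1000 * x$tau_best, x$lse_min, x$lse_method, x$n_conditions))
  cat(sprintf("  flat band (+%s): %.1f-%.1f ms; implied f_opt = %.2f Hz\n",
              "tol", 1000 * x$flat_band[1], 1000 * x$flat_band[2],
              optimal_frequency(x$tau_best)))
  invisible(x)
}
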