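# Find the sign-aware extremum (largest |current|) of a segment after a
# guard interval that excludes capacitive transients.
segment_peak <- function(seg_df, guard_ms = 2, window_ms = NULL) {
  t0 <- min(seg_df$time_ms)
  tt <- seg_df$time_ms - t0
  keep <- tt >= guard_ms
  if (!is.null(window_ms)) keep <- keep & tt <= guard_ms + window_ms
  if (!any(keep)) abort("Peak window is empty; check guard/window settings.")
  cur <- seg_df$current[keep]
  cur[which.max(abs(cur))]
}

#' Extract G-V points from tail-current sweeps
#'
#' For each sweep, picks the peak tail current (sign-aware extremum
#' within the tail segment, after a guard interval that skips the
#' capacitive onset), normalizes peak magnitudes within each experiment
#' by that experiment's maximum, and averages across experiments per
#' test-pulse voltage.
#'
#' @param traces Long tibble of sweeps (`experiment`, `sweep`, `segment`,
#'   `time_ms`, `voltage_mV`, `current`), e.g. from
#'   [generate_tail_current_traces()].
#' @param protocol The [voltage_protocol()] used; the varied segment
#'   gives the test voltage, the following fixed segment is the tail.
#' @param guard_ms Guard interval after the tail step, ms.
#' @param window_ms Optional peak-search window length after the guard, ms.
#' @return A tibble `voltage_mV`, `g` (mean normalized conductance),
#'   `se`, `n_experiments`.
#' @export
extract_gv_points <- function(traces, protocol, guard_ms = 2, window_ms = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  vi <- varied_segment(protocol)
  if (vi >= nrow(protocol$segments)) abort("No tail segment after the varied pulse.")
  tail_label <- protocol$segments$label[vi + 1L]
  test_label <- protocol$segments$label[vi]
  if (!tail_label %in% traces$segment) {
    abort(sprintf("Tail segment '%s' missing from the traces.", tail_label))
  }
  if (!"experiment" %in% names(traces)) traces$experiment <- 1L

  peaks <- traces |>
    filter(.data$segment == tail_label) |>
    group_by(.data$experiment, .data$sweep) |>
    group_modify(~ tibble(peak = segment_peak(.x, guard_ms, window_ms))) |>
    ungroup()
  volts <- traces |>
    filter(.data$segment == test_label) |>
    distinct(.data$experiment, .data$sweep, test_mV = .data$voltage_mV)
  peaks |>
    left_join(volts, by = c("experiment", "sweep")) |>
    group_by(.data$experiment) |>
    mutate(g = abs(.data$peak) / max(abs(.data$peak))) |>
    ungroup() |>
    group_by(voltage_mV = .data$test_mV) |>
    summarise(se = if (dplyr::n() > 1) sd(.data$g) / sqrt(dplyr::n()) else NA_real_,
              n_experiments = dplyr::n(),
              g = mean(.data$g), .groups = "drop") |>
    select("voltage_mV", "g", "se", "n_experiments") |>
    arrange(.data$voltage_mV)
}

#' Correct triple-pulse P3 peaks for deactivation during P2
#'
#' At strongly hyperpolarized P2 voltages channels deactivate during the
#' brief P2 pulse, so the raw P3 peak underestimates availability. For
#' sweeps with P2 below `threshold_mV`, a mono-exponential is fitted to
#' the P2 falling phase and extrapolated back to the start of P2; the
#' extrapolated amplitude replaces the raw peak. If the P2 segment does
#' not decay, the fit is skipped and the raw peak kept, with a warning.
#'
#' @param traces Long tibble of triple-pulse sweeps.
#' @param protocol The [triple_pulse_protocol()]-style protocol used
#'   (P2 varied, P3 the test segment).
#' @param threshold_mV Apply the correction only for P2 voltages below
#'   this value (default -120 mV).
#' @param guard_ms Guard interval after each step, ms.
#' @return A tibble `experiment`, `sweep`, `voltage_mV` (P2), `raw_peak`,
#'   `corrected_peak`, `tau_ms`, `corrected` (logical).
#' @export
correct_inactivation_peaks <- function(traces, protocol, threshold_mV = -120,
                                       guard_ms = 2) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  vi <- varied_segment(protocol)
  p2_label <- protocol$segments$label[vi]
  if (vi >= nrow(protocol$segments)) abort("No test segment after P2.")
  p3_label <- protocol$segments$label[vi + 1L]
  if (!all(c(p2_label, p3_label) %in% traces$segment)) {
    abort("P2/P3 segments missing from the traces.")
  }
  if (!"experiment" %in% names(traces)) traces$experiment <- 1L

  fit_decay <- function(seg_df) {
    t0 <- min(seg_df$time_ms)
    tt <- seg_df$time_ms - t0
    keep <- tt >= guard_ms
    tt <- tt[keep]; cur <- seg_df$current[keep]
    sgn <- sign(mean(cur))
    if (sgn == 0) return(NULL)
    y <- sgn * cur
    # require a genuinely falling phase before trusting an extrapolation
    half <- length(y) %/% 2
    if (half < 3 || mean(y[seq_len(half)]) <= mean(y[-seq_len(half)]) * 1.02) {
      return(NULL)
    }
    start <- list(A = max(y), tau = max(diff(range(tt)) / 3, 1))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-tt / tau), start = start,
                        lower = c(A = 0, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    cf <- coef(fit)
    # extrapolate to the start of P2 (t = 0)
    list(amp = sgn * unname(cf["A"]), tau = unname(cf["tau"]))
  }

  sweeps <- traces |>
    filter(.data$segment == p2_label) |>
    distinct(.data$experiment, .data$sweep, p2_mV = .data$voltage_mV)
  purrr::pmap_dfr(sweeps, function(experiment, sweep, p2_mV) {
    p3 <- traces[traces$experiment == experiment & traces$sweep == sweep &
                   traces$segment == p3_label, ]
    raw <- segment_peak(p3, guard_ms)
    corrected <- raw; tau <- NA_real_; did <- FALSE
    if (p2_mV < threshold_mV) {
      p2 <- traces[traces$experiment == experiment & traces$sweep == sweep &
                     traces$segment == p2_label, ]
      dec <- fit_decay(p2)
      if (is.null(dec)) {
        warn(sprintf(
          "Sweep %s (P2 = %g mV): P2 decay fit failed; raw peak kept.",
          sweep, p2_mV))
      } else {
        corrected <- dec$amp
        tau <- dec$tau
        did <- TRUE
      }
    }
    tibble(experiment = experiment, sweep = sweep, voltage_mV = p2_mV,
           raw_peak = raw, corrected_peak = corrected, tau_ms = tau,
           corrected = did)
  })
}

#' Extract availability points from triple-pulse sweeps
#'
#' Applies [correct_inactivation_peaks()], normalizes corrected peak
#' magnitudes within each experiment by their maximum, and averages
#' across experiments per P2 voltage, yielding the steady-state
#' inactivation (availability) curve I/Imax vs V.
#'
#' @inheritParams correct_inactivation_peaks
#' @return A tibble `voltage_mV`, `g` (mean I/Imax), `se`,
#'   `n_experiments`.
#' @export
extract_availability_points <- function(traces, protocol, threshold_mV = -120,
                                        guard_ms = 2) {
  correct_inactivation_peaks(traces, protocol, threshold_mV, guard_ms) |>
    group_by(.data$experiment) |>
    mutate(g = abs(.data$corrected_peak) / max(abs(.data$corrected_peak))) |>
    ungroup() |>
    group_by(.data$voltage_mV) |>
    summarise(se = if (dplyr::n() > 1) sd(.data$g) / sqrt(dplyr::n()) else NA_real_,
              n_experiments = dplyr::n(),
              g = mean(.data$g), .groups = "drop") |>
    select("voltage_mV", "g", "se", "n_experiments") |>
    arrange(.data$voltage_mV)
}

fit_boltzmann <- function(points, kind, temperature) {
  points <- as_tibble(points)
  if (!"g" %in% names(points) && "value" %in% names(points)) {
    points <- rename(points, g = "value")
  }
  stopifnot(all(c("voltage_mV", "g") %in% names(points)))
  if (length(unique(points$voltage_mV)) < 4L) {
    abort("Need at least 4 distinct voltages spanning the transition.")
  }
  v <- points$voltage_mV
  g <- points$g
  slope_sign <- if (kind == "activation") 1 else -1

  # self-start: logit-linear regression gives z and V_half
  gc <- pmin(pmax(g, 1e-4), 1 - 1e-4)
  ll <- lm(log(gc / (1 - gc)) ~ v)
  b <- unname(coef(ll)[2]) * slope_sign
  kT <- FARADAY_C / (GAS_R * temperature) / 1000  # per mV per unit z
  z0 <- max(abs(b) / kT, 0.1)
  vh0 <- -unname(coef(ll)[1]) / unname(coef(ll)[2])
  if (!is.finite(vh0)) vh0 <- median(v)

  form <- if (kind == "activation") {
    g ~ 1 / (1 + exp(z * kT * (vh - v)))
  } else {
    g ~ 1 / (1 + exp(-z * kT * (vh - v)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = list(z = z0, vh = vh0),
                      data = list(g = g, v = v, kT = kT),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf(
        "Boltzmann fit failed to converge (%s). Residual range of start curve: [%.3g, %.3g].",
        conditionMessage(e),
        min(g - 1 / (1 + exp(slope_sign * z0 * kT * (vh0 - v)))),
        max(g - 1 / (1 + exp(slope_sign * z0 * kT * (vh0 - v))))
      ))
    }
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(z = NA, vh = NA))
  structure(
    list(kind = kind, z = unname(cf["z"]), v_half = unname(cf["vh"]),
         z_se = unname(se["z"]), v_half_se = unname(se["vh"]),
         temperature = temperature, n_points = length(g),
         fit = fit, data = points),
    class = "boltzmann_fit"
  )
}

#' Fit a two-state Boltzmann to G-V points
#'
#' Least-squares fit of `G(V) = 1 / (1 + exp(zF/RT (V_half - V)))`
#' (increasing in V) returning the apparent valence `z` and midpoint
#' `V_half` with asymptotic standard errors.
#'
#' @param points Tibble with `voltage_mV` and `g` (or `value`) columns;
#'   replicate rows per voltage are allowed and fitted unweighted.
#' @param temperature Temperature, K.
#' @return A `boltzmann_fit` object; see [tidy.boltzmann_fit()].
#' @export
fit_gv <- function(points, temperature = DEFAULT_TEMP_K) {
  fit_boltzmann(points, "activation", temperature)
}

#' Fit a two-state Boltzmann to availability points
#'
#' As [fit_gv()] but for the decreasing steady-state inactivation curve
#' `I/Imax(V) = 1 / (1 + exp(-zF/RT (V_half - V)))`.
#'
#' @inheritParams fit_gv
#' @return A `boltzmann_fit` object.
#' @export
fit_inactivation <- function(points, temperature = DEFAULT_TEMP_K) {
  fit_boltzmann(points, "inactivation", temperature)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> %s: z = %.3f +/- %.3f, V_half = %.2f +/- %.2f mV (T = %.2f K, n = %d)\n",
    x$kind, x$z, x$z_se, x$v_half, x$v_half_se, x$temperature, x$n_points))
  invisible(x)
}

#' Predicted Boltzmann curve
#'
#' @param object A `boltzmann_fit`.
#' @param newdata Optional tibble with a `voltage_mV` column.
#' @param ... Unused.
#' @return Numeric vector of fitted open/available fractions.
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage_mV else newdata$voltage_mV
  if (object$kind == "activation") {
    boltzmann_g(v, object$z, object$v_half, object$temperature)
  } else {
    boltzmann_avail(v, object$z, object$v_half, object$temperature)
  }
}
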