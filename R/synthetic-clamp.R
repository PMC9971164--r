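#' Two-state Boltzmann curves
#'
#' `boltzmann_g()` is the activation (conductance) curve, increasing in
#' voltage: `G(V) = 1 / (1 + exp(zF/RT (V_half - V)))`.
#' `boltzmann_avail()` is the availability (steady-state inactivation)
#' curve, decreasing in voltage: `I/Imax(V) = 1 / (1 + exp(-zF/RT (V_half - V)))`.
#'
#' @param v Membrane voltage(s), mV.
#' @param z Apparent valence (dimensionless).
#' @param v_half Midpoint voltage, mV.
#' @param temperature Temperature in K (default 290.65, ~17.5 C).
#' @return Values in (0, 1).
#' @export
boltzmann_g <- function(v, z, v_half, temperature = DEFAULT_TEMP_K) {
  s <- z * FARADAY_C / (GAS_R * temperature) / 1000  # per mV
  1 / (1 + exp(s * (v_half - v)))
}

#' @rdname boltzmann_g
#' @export
boltzmann_avail <- function(v, z, v_half, temperature = DEFAULT_TEMP_K) {
  s <- z * FARADAY_C / (GAS_R * temperature) / 1000
  1 / (1 + exp(-s * (v_half - v)))
}

#' Specification for synthetic voltage-clamp data
#'
#' Ground truth for the clamp generators: a two-state Boltzmann with
#' apparent valence `z_true` and midpoint `v_half_true`, sampled at the
#' given voltages with fractional Gaussian noise.
#'
#' @param z_true Apparent valence (dimensionless).
#' @param v_half_true Midpoint, mV.
#' @param voltages Strictly increasing test voltages, mV.
#' @param noise_sd Noise SD as a fraction of full scale.
#' @param n_sweeps_per_voltage Replicate sweeps per voltage.
#' @param tau_decay Decay time constant (ms) of current relaxation
#'   phases in trace generators.
#' @param temperature Temperature, K.
#' @param seed RNG seed.
#' @return A `clamp_spec` list.
#' @export
clamp_spec <- function(z_true = 2.8, v_half_true = -24.6,
                       voltages = seq(-80, 40, by = 10), noise_sd = 0.02,
                       n_sweeps_per_voltage = 3L, tau_decay = 10,
                       temperature = DEFAULT_TEMP_K, seed = 1L) {
  if (length(voltages) == 0L) abort("`voltages` must be non-empty.")
  if (is.unsorted(voltages, strictly = TRUE)) {
    abort("`voltages` must be strictly increasing.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (tau_decay <= 0) abort("`tau_decay` must be positive.")
  structure(
    list(z_true = z_true, v_half_true = v_half_true,
         voltages = as.numeric(voltages), noise_sd = noise_sd,
         n_sweeps_per_voltage = as.integer(n_sweeps_per_voltage),
         tau_decay = tau_decay, temperature = temperature,
         seed = as.integer(seed)),
    class = "clamp_spec"
  )
}

#' Generate normalized conductance samples
#'
#' Samples `value = G(V) + noise` per sweep and voltage from the
#' activation Boltzmann at the spec's ground truth. Noise is additive
#' Gaussian (unclipped, so the sample mean is unbiased for the curve).
#'
#' @param spec A [clamp_spec()].
#' @return A tibble `voltage_mV`, `sweep`, `value`.
#' @export
generate_boltzmann_currents <- function(spec) {
  stopifnot(inherits(spec, "clamp_spec"))
  set.seed(spec$seed)
  tidyr::expand_grid(voltage_mV = spec$voltages,
                     sweep = seq_len(spec$n_sweeps_per_voltage)) |>
    mutate(value = boltzmann_g(.data$voltage_mV, spec$z_true, spec$v_half_true,
                               spec$temperature) +
             rnorm(dplyr::n(), sd = spec$noise_sd))
}

#' Voltage protocol definition
#'
#' Ordered pulse segments applied each sweep. A segment with
#' `voltage_mV = NA` is the varied segment, swept over the voltages of
#' the generating / analyzed series.
#'
#' @param segments Tibble (or data frame) with columns `label`,
#'   `voltage_mV`, `duration_ms`.
#' @param holding_mV Holding potential, mV.
#' @return A `voltage_protocol`.
#' @export
voltage_protocol <- function(segments, holding_mV = -100) {
  segments <- as_tibble(segments)
  stopifnot(all(c("label", "voltage_mV", "duration_ms") %in% names(segments)))
  if (any(segments$duration_ms <= 0)) abort("Segment durations must be positive.")
  if (anyDuplicated(segments$label) > 0) abort("Segment labels must be unique.")
  structure(list(segments = segments, holding_mV = holding_mV),
            class = "voltage_protocol")
}

#' Standard protocols
#'
#' `gv_tail_protocol()`: depolarizing test pulse P1 (varied) followed by
#' a fixed repolarizing tail pulse P2 at -100 mV, the classical G-V tail
#' measurement. `triple_pulse_protocol()`: conditioning P1 (+20 mV, 1 s),
#' short varied P2 (30 ms), test P3 (+20 mV, 0.6 s), the classical
#' steady-state inactivation protocol.
#'
#' @param p1_ms,p2_ms,p3_ms Segment durations, ms.
#' @param tail_mV Tail voltage for the G-V protocol, mV.
#' @param p1_mV,p3_mV Conditioning/test voltages for the triple-pulse
#'   protocol, mV.
#' @return A [voltage_protocol()].
#' @export
gv_tail_protocol <- function(p1_ms = 1000, p2_ms = 100, tail_mV = -100) {
  voltage_protocol(tibble(
    label = c("P1", "P2"),
    voltage_mV = c(NA, tail_mV),
    duration_ms = c(p1_ms, p2_ms)
  ))
}

#' @rdname gv_tail_protocol
#' @export
triple_pulse_protocol <- function(p1_mV = 20, p1_ms = 1000, p2_ms = 30,
                                  p3_mV = 20, p3_ms = 600) {
  voltage_protocol(tibble(
    label = c("P1", "P2", "P3"),
    voltage_mV = c(p1_mV, NA, p3_mV),
    duration_ms = c(p1_ms, p2_ms, p3_ms)
  ))
}

varied_segment <- function(protocol) {
  idx <- which(is.na(protocol$segments$voltage_mV))
  if (length(idx) != 1L) abort("Protocol must have exactly one varied segment.")
  idx
}

# Shared trace assembly: given per-segment amplitude functions, sample a
# sweep at dt resolution into a long tibble.
assemble_sweep <- function(protocol, sweep_id, varied_v, seg_funs, dt, noise_sd) {
  segs <- protocol$segments
  t0 <- 0
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    tt <- seq(0, segs$duration_ms[i] - dt, by = dt)
    v <- if (is.na(segs$voltage_mV[i])) varied_v else segs$voltage_mV[i]
    cur <- seg_funs[[i]](tt, v)
    out[[i]] <- tibble(
      sweep = sweep_id, segment = segs$label[i],
      time_ms = t0 + tt, voltage_mV = v,
      current = cur + rnorm(length(tt), sd = noise_sd)
    )
    t0 <- t0 + segs$duration_ms[i]
  }
  dplyr::bind_rows(out)
}

#' Generate tail-current sweeps for a G-V measurement
#'
#' One sweep per spec voltage: during P1 (varied) the open fraction
#' relaxes toward the activation Boltzmann at that voltage; the tail
#' segment carries an inward (negative) current whose instantaneous
#' amplitude is proportional to the open fraction reached at the end of
#' P1 and decays with `tau_decay`. A brief capacitive-like spike at the
#' start of the tail exercises peak-window guarding.
#'
#' @param spec A [clamp_spec()] (activation ground truth).
#' @param protocol A [gv_tail_protocol()]-style protocol (P1 varied, then
#'   a fixed tail segment).
#' @param dt Sample interval, ms.
#' @param experiment Experiment identifier added to the output.
#' @return A tibble `experiment`, `sweep`, `segment`, `time_ms`,
#'   `voltage_mV`, `current`.
#' @export
generate_tail_current_traces <- function(spec, protocol = gv_tail_protocol(),
                                         dt = 0.5, experiment = 1L) {
  stopifnot(inherits(spec, "clamp_spec"), inherits(protocol, "voltage_protocol"))
  set.seed(spec$seed + 7919L * (as.integer(experiment) - 1L))
  vi <- varied_segment(protocol)
  if (vi != 1L) abort("The G-V protocol varies P1.")
  traces <- purrr::imap_dfr(spec$voltages, function(v1, k) {
    g_open <- boltzmann_g(v1, spec$z_true, spec$v_half_true, spec$temperature)
    seg_funs <- list(
      function(tt, v) g_open * (1 - exp(-(tt + dt) / 50)),           # activation rise
      function(tt, v) {
        tail_cur <- -g_open * exp(-tt / spec$tau_decay)
        tail_cur[tt < 1] <- tail_cur[tt < 1] + 2 * exp(-tt[tt < 1] / 0.2)  # capacitive spike
        tail_cur
      }
    )
    assemble_sweep(protocol, k, v1, seg_funs, dt, spec$noise_sd)
  })
  mutate(traces, experiment = experiment, .before = 1)
}

#' Generate triple-pulse inactivation sweeps
#'
#' One sweep per P2 voltage. The current available at the start of P2
#' follows the availability Boltzmann at that voltage; during P2 the
#' current decays mono-exponentially with `tau_decay`. Below
#' `deactivation_below_mV` this decay reflects channel deactivation and
#' also attenuates the raw P3 peak (so that extrapolating the P2 falling
#' phase back to the start of P2 recovers the true availability); at
#' less negative P2 voltages the P3 peak is the availability itself.
#'
#' @param spec A [clamp_spec()] (inactivation ground truth: decreasing
#'   availability with `z_true`, `v_half_true`).
#' @param protocol A [triple_pulse_protocol()]-style protocol (P2 varied).
#' @param deactivation_below_mV Deactivation threshold, mV; set to `-Inf`
#'   to disable deactivation entirely.
#' @param dt Sample interval, ms.
#' @param experiment Experiment identifier.
#' @return A tibble as in [generate_tail_current_traces()].
#' @export
generate_triple_pulse_traces <- function(spec, protocol = triple_pulse_protocol(),
                                         deactivation_below_mV = -120,
                                         dt = 0.5, experiment = 1L) {
  stopifnot(inherits(spec, "clamp_spec"), inherits(protocol, "voltage_protocol"))
  set.seed(spec$seed + 104729L * (as.integer(experiment) - 1L))
  vi <- varied_segment(protocol)
  if (vi != 2L) abort("The triple-pulse protocol varies P2.")
  dur2 <- protocol$segments$duration_ms[vi]
  traces <- purrr::imap_dfr(spec$voltages, function(v2, k) {
    avail <- boltzmann_avail(v2, spec$z_true, spec$v_half_true, spec$temperature)
    deact <- v2 < deactivation_below_mV
    atten <- if (deact) exp(-dur2 / spec$tau_decay) else 1
    seg_funs <- list(
      function(tt, v) 0.8 * (1 - exp(-(tt + dt) / 40)) * exp(-tt / 400),
      function(tt, v) {
        if (deact) avail * exp(-tt / spec$tau_decay) else rep(avail, length(tt))
      },
      function(tt, v) avail * atten * exp(-tt / 120)
    )
    assemble_sweep(protocol, k, v2, seg_funs, dt, spec$noise_sd)
  })
  mutate(traces, experiment = experiment, .before = 1)
}

#' Write a conductance table to CSV
#'
#' @param tbl Output of [generate_boltzmann_currents()].
#' @param path Output CSV path (columns `voltage_mV`, `sweep`, `value`).
#' @param spec Optional generating [clamp_spec()]; when given, a JSON
#'   sidecar with the ground truth is written next to the CSV.
#' @return Invisibly, `path`.
#' @export
write_conductance_csv <- function(tbl, path, spec = NULL) {
  write.csv(tbl[c("voltage_mV", "sweep", "value")], path, row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
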