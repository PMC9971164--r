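#' Gating free energy from a Boltzmann fit
#'
#' `Delta G = z F V_half`, with `F = 23.061` kcal mol^-1 V^-1 and
#' `V_half` in volts: the chemical free-energy difference between the
#' two gating states at 0 mV implied by the fitted curve. Temperature
#' enters the fit steepness only, never this energy.
#'
#' @param fit A `boltzmann_fit`, or any list/one-row data frame with
#'   elements `z` and `v_half` (mV).
#' @param faraday Faraday constant in kcal mol^-1 V^-1.
#' @return Free energy in kcal/mol.
#' @export
#' @examples
#' gating_free_energy(list(z = 2.8, v_half = -24.6))  # -1.6 kcal/mol
gating_free_energy <- function(fit, faraday = FARADAY_KCAL) {
  z <- fit$z
  v_half <- fit$v_half
  stopifnot(is.numeric(z), is.numeric(v_half))
  z * faraday * v_half / 1000
}

#' Gating-energy perturbation of a mutant
#'
#' `Delta Delta G = Delta G(mutant) - Delta G(wild type)`. Both
#' arguments may be `boltzmann_fit` objects (their `kind`s must match:
#' activation with activation, inactivation with inactivation) or plain
#' Delta G numbers in kcal/mol.
#'
#' @param mut,wt Mutant and wild-type fits or Delta G values.
#' @param faraday Faraday constant in kcal mol^-1 V^-1.
#' @return Delta Delta G in kcal/mol.
#' @export
ddG <- function(mut, wt, faraday = FARADAY_KCAL) {
  if (inherits(mut, "boltzmann_fit") || inherits(wt, "boltzmann_fit")) {
    if (!inherits(mut, "boltzmann_fit") || !inherits(wt, "boltzmann_fit")) {
      abort("Give two fits or two Delta G numbers, not a mixture.")
    }
    if (!identical(mut$kind, wt$kind)) {
      abort(sprintf("Process kinds differ: %s vs %s.", mut$kind, wt$kind))
    }
    return(gating_free_energy(mut, faraday) - gating_free_energy(wt, faraday))
  }
  stopifnot(is.numeric(mut), is.numeric(wt))
  mut - wt
}

#' Propagated error of a gating energy
#'
#' Per-channel error propagation
#' `delta = F sqrt((dz * V_half)^2 + (dV_half * z)^2)` with voltages in
#' volts. For a mutant-minus-wild-type perturbation the per-channel
#' errors of the two constructs are combined in quadrature by
#' [gating_energy_table()]; this function evaluates the single-channel
#' expression.
#'
#' @param z,v_half Fitted valence and midpoint (mV).
#' @param z_se,v_half_se Their standard errors (midpoint SE in mV).
#' @param faraday Faraday constant in kcal mol^-1 V^-1.
#' @return Standard error in kcal/mol.
#' @export
ddG_error <- function(z, z_se, v_half, v_half_se, faraday = FARADAY_KCAL) {
  stopifnot(z_se >= 0, v_half_se >= 0)
  faraday * sqrt((z_se * v_half / 1000)^2 + (v_half_se / 1000 * z)^2)
}

#' Gating energy table for a set of constructs
#'
#' Turns a table of Boltzmann fits into per-construct gating free
#' energies and mutant-minus-wild-type perturbations with propagated
#' errors, the analogue of a published energetics table. Activation and
#' inactivation rows are handled separately and each mutant is compared
#' with the wild-type row of its own kind.
#'
#' @param fits Tibble with columns `construct`, `kind` ("activation" or
#'   "inactivation"), `z`, `z_se`, `v_half` (mV), `v_half_se` (mV).
#' @param wt Name of the reference construct (default `"WT"`).
#' @param faraday Faraday constant in kcal mol^-1 V^-1.
#' @return A tibble with `dg`, `dg_se` (per-channel propagated error),
#'   `ddg` (0 for the reference), `ddg_se_channel` (mutant-only
#'   expression) and `ddg_se` (mutant and wild-type combined in
#'   quadrature; `NA` for the reference row).
#' @export
gating_energy_table <- function(fits, wt = "WT", faraday = FARADAY_KCAL) {
  fits <- as_tibble(fits)
  need <- c("construct", "kind", "z", "z_se", "v_half", "v_half_se")
  stopifnot(all(need %in% names(fits)))
  if (!wt %in% fits$construct) {
    abort(sprintf("Reference construct '%s' not found.", wt))
  }
  fits |>
    group_by(.data$kind) |>
    group_modify(function(df, key) {
      wt_row <- df[df$construct == wt, ]
      if (nrow(wt_row) != 1L) {
        abort(sprintf("Need exactly one '%s' row per kind.", wt))
      }
      dg_wt <- gating_free_energy(wt_row, faraday)
      err_wt <- ddG_error(wt_row$z, wt_row$z_se, wt_row$v_half,
                          wt_row$v_half_se, faraday)
      df |>
        mutate(
          dg = gating_free_energy(list(z = .data$z, v_half = .data$v_half), faraday),
          dg_se = ddG_error(.data$z, .data$z_se, .data$v_half, .data$v_half_se,
                            faraday),
          ddg = .data$dg - dg_wt,
          ddg_se_channel = .data$dg_se,
          ddg_se = ifelse(.data$construct == wt, NA_real_,
                          sqrt(.data$dg_se^2 + err_wt^2))
        )
    }) |>
    ungroup() |>
    relocate("construct", "kind")
}

#' Published hERG Boltzmann fit parameters
#'
#' Fitted `(z, V_half)` values (with standard errors) for wild-type hERG
#' and ten single mutants, for both the conductance-voltage (activation)
#' and the steady-state inactivation curves, as reported for cut-open
#' oocyte recordings at room temperature. Constructs that did not
#' express are omitted. These printed fits are the tabular entry point
#' of the energetics arm: [gating_energy_table()] applied to them
#' reproduces the published gating-energy and perturbation tables.
#'
#' @return A tibble `construct`, `kind`, `z`, `z_se`, `v_half` (mV),
#'   `v_half_se` (mV).
#' @export
herg_fit_table <- function() {
  act <- dplyr::tribble(
    ~construct, ~v_half, ~v_half_se, ~z, ~z_se,
    "WT",    -24.6, 0.5, 2.8, 0.1,
    "T425L",  -5.2, 0.4, 2.6, 0.1,
    "L524R", -39.6, 0.7, 2.1, 0.1,
    "A527L", -30.8, 1.6, 2.9, 0.5,
    "L529H", -56.7, 0.9, 2.8, 0.3,
    "L532H", -33.9, 1.4, 3.0, 0.4,
    "W563L", -51.7, 1.0, 3.3, 0.4,
    "A614G", -21.2, 0.2, 3.3, 0.1,
    "T618L", -18.9, 0.7, 2.7, 0.2
  )
  inact <- dplyr::tribble(
    ~construct, ~v_half, ~v_half_se, ~z, ~z_se,
    "WT",    -61.8, 0.7, 0.9, 0.1,
    "T425L", -34.8, 1.1, 0.7, 0.1,
    "L524R", -89.6, 1.5, 0.7, 0.1,
    "A527L", -78.6, 0.6, 0.9, 0.1,
    "L529H", -77.5, 1.6, 0.8, 0.1,
    "L532H", -86.6, 1.5, 0.6, 0.1,
    "W563L", -60.7, 0.7, 0.9, 0.1,
    "A614G", -69.7, 2.0, 1.1, 0.1,
    "T618L", -63.0, 0.7, 0.9, 0.1
  )
  bind_rows(
    mutate(act, kind = "activation"),
    mutate(inact, kind = "inactivation")
  ) |>
    select("construct", "kind", "z", "z_se", "v_half", "v_half_se")
}
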