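#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a Boltzmann fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return One row per parameter (`z`, `v_half`) with `estimate` and
#'   `std.error`.
#' @method tidy boltzmann_fit
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("z", "v_half"),
         estimate = c(x$z, x$v_half),
         std.error = c(x$z_se, x$v_half_se))
}

#' @rdname tidy.boltzmann_fit
#' @return `glance()`: a one-row model summary with the fitted
#'   parameters, residual standard error, and the implied gating free
#'   energy (kcal/mol).
#' @method glance boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  res <- stats::residuals(x$fit)
  tibble(kind = x$kind, z = x$z, z_se = x$z_se,
         v_half = x$v_half, v_half_se = x$v_half_se,
         sigma = sqrt(sum(res^2) / max(length(res) - 2, 1)),
         n = x$n_points,
         temperature = x$temperature,
         dg = gating_free_energy(x))
}

#' @rdname tidy.boltzmann_fit
#' @return `augment()`: the fitted points with `.fitted` and `.resid`.
#' @method augment boltzmann_fit
#' @export
augment.boltzmann_fit <- function(x, ...) {
  d <- as_tibble(x$data)
  d$.fitted <- predict(x)
  d$.resid <- d$g - d$.fitted
  d
}
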