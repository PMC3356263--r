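# Activation-energy estimation from temperature series of permeability.

#' Fit an Arrhenius plot and estimate the activation energy
#'
#' Ordinary least squares of `ln P` against `1/T` (T in kelvin,
#' `K = degC + 273.15`); the activation energy is the negative slope times
#' the gas constant, `Ea = -slope * R` with `R = 1.987e-3 kcal mol^-1 K^-1`.
#' Unweighted. Low Ea (< ~5 kcal/mol) indicates channel-mediated transport;
#' high values indicate diffusion across the lipid bilayer.
#'
#' @param temperatures_c temperatures in degC (>= 2 distinct; >= 3 for a
#'   slope standard error).
#' @param permeabilities permeabilities in cm s^-1 (> 0).
#' @param constants a [physical_constants()].
#' @return an object of class `arrhenius_fit` with `ea_kcal`, `se_ea`,
#'   `slope_k` (K), `intercept`, `r_squared`, `n_temperatures`.
#' @export
#' @examples
#' # doubling P between 283 K and 310 K implies Ea = 4.47 kcal/mol
#' fit_arrhenius(c(283, 310) - 273.15, c(1e-5, 2e-5))$ea_kcal
fit_arrhenius <- function(temperatures_c, permeabilities,
                          constants = physical_constants()) {
  if (length(temperatures_c) != length(permeabilities))
    aqp_stop("'temperatures_c' and 'permeabilities' lengths differ")
  if (any(!is.finite(permeabilities)) || any(permeabilities <= 0))
    aqp_stop("permeabilities must all be positive")
  if (length(unique(temperatures_c)) < 2L)
    aqp_stop("need at least 2 distinct temperatures")
  inv_t <- 1 / celsius_to_kelvin(temperatures_c)
  fit <- lm(log(permeabilities) ~ inv_t)
  cf <- coef(fit)
  slope <- unname(cf[2])
  # slope SE and R^2 computed directly (summary.lm warns on perfect fits)
  n <- length(permeabilities)
  rss <- sum(fit$residuals^2)
  sxx <- sum((inv_t - mean(inv_t))^2)
  tss <- sum((log(permeabilities) - mean(log(permeabilities)))^2)
  se_slope <- if (n >= 3L) sqrt(rss / (n - 2) / sxx) else NA_real_
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(list(ea_kcal = -slope * constants$r_gas_kcal,
                 se_ea = se_slope * constants$r_gas_kcal,
                 slope_k = slope, intercept = unname(cf[1]),
                 r_squared = r2,
                 n_temperatures = length(unique(temperatures_c))),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.4g +/- %.2g kcal/mol (slope %.4g K, R^2 = %.4f, %d temperatures)\n",
              x$ea_kcal, x$se_ea, x$slope_k, x$r_squared, x$n_temperatures))
  invisible(x)
}

#' Percent change of activation energy between conditions
#'
#' `100 (Ea_treated - Ea_control) / Ea_control`. A marked Ea increase under
#' an inhibitor indicates that transport has shifted from the (low-barrier)
#' channel pathway toward the (high-barrier) bilayer pathway.
#'
#' @param ea_control,ea_treated activation energies in kcal mol^-1 (numbers
#'   or `arrhenius_fit` objects); `ea_control != 0`.
#' @return percent change.
#' @export
#' @examples
#' ea_percent_change(8.5, 13.2) # 55.3
ea_percent_change <- function(ea_control, ea_treated) {
  val <- function(x) if (inherits(x, "arrhenius_fit")) x$ea_kcal else x
  ec <- val(ea_control); et <- val(ea_treated)
  if (!is_number(ec) || ec == 0)
    aqp_stop("control activation energy must be nonzero")
  100 * (et - ec) / ec
}
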