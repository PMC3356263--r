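# Forward two-compartment osmotic model: water flux driven by the total
# osmotic gradient, optional permeant-solute flux driven by its own chemical
# gradient. Reflection coefficients are 1 for all solutes and there is no
# solvent drag; membrane area is constant during volume changes.

#' Boyle-van't Hoff equilibrium volume
#'
#' Final cell volume after full osmotic equilibration with a bath. A permeant
#' species, if present, is treated as fully equilibrated and therefore
#' osmotically silent: only the impermeant external osmolarity balances the
#' internal impermeant solutes, offset by the osmotically inactive fraction:
#' `V_inf = b V0 + (1 - b) V0 (iso / osm_impermeant_out)`.
#'
#' @param cell a [cell_spec()].
#' @param bath a [bath_spec()].
#' @return equilibrium volume in fL.
#' @export
#' @examples
#' equilibrium_volume(cell_spec(82, 91.1, 0.5, 300), bath_spec(400)) # 71.75
equilibrium_volume <- function(cell, bath) {
  stopifnot(inherits(cell, "cell_spec"), inherits(bath, "bath_spec"))
  if (bath$impermeant_mosm <= 0)
    aqp_stop("external impermeant osmolarity must be > 0",
             class = "aquaflow_bath_error")
  b <- cell$inactive_fraction
  b * cell$v0_fl +
    (1 - b) * cell$v0_fl * (cell$iso_mosm / bath$impermeant_mosm)
}

#' A simulated cell-volume time course
#'
#' Container for simulated volume kinetics; the unit the optical model
#' renders into scattering traces.
#'
#' @param times time grid in s, strictly increasing, `times[1] >= 0`.
#' @param volumes_fl cell volumes in fL.
#' @param v0_fl reference initial (isotonic) volume in fL.
#' @param temperature_c sample temperature in degC.
#' @param truth optional record of the permeabilities used to generate the
#'   trace (kept for recovery tests; strippable for blind analysis).
#' @return an object of class `volume_trace`.
#' @export
volume_trace <- function(times, volumes_fl, v0_fl,
                         temperature_c = NA_real_, truth = NULL) {
  if (length(times) != length(volumes_fl) || length(times) < 2L)
    aqp_stop("'times' and 'volumes_fl' must have equal length >= 2")
  if (times[1] < 0 || any(diff(times) <= 0))
    aqp_stop("'times' must be non-negative and strictly increasing")
  structure(list(times = as.numeric(times),
                 volumes_fl = as.numeric(volumes_fl),
                 v0_fl = v0_fl, temperature_c = temperature_c, truth = truth),
            class = "volume_trace")
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf("<volume_trace> %d points, t = [%g, %g] s, V = [%.4g, %.4g] fL (V0 = %g fL)\n",
              length(x$times), min(x$times), max(x$times),
              min(x$volumes_fl), max(x$volumes_fl), x$v0_fl))
  invisible(x)
}

#' @export
as.data.frame.volume_trace <- function(x, ...) {
  data.frame(time_s = x$times, volume_fl = x$volumes_fl)
}

#' Simulate an osmotic cell-volume time course
#'
#' Integrates the two-compartment osmotic model
#' \deqn{dV_w/dt = -P_f A \bar{V}_w (C_{out} - C_{in}), \qquad
#'       dN_s/dt = P_s A (C_{s,out} - N_s/V_w),}
#' where `Vw` is the osmotically active water volume, `Ns` the moles of
#' internal permeant solute (zero at t = 0), `C_in = (N_imp + Ns)/Vw` and
#' `C_out` the constant total external osmolarity (infinite bath). The
#' reported volume is `V(t) = b V0 + Vw(t)`. With an impermeant-only bath the
#' trace shrinks monotonically to the Boyle-van't Hoff equilibrium; with a
#' permeant gradient it is biphasic (fast shrinkage, slow reswelling back to
#' `V0` when the external impermeant osmolarity equals the isotonic value).
#'
#' @param cell a [cell_spec()].
#' @param bath a [bath_spec()].
#' @param pf osmotic water permeability in cm s^-1 (> 0).
#' @param psolute permeant-solute permeability in cm s^-1 (>= 0).
#' @param times strictly increasing time grid in s.
#' @param constants a [physical_constants()].
#' @param temperature_c recorded sample temperature in degC.
#' @param rtol relative tolerance of the adaptive (stiff-capable) integrator.
#' @return a [volume_trace()] carrying the generating truth.
#' @export
#' @examples
#' tr <- simulate_volume(hrbc_cell(0), bath_spec(400), pf = 0.042,
#'                       times = seq(0, 2, by = 0.002))
simulate_volume <- function(cell, bath, pf, psolute = 0, times,
                            constants = physical_constants(),
                            temperature_c = NA_real_, rtol = 1e-8) {
  stopifnot(inherits(cell, "cell_spec"), inherits(bath, "bath_spec"))
  stopifnot_number(pf, "pf", 0, strict_lower = TRUE)
  stopifnot_number(psolute, "psolute", 0)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1] < 0)
    aqp_stop("'times' must be strictly increasing and start at t >= 0")
  if (bath$impermeant_mosm <= 0)
    aqp_stop("external impermeant osmolarity must be > 0",
             class = "aquaflow_bath_error")

  a_cm2 <- um2_to_cm2(cell$area_um2)
  vw0 <- fl_to_cm3((1 - cell$inactive_fraction) * cell$v0_fl) # active water
  c_iso <- mosm_to_mol_cm3(cell$iso_mosm)
  c_out <- bath_osm_inf(bath)
  cs_out <- mosm_to_mol_cm3(bath$permeant_mm)
  kw <- pf * a_cm2 * constants$vw_molar / vw0     # s^-1 per (mol cm^-3)... scaled below
  ks <- psolute * a_cm2 / vw0

  # State: x = Vw/Vw0 (dimensionless), s = Ns/Vw0 (mol cm^-3).
  derivs <- function(t, y, p) {
    x <- y[1]; s <- y[2]
    c_in <- (c_iso + s) / x
    list(c(-kw * (c_out - c_in),
           if (ks > 0) ks * (cs_out - s / x) else 0))
  }

  grid <- times
  prepended <- FALSE
  if (grid[1] > 0) { grid <- c(0, grid); prepended <- TRUE }
  sol <- tryCatch(
    deSolve::lsoda(c(x = 1, s = 0), grid, derivs, parms = NULL,
                   rtol = rtol, atol = 1e-12),
    warning = function(w) aqp_stop(
      paste0("integration failed: ", conditionMessage(w)),
      class = "aquaflow_numerical_error"),
    error = function(e) aqp_stop(
      paste0("integration failed: ", conditionMessage(e)),
      class = "aquaflow_numerical_error"))
  if (nrow(sol) != length(grid) || anyNA(sol))
    aqp_stop(sprintf(
      "integration failed: returned %d of %d requested steps (step underflow?)",
      nrow(sol), length(grid)), class = "aquaflow_numerical_error")
  if (prepended) sol <- sol[-1L, , drop = FALSE]

  v_fl <- cell$inactive_fraction * cell$v0_fl + sol[, "x"] * cm3_to_fl(vw0)
  volume_trace(times, v_fl, v0_fl = cell$v0_fl, temperature_c = temperature_c,
               truth = list(pf = pf, psolute = psolute,
                            cell = unclass(cell), bath = unclass(bath)))
}

#' Linearized shrinkage rate constant implied by a water permeability
#'
#' The single-exponential rate constant the classic estimator associates
#' with a water permeability on an impermeant-gradient challenge:
#' `k = Pf (A/V0) Vw_molar (osm_out)inf`, the exact algebraic inverse of
#' [pf_from_rate()]. The formula treats the whole initial cell volume as
#' osmotically active water; see the methods vignette for its accuracy
#' against the full model.
#'
#' @param cell a [cell_spec()].
#' @param bath a [bath_spec()] with no permeant species.
#' @param pf water permeability in cm s^-1 (>= 0).
#' @param constants a [physical_constants()].
#' @return rate constant k in s^-1.
#' @export
#' @examples
#' # Pf = 4.2e-2 cm/s, V0/A = 9e-5 cm, 400 mOsM -> k = 3.36 s^-1
#' linearized_rate(hrbc_cell(0), bath_spec(400), 4.2e-2)
linearized_rate <- function(cell, bath, pf,
                            constants = physical_constants()) {
  stopifnot(inherits(cell, "cell_spec"), inherits(bath, "bath_spec"))
  stopifnot_number(pf, "pf", 0)
  if (!is.null(bath$permeant))
    aqp_stop("linearized_rate applies to impermeant-only baths")
  pf / v0_over_a(cell) * constants$vw_molar * bath_osm_inf(bath)
}
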