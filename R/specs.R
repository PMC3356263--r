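# Domain specification objects: cell geometry, bath composition, physical
# constants and optics. All are plain validated lists with S3 classes so that
# they serialize cleanly to/from JSON manifests.

#' Cell geometry and osmotic parameters
#'
#' Describes the cell population loaded into the stopped-flow instrument:
#' initial volume, membrane area (assumed constant during volume changes --
#' shrinkage unfolds membrane rather than removing it), the osmotically
#' inactive volume fraction `b` (solids and bound water that do not exchange),
#' and the isotonic osmolarity the cells are equilibrated with at time zero.
#'
#' @param v0_fl initial (isotonic) cell volume in fL.
#' @param area_um2 membrane area in um^2.
#' @param inactive_fraction osmotically inactive volume fraction `b`,
#'   `0 <= b < 1`.
#' @param iso_mosm isotonic internal/external osmolarity in mOsM.
#' @param label optional free-text label.
#' @return an object of class `cell_spec`.
#' @seealso [hrbc_cell()], [pc12_cell()], [v0_over_a()]
#' @export
#' @examples
#' cell_spec(v0_fl = 82, area_um2 = 91.1, inactive_fraction = 0.43)
cell_spec <- function(v0_fl, area_um2, inactive_fraction = 0,
                      iso_mosm = 300, label = NULL) {
  stopifnot_number(v0_fl, "v0_fl", 0, strict_lower = TRUE)
  stopifnot_number(area_um2, "area_um2", 0, strict_lower = TRUE)
  stopifnot_number(inactive_fraction, "inactive_fraction", 0, 1 - 1e-12)
  stopifnot_number(iso_mosm, "iso_mosm", 0, strict_lower = TRUE)
  structure(list(v0_fl = v0_fl, area_um2 = area_um2,
                 inactive_fraction = inactive_fraction,
                 iso_mosm = iso_mosm, label = label),
            class = "cell_spec")
}

#' Initial volume-to-area ratio of a cell, in cm
#'
#' `V0/A` is the geometric factor entering all permeability formulas.
#'
#' @param cell a [cell_spec()].
#' @return `V0/A` in cm.
#' @export
v0_over_a <- function(cell) {
  stopifnot(inherits(cell, "cell_spec"))
  fl_to_cm3(cell$v0_fl) / um2_to_cm2(cell$area_um2)
}

#' Default human red blood cell specification
#'
#' Volume 82 fL (Coulter-type sizing of fresh erythrocytes in isotonic
#' buffer). The membrane area is a configuration choice, not a measured
#' value: the default 91.1 um^2 makes `V0/A = 9.0e-5` cm, the ratio
#' consistent with rate constants of a few s^-1 mapping onto water
#' permeabilities of a few 1e-2 cm/s as observed for erythrocytes.
#'
#' @param inactive_fraction osmotically inactive fraction; the standard
#'   erythrocyte literature value 0.43 by default. Use 0 when the fitted rate
#'   is to be converted with the classic `Pf = k (V0/A)/(Vw (osm)inf)`
#'   estimator, which treats the whole cell volume as osmotically active
#'   water (see the methods vignette).
#' @param v0_fl,area_um2,iso_mosm overrides of the defaults.
#' @return a [cell_spec()].
#' @export
hrbc_cell <- function(inactive_fraction = 0.43, v0_fl = 82,
                      area_um2 = v0_fl / FL_PER_CM3 / 9e-5 * UM2_PER_CM2,
                      iso_mosm = 300) {
  cell_spec(v0_fl, area_um2, inactive_fraction, iso_mosm, label = "hRBC")
}

#' Default PC12 cell specification (spherical geometry)
#'
#' Equilibrium volume 1076 um^3 (= 1076 fL) as measured by phase-contrast
#' imaging of suspended cells; the membrane area follows from the spherical
#' shape assumption, A = 4\*pi\*r^2 with radius (3V / 4pi)^(1/3).
#'
#' @param inactive_fraction osmotically inactive fraction; 0.30 by default,
#'   a standard value for nucleated cells.
#' @param v0_fl,iso_mosm overrides of the defaults.
#' @return a [cell_spec()].
#' @export
pc12_cell <- function(inactive_fraction = 0.30, v0_fl = 1076, iso_mosm = 300) {
  r_um <- (3 * v0_fl / (4 * pi))^(1 / 3)  # fL == um^3
  cell_spec(v0_fl, 4 * pi * r_um^2, inactive_fraction, iso_mosm,
            label = "PC12")
}

#' Bath (external medium) composition after mixing
#'
#' The external solution the cells face after the stopped-flow mixer:
#' an impermeant osmolarity (buffer plus any impermeant osmolyte such as
#' sucrose) and optionally one permeant species (glycerol or urea) at a given
#' concentration. Concentrations are post-mixing values; mixing equal volumes
#' of cell suspension with a hyperosmotic solution containing 200 mM permeant
#' yields a 100 mM inwardly directed gradient.
#'
#' @param impermeant_mosm impermeant external osmolarity in mOsM.
#' @param permeant optional permeant species name (`"glycerol"` or `"urea"`).
#' @param permeant_mm permeant concentration in mM (0 if absent).
#' @return an object of class `bath_spec`.
#' @export
#' @examples
#' bath_spec(400)                           # 100 mM sucrose gradient on 300 iso
#' bath_spec(300, "glycerol", 100)          # 100 mM glycerol gradient
bath_spec <- function(impermeant_mosm, permeant = NULL, permeant_mm = 0) {
  stopifnot_number(impermeant_mosm, "impermeant_mosm", 0)
  stopifnot_number(permeant_mm, "permeant_mm", 0)
  if (!is.null(permeant)) {
    permeant <- match.arg(permeant, c("glycerol", "urea"))
    if (permeant_mm <= 0)
      aqp_stop("'permeant_mm' must be > 0 when a permeant species is named")
  } else if (permeant_mm > 0) {
    aqp_stop("a permeant concentration requires a permeant species name")
  }
  structure(list(impermeant_mosm = impermeant_mosm, permeant = permeant,
                 permeant_mm = permeant_mm),
            class = "bath_spec")
}

# Total external osmolarity (mol cm^-3), the (osm_out)inf of the Pf formula.
bath_osm_inf <- function(bath) {
  mosm_to_mol_cm3(bath$impermeant_mosm + bath$permeant_mm)
}

#' Physical constants
#'
#' @param vw_molar molar volume of water in cm^3 mol^-1 (must lie in
#'   17.9--18.2).
#' @param r_gas_kcal gas constant in kcal mol^-1 K^-1 (1.987e-3).
#' @return an object of class `physical_constants`.
#' @export
physical_constants <- function(vw_molar = 18.02, r_gas_kcal = 1.987e-3) {
  stopifnot_number(vw_molar, "vw_molar", 17.9, 18.2)
  if (abs(r_gas_kcal - 1.987e-3) > 0.001 * 1.987e-3)
    aqp_stop("'r_gas_kcal' must equal 1.987e-3 within 0.1%")
  structure(list(vw_molar = vw_molar, r_gas_kcal = r_gas_kcal),
            class = "physical_constants")
}

#' Optical model of the stopped-flow detector
#'
#' The 90-degree scattered intensity is modelled as an affine function of the
#' relative volume change, `I(t) = alpha + beta (1 - V(t)/V0) + noise`:
#' intensity rises as cells shrink. The mapping is the simplest monotone
#' choice consistent with the observed signal direction, and exponential rate
#' constants are exactly invariant under it, so no optical calibration is
#' needed to extract `k`.
#'
#' @param alpha intensity offset (a.u.).
#' @param beta intensity gain (a.u., > 0).
#' @param noise_sigma additive Gaussian noise s.d. (a.u.).
#' @param sampling_rate acquisition rate in Hz.
#' @param dead_time instrument dead time in s (default 0.002 s = 2 ms);
#'   samples before the dead time are never observed.
#' @return an object of class `optics_spec`.
#' @export
optics_spec <- function(alpha = 0.1, beta = 1, noise_sigma = 0.002,
                        sampling_rate = 100, dead_time = 0.002) {
  stopifnot_number(alpha, "alpha")
  stopifnot_number(beta, "beta", 0, strict_lower = TRUE)
  stopifnot_number(noise_sigma, "noise_sigma", 0)
  stopifnot_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  stopifnot_number(dead_time, "dead_time", 0)
  structure(list(alpha = alpha, beta = beta, noise_sigma = noise_sigma,
                 sampling_rate = sampling_rate, dead_time = dead_time),
            class = "optics_spec")
}

#' Default optics for fast water-permeability traces (1000 Hz)
#' @param ... overrides passed to [optics_spec()].
#' @return an [optics_spec()].
#' @export
water_optics <- function(...) {
  do.call(optics_spec, modifyList(list(sampling_rate = 1000), list(...)))
}

#' Default optics for slower glycerol/urea traces (100 Hz)
#' @param ... overrides passed to [optics_spec()].
#' @return an [optics_spec()].
#' @export
solute_optics <- function(...) {
  do.call(optics_spec, modifyList(list(sampling_rate = 100), list(...)))
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf("<cell_spec%s> V0 = %g fL, A = %.4g um^2 (V0/A = %.4g cm), b = %g, iso = %g mOsM\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$v0_fl, x$area_um2, v0_over_a(x), x$inactive_fraction,
              x$iso_mosm))
  invisible(x)
}

#' @export
print.bath_spec <- function(x, ...) {
  cat(sprintf("<bath_spec> impermeant %g mOsM%s\n", x$impermeant_mosm,
              if (is.null(x$permeant)) ""
              else sprintf(" + %g mM %s", x$permeant_mm, x$permeant)))
  invisible(x)
}
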