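# Conversion of fitted rate constants into permeability coefficients,
# replicate aggregation (mean +/- SEM), fold changes and the channel+bilayer
# two-pathway decomposition.

#' A permeability estimate with replicate uncertainty
#'
#' @param value permeability in cm s^-1 (>= 0).
#' @param kind `"water"`, `"glycerol"` or `"urea"`.
#' @param sem standard error of the mean over replicates (0 for a single
#'   measurement).
#' @param n_replicates number of replicates aggregated.
#' @param temperature_c sample temperature in degC.
#' @param condition optional condition metadata list.
#' @return an object of class `permeability_estimate`.
#' @export
permeability_estimate <- function(value, kind = c("water", "glycerol", "urea"),
                                  sem = 0, n_replicates = 1L,
                                  temperature_c = NA_real_,
                                  condition = list()) {
  kind <- match.arg(kind)
  stopifnot_number(value, "value", 0)
  stopifnot_number(sem, "sem", 0)
  if (!is_number(n_replicates) || n_replicates < 1)
    aqp_stop("'n_replicates' must be >= 1")
  structure(list(value = value, kind = kind, sem = sem,
                 n_replicates = as.integer(n_replicates),
                 temperature_c = temperature_c, condition = condition),
            class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("<permeability_estimate> P_%s = (%.3g +/- %.2g) cm/s (n = %d%s)\n",
              switch(x$kind, water = "f", glycerol = "gly", urea = "urea"),
              x$value, x$sem, x$n_replicates,
              if (is.na(x$temperature_c)) ""
              else sprintf(", %g degC", x$temperature_c)))
  invisible(x)
}

#' Osmotic water permeability from a shrinkage rate constant
#'
#' The classic stopped-flow estimator
#' `Pf = k (V0/A) / (Vw_molar (osm_out)inf)`, the exact algebraic inverse of
#' [linearized_rate()]. `k` is the single-exponential rate constant fitted to
#' the shrinkage signal (or the amplitude-weighted biexponential rate,
#' [weighted_rate()], for cells with biexponential shrinkage).
#'
#' @param k rate constant in s^-1 (>= 0).
#' @param cell a [cell_spec()].
#' @param osm_out_inf final total external osmolarity in mol cm^-3 (use
#'   [bath_osm_inf_mosm()] or `mOsM * 1e-6`).
#' @param constants a [physical_constants()].
#' @param temperature_c,condition metadata attached to the estimate.
#' @return a [permeability_estimate()] of kind `"water"`.
#' @export
#' @examples
#' # k = 3.36 s^-1, V0/A = 9e-5 cm, 400 mOsM -> Pf = 4.2e-2 cm/s
#' pf_from_rate(3.36, hrbc_cell(0), osm_out_inf = 4e-4)$value
pf_from_rate <- function(k, cell, osm_out_inf,
                         constants = physical_constants(),
                         temperature_c = NA_real_, condition = list()) {
  stopifnot_number(k, "k", 0)
  stopifnot_number(osm_out_inf, "osm_out_inf", 0, strict_lower = TRUE)
  permeability_estimate(
    k * v0_over_a(cell) / (constants$vw_molar * osm_out_inf),
    kind = "water", temperature_c = temperature_c, condition = condition)
}

#' Total external osmolarity of a bath in mol cm^-3
#' @param bath a [bath_spec()].
#' @return `(osm_out)inf` in mol cm^-3.
#' @export
bath_osm_inf_mosm <- function(bath) {
  stopifnot(inherits(bath, "bath_spec"))
  bath_osm_inf(bath)
}

#' Solute (glycerol/urea) permeability from a reswelling rate constant
#'
#' `Psol = k (V0/A)`, with `k` the single-exponential rate constant fitted to
#' the solute-influx (reswelling) phase of the scattering signal. Urea traces
#' use the identical machinery.
#'
#' @param k rate constant in s^-1 (>= 0).
#' @param cell a [cell_spec()].
#' @param kind `"glycerol"` or `"urea"`.
#' @param temperature_c,condition metadata attached to the estimate.
#' @return a [permeability_estimate()].
#' @export
#' @examples
#' psolute_from_rate(0.2, hrbc_cell(0))$value # 1.8e-5 cm/s
psolute_from_rate <- function(k, cell, kind = c("glycerol", "urea"),
                              temperature_c = NA_real_, condition = list()) {
  kind <- match.arg(kind)
  if (!is_number(k) || k < 0)
    aqp_stop("'k' must be a single non-negative number")
  permeability_estimate(k * v0_over_a(cell), kind = kind,
                        temperature_c = temperature_c, condition = condition)
}

#' Aggregate replicate permeability estimates into mean +/- SEM
#'
#' @param estimates list of [permeability_estimate()]s from replicates of one
#'   homogeneous condition (same kind and temperature).
#' @return a [permeability_estimate()] with `sem = sd/sqrt(n)`; a single
#'   replicate yields `sem = 0` with a warning (documented convention to keep
#'   pipelines running on toy data).
#' @export
aggregate_replicates <- function(estimates) {
  if (!length(estimates)) aqp_stop("need at least one estimate")
  if (!all(vapply(estimates, inherits, TRUE, "permeability_estimate")))
    aqp_stop("all elements must be permeability_estimate objects")
  kinds <- unique(vapply(estimates, `[[`, "", "kind"))
  temps <- unique(vapply(estimates, `[[`, 0, "temperature_c"))
  if (length(kinds) != 1L)
    aqp_stop("mixed permeability kinds cannot be aggregated")
  if (length(temps[!is.na(temps)]) > 1L)
    aqp_stop("mixed temperatures cannot be aggregated")
  vals <- vapply(estimates, `[[`, 0, "value")
  n <- length(vals)
  sem <- if (n > 1L) sd(vals) / sqrt(n) else {
    warning("single replicate: SEM reported as 0", call. = FALSE)
    0
  }
  permeability_estimate(mean(vals), kind = kinds, sem = sem,
                        n_replicates = n,
                        temperature_c = temps[!is.na(temps)][1] %||% NA_real_,
                        condition = estimates[[1]]$condition)
}

#' Fold change of a permeability relative to a reference
#'
#' `fold = P_clone / P_ref`; the standard normalization of overexpressing
#' clones against wild type. Scale-invariant and dimensionless.
#'
#' @param p_clone,p_ref [permeability_estimate()]s (or bare numbers) of the
#'   same kind; `p_ref > 0`.
#' @return fold change (dimensionless).
#' @export
#' @examples
#' fold_change(permeability_estimate(10.11e-2), permeability_estimate(3.76e-2))
fold_change <- function(p_clone, p_ref) {
  val <- function(x) if (inherits(x, "permeability_estimate")) x$value else x
  knd <- function(x) if (inherits(x, "permeability_estimate")) x$kind else NULL
  if (!is.null(knd(p_clone)) && !is.null(knd(p_ref)) &&
      knd(p_clone) != knd(p_ref))
    aqp_stop("fold change requires permeabilities of the same kind")
  if (!is_number(val(p_ref)) || val(p_ref) <= 0)
    aqp_stop("reference permeability must be > 0")
  val(p_clone) / val(p_ref)
}

#' Residual total permeability under the two-pathway decomposition
#'
#' Total membrane permeability is decomposed into a channel fraction (in
#' erythrocytes usually ~90% of water flux) and a lipid-bilayer fraction
#' (~10%). An inhibitor acts only on the channel share, so the residual total
#' permeability fraction is `1 - channel_fraction * channel_inhibition`.
#'
#' @param channel_fraction fraction of total permeability carried by
#'   channels, in `[0, 1]`.
#' @param channel_inhibition inhibited fraction of the channel pathway, in
#'   `[0, 1]`.
#' @return residual total permeability as a fraction of the untreated value.
#' @export
#' @examples
#' two_pathway_residual(0.9, 1)   # full channel block leaves the 10% bilayer
two_pathway_residual <- function(channel_fraction, channel_inhibition) {
  stopifnot_number(channel_fraction, "channel_fraction", 0, 1)
  stopifnot_number(channel_inhibition, "channel_inhibition", 0, 1)
  1 - channel_fraction * channel_inhibition
}
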