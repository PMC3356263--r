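# Synthetic experiment generators: full bundles (replicated scattering traces
# + manifest + ground truth) for dose-response, incubation time-course and
# temperature (Arrhenius) series.

#' Ground truth of an inhibition experiment
#'
#' @param p_control uninhibited permeability in cm s^-1 (solute permeability
#'   for a glycerol/urea assay).
#' @param ic50_um half-maximal inhibitor concentration in uM.
#' @param hill Hill slope of the dose-response curve.
#' @param max_inhibition maximal inhibited fraction of the channel-mediated
#'   permeability, in (0, 1]. 0.9 by default: a potent blocker leaves ~10%
#'   residual transport through the bilayer and unblocked channels.
#' @param tau_incubation_min time constant (min) of the exponential approach
#'   of inhibition to its maximum during pre-incubation. The default 10 min
#'   puts >95% of maximal inhibition at 30 min incubation.
#' @return an object of class `inhibition_truth`.
#' @export
inhibition_truth <- function(p_control = 1.8e-5, ic50_um = 0.8, hill = 1,
                             max_inhibition = 0.9, tau_incubation_min = 10) {
  stopifnot_number(p_control, "p_control", 0, strict_lower = TRUE)
  stopifnot_number(ic50_um, "ic50_um", 0, strict_lower = TRUE)
  stopifnot_number(hill, "hill", 0, strict_lower = TRUE)
  stopifnot_number(max_inhibition, "max_inhibition", 0, 1, strict_lower = TRUE)
  stopifnot_number(tau_incubation_min, "tau_incubation_min", 0,
                   strict_lower = TRUE)
  structure(list(p_control = p_control, ic50_um = ic50_um, hill = hill,
                 max_inhibition = max_inhibition,
                 tau_incubation_min = tau_incubation_min),
            class = "inhibition_truth")
}

#' Hill-model inhibited fraction at a given inhibitor concentration
#'
#' `inhibition(c) = max_inhibition / (1 + 10^((log10 IC50 - log10 c) H))`,
#' the log-logistic law; zero at zero concentration.
#'
#' @param conc_um inhibitor concentration(s) in uM (>= 0).
#' @param truth an [inhibition_truth()].
#' @return inhibited fraction(s) in `[0, max_inhibition)`.
#' @export
hill_inhibition <- function(conc_um, truth) {
  stopifnot(inherits(truth, "inhibition_truth"))
  ifelse(conc_um <= 0, 0,
         truth$max_inhibition /
           (1 + 10^((log10(truth$ic50_um) - log10(conc_um)) * truth$hill)))
}

#' Arrhenius-law permeability at a given temperature
#'
#' `p(T) = p_ref exp(-Ea/R (1/T - 1/T_ref))` with temperatures in kelvin.
#'
#' @param ea_kcal activation energy in kcal mol^-1.
#' @param p_ref permeability at the reference temperature, cm s^-1.
#' @param t_ref_c reference temperature in degC.
#' @param t_c temperature(s) in degC.
#' @param constants a [physical_constants()].
#' @return permeability(ies) in cm s^-1.
#' @export
arrhenius_permeability <- function(ea_kcal, p_ref, t_ref_c, t_c,
                                   constants = physical_constants()) {
  p_ref * exp(-ea_kcal / constants$r_gas_kcal *
                (1 / celsius_to_kelvin(t_c) - 1 / celsius_to_kelvin(t_ref_c)))
}

# --- bundle plumbing ---------------------------------------------------------

new_bundle <- function(manifest, traces) {
  structure(list(manifest = manifest, traces = traces),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %d conditions, %d traces, seed %s%s\n",
              length(x$manifest$conditions),
              sum(lengths(x$traces)), format(x$manifest$seed),
              if (is.null(x$manifest$truth)) "" else " (truth recorded)"))
  invisible(x)
}

# Simulate one condition and render its replicates. `ci` indexes the
# condition within the bundle; replicate r then uses derive_seed(seed, ci, r).
condition_traces <- function(cell, bath, pf, psolute, duration_s, optics,
                             n_reps, seed, ci, condition, temperature_c) {
  times <- seq(0, duration_s, by = 1 / optics$sampling_rate)
  vt <- simulate_volume(cell, bath, pf = pf, psolute = psolute, times = times,
                        temperature_c = temperature_c)
  make_replicates(vt, optics, n = n_reps, seed = derive_seed(seed, ci),
                  condition = condition)
}

base_condition <- function(id, role, compound, concentration_um,
                           incubation_min, temperature_c, solute, bath,
                           n_reps, seed, ci) {
  list(id = id, role = role, compound = compound,
       concentration_um = concentration_um, incubation_min = incubation_min,
       temperature_c = temperature_c, solute = solute,
       bath = unclass(bath), n_replicates = n_reps,
       seed = derive_seed(seed, ci))
}

base_manifest <- function(seed, cell, optics, conditions, truth,
                          analysis = list()) {
  list(schema = "aquaflow-manifest-1",
       package_version = as.character(packageVersion("aquaflow")),
       seed = as.integer(seed),
       seed_rule = "replicate r of condition i uses derive_seed(seed, i, r)",
       cell = unclass(cell), optics = unclass(optics),
       analysis = analysis, conditions = conditions, truth = truth)
}

# --- generators --------------------------------------------------------------

#' Generate a synthetic dose-response experiment bundle
#'
#' Simulates a concentration series of permeant-solute stopped-flow traces
#' in which the treated solute permeability follows the Hill law
#' `p(c) = p_control (1 - max_inhibition / (1 + 10^((log10 IC50 - log10 c) H)))`,
#' plus an untreated control condition at zero concentration. Each condition
#' is rendered into `n_reps` replicate noisy traces. The bundle records the
#' generating truth (strippable for blind analysis).
#'
#' @param truth an [inhibition_truth()]; `p_control` is the control solute
#'   permeability.
#' @param concentrations_um inhibitor concentrations in uM (> 0); the default
#'   0.1--10 uM series spans the transition around an IC50 near 1 uM.
#' @param cell,bath,optics condition specs; defaults are an erythrocyte
#'   under a 100 mM glycerol gradient sampled at 100 Hz.
#' @param n_reps replicates per condition.
#' @param seed bundle seed; all trace noise derives from it.
#' @param pf_water water permeability (cm s^-1) used for the shrinkage phase,
#'   held constant across concentrations (the inhibitor acts on the solute
#'   pathway in this design).
#' @param duration_s acquisition window per trace in s.
#' @param temperature_c sample temperature in degC (23 for glycerol assays).
#' @param incubation_min pre-incubation time in min.
#' @param compound inhibitor name.
#' @return an `experiment_bundle`.
#' @export
make_dose_response_experiment <- function(truth = inhibition_truth(),
                                          concentrations_um = c(0.1, 0.3, 1, 3, 10),
                                          cell = hrbc_cell(),
                                          bath = bath_spec(300, "glycerol", 100),
                                          optics = solute_optics(),
                                          n_reps = 5L, seed = 1L,
                                          pf_water = 4.2e-2,
                                          duration_s = 120,
                                          temperature_c = 23,
                                          incubation_min = 30,
                                          compound = "Auphen") {
  stopifnot(inherits(truth, "inhibition_truth"))
  if (any(concentrations_um <= 0))
    aqp_stop("'concentrations_um' must all be > 0 (the control is added automatically)")
  if (is.null(bath$permeant))
    aqp_stop("dose-response generation needs a permeant-solute bath")
  concentrations_um <- sort(concentrations_um)
  conc_all <- c(0, concentrations_um)
  conditions <- list(); traces <- list()
  for (i in seq_along(conc_all)) {
    conc <- conc_all[i]
    p_i <- truth$p_control * (1 - hill_inhibition(conc, truth))
    id <- if (conc == 0) "control" else sprintf("dose-%02d", i - 1L)
    cond <- base_condition(id, role = if (conc == 0) "control" else "treated",
                           compound = if (conc == 0) "none" else compound,
                           concentration_um = conc,
                           incubation_min = incubation_min,
                           temperature_c = temperature_c,
                           solute = bath$permeant, bath = bath,
                           n_reps = n_reps, seed = seed, ci = i)
    conditions[[i]] <- cond
    traces[[id]] <- condition_traces(
      cell, bath, pf = pf_water, psolute = p_i, duration_s = duration_s,
      optics = optics, n_reps = n_reps, seed = seed, ci = i,
      condition = cond[c("id", "compound", "concentration_um",
                         "incubation_min", "solute")],
      temperature_c = temperature_c)
  }
  new_bundle(base_manifest(seed, cell, optics, conditions,
                           truth = c(list(kind = "dose_response",
                                          pf_water = pf_water),
                                     unclass(truth))),
             traces)
}

#' Generate a synthetic incubation time-course experiment bundle
#'
#' Inhibition grows with pre-incubation time as
#' `inhibition(t) = max_inhibition (1 - exp(-t / tau))`, applied to the
#' control solute permeability; the zero-time point is the untreated control.
#'
#' @param truth an [inhibition_truth()].
#' @param incubation_times_min incubation times in min (>= 0).
#' @param concentration_um fixed inhibitor concentration in uM.
#' @inheritParams make_dose_response_experiment
#' @return an `experiment_bundle`.
#' @export
make_time_course_experiment <- function(truth = inhibition_truth(),
                                        incubation_times_min = c(0, 2, 5, 10, 15, 20, 30, 45),
                                        concentration_um = 5,
                                        cell = hrbc_cell(),
                                        bath = bath_spec(300, "glycerol", 100),
                                        optics = solute_optics(),
                                        n_reps = 5L, seed = 1L,
                                        pf_water = 4.2e-2,
                                        duration_s = 120,
                                        temperature_c = 23,
                                        compound = "Auphen") {
  stopifnot(inherits(truth, "inhibition_truth"))
  if (any(incubation_times_min < 0))
    aqp_stop("'incubation_times_min' must be >= 0")
  if (is.null(bath$permeant))
    aqp_stop("time-course generation needs a permeant-solute bath")
  incubation_times_min <- sort(incubation_times_min)
  conditions <- list(); traces <- list()
  for (i in seq_along(incubation_times_min)) {
    tm <- incubation_times_min[i]
    inh <- truth$max_inhibition * (1 - exp(-tm / truth$tau_incubation_min))
    p_i <- truth$p_control * (1 - inh)
    id <- if (tm == 0) "control" else sprintf("time-%02d", i - 1L)
    cond <- base_condition(id, role = if (tm == 0) "control" else "treated",
                           compound = if (tm == 0) "none" else compound,
                           concentration_um = if (tm == 0) 0 else concentration_um,
                           incubation_min = tm,
                           temperature_c = temperature_c,
                           solute = bath$permeant, bath = bath,
                           n_reps = n_reps, seed = seed, ci = i)
    conditions[[i]] <- cond
    traces[[id]] <- condition_traces(
      cell, bath, pf = pf_water, psolute = p_i, duration_s = duration_s,
      optics = optics, n_reps = n_reps, seed = seed, ci = i,
      condition = cond[c("id", "compound", "concentration_um",
                         "incubation_min", "solute")],
      temperature_c = temperature_c)
  }
  new_bundle(base_manifest(seed, cell, optics, conditions,
                           truth = c(list(kind = "time_course",
                                          concentration_um = concentration_um,
                                          pf_water = pf_water),
                                     unclass(truth))),
             traces)
}

#' Generate a synthetic temperature-series (Arrhenius) experiment bundle
#'
#' Permeability follows the Arrhenius law
#' `p(T) = p_ref exp(-Ea/R (1/T - 1/T_ref))`; one condition per listed
#' temperature (duplicate temperatures simply add replicate conditions).
#' For a water series the varying permeability is `Pf` on an impermeant
#' (sucrose) gradient; for a glycerol/urea series it is the solute
#' permeability on a permeant gradient, with the water permeability held at
#' `pf_water` (the water pathway's own temperature dependence does not enter
#' the fitted solute phase).
#'
#' @param ea_kcal activation energy in kcal mol^-1.
#' @param p_ref permeability at `t_ref_c`, cm s^-1.
#' @param t_ref_c reference temperature in degC.
#' @param temperatures_c temperature series in degC (>= 3 values; the
#'   default spans the 10--37 degC working range).
#' @param kind `"water"`, `"glycerol"` or `"urea"`.
#' @inheritParams make_dose_response_experiment
#' @param compound condition label (e.g. `"control"` or an inhibitor name).
#' @return an `experiment_bundle`.
#' @export
make_arrhenius_experiment <- function(ea_kcal = 8.5, p_ref = 1.8e-5,
                                      t_ref_c = 23,
                                      temperatures_c = c(10, 15, 20, 25, 30, 37),
                                      kind = c("glycerol", "water", "urea"),
                                      cell = hrbc_cell(),
                                      optics = NULL,
                                      n_reps = 5L, seed = 1L,
                                      pf_water = 4.2e-2,
                                      duration_s = NULL,
                                      compound = "control") {
  kind <- match.arg(kind)
  if (length(temperatures_c) < 3L)
    aqp_stop("an Arrhenius series needs at least 3 temperatures")
  bath <- if (kind == "water") bath_spec(400)
          else bath_spec(300, kind, 100)
  if (is.null(optics)) optics <- if (kind == "water") water_optics()
                                 else solute_optics()
  if (is.null(duration_s)) duration_s <- if (kind == "water") 3 else 120
  conditions <- list(); traces <- list()
  for (i in seq_along(temperatures_c)) {
    tc <- temperatures_c[i]
    p_i <- arrhenius_permeability(ea_kcal, p_ref, t_ref_c, tc)
    id <- sprintf("temp-%02d", i)
    cond <- base_condition(id, role = "treated", compound = compound,
                           concentration_um = 0, incubation_min = 0,
                           temperature_c = tc, solute = if (kind == "water")
                             "none" else kind,
                           bath = bath, n_reps = n_reps, seed = seed, ci = i)
    conditions[[i]] <- cond
    traces[[id]] <- condition_traces(
      cell, bath,
      pf = if (kind == "water") p_i else pf_water,
      psolute = if (kind == "water") 0 else p_i,
      duration_s = duration_s, optics = optics, n_reps = n_reps,
      seed = seed, ci = i,
      condition = cond[c("id", "compound", "concentration_um",
                         "incubation_min", "solute")],
      temperature_c = tc)
  }
  new_bundle(base_manifest(seed, cell, optics, conditions,
                           truth = list(kind = "arrhenius",
                                        permeability_kind = kind,
                                        ea_kcal = ea_kcal, p_ref = p_ref,
                                        t_ref_c = t_ref_c,
                                        pf_water = pf_water)),
             traces)
}

#' Strip the ground-truth block from a bundle (for blind analysis)
#' @param bundle an `experiment_bundle`.
#' @return the bundle without its `truth` block.
#' @export
strip_truth <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  bundle$manifest$truth <- NULL
  bundle
}
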