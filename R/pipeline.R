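# End-to-end pipeline: manifest/bundle -> per-condition fits ->
# permeabilities -> inhibition, dose-response, time-course and Arrhenius
# analyses -> machine-readable results plus a human-readable report.

# Analyze the replicates of one condition; returns list of
# permeability_estimate (one per replicate that fitted successfully).
analyze_condition <- function(traces, cell, bath, solute,
                              biexponential = FALSE) {
  kind <- if (is.null(solute) || solute %in% c("none", "water")) "water"
          else solute
  lapply(traces, function(tr) {
    tryCatch({
      if (kind == "water") {
        k <- if (biexponential) weighted_rate(fit_double_exponential(tr))
             else fit_single_exponential(tr)$k
        pf_from_rate(k, cell, bath_osm_inf(bath),
                     temperature_c = tr$temperature_c,
                     condition = tr$condition)
      } else {
        ph <- split_phases(tr)
        k <- fit_single_exponential(tr, window = ph$reswell)$k
        psolute_from_rate(k, cell, kind = kind,
                          temperature_c = tr$temperature_c,
                          condition = tr$condition)
      }
    }, aquaflow_error = function(e) {
      warning(sprintf("replicate dropped (%s)", conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
}

cond_field <- function(conds, field, default = NA) {
  vapply(conds, function(c) {
    v <- c[[field]]
    if (is.null(v)) default else v
  }, default)
}

#' Run the full stopped-flow analysis pipeline
#'
#' Takes an experiment bundle (in memory, or a bundle directory / manifest
#' path) and computes, per condition, the replicate rate fits and
#' permeability estimates (mean +/- SEM); percent inhibition of every treated
#' condition against the designated control; a Hill dose-response fit when a
#' concentration series (>= 4 distinct positive concentrations) is present; an
#' incubation time-course fit when >= 4 distinct incubation times are present;
#' and Arrhenius fits per compound group when >= 3 distinct temperatures are
#' present (with the control-vs-treated Ea percent change when both exist).
#' Deterministic given the manifest and its seeds.
#'
#' @param x an `experiment_bundle`, a bundle directory, or a manifest path.
#' @param out_dir optional output directory; when given, writes
#'   `results.json`, `permeability.csv`, `inhibition.csv` (if applicable) and
#'   a human-readable `report.txt`.
#' @param control id of the control condition; by default the condition with
#'   `role == "control"`.
#' @param biexponential fit water traces with the double-exponential model
#'   and use the amplitude-weighted rate (the PC12 convention); by default
#'   taken from the manifest's `analysis$biexponential`, else FALSE.
#' @return a results list (class `aquaflow_results`) with elements
#'   `permeability` (data.frame), `inhibition` (data.frame or NULL),
#'   `dose_response`, `time_course`, `arrhenius`, `log`.
#' @export
run_pipeline <- function(x, out_dir = NULL, control = NULL,
                         biexponential = NULL) {
  bundle <- if (inherits(x, "experiment_bundle")) x else read_bundle(x)
  manifest <- bundle$manifest
  cell <- as_cell_spec(manifest$cell)
  biexp <- biexponential %||% isTRUE(manifest$analysis$biexponential)
  conds <- manifest$conditions

  # permeability per condition
  rows <- list(); estimates <- list()
  for (cond in conds) {
    traces <- bundle$traces[[cond$id]]
    if (is.null(traces) || !length(traces))
      aqp_stop(sprintf("condition '%s' has no traces", cond$id),
               class = "aquaflow_format_error")
    bath <- as_bath_spec(cond$bath)
    reps <- Filter(Negate(is.null),
                   analyze_condition(traces, cell, bath, cond$solute, biexp))
    if (!length(reps))
      aqp_stop(sprintf("condition '%s': no replicate could be fitted",
                       cond$id), class = "aquaflow_fit_error")
    agg <- suppressWarnings(aggregate_replicates(reps))
    estimates[[cond$id]] <- agg
    rows[[cond$id]] <- data.frame(
      condition = cond$id, role = cond$role %||% "treated",
      compound = cond$compound %||% "none",
      concentration_um = cond$concentration_um %||% NA_real_,
      incubation_min = cond$incubation_min %||% NA_real_,
      temperature_c = cond$temperature_c %||% NA_real_,
      kind = agg$kind, permeability_cm_s = agg$value, sem = agg$sem,
      n = agg$n_replicates, stringsAsFactors = FALSE)
  }
  perm <- do.call(rbind, rows)
  rownames(perm) <- NULL

  # control and inhibition
  control_id <- control %||% {
    ids <- cond_field(conds, "id", NA_character_)
    roles <- cond_field(conds, "role", "treated")
    if (any(roles == "control")) ids[roles == "control"][1] else NULL
  }
  inhibition <- NULL
  if (!is.null(control_id)) {
    if (!control_id %in% names(estimates))
      aqp_stop(sprintf("control condition '%s' not found", control_id),
               class = "aquaflow_config_error")
    ctrl <- estimates[[control_id]]
    treated <- setdiff(names(estimates), control_id)
    treated <- treated[vapply(estimates[treated], `[[`, "", "kind") ==
                         ctrl$kind]
    if (length(treated)) {
      inh <- lapply(treated, function(id)
        percent_inhibition(estimates[[id]], ctrl))
      inhibition <- cbind(
        perm[match(treated, perm$condition),
             c("condition", "compound", "concentration_um",
               "incubation_min", "temperature_c", "kind")],
        inhibition_pct = vapply(inh, `[[`, 0, "inhibition_pct"),
        sem = vapply(inh, `[[`, 0, "sem"))
      rownames(inhibition) <- NULL
    }
  }

  # dose-response fit over the concentration series
  dose_fit <- NULL
  if (!is.null(inhibition)) {
    ds <- inhibition[!is.na(inhibition$concentration_um) &
                       inhibition$concentration_um > 0, ]
    if (length(unique(ds$concentration_um)) >= 4L)
      dose_fit <- tryCatch(
        fit_dose_response(ds$concentration_um, ds$inhibition_pct),
        aquaflow_error = function(e) {
          warning(sprintf("dose-response fit skipped (%s)",
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
  }

  # incubation time-course fit
  time_fit <- NULL
  if (!is.null(inhibition)) {
    tc <- inhibition[!is.na(inhibition$incubation_min), ]
    times <- c(0, tc$incubation_min)      # control anchors t = 0
    vals <- c(0, tc$inhibition_pct)
    if (length(unique(tc$incubation_min)) >= 3L &&
        length(unique(times)) >= 4L)
      time_fit <- tryCatch(
        fit_time_dependence(times, vals),
        aquaflow_error = function(e) NULL)
  }

  # Arrhenius fits per compound group
  arrhenius <- NULL
  temps_by_grp <- split(perm, perm$compound)
  grp_fits <- list()
  for (grp in names(temps_by_grp)) {
    g <- temps_by_grp[[grp]]
    if (length(unique(g$temperature_c[!is.na(g$temperature_c)])) >= 3L)
      grp_fits[[grp]] <- fit_arrhenius(g$temperature_c, g$permeability_cm_s)
  }
  if (length(grp_fits)) {
    arrhenius <- list(fits = grp_fits)
    ctrl_grp <- intersect(c("control", "none"), names(grp_fits))
    other <- setdiff(names(grp_fits), ctrl_grp)
    if (length(ctrl_grp) == 1L && length(other) == 1L)
      arrhenius$ea_percent_change <-
        ea_percent_change(grp_fits[[ctrl_grp]], grp_fits[[other]])
  }

  log <- list(
    package_version = as.character(packageVersion("aquaflow")),
    manifest_schema = manifest$schema %||% "unversioned",
    config_hash = manifest_hash(manifest),
    seed = manifest$seed,
    defaults = list(
      cell_v0_fl = cell$v0_fl, cell_area_um2 = cell$area_um2,
      cell_v0_over_a_cm = v0_over_a(cell),
      inactive_fraction = cell$inactive_fraction,
      iso_mosm = cell$iso_mosm,
      biexponential = biexp,
      fit_window = "dead time to 90% of total amplitude",
      split_smoothing = "max(5 samples, 1% of trace length)"))

  results <- structure(list(permeability = perm, inhibition = inhibition,
                            dose_response = dose_fit, time_course = time_fit,
                            arrhenius = arrhenius, log = log),
                       class = "aquaflow_results")
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

manifest_hash <- function(manifest) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(manifest, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  unname(tools::md5sum(tf))
}

#' @export
print.aquaflow_results <- function(x, ...) {
  cat("<aquaflow_results>\n")
  cat(sprintf("  %d conditions; control: %s\n", nrow(x$permeability),
              if (is.null(x$inhibition)) "none" else "present"))
  print(x$permeability, digits = 4)
  if (!is.null(x$dose_response)) print(x$dose_response)
  if (!is.null(x$time_course)) print(x$time_course)
  if (!is.null(x$arrhenius)) for (f in x$arrhenius$fits) print(f)
  invisible(x)
}

fit_to_list <- function(f) if (is.null(f)) NULL else unclass(f)

#' Write pipeline results to a directory
#'
#' Emits `results.json` (all fits and tables), `permeability.csv`,
#' `inhibition.csv` (when inhibition was computed) and a human-readable
#' `report.txt`. Output is deterministic: rerunning on the same bundle
#' produces byte-identical files.
#'
#' @param results an `aquaflow_results` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    log = results$log,
    permeability = results$permeability,
    inhibition = results$inhibition,
    dose_response = fit_to_list(results$dose_response),
    time_course = fit_to_list(results$time_course),
    arrhenius = if (is.null(results$arrhenius)) NULL else
      list(fits = lapply(results$arrhenius$fits, unclass),
           ea_percent_change = results$arrhenius$ea_percent_change))
  jsonlite::write_json(out, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null", na = "null")
  write.csv(results$permeability, file.path(dir, "permeability.csv"),
            row.names = FALSE)
  if (!is.null(results$inhibition))
    write.csv(results$inhibition, file.path(dir, "inhibition.csv"),
              row.names = FALSE)

  rep <- c(sprintf("aquaflow %s results", results$log$package_version),
           sprintf("manifest hash: %s; seed: %s", results$log$config_hash,
                   format(results$log$seed)),
           "", "Permeability (cm/s, mean +/- SEM):",
           sprintf("  %-12s %-10s %10.4g +/- %-10.3g (n=%d, %s)",
                   results$permeability$condition,
                   results$permeability$kind,
                   results$permeability$permeability_cm_s,
                   results$permeability$sem, results$permeability$n,
                   ifelse(is.na(results$permeability$temperature_c), "-",
                          sprintf("%g degC",
                                  results$permeability$temperature_c))))
  if (!is.null(results$inhibition))
    rep <- c(rep, "", "Inhibition vs control (%):",
             sprintf("  %-12s %8.2f +/- %-8.3g",
                     results$inhibition$condition,
                     results$inhibition$inhibition_pct,
                     results$inhibition$sem))
  if (!is.null(results$dose_response))
    rep <- c(rep, "", sprintf(
      "Dose-response: IC50 = %.4g +/- %.2g uM, Hill = %.3g, ymax = %.3g%%",
      results$dose_response$ic50_um, results$dose_response$ic50_se,
      results$dose_response$hill, results$dose_response$ymax))
  if (!is.null(results$time_course))
    rep <- c(rep, "", sprintf(
      "Time course: tau = %.4g min, plateau = %.4g%%",
      results$time_course$tau_min, results$time_course$plateau_pct))
  if (!is.null(results$arrhenius)) {
    rep <- c(rep, "", "Arrhenius:")
    for (grp in names(results$arrhenius$fits)) {
      f <- results$arrhenius$fits[[grp]]
      rep <- c(rep, sprintf("  %-12s Ea = %.4g +/- %.2g kcal/mol (R^2 = %.4f)",
                            grp, f$ea_kcal, f$se_ea, f$r_squared))
    }
    if (!is.null(results$arrhenius$ea_percent_change))
      rep <- c(rep, sprintf("  Ea change: %.3g%%",
                            results$arrhenius$ea_percent_change))
  }
  writeLines(rep, file.path(dir, "report.txt"))
  invisible(dir)
}
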