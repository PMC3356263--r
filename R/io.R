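# File formats: two-column delimited trace files with a JSON comment header,
# JSON experiment manifests, and experiment-bundle directories.

trace_header_prefix <- "# aquaflow-trace "

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write a trace to a two-column delimited text file
#'
#' Scattering traces are written as `time_s<TAB>intensity`, volume traces as
#' `time_s<TAB>volume_fl`, preceded by a single JSON comment header line
#' carrying all metadata (temperature, condition, seed, generating truth).
#' Values are written with 15 significant digits, so a write/read round trip
#' preserves them to at least 12 significant digits.
#'
#' @param trace a [scatter_trace()] or [volume_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) UseMethod("write_trace")

#' @export
write_trace.scatter_trace <- function(trace, path) {
  meta <- list(type = "scatter", temperature_c = trace$temperature_c,
               condition = trace$condition, seed = trace$seed,
               meta = trace$meta)
  header <- paste0(trace_header_prefix,
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null"))
  writeLines(c(header, "time_s\tintensity",
               paste(fmt_num(trace$times), fmt_num(trace$intensities),
                     sep = "\t")),
             path)
  invisible(path)
}

#' @export
write_trace.volume_trace <- function(trace, path) {
  meta <- list(type = "volume", v0_fl = trace$v0_fl,
               temperature_c = trace$temperature_c, truth = trace$truth)
  header <- paste0(trace_header_prefix,
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null"))
  writeLines(c(header, "time_s\tvolume_fl",
               paste(fmt_num(trace$times), fmt_num(trace$volumes_fl),
                     sep = "\t")),
             path)
  invisible(path)
}

#' Read a trace file
#'
#' Reads the two-column delimited format written by [write_trace()]. Files
#' without the JSON comment header are accepted as legacy scattering traces
#' with empty metadata (a warning is logged). Non-monotone time stamps or a
#' wrong column count raise a format error naming the offending line.
#'
#' @param path input file path.
#' @return a [scatter_trace()] or [volume_trace()] according to the header.
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    aqp_stop(sprintf("trace file not found: %s", path),
             class = "aquaflow_format_error")
  lines <- readLines(path, warn = FALSE)
  meta <- NULL
  ln0 <- 0L
  if (length(lines) && startsWith(lines[1], "#")) {
    json <- sub("^#\\s*(aquaflow-trace\\s*)?", "", lines[1])
    meta <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (is.null(meta))
      aqp_stop(sprintf("line 1 of %s: malformed JSON header", path),
               class = "aquaflow_format_error")
    lines <- lines[-1]; ln0 <- 1L
  } else {
    warning(sprintf("%s: no metadata header; reading as legacy trace", path),
            call. = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("[A-Za-z]", lines[1])) { # column header line
    lines <- lines[-1]; ln0 <- ln0 + 1L
  }
  if (length(lines) < 2L)
    aqp_stop(sprintf("%s: fewer than 2 data rows", path),
             class = "aquaflow_format_error")
  parts <- strsplit(trimws(lines), "[\t, ]+")
  ncols <- lengths(parts)
  bad <- which(ncols != 2L)
  if (length(bad))
    aqp_stop(sprintf("line %d of %s: expected 2 columns, found %d",
                     bad[1] + ln0, path, ncols[bad[1]]),
             class = "aquaflow_format_error")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
              byrow = TRUE)
  nonnum <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]))
  if (length(nonnum))
    aqp_stop(sprintf("line %d of %s: non-numeric value", nonnum[1] + ln0, path),
             class = "aquaflow_format_error")
  nonmono <- which(diff(m[, 1]) <= 0)
  if (length(nonmono))
    aqp_stop(sprintf("line %d of %s: time stamps not strictly increasing",
                     nonmono[1] + 1L + ln0, path),
             class = "aquaflow_format_error")
  type <- meta$type %||% "scatter"
  if (identical(type, "volume")) {
    volume_trace(m[, 1], m[, 2], v0_fl = meta$v0_fl %||% m[1, 2],
                 temperature_c = meta$temperature_c %||% NA_real_,
                 truth = meta$truth)
  } else {
    scatter_trace(m[, 1], m[, 2],
                  temperature_c = meta$temperature_c %||% NA_real_,
                  condition = as.list(meta$condition %||% list()),
                  seed = meta$seed %||% NA_integer_,
                  meta = as.list(meta$meta %||% list()))
  }
}

# --- manifests and bundle directories ---------------------------------------

#' Write an experiment manifest to JSON
#' @param manifest manifest list (as in `bundle$manifest`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read an experiment manifest (JSON, or YAML if the yaml package is present)
#' @param path manifest file path.
#' @return manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    aqp_stop(sprintf("manifest not found: %s", path),
             class = "aquaflow_format_error")
  m <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      aqp_stop("YAML manifests require the 'yaml' package",
               class = "aquaflow_format_error")
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) aqp_stop(
               sprintf("%s: malformed JSON manifest (%s)", path,
                       conditionMessage(e)),
               class = "aquaflow_format_error"))
  }
  if (is.null(m$conditions) || !length(m$conditions))
    aqp_stop(sprintf("%s: manifest has no conditions", path),
             class = "aquaflow_format_error")
  m
}

as_cell_spec <- function(x) {
  if (inherits(x, "cell_spec")) return(x)
  cell_spec(x$v0_fl, x$area_um2, x$inactive_fraction %||% 0,
            x$iso_mosm %||% 300, x$label)
}

as_bath_spec <- function(x) {
  if (inherits(x, "bath_spec")) return(x)
  bath_spec(x$impermeant_mosm, x$permeant, x$permeant_mm %||% 0)
}

as_optics_spec <- function(x) {
  if (inherits(x, "optics_spec")) return(x)
  optics_spec(x$alpha %||% 0.1, x$beta %||% 1, x$noise_sigma %||% 0.002,
              x$sampling_rate %||% 100, x$dead_time %||% 0.002)
}

#' Write an experiment bundle to a directory
#'
#' Creates `<dir>/manifest.json` plus one trace file per replicate,
#' `<condition id>_rep<k>.txt`; the manifest's conditions record the file
#' names. Writing is deterministic: identical bundles produce byte-identical
#' directories.
#'
#' @param bundle an `experiment_bundle`.
#' @param dir output directory (created if needed).
#' @param strip_truth drop the ground-truth block from the written manifest
#'   (for blind analysis).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, strip_truth = FALSE) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- bundle$manifest
  for (i in seq_along(manifest$conditions)) {
    cond <- manifest$conditions[[i]]
    reps <- bundle$traces[[cond$id]]
    files <- sprintf("%s_rep%d.txt", cond$id, seq_along(reps))
    for (r in seq_along(reps))
      write_trace(reps[[r]], file.path(dir, files[r]))
    manifest$conditions[[i]]$files <- files
  }
  if (strip_truth) manifest$truth <- NULL
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read an experiment bundle from a directory or manifest path
#'
#' @param path bundle directory containing `manifest.json`, or the manifest
#'   file itself (trace files are resolved relative to it).
#' @return an `experiment_bundle`.
#' @export
read_bundle <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json")
                   else path
  base <- dirname(manifest_path)
  manifest <- read_manifest(manifest_path)
  traces <- list()
  for (cond in manifest$conditions) {
    files <- unlist(cond$files)
    if (is.null(files) || !length(files))
      aqp_stop(sprintf("condition '%s' lists no trace files", cond$id),
               class = "aquaflow_format_error")
    missing <- files[!file.exists(file.path(base, files))]
    if (length(missing))
      aqp_stop(sprintf("condition '%s': missing trace file %s",
                       cond$id, missing[1]),
               class = "aquaflow_format_error")
    traces[[cond$id]] <- lapply(file.path(base, files), read_trace)
  }
  new_bundle(manifest, traces)
}
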