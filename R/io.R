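# Plain-text IO: traces as two-column delimited text with a JSON sidecar for
# stimulus windows, dose-response tables and fields as CSV, detectability
# sweeps as JSON, run configuration as YAML with explicit unit suffixes.

#' Read a nerve trace from two-column text plus a JSON sidecar
#'
#' The trace file holds two delimited columns (time s, signal V); the sidecar
#' is JSON with `stimuli` (array of objects with `label`, `onset`, `offset`
#' in s) and optional `species`.
#'
#' @param trace_file path to the two-column trace file.
#' @param sidecar_file path to the JSON stimulus sidecar.
#' @param sep field separator (default any whitespace).
#' @return a [nerve_trace()].
#' @export
read_nerve_trace <- function(trace_file, sidecar_file, sep = "") {
  if (!file.exists(trace_file))
    stop("read_nerve_trace: trace file not found: ", trace_file)
  if (!file.exists(sidecar_file))
    stop("read_nerve_trace: stimulus sidecar not found: ", sidecar_file)
  d <- read.table(trace_file, header = FALSE, sep = sep,
                  col.names = c("time_s", "volts"))
  dt <- diff(d$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt))
    stop("read_nerve_trace: time column must be uniformly sampled")
  side <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
  stim <- as.data.frame(side$stimuli)
  nerve_trace(d$volts, fs = 1 / mean(dt), stimuli = stim,
              species = if (!is.null(side$species)) side$species else "")
}

#' Write a nerve trace as two-column text plus a JSON sidecar
#' @param trace a [nerve_trace()].
#' @param trace_file,sidecar_file output paths.
#' @return the trace file path, invisibly.
#' @export
write_nerve_trace <- function(trace, trace_file, sidecar_file) {
  stopifnot(inherits(trace, "nerve_trace"))
  tt <- (seq_along(trace$samples) - 1L) / trace$fs
  write.table(data.frame(time_s = tt, volts = trace$samples), trace_file,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  jsonlite::write_json(list(species = trace$species,
                            stimuli = trace$stimuli),
                       sidecar_file, auto_unbox = TRUE, digits = NA)
  invisible(trace_file)
}

#' Write / read a concentration field as long-format CSV
#'
#' Columns: `scenario, t, x, y, z, c` (SI units).
#'
#' @param field a `concentration_field`.
#' @param path CSV path.
#' @return the path (write) or a data.frame (read).
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) read.csv(path)

#' Write a detectability sweep as JSON records
#' @param map a `detectability_map` (or single `detectability_result`).
#' @param path JSON path.
#' @export
write_detectability_json <- function(map, path) {
  if (inherits(map, "detectability_result")) map <- list(map)
  recs <- lapply(unclass(map), function(r) {
    r <- unclass(r)
    r$onset_time <- if (is.na(r$onset_time)) NULL else r$onset_time
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write / read a dose-response table as CSV
#'
#' Columns: `compound, species, dose_molar, replicate, area`; doses are in
#' molar units (M) in the file and mol/m3 internally (1 M = 1000 mol/m3);
#' blanks are rows with `dose_molar = 0`.
#'
#' @param series a [dose_response_series()].
#' @param path CSV path.
#' @export
write_dose_response_csv <- function(series, path) {
  stopifnot(inherits(series, "dose_response_series"))
  rows <- data.frame(compound = series$compound, species = series$species,
                     dose_molar = 0,
                     replicate = seq_along(series$blanks),
                     area = series$blanks)
  for (i in seq_along(series$doses)) {
    rows <- rbind(rows, data.frame(compound = series$compound,
                                   species = series$species,
                                   dose_molar = series$doses[i] / 1000,
                                   replicate = seq_along(series$responses[[i]]),
                                   area = series$responses[[i]]))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("compound", "species", "dose_molar", "replicate",
                  "area") %in% names(d)))
  blanks <- d$area[d$dose_molar == 0]
  d <- d[d$dose_molar > 0, , drop = FALSE]
  doses <- sort(unique(d$dose_molar)) * 1000
  responses <- lapply(doses, function(x)
    d$area[abs(d$dose_molar * 1000 - x) < 1e-12 * x])
  dose_response_series(d$compound[1L], d$species[1L], doses, responses,
                       blanks)
}

# Recognized unit suffixes and their SI conversion factors.
.unit_factors <- c(m = 1, mm = 1e-3, um = 1e-6,
                   s = 1, K = 1, Pa_s = 1,
                   m2_s = 1, mL = 1e-6, m3 = 1,
                   M = 1e3, mM = 1, uM = 1e-3)

# "depth_mm" -> list(name = "depth", value_si). Errors name the field.
# Two-part suffixes (Pa_s, m2_s) are matched before one-part ones so the
# trailing "s" of a compound unit is not mistaken for seconds.
.parse_unit_key <- function(key, value) {
  parts <- strsplit(key, "_")[[1L]]
  for (ns in 2:1) {
    if (length(parts) <= ns) next
    suffix <- paste(utils::tail(parts, ns), collapse = "_")
    if (suffix %in% names(.unit_factors))
      return(list(name = paste(parts[seq_len(length(parts) - ns)],
                               collapse = "_"),
                  value = as.numeric(value) * .unit_factors[[suffix]]))
  }
  stop("config field `", key, "` has no recognized unit suffix (",
       paste(names(.unit_factors), collapse = ", "), ")")
}

#' Read a run configuration file
#'
#' YAML configuration whose `physical` block uses explicit unit suffixes
#' (e.g. `c0_mM: 100`, `depth_mm: 5`, `c_star_uM: 10`, `D_m2_s: 1e-9`,
#' `V_mL: 1`, `a_major_mm: 16`); unsuffixed or unknown keys are a validation
#' error naming the field. Optional top-level keys: `scenario`, `seed`, and
#' a `sweep` block (`c0_mM`, `depth_mm` lists) for detectability sweeps.
#'
#' @param path YAML file path.
#' @return list with `params` ([physical_params()]), `scenario`, `seed`,
#'   `sweep` (SI lists) and the `raw` parsed YAML.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$physical)) stop("config is missing the `physical` block")
  si <- list()
  for (key in names(raw$physical)) {
    p <- .parse_unit_key(key, raw$physical[[key]])
    si[[p$name]] <- p$value
  }
  known <- c(D = "D", temperature = "T_K", eta = "eta", r_mol = "r_mol",
             c0 = "c0", V = "V", a_major = "a_major", a_minor = "a_minor",
             depth = "depth_l", c_star = "c_star", t_max = "t_max",
             layer_depth = "layer_depth")
  bad <- setdiff(names(si), names(known))
  if (length(bad))
    stop("config field(s) not recognized: ", paste(bad, collapse = ", "))
  args <- setNames(si, known[names(si)])
  params <- do.call(physical_params, args)
  scenario <- if (is.null(raw$scenario)) "free_interface" else raw$scenario
  if (!scenario %in% c("free_interface", "dirichlet"))
    stop("config field `scenario` must be free_interface or dirichlet")
  sweep <- NULL
  if (!is.null(raw$sweep)) {
    sweep <- list()
    for (key in names(raw$sweep)) {
      p <- .parse_unit_key(key, unlist(raw$sweep[[key]]))
      sweep[[p$name]] <- p$value
    }
  }
  list(params = params, scenario = scenario,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       sweep = sweep, raw = raw)
}
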