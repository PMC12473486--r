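# Unit ledger. Every persisted number carries its unit in the column header
# (time_min, dissolved_mg, ...); this table backs explicit conversions where
# in-vitro constants (per minute) meet in-vivo physiology (per hour).
unit_table <- function() {
  data.frame(
    unit = c("s", "min", "h",
             "min^-1", "h^-1", "s^-1",
             "cm/s", "cm/min", "cm/h",
             "mL", "L",
             "mg", "ug",
             "mg/mL", "ug/mL",
             "mL/mg", "mg/L"),
    dimension = c("time", "time", "time",
                  "rate", "rate", "rate",
                  "velocity", "velocity", "velocity",
                  "volume", "volume",
                  "mass", "mass",
                  "concentration", "concentration",
                  "inv_concentration", "concentration"),
    to_base = c(1, 60, 3600,             # time base: s
                1 / 60, 1 / 3600, 1,     # rate base: s^-1
                1, 1 / 60, 1 / 3600,     # velocity base: cm/s
                1, 1000,                 # volume base: mL
                1, 1e-3,                 # mass base: mg
                1, 1e-3,                 # concentration base: mg/mL
                1, 1e-3),                # mg/L = ug/mL
    stringsAsFactors = FALSE)
}

#' Exact unit conversion
#'
#' Converts between the units used across the apparatus model (minutes,
#' mg, mL, cm/s) and the physiology model (hours, cm/h): `min^-1` to `h^-1`
#' by 60, `cm/s` to `cm/h` by 3600, and so on. Incompatible dimensions are
#' an error.
#'
#' @param value Numeric value(s).
#' @param from,to Unit strings; see the supported set in the error message
#'   of an unknown unit.
#' @return Converted value(s).
#' @examples
#' convert_units(2.8, "h^-1", "min^-1")
#' convert_units(1.34e-4, "cm/s", "cm/h")
#' @export
convert_units <- function(value, from, to) {
  tab <- unit_table()
  lookup <- function(u) {
    i <- match(u, tab$unit)
    if (is.na(i))
      stop(sprintf("unknown unit '%s'; supported: %s", u,
                   paste(tab$unit, collapse = ", ")), call. = FALSE)
    tab[i, ]
  }
  f <- lookup(from); t <- lookup(to)
  if (f$dimension != t$dimension)
    stop(sprintf("incompatible dimensions: %s (%s) -> %s (%s)",
                 from, f$dimension, to, t$dimension), call. = FALSE)
  value * f$to_base / t$to_base
}

required_config_keys <- function() {
  list(drug = c("name", "pKa", "Cs_gastric", "Cs_intestinal", "Papp"),
       protocol = c("V0", "q", "t_infusion", "dose"))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with `drug`, `protocol` and optional
#' `physiology`, `disposition` and `fitting` blocks, validates required keys
#' (the apparatus operating values `V0` and `q` must be present -- they have
#' no published defaults), rejects unknown keys, and fills physiology
#' defaults from the published constants (logging each applied default).
#'
#' @param path YAML file path.
#' @param quiet Suppress default-logging messages.
#' @return A validated list of class `run_config` with constructed
#'   [drug_properties()], [be_protocol()], [physiology_config()] and, when
#'   a disposition block is present, [disposition_params()].
#' @export
load_config <- function(path, quiet = FALSE) {
  raw <- yaml::read_yaml(path)
  known_blocks <- c("drug", "protocol", "physiology", "disposition", "fitting")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("unknown config blocks: ", paste(unknown, collapse = ", "), call. = FALSE)

  req <- required_config_keys()
  for (block in names(req)) {
    if (is.null(raw[[block]]))
      stop(sprintf("config block '%s' is required", block), call. = FALSE)
    missing <- setdiff(req[[block]], names(raw[[block]]))
    if (length(missing))
      stop(sprintf("config block '%s' is missing required keys: %s",
                   block, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(raw$protocol$dose) && raw$protocol$dose <= 0)
    stop("dose must be positive", call. = FALSE)

  drug <- do.call(drug_properties, raw$drug)
  protocol <- do.call(be_protocol, raw$protocol)

  phys_args <- raw$physiology
  if (is.null(phys_args)) phys_args <- list()
  defaults <- formals(physiology_config)
  for (key in setdiff(names(defaults), names(phys_args))) {
    if (!quiet)
      message(sprintf("physiology: using published default %s = %s",
                      key, deparse(defaults[[key]])))
  }
  physio <- do.call(physiology_config, phys_args)

  dispo <- if (!is.null(raw$disposition))
    do.call(disposition_params, raw$disposition)

  structure(list(drug = drug, protocol = protocol, physio = physio,
                 dispo = dispo, fitting = raw$fitting, raw = raw),
            class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' Dumps the raw configuration, so that load - dump - load round-trips to
#' an identical object.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Read an observed apparatus dataset from CSV
#'
#' Expects columns `time_min`, `dissolved_mg` and optionally `permeated_mg`.
#'
#' @param path CSV file path.
#' @param dose Dose, mg.
#' @param condition_label Label passed through to the dataset.
#' @return An [observed_dataset()].
#' @export
read_observed_csv <- function(path, dose, condition_label = "") {
  d <- read.csv(path)
  if (!all(c("time_min", "dissolved_mg") %in% names(d)))
    stop("CSV must contain columns time_min and dissolved_mg", call. = FALSE)
  observed_dataset(d$time_min, d$dissolved_mg,
                   permeated_obs = d$permeated_mg, dose = dose,
                   condition_label = condition_label)
}
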