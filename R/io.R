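# Readers/writers for parameter configs (YAML/JSON), trajectory CSVs and
# JSON reports. All numeric output is written at full (round-trip exact)
# precision so write -> read -> write is bit-identical.

.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.1f", v))
    formatC(v, digits = 17, format = "g")
  }, character(1))
}

#' Read a circuit parameter configuration
#'
#' Reads a flat YAML (or JSON) mapping with exactly the parameter keys of
#' [circuit_parameters()] plus `self_activation_form`, `variant` and the
#' optional `c_pf`. Unknown keys are rejected by name; all invariants are
#' enforced.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `circuit_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  if (!is.null(raw$c_pf) && is.na(raw$c_pf)) raw$c_pf <- NULL
  validate_circuit_parameters(raw)
}

#' Write a circuit parameter configuration
#'
#' Writes a flat YAML mapping at full numeric precision; the file
#' round-trips through [read_parameters()] bit-identically.
#'
#' @param p A `circuit_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "circuit_parameters"))
  lines <- c(
    vapply(.param_keys, function(k) paste0(k, ": ", .fmt_num(p[[k]])),
           character(1)),
    paste0("self_activation_form: ", p$self_activation_form),
    paste0("variant: ", p$variant)
  )
  if (!is.null(p$c_pf)) lines <- c(lines, paste0("c_pf: ", .fmt_num(p$c_pf)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a stepped/control trajectory pair as CSV
#'
#' Columns: `time_h, A, B, output, series, input_uM` (comma-separated, dot
#' decimal, header row, UTF-8). Only sampling-grid points are written (the
#' measured-like view of the simulation).
#'
#' @param sim Result of [simulate_step()], or a list with `stepped` and/or
#'   `control` trajectories.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  series <- intersect(c("stepped", "control"), names(sim))
  if (length(series) == 0L) stop("no trajectories to write", call. = FALSE)
  tabs <- lapply(series, function(s) {
    traj <- sim[[s]]
    d <- trajectory_outputs(traj)
    data.frame(time_h = .fmt_num(d$time_h), A = .fmt_num(d$A),
               B = .fmt_num(d$B), output = .fmt_num(d$output),
               series = traj$series, input_uM = .fmt_num(traj$input_uM),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Inverse of [write_trajectory_csv()]: returns the trajectories keyed by
#' their `series` labels.
#'
#' @param path CSV path.
#' @return A named list of `circuit_trajectory` objects.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("time_h", "A", "B", "output", "series", "input_uM")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L) {
    stop("trajectory CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(d, d$series), function(s) {
    dat <- data.frame(time_h = s$time_h, A = s$A, B = s$B,
                      output = s$output, sampled = TRUE)
    .make_trajectory(NULL, dat, s$series[1], s$input_uM[1])
  })
  out
}

.config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", pretty = FALSE)
  unname(tools::md5sum(f))
}

#' Write a structured JSON report
#'
#' Serializes any report list (e.g. a `scan_report` or `adaptation_result`)
#' as JSON with a `schema_version` field and a provenance block (seed,
#' config hash, package version). Floats are written at full precision and
#' no volatile fields (timestamps) are included, so write -> read -> write
#' is byte-identical.
#'
#' @param report A serializable list-like object.
#' @param path Output path.
#' @param seed Seed to stamp into the provenance block (defaults to
#'   `report$seed` when present).
#' @param config Optional configuration object hashed into the provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  payload <- unclass(report)
  if (is.null(seed)) seed <- payload$seed
  doc <- list(schema_version = "1.0",
              provenance = list(
                seed = seed,
                config_hash = .config_hash(if (is.null(config)) payload
                                           else unclass(config)),
                tool = "rpacirc",
                tool_version = as.character(utils::packageVersion("rpacirc"))),
              payload = payload)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              dataframe = "columns", null = "null",
                              pretty = TRUE),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a JSON report
#'
#' @param path JSON path written by [write_report()].
#' @return The parsed document (list with `schema_version`, `provenance`,
#'   `payload`).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
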