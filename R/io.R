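#' Write analysis results to JSON
#'
#' Serialises a [analyze_trial()] result (or any list with `windows` and
#' `steps` tibbles) into a stable JSON document: a `meta` block with the
#' units of every exported variable, a `windows` array of per-window
#' summaries, and a `steps` array of per-step records. Absolute values of
#' the negative braking quantities (`abs_f_h_b`, `abs_lr_b`, `abs_i_b`)
#' are added to mirror the usual reporting convention.
#'
#' @param results A `run_analysis` or list with `windows`/`steps` tibbles
#'   (either may have zero rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  steps <- as_tibble(results$steps %||% tibble())
  windows <- as_tibble(results$windows %||% tibble())
  if (nrow(steps) > 0 && all(c("f_h_b", "lr_b", "i_b") %in% names(steps))) {
    steps <- mutate(steps, abs_f_h_b = abs(.data$f_h_b),
                    abs_lr_b = abs(.data$lr_b), abs_i_b = abs(.data$i_b))
  }
  doc <- list(
    format = "runmech-results",
    version = 1L,
    meta = list(units = list(
      time = "s", force = "N", loading_rate = "N/s", impulse = "N s",
      stiffness = "N/m", work = "J/kg/m", sf = "Hz", df = "dimensionless",
      dz = "m"
    )),
    windows = windows,
    steps = steps
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a results document
#'
#' @param path Path to a JSON file written by [write_results()].
#' @return A list with `format`, `version`, `meta`, `windows` and `steps`
#'   (tibbles).
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$windows <- as_tibble(doc$windows)
  doc$steps <- as_tibble(doc$steps)
  doc
}

#' Validate a results document against the packaged schema
#'
#' Structural validation of a document produced by [write_results()]:
#' required top-level keys, declared units, and per-record field types.
#' The schema is also shipped as a human-readable JSON document under
#' `inst/extdata/results-schema.json`.
#'
#' @param doc A list as returned by [read_results()].
#' @return `TRUE` invisibly; aborts with the first violation otherwise.
#' @export
validate_results <- function(doc) {
  need_top <- c("format", "version", "meta", "windows", "steps")
  miss <- setdiff(need_top, names(doc))
  if (length(miss) > 0) abort(paste0("missing top-level key(s): ",
                                     paste(miss, collapse = ", ")),
                              class = "runmech_error_schema")
  if (!identical(doc$format, "runmech-results")) {
    abort("not a runmech-results document", class = "runmech_error_schema")
  }
  if (is.null(doc$meta$units) || is.null(doc$meta$units$work)) {
    abort("meta.units is incomplete", class = "runmech_error_schema")
  }
  steps <- as_tibble(doc$steps)
  if (nrow(steps) > 0) {
    need <- c("step", "t_c", "t_f", "sf", "df", "f_v_max", "has_impact",
              "i_v")
    miss <- setdiff(need, names(steps))
    if (length(miss) > 0) abort(paste0("steps records lack field(s): ",
                                       paste(miss, collapse = ", ")),
                                class = "runmech_error_schema")
    if (!is.logical(steps$has_impact)) {
      abort("steps.has_impact must be boolean", class = "runmech_error_schema")
    }
  }
  windows <- as_tibble(doc$windows)
  if (nrow(windows) > 0) {
    need <- c("window", "n_steps", "w_pot", "w_kin", "w_ext", "w_int",
              "w_tot")
    miss <- setdiff(need, names(windows))
    if (length(miss) > 0) abort(paste0("windows records lack field(s): ",
                                       paste(miss, collapse = ", ")),
                                class = "runmech_error_schema")
  }
  invisible(TRUE)
}

#' Read pipeline settings from a YAML configuration file
#'
#' Optional carrier for the tunable constants of the pipeline (detection
#' threshold, filter cutoff and order, strides per window, gravity).
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `threshold_n`, `cutoff_hz`, `order`,
#'   `n_strides`, `gravity`, defaults filled in.
#' @export
read_config <- function(path) {
  defaults <- list(threshold_n = 20, cutoff_hz = 20, order = 5,
                   n_strides = 10, gravity = 9.81)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) abort(paste0("unknown config key(s): ",
                                        paste(unknown, collapse = ", ")),
                                 class = "runmech_error_config")
  utils::modifyList(defaults, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
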