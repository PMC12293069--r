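# Configuration and result serialization: flat JSON/YAML configs keyed by
# model symbols, unit-annotated trajectory CSVs, tidy metrics tables.

config_keys <- function() {
  c(parameter_names(), paste0(state_names(), "0"))
}

#' Write a flat model configuration
#'
#' Serializes a parameter set and initial conditions as one flat key-value
#' map: parameters under their symbols (`k1`, ..., `g1`, `d0`) and initial
#' conditions with a trailing zero (`S_B0`, ..., `I_C0`). The format is
#' chosen from the file extension (`.json`, `.yaml`/`.yml`) unless given.
#'
#' @param params Named parameter vector.
#' @param ic Named initial-condition vector.
#' @param path Output file path.
#' @param format `"json"`, `"yaml"`, or `NULL` to infer from `path`.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, ic, path, format = NULL) {
  validate_parameters(params)
  ic <- validate_state(ic, "initial condition")
  format <- infer_format(path, format)
  flat <- c(as.list(params[parameter_names()]),
            stats::setNames(as.list(as.numeric(ic)),
                            paste0(state_names(), "0")))
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

#' Read a flat model configuration
#'
#' Reads a JSON or YAML configuration written in the flat key-value dialect
#' of [write_config()] and resolves it against baseline parameters and
#' initial conditions: keys present in the file override the baselines.
#' Unknown keys are rejected with a message naming the nearest valid key.
#'
#' @param path Config file path.
#' @param base_params Parameter set the config overrides.
#' @param base_ic Initial conditions the config overrides.
#' @return List with elements `params` and `ic`.
#' @export
read_config <- function(path, base_params = baseline_parameters(),
                        base_ic = baseline_initial_conditions()) {
  format <- infer_format(path, NULL)
  raw <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(raw) == 0L) return(list(params = base_params, ic = base_ic))
  nms <- names(raw)
  valid <- config_keys()
  unknown <- setdiff(nms, valid)
  if (length(unknown) > 0L) {
    hints <- vapply(unknown, function(u) {
      valid[which.min(utils::adist(u, valid, ignore.case = TRUE))]
    }, character(1))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, hints),
               collapse = ", "), call. = FALSE)
  }
  attr(base_ic, "param_overrides") <- NULL
  resolved <- apply_overrides(base_params, base_ic, raw)
  validate_parameters(resolved$params)
  validate_state(resolved$ic, "initial condition")
  resolved
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "yaml")))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") "json"
  else if (ext %in% c("yaml", "yml")) "yaml"
  else stop("cannot infer config format from extension: ", path,
            call. = FALSE)
}

#' Write a trajectory as CSV
#'
#' Columns carry unit-annotated headers: `time[day]`, `S_B[CFU]`,
#' `S_T[CFU]`, `T_U[cells]`, `T_I[cells]`, `E_B[cells]`, `E_T[cells]`,
#' `E_N[cells]`, `I_C[ng/mL]`.
#'
#' @param traj A `"trajectory"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj)
  units <- state_units()
  names(df) <- c("time[day]",
                 sprintf("%s[%s]", state_names(), units[state_names()]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write scenario metrics
#'
#' Writes the tidy per-arm metric table of a scenario result as CSV
#' (columns `arm`, `metric`, `value`, `unit`) and/or nested JSON.
#'
#' @param result A `"scenario_result"`.
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, the written paths.
#' @export
write_metrics <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (!is.null(csv_path)) {
    utils::write.csv(result$table, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    nested <- lapply(result$arms, function(a) {
      m <- a$metrics
      m[!vapply(m, is.null, logical(1))]
    })
    jsonlite::write_json(nested, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(csv_path, json_path))
}

#' Write PRCC results
#'
#' @param result A `"prcc_result"`.
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, the written paths.
#' @export
write_prcc <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "prcc_result"))
  if (!is.null(csv_path)) {
    utils::write.csv(result$table, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(n_samples = result$n_samples,
                    n_controlled = result$n_controlled,
                    alpha = result$alpha,
                    output = result$output,
                    failures = result$failures,
                    table = result$table)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(csv_path, json_path))
}
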