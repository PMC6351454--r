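## Serialization: parameter sets (JSON/YAML, with exact fraction strings),
## trajectories and equilibrium tables (tidy CSV).

.parse_numeric_field <- function(x, nm) {
  if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^\\s*-?[0-9.eE+-]+\\s*/\\s*-?[0-9.eE+-]+\\s*$", x)) {
      parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
      return(parts[1] / parts[2])
    }
    v <- suppressWarnings(as.numeric(x))
    if (!is.na(v)) return(v)
  }
  stop("field '", nm, "' is not a number or \"p/q\" fraction string")
}

#' Read a model parameter set from JSON or YAML
#'
#' Field names follow the model's rate-constant notation (`eta_me`, `K_E0`,
#' ...), plus `variant`.  Numeric fields may be written as exact fraction
#' strings such as `"1/72"`, which are parsed at full precision.  Unknown
#' keys are rejected.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return an `emtmac_params` object.
#' @export
read_model_parameters <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path, eval.expr = FALSE)
  } else {
    stop("unrecognized parameter file extension: ", path)
  }
  ## YAML 1.1 parses a bare key `n` as the boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  variant <- raw$variant
  if (is.null(variant)) stop("parameter file must name a 'variant'")
  raw$variant <- NULL
  unknown <- setdiff(names(raw), model_parameter_names())
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  }
  vals <- lapply(seq_along(raw), function(i) {
    .parse_numeric_field(raw[[i]], names(raw)[i])
  })
  names(vals) <- names(raw)
  do.call(model_parameters, c(list(variant = variant), vals))
}

#' Write a model parameter set to JSON or YAML
#'
#' @param params an `emtmac_params` object.
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_model_parameters <- function(params, path) {
  validate_parameters(params)
  out <- c(list(variant = params$variant), params[model_parameter_names()])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path, precision = 15L)
  }
  invisible(path)
}

#' Write a trajectory as tidy CSV with a JSON metadata sidecar
#'
#' The CSV has columns `t, E, M, M1, M2, M0[, C]`; the sidecar
#' (`<path>.meta.json`) records the parameter set, tolerances and
#' convergence information.
#'
#' @param trajectory an `emtmac_trajectory` from [integrate_model()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "emtmac_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  params <- attr(trajectory, "params")
  meta <- list(variant = params$variant,
               params = params[model_parameter_names()],
               converged = attr(trajectory, "converged"),
               final_residual = attr(trajectory, "final_residual"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flatten steady states into a tidy data frame / CSV
#'
#' One row per equilibrium: state columns, residual, leading eigenvalue real
#' part, stability, category, provenance and a short parameter hash.
#'
#' @param steadies list of [steady_state()] objects.
#' @param path optional CSV output path.
#' @return the data frame (invisibly if `path` is given).
#' @export
equilibria_table <- function(steadies, path = NULL) {
  rows <- lapply(steadies, function(e) {
    data.frame(as.list(e$state),
               residual = e$residual,
               max_real_part = e$spectrum$max_real_part,
               n_zero = e$spectrum$n_zero,
               stability = e$stability,
               category = e$category,
               provenance = e$provenance,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
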