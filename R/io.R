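# Configuration parsing, result writers and the canonical fixtures dump.
# Config files are JSON with units encoded in the key names; unknown keys
# are rejected so unit mistakes fail loudly instead of silently.

#' Load a run configuration
#'
#' Reads a JSON configuration selecting a model variant, parameter
#' overrides (keys as in [gnp_parameters()], units in the names), a pump
#' specification and a stimulus schedule, and returns a fully validated
#' [gnp_model()]. An empty file (or `{}`) yields the full default model.
#'
#' Recognized top-level keys: `variant`, `parameters` (named overrides),
#' `pump` (`mode`, `I_const_uA_per_cm2`, `M_NaK_mM_per_s`), `stimulus`
#' (array of `[t_on_ms, t_off_ms, po]` triplets), `solver`
#' (`dt_sample_ms`, `rtol`, `tmax_ms`).
#'
#' @param path file path.
#' @return list with `model` (a [gnp_model()]) and `solver` options.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
         else list()
  known <- c("variant", "parameters", "pump", "stimulus", "solver")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  variant <- cfg$variant %||% "gnp"
  pump <- if (!is.null(cfg$pump)) {
    mode <- cfg$pump$mode %||% "constant"
    pump_spec(mode,
              I_const = cfg$pump$I_const_uA_per_cm2 %||% -1.16,
              M_NaK = cfg$pump$M_NaK_mM_per_s %||% 0.3)
  } else pump_spec()
  stim <- if (!is.null(cfg$stimulus) && length(cfg$stimulus)) {
    s <- matrix(unlist(cfg$stimulus), ncol = 3, byrow = !is.matrix(cfg$stimulus))
    if (is.matrix(cfg$stimulus)) s <- cfg$stimulus
    stimulus_protocol(t_on = s[, 1], t_off = s[, 2], po = s[, 3])
  } else stimulus_protocol()
  over <- cfg$parameters %||% list()
  if ("T_K" %in% names(over)) stopifnot(over$T_K > 0)
  model <- do.call(gnp_model,
                   c(list(variant = variant, pump = pump, stimulus = stim),
                     as.list(over)))
  solver <- list(dt_sample_ms = cfg$solver$dt_sample_ms %||% 0.1,
                 rtol = cfg$solver$rtol %||% 1e-8,
                 tmax_ms = cfg$solver$tmax_ms %||% 1000)
  list(model = model, solver = solver)
}

#' Write simulation / analysis results
#'
#' Writes a CSV with a header row plus a JSON metadata sidecar
#' (`<path>.meta.json`) recording the variant and the fully resolved
#' parameter set, so any table can be traced back to the exact model that
#' produced it. Accepts a `gnp_sim`, a `bifurcation_diagram` or any data
#' frame (e.g. a [single_channel_iv()] table).
#'
#' @param x object to write.
#' @param path output CSV path (parent directory must exist).
#' @param extra optional named list merged into the metadata.
#' @return invisibly, the paths written.
#' @export
write_results <- function(x, path, extra = list()) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  meta <- list(package = "gnpneuro",
               version = as.character(utils::packageVersion("gnpneuro")),
               written = "deterministic")
  if (inherits(x, "gnp_sim")) {
    d <- as.data.frame(x)
    meta$variant <- x$model$variant
    meta$parameters <- x$model$par
    meta$pump <- unclass(x$model$pump)
    meta$stimulus <- unclass(x$model$stimulus)
  } else if (inherits(x, "bifurcation_diagram")) {
    d <- x$points
    meta$variant <- x$variant
    meta$INaK_range <- x$range
  } else {
    d <- as.data.frame(x)
  }
  meta <- c(meta, extra)
  utils::write.csv(d, path, row.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(path, meta_path))
}

#' Dump the canonical parameter and preset registry
#'
#' Machine-readable dump of [gnp_parameters()] (every printed constant the
#' models use, including the conservation constants, the calcium permeation
#' parameters of the GluR2-lacking AMPA channel and the fq coefficient
#' quadruples) as JSON.
#'
#' @param path output path; default returns the list without writing.
#' @return the parameter list, invisibly when written.
#' @export
write_fixtures <- function(path = NULL) {
  p <- gnp_parameters()
  if (is.null(path)) return(p)
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}
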