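# The JSON run configuration: a single file drives the whole pipeline so
# an analysis can be re-run with one command and reloaded a posteriori.

.default_config <- function() {
  list(
    axes = list(x = list(), y = list("y0"), z = list("z0")),
    peaklists = list(),
    sequence = NULL,
    curation = list(fill_policy = "carry_last", sidechains = "drop"),
    observables = list(
      csp = TRUE, height_ratio = FALSE, volume_ratio = FALSE, dpre = FALSE,
      alpha = list(default = 0.14, G = 0.2),
      smoothing = list(sigma = 3, halfwidth = NULL),
      dpre_sign = 1, predicted_pre = NULL,
      shift_normalize = NULL, threshold = NULL
    ),
    fitting = list(enabled = FALSE, model = "hill", p0 = NULL,
                   observable = "csp"),
    comparative = list(enabled = FALSE, parameter = "dpre",
                       present_along = "y"),
    plotting = list(templates = list(), format = "pdf", dpi = 300),
    export = list(chimera = list()),
    output = list(root = "output", overwrite = FALSE)
  )
}

.merge_defaults <- function(user, defaults) {
  for (key in names(defaults)) {
    if (is.null(user[[key]])) {
      user[key] <- list(defaults[[key]])
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
               is.list(user[[key]])) {
      user[[key]] <- .merge_defaults(user[[key]], defaults[[key]])
    }
  }
  user
}

#' Load and validate a run configuration
#'
#' Reads the JSON configuration, applies defaults for every unset field,
#' warns about unknown keys and validates the whole schema at once: all
#' violations are reported in a single error.  Relative peaklist paths
#' resolve against the configuration file's directory.
#'
#' @param path JSON file.
#' @return validated `run_config` (a list; attribute `base_dir`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  defaults <- .default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    nc_log("unknown configuration key(s) ignored: ",
           paste(unknown, collapse = ", "), level = "warn")
  }
  cfg <- .merge_defaults(raw[intersect(names(raw), names(defaults))],
                         defaults)
  errors <- character(0)
  bad <- function(...) errors <<- c(errors, paste0(...))
  for (a in c("x", "y", "z")) {
    labs <- unlist(cfg$axes[[a]])
    if (length(labs) < 1) bad("axes.", a, ": at least one label required")
    if (anyDuplicated(labs)) bad("axes.", a, ": duplicate labels")
    cfg$axes[[a]] <- as.character(labs)
  }
  if (!length(cfg$peaklists)) bad("peaklists: none declared")
  for (i in seq_along(cfg$peaklists)) {
    p <- cfg$peaklists[[i]]
    if (!all(c("z", "y", "x", "path") %in% names(p))) {
      bad("peaklists[", i, "]: needs z, y, x and path")
    }
  }
  if (!cfg$curation$fill_policy %in% c("carry_last", "blank")) {
    bad("curation.fill_policy: must be carry_last or blank")
  }
  if (!cfg$curation$sidechains %in% c("drop", "keep")) {
    bad("curation.sidechains: must be drop or keep")
  }
  if (isTRUE(cfg$fitting$enabled)) {
    xv <- suppressWarnings(as.numeric(cfg$axes$x))
    if (anyNA(xv)) {
      bad("fitting.enabled: fitting of continuous data is only possible ",
          "along a numeric x axis; x labels are not numeric (",
          paste(cfg$axes$x, collapse = ", "), ")")
    }
  }
  if (isTRUE(cfg$observables$dpre)) {
    if (length(cfg$axes$z) < 2) {
      bad("observables.dpre: paramagnetic analysis runs along the z axis, ",
          "which needs at least 2 points (dia/para)")
    }
    if (is.null(cfg$observables$predicted_pre)) {
      bad("observables.dpre: predicted_pre profile path required")
    }
  }
  bad_t <- setdiff(unlist(cfg$plotting$templates), .templates)
  if (length(bad_t)) {
    bad("plotting.templates: unknown template(s) ",
        paste(bad_t, collapse = ", "))
  }
  if (length(errors)) {
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config", base_dir = dirname(path))
}

#' Save a normalized run configuration
#'
#' Writes the fully default-populated configuration back to JSON so a run
#' can be reloaded and repeated a posteriori;
#' `load_config(save_config(cfg))` reproduces `cfg`.
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  attr(out, "base_dir") <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
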