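# Per-residue fitting of observable-vs-x curves (continuous x only).
# Two built-in models; further models can be registered at run time.

#' Hill binding curve
#'
#' `y(x) = ymax * x^n / (kd^n + x^n)`: under fast exchange the observed
#' CSP is the bound-population-weighted plateau value, so `kd` estimates
#' the dissociation constant in the units of x and `ymax` the saturation
#' response.
#'
#' @param x ligand concentrations (x-axis units).
#' @param ymax plateau response.
#' @param kd midpoint (dissociation constant).
#' @param n Hill coefficient.
#' @return predicted response.
#' @export
hill_curve <- function(x, ymax, kd, n = 1) {
  ifelse(x == 0, 0, ymax * x^n / (kd^n + x^n))
}

#' One-site binding with ligand depletion
#'
#' Quadratic (tight-binding) isotherm at total protein concentration
#' `p0`: the bound fraction solves the mass-balance quadratic, so the free
#' ligand concentration is not assumed equal to the total.
#'
#' @param x total ligand concentrations.
#' @param ymax plateau response.
#' @param kd dissociation constant.
#' @param p0 total protein concentration, same units as x.
#' @return predicted response.
#' @export
one_site_depletion_curve <- function(x, ymax, kd, p0) {
  b <- p0 + x + kd
  fb <- (b - sqrt(pmax(b^2 - 4 * p0 * x, 0))) / (2 * p0)
  ymax * fb
}

# model registry: name -> list(fun(x, params...), par_names, n_free)
.fit_models <- new.env(parent = emptyenv())

.register_builtin_models <- function() {
  assign("hill", list(
    fun = function(x, p) hill_curve(x, p[["ymax"]], p[["kd"]], p[["n"]]),
    par_names = c("ymax", "kd", "n")
  ), envir = .fit_models)
  assign("hill_n1", list(
    fun = function(x, p) hill_curve(x, p[["ymax"]], p[["kd"]], 1),
    par_names = c("ymax", "kd")
  ), envir = .fit_models)
  assign("one_site_depletion", list(
    fun = function(x, p) one_site_depletion_curve(x, p[["ymax"]], p[["kd"]],
                                                  p[["p0"]]),
    par_names = c("ymax", "kd", "p0")
  ), envir = .fit_models)
}

#' Register a fitting model
#'
#' Plug-in point for user fitting routines: a model is a prediction
#' function `fun(x, params)` (params a named vector) plus the parameter
#' names to optimise.
#'
#' @param name model identifier.
#' @param fun prediction function `function(x, params)`.
#' @param par_names character vector of free parameter names.
#' @export
register_fit_model <- function(name, fun, par_names) {
  assign(name, list(fun = fun, par_names = par_names), envir = .fit_models)
  invisible(name)
}

.get_model <- function(name) {
  if (!exists(name, envir = .fit_models)) .register_builtin_models()
  if (!exists(name, envir = .fit_models)) stop("unknown fit model: ", name)
  get(name, envir = .fit_models)
}

.fit_failure <- function(residue_number, model, reason, n_used = 0L) {
  data.frame(residue_number = residue_number, model = model,
             ymax = NA_real_, kd = NA_real_, n = NA_real_,
             rmse = NA_real_, converged = FALSE, n_points_used = n_used,
             note = reason, stringsAsFactors = FALSE)
}

#' Fit one residue's response curve
#'
#' Least-squares fit of the chosen model to measured points only.
#' Failures (too few points, optimizer breakdown) are reported in the
#' result's `converged`/`note` fields, never as exceptions.  Initial
#' values default to `ymax0 = max response`, `kd0 =` the x at half-max by
#' linear interpolation, `n0 = 1`; all parameters are bounded positive.
#'
#' @param x_values numeric, monotonic x-axis values.
#' @param observable per-point response (NA allowed; dropped).
#' @param model `"hill"` (default), `"hill_n1"`, `"one_site_depletion"`
#'   or a registered model.
#' @param init optional named vector of starting values.
#' @param residue_number carried through into the result row.
#' @param p0 total protein concentration (one_site_depletion only).
#' @param no_response_threshold |ymax| below which a converged fit is
#'   annotated `"no response"`.
#' @return one-row data.frame (`fit_result`): parameters, `rmse`,
#'   `converged`, `n_points_used`, `note`.
#' @export
fit_residue <- function(x_values, observable, model = "hill", init = NULL,
                        residue_number = NA_integer_, p0 = NULL,
                        no_response_threshold = 0) {
  if (!is.numeric(x_values) || anyNA(x_values)) {
    stop("fitting needs numeric x values (axis policy violated)")
  }
  m <- .get_model(model)
  ok <- !is.na(observable)
  x <- x_values[ok]
  y <- observable[ok]
  n_free <- length(m$par_names) - as.integer(model == "one_site_depletion")
  if (length(x) < max(4, n_free + 1)) {
    return(.fit_failure(residue_number, model, "insufficient points",
                        length(x)))
  }
  ymax0 <- y[which.max(abs(y))]
  if (abs(ymax0) <= no_response_threshold) {
    out <- .fit_failure(residue_number, model, "no response", length(x))
    out$ymax <- 0
    out$converged <- TRUE
    out$rmse <- sqrt(mean(y^2))
    return(out)
  }
  # fit the magnitude; the plateau sign is restored afterwards
  ysign <- if (ymax0 < 0) -1 else 1
  yf <- y * ysign
  # kd0: x at half-max by linear interpolation on the response magnitude
  kd0 <- tryCatch({
    v <- stats::approx(yf, x, xout = max(yf) / 2, ties = "ordered")$y
    if (is.na(v) || v <= 0) stats::median(x[x > 0]) else v
  }, error = function(e) stats::median(x[x > 0]))
  start <- c(ymax = abs(ymax0), kd = kd0, n = 1, p0 = p0 %||% NA_real_)
  if (!is.null(init)) start[names(init)] <- abs(init)
  free <- setdiff(m$par_names, if (model == "one_site_depletion") "p0")
  fixed <- start[setdiff(m$par_names, free)]
  obj <- function(logp) {
    p <- c(exp(logp), fixed)
    names(p) <- c(free, names(fixed))
    rss <- sum((yf - m$fun(x, p))^2)
    if (!is.finite(rss)) 1e300 else rss
  }
  safe_optim <- function(par, method, ...) {
    tryCatch(suppressWarnings(stats::optim(par, obj, method = method, ...)),
             error = function(e) NULL)
  }
  p0v <- log(start[free])
  runs <- list()
  if (length(free) == 1) {
    # 1-D: golden-section over 17 decades around the start
    runs[[1]] <- safe_optim(p0v, "Brent", lower = p0v - 20, upper = p0v + 20,
                            control = list(maxit = 1000))
  } else {
    runs[[1]] <- safe_optim(p0v, "BFGS",
                            control = list(maxit = 500, reltol = 1e-14))
    runs[[2]] <- safe_optim(p0v, "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-15))
  }
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) {
    return(.fit_failure(residue_number, model, "optimizer failure",
                        length(x)))
  }
  fit <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  if (length(free) > 1) {
    # polish from the best point with both methods, keep any improvement
    for (meth in c("Nelder-Mead", "BFGS")) {
      pol <- safe_optim(fit$par, meth,
                        control = list(maxit = 2000, reltol = 1e-15))
      if (!is.null(pol) && pol$value < fit$value) fit <- pol
    }
  }
  p <- exp(fit$par)
  names(p) <- free
  p[["ymax"]] <- ysign * p[["ymax"]]
  rmse <- sqrt(fit$value / length(x))
  data.frame(
    residue_number = residue_number, model = model,
    ymax = unname(p["ymax"]),
    kd = unname(p["kd"]),
    n = if ("n" %in% free) unname(p["n"]) else NA_real_,
    rmse = rmse, converged = TRUE, n_points_used = length(x),
    note = if (abs(p[["ymax"]]) < no_response_threshold) "no response" else "",
    stringsAsFactors = FALSE
  )
}

#' Fit every eligible residue of a series
#'
#' Gathers, per residue, the observable across the series' measured
#' points and fits the chosen model.  Residues whose maximal response is
#' below the response floor (default 3x a robust noise estimate: the
#' median absolute response at the first non-reference point) are
#' reported unfitted rather than fitted to noise.
#'
#' @param series a series with observables computed
#'   ([compute_observables()]).
#' @param observable derived column to fit (default `"csp"`).
#' @param model see [fit_residue()].
#' @param response_floor absolute floor; `NULL` = estimate from the data.
#' @param p0 protein concentration for `one_site_depletion`.
#' @param curve_points grid size of the fitted-curve table.
#' @return list with `fits` (one row per residue) and `curves`
#'   (data.frame `residue_number`, `x`, `fitted`, 100-point grid per
#'   converged residue).
#' @export
fit_series <- function(series, observable = "csp", model = "hill",
                       response_floor = NULL, p0 = NULL,
                       curve_points = 100) {
  x <- series$values
  if (anyNA(x)) stop("fitting requires numeric x labels")
  universe <- series$tables[[1]]$residue_number
  obs_mat <- vapply(series$tables, function(t) {
    v <- t[[observable]]
    v[t$status != "measured"] <- NA_real_
    v
  }, numeric(length(universe)))
  if (is.null(response_floor)) {
    first_resp <- abs(obs_mat[, 2])
    noise <- stats::median(first_resp, na.rm = TRUE)
    response_floor <- 3 * (if (is.na(noise)) 0 else noise)
  }
  fits <- vector("list", length(universe))
  skipped <- integer(0)
  for (i in seq_along(universe)) {
    yv <- obs_mat[i, ]
    if (all(is.na(yv))) {
      skipped <- c(skipped, universe[i])
      next
    }
    maxresp <- max(abs(yv), na.rm = TRUE)
    if (maxresp < response_floor) {
      fits[[i]] <- .fit_failure(universe[i], model, "below response floor",
                                sum(!is.na(yv)))
      next
    }
    fits[[i]] <- fit_residue(x, yv, model = model,
                             residue_number = universe[i], p0 = p0)
  }
  fits_df <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (length(skipped)) {
    nc_log(length(skipped), " residue(s) without data skipped from fitting")
  }
  grid <- seq(min(x), max(x), length.out = curve_points)
  m <- .get_model(model)
  curves <- list()
  if (!is.null(fits_df)) {
    conv <- fits_df[fits_df$converged & fits_df$note == "", , drop = FALSE]
    for (i in seq_len(nrow(conv))) {
      p <- c(ymax = conv$ymax[i], kd = conv$kd[i], n = conv$n[i],
             p0 = p0 %||% NA_real_)
      curves[[i]] <- data.frame(residue_number = conv$residue_number[i],
                                x = grid, fitted = m$fun(grid, p))
    }
  }
  list(
    fits = fits_df %||% .fit_failure(NA_integer_, model, "no data")[0, ],
    curves = if (length(curves)) do.call(rbind, curves) else
      data.frame(residue_number = integer(0), x = numeric(0),
                 fitted = numeric(0)),
    skipped = skipped
  )
}
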