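# Per-residue derived parameters for a normalized series, always evaluated
# against the series' reference experiment (the first table).

#' Observable configuration
#'
#' @param alpha heteronucleus weight for the combined CSP; default 0.14
#'   for all residue types with 0.2 for glycine (the usual 15N weighting).
#'   Supply a named vector of per-residue-type overrides, e.g.
#'   `c(default = 0.14, G = 0.2)`.
#' @param ratio_kind `"height"` or `"volume"` for intensity ratios.
#' @param smoothing_sigma Gaussian smoothing width, in residues.
#' @param smoothing_halfwidth kernel half-width, in residues; default
#'   `ceiling(4 * sigma)`.
#' @param dpre_sign +1 (default) for delta-PRE = predicted - observed
#'   intensity ratio (positive = more broadening than the random-coil
#'   expectation), -1 for the opposite convention.
#' @param significance_threshold optional constant drawn on plots, in the
#'   units of the observable.
#' @return a list of class `observable_config`.
#' @export
observable_config <- function(alpha = c(default = 0.14, G = 0.2),
                              ratio_kind = c("height", "volume"),
                              smoothing_sigma = 3,
                              smoothing_halfwidth = NULL,
                              dpre_sign = 1,
                              significance_threshold = NULL) {
  ratio_kind <- match.arg(ratio_kind)
  if (is.null(names(alpha))) names(alpha) <- "default"
  stopifnot(all(alpha > 0), smoothing_sigma > 0, dpre_sign %in% c(-1, 1))
  halfwidth <- smoothing_halfwidth %||% ceiling(4 * smoothing_sigma)
  stopifnot(halfwidth >= 1)
  structure(list(alpha = alpha, ratio_kind = ratio_kind,
                 smoothing_sigma = smoothing_sigma,
                 smoothing_halfwidth = halfwidth,
                 dpre_sign = dpre_sign,
                 significance_threshold = significance_threshold),
            class = "observable_config")
}

.alpha_for <- function(types, alpha) {
  def <- if ("default" %in% names(alpha)) alpha[["default"]] else 0.14
  out <- rep(def, length(types))
  named <- setdiff(names(alpha), "default")
  for (nm in named) out[!is.na(types) & types == nm] <- alpha[[nm]]
  out
}

#' Chemical shift differences against the reference
#'
#' @param reference,target normalized `nmr_peaklist`s on the same residue
#'   index.
#' @return data.frame with `residue_number`, `delta_h` (F2, 1H, ppm) and
#'   `delta_x` (F1, heteronucleus, ppm); NA where either row has no shift.
#' @export
delta_shifts <- function(reference, target) {
  if (!identical(reference$residue_number, target$residue_number)) {
    stop("internal error: tables are not normalized to the same residue ",
         "index (curation contract violated)")
  }
  data.frame(
    residue_number = reference$residue_number,
    delta_h = target$shift_f2 - reference$shift_f2,
    delta_x = target$shift_f1 - reference$shift_f1
  )
}

#' Combined chemical shift perturbation
#'
#' The weighted Euclidean combination
#' `csp = sqrt(0.5 * (delta_h^2 + (alpha * delta_x)^2))`, the standard way
#' to collapse amide 1H and 15N shift changes into a single per-residue
#' perturbation.
#'
#' @param delta_h,delta_x per-residue shift differences, ppm.
#' @param alpha heteronucleus weight: scalar or per-residue vector.
#' @return non-negative CSP values, ppm; zero iff both deltas are zero.
#' @export
combined_csp <- function(delta_h, delta_x, alpha = 0.14) {
  sqrt(0.5 * (delta_h^2 + (alpha * delta_x)^2))
}

#' Peak intensity ratio against the reference
#'
#' @param reference,target normalized `nmr_peaklist`s.
#' @param kind `"height"` or `"volume"`.
#' @return data.frame `residue_number`, `ratio` (target/reference); NA
#'   (with a logged count) where the reference value is zero or absent —
#'   never infinity.
#' @export
intensity_ratio <- function(reference, target, kind = c("height", "volume")) {
  kind <- match.arg(kind)
  if (!identical(reference$residue_number, target$residue_number)) {
    stop("internal error: tables are not normalized to the same residue ",
         "index (curation contract violated)")
  }
  ref <- reference[[kind]]
  tgt <- target[[kind]]
  bad <- is.na(ref) | ref == 0
  ratio <- ifelse(bad, NA_real_, tgt / ref)
  n_zero <- sum(!is.na(ref) & ref == 0)
  if (n_zero > 0) {
    nc_log(n_zero, " residue(s) with zero reference ", kind,
           "; ratio left empty", level = "warn")
  }
  data.frame(residue_number = reference$residue_number, ratio = ratio)
}

#' Deviation of an observed PRE profile from a random-coil prediction
#'
#' Both profiles are paramagnetic/diamagnetic intensity ratios on the same
#' residue numbering.  With the default sign convention
#' `dpre = predicted - observed`, positive values mark residues more
#' broadened (closer to the paramagnetic centre, or transiently compact)
#' than the random-coil model predicts.
#'
#' @param observed data.frame `residue_number`, `ratio` (I_para/I_dia).
#' @param predicted data.frame `residue_number`, `ratio` from the
#'   random-coil model (e.g. a Flexible-Meccano profile read with
#'   [read_predicted_pre()]).
#' @param sign +1 or -1; flips the convention.
#' @return data.frame `residue_number`, `dpre`; NA with a warning for
#'   residues present in only one profile.
#' @export
dpre <- function(observed, predicted, sign = 1) {
  stopifnot(sign %in% c(-1, 1))
  residues <- sort(union(observed$residue_number, predicted$residue_number))
  obs <- observed$ratio[match(residues, observed$residue_number)]
  pre <- predicted$ratio[match(residues, predicted$residue_number)]
  only_one <- xor(residues %in% observed$residue_number,
                  residues %in% predicted$residue_number)
  if (any(only_one)) {
    nc_log(sum(only_one), " residue(s) present in only one PRE profile; ",
           "delta-PRE left empty", level = "warn")
  }
  data.frame(residue_number = residues, dpre = sign * (pre - obs))
}

#' Read a predicted PRE profile table
#'
#' Two columns (residue_number, predicted intensity ratio), comma- or
#' whitespace-delimited, `#` comments allowed.
#'
#' @param path file to read.
#' @return data.frame `residue_number`, `ratio`.
#' @export
read_predicted_pre <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else ""
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) df <- df[-1, , drop = FALSE]  # header row
  out <- data.frame(residue_number = as.integer(df[[1]]),
                    ratio = as.numeric(df[[2]]))
  out[order(out$residue_number), , drop = FALSE]
}

#' Gaussian convolution smoothing of a per-residue profile
#'
#' Running Gaussian filter with kernel weights
#' `w_j = exp(-j^2 / (2 sigma^2))` over offsets `j` in
#' `[-halfwidth, halfwidth]`, renormalized at profile edges and across
#' gaps (residues without a value get no weight and produce NA output).
#' The filter is linear and its convex weights keep the output inside the
#' range of the input.
#'
#' @param values numeric profile values (NA = gap).
#' @param residue_numbers integer positions of `values` (need not be
#'   consecutive).
#' @param sigma kernel width in residues (> 0).
#' @param halfwidth kernel half-width in residues; default
#'   `ceiling(4 * sigma)`.
#' @return numeric vector parallel to `values`.
#' @export
gaussian_smooth <- function(values, residue_numbers = seq_along(values),
                            sigma = 3, halfwidth = NULL) {
  stopifnot(sigma > 0, length(values) == length(residue_numbers))
  halfwidth <- halfwidth %||% ceiling(4 * sigma)
  if (sum(!is.na(values)) < 1) return(rep(NA_real_, length(values)))
  # dense grid over the residue range, NA in gaps
  lo <- min(residue_numbers)
  dense <- rep(NA_real_, max(residue_numbers) - lo + 1L)
  dense[residue_numbers - lo + 1L] <- values
  n <- length(dense)
  offs <- -halfwidth:halfwidth
  w <- exp(-offs^2 / (2 * sigma^2))
  num <- rep(0, n)
  den <- rep(0, n)
  has <- !is.na(dense)
  v0 <- ifelse(has, dense, 0)
  for (k in seq_along(offs)) {
    j <- offs[k]
    src <- seq_len(n) + j
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + w[k] * v0[src[ok]] * has[src[ok]]
    den[ok] <- den[ok] + w[k] * has[src[ok]]
  }
  out <- ifelse(has & den > 0, num / den, NA_real_)
  out[residue_numbers - lo + 1L]
}

#' Remove per-spectrum global shift offsets
#'
#' Referencing drift between spectra shifts every peak of a spectrum by
#' the same (1H, X) offset.  Given a residue known to be unperturbed, the
#' offset observed on it in each spectrum is subtracted from all peaks of
#' that spectrum, so its own shift change becomes exactly (0, 0) at every
#' point.  Applying the normalization twice equals applying it once.
#'
#' @param series a normalized `nmr_series` (after [pad_tables()]).
#' @param reference_residue residue number measured at every point.
#' @return the series with corrected shifts.
#' @export
shift_normalize <- function(series, reference_residue) {
  idx <- vapply(series$tables, function(t) {
    match(reference_residue, t$residue_number)
  }, integer(1))
  bad <- vapply(seq_along(series$tables), function(j) {
    i <- idx[j]
    is.na(i) || series$tables[[j]]$status[i] != "measured"
  }, logical(1))
  if (any(bad)) {
    stop("shift normalization impossible: reference residue ",
         reference_residue, " not measured at point(s) ",
         paste(series$labels[bad], collapse = ", "))
  }
  ref_tab <- series$tables[[1]]
  ref_h <- ref_tab$shift_f2[idx[1]]
  ref_x <- ref_tab$shift_f1[idx[1]]
  out <- series
  for (j in seq_along(series$tables)) {
    t <- series$tables[[j]]
    off_h <- t$shift_f2[idx[j]] - ref_h
    off_x <- t$shift_f1[idx[j]] - ref_x
    t$shift_f2 <- t$shift_f2 - off_h
    t$shift_f1 <- t$shift_f1 - off_x
    out$tables[[j]] <- t
  }
  out
}

#' Compute derived parameters for every table of a series
#'
#' Appends the requested derived columns (`delta_h`, `delta_x`, `csp`,
#' `height_ratio` / `volume_ratio`, `dpre`, `smoothed_dpre`) to each table
#' of a normalized series, always against the first table as reference.
#' Derived values are empty for unassigned rows; rows filled by the
#' carry-last policy keep their `missing` status so plots can flag them.
#'
#' @param series normalized `nmr_series`.
#' @param config an [observable_config()].
#' @param what character vector among `"csp"`, `"height_ratio"`,
#'   `"volume_ratio"`, `"dpre"`.
#' @param predicted_pre required when `"dpre"` is requested: data.frame
#'   `residue_number`, `ratio`.
#' @return the series with result tables (derived columns appended).
#' @export
compute_observables <- function(series, config = observable_config(),
                                what = c("csp"),
                                predicted_pre = NULL) {
  if (length(series$tables) < 2) {
    nc_log("series has a single point; nothing to compare")
    return(series)
  }
  ref <- series$tables[[1]]
  out <- series
  for (j in seq_along(series$tables)) {
    tab <- series$tables[[j]]
    unass <- tab$status == "unassigned"
    if ("csp" %in% what) {
      ds <- delta_shifts(ref, tab)
      alpha <- .alpha_for(tab$residue_type, config$alpha)
      tab$delta_h <- ds$delta_h
      tab$delta_x <- ds$delta_x
      tab$csp <- combined_csp(ds$delta_h, ds$delta_x, alpha)
      tab$delta_h[unass] <- NA_real_
      tab$delta_x[unass] <- NA_real_
      tab$csp[unass] <- NA_real_
    }
    for (kind in c("height", "volume")) {
      key <- paste0(kind, "_ratio")
      if (key %in% what) {
        rr <- intensity_ratio(ref, tab, kind)
        tab[[key]] <- rr$ratio
        tab[[key]][unass] <- NA_real_
      }
    }
    if ("dpre" %in% what) {
      if (is.null(predicted_pre)) {
        stop("dpre requested but no predicted PRE profile supplied")
      }
      rr <- intensity_ratio(ref, tab, config$ratio_kind)
      dp <- dpre(rr, predicted_pre, sign = config$dpre_sign)
      tab$dpre <- dp$dpre[match(tab$residue_number, dp$residue_number)]
      tab$dpre[unass] <- NA_real_
      tab$smoothed_dpre <- gaussian_smooth(
        tab$dpre, tab$residue_number,
        sigma = config$smoothing_sigma,
        halfwidth = config$smoothing_halfwidth)
    }
    out$tables[[j]] <- tab
  }
  out
}
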