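# The eight figure templates.  Every rendered figure is accompanied by a
# sidecar CSV holding exactly the plotted values; tests (and users
# re-plotting elsewhere) rely on the sidecar, not on pixel content.
# Colour semantics throughout: measured = black, missing = red,
# unassigned = grey; prolines are labelled "P"; an optional significance
# threshold is drawn as a red line.

.templates <- c("bar_extended", "bar_compacted", "bar_vertical",
                "scatter_shift_map", "scatter_trajectory", "heat_map",
                "dpre_profile", "residue_evolution")

#' Plot configuration
#'
#' @param colours named vector with `measured`, `missing`, `unassigned`
#'   colours.
#' @param threshold significance threshold value (observable units), or
#'   `NULL` for none.
#' @param threshold_colour colour of the threshold line.
#' @param format figure file format: `"pdf"` (vector, default), `"png"`
#'   or `"svg"`.
#' @param dpi raster resolution (png only).
#' @param width,height figure size in inches.
#' @return list of class `plot_config`.
#' @export
plot_config <- function(colours = c(measured = "black", missing = "red",
                                    unassigned = "grey60"),
                        threshold = NULL, threshold_colour = "red",
                        format = c("pdf", "png", "svg"), dpi = 300,
                        width = 10, height = 4) {
  format <- match.arg(format)
  stopifnot(dpi > 0)
  structure(list(colours = colours, threshold = threshold,
                 threshold_colour = threshold_colour, format = format,
                 dpi = dpi, width = width, height = height),
            class = "plot_config")
}

.open_device <- function(path, config) {
  switch(config$format,
    pdf = grDevices::pdf(path, width = config$width,
                         height = config$height),
    png = grDevices::png(path, width = config$width, height = config$height,
                         units = "in", res = config$dpi),
    svg = grDevices::svg(path, width = config$width, height = config$height)
  )
}

.status_colours <- function(status, config) {
  unname(config$colours[status])
}

.write_sidecar <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Render one figure template
#'
#' Writes the figure file and its sidecar CSV (the exact plotted values)
#' next to it.  Expected `data` per template: the three bar templates and
#' `scatter_shift_map` take a result table (one series point with derived
#' columns); `scatter_trajectory` and `residue_evolution` take a series
#' with observables computed; `heat_map` takes a `comparative_table`;
#' `dpre_profile` takes a data.frame with `residue_number` and any of
#' `predicted`, `observed`, `dpre`, `smoothed_dpre`.
#'
#' @param template one of the eight template names.
#' @param data see above.
#' @param config a [plot_config()].
#' @param path figure file path (extension decides nothing; the format
#'   comes from `config`).
#' @param column derived column to plot for bar templates (default
#'   `"csp"`).
#' @param fits optional `fit_series()` curves for `residue_evolution`.
#' @return invisible list `figure`, `sidecar`.
#' @export
render <- function(template, data, config = plot_config(), path,
                   column = "csp", fits = NULL) {
  template <- match.arg(template, .templates)
  if (is.null(data) ||
      (is.data.frame(data) && nrow(data) == 0) ||
      (inherits(data, "comparative_table") && nrow(data$matrix) == 0)) {
    stop("nothing to plot")
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), "_data.csv")
  .open_device(path, config)
  on.exit(grDevices::dev.off(), add = TRUE)
  sdf <- switch(template,
    bar_extended = .plot_bar(data, config, column, style = "extended"),
    bar_compacted = .plot_bar(data, config, column, style = "compacted"),
    bar_vertical = .plot_bar(data, config, column, style = "vertical"),
    scatter_shift_map = .plot_shift_map(data, config),
    scatter_trajectory = .plot_trajectory(data, config),
    heat_map = .plot_heatmap(data, config),
    dpre_profile = .plot_dpre_profile(data, config),
    residue_evolution = .plot_residue_evolution(data, config, column, fits)
  )
  .write_sidecar(sdf, sidecar)
  invisible(list(figure = path, sidecar = sidecar))
}

.need_cols <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
}

.plot_bar <- function(tab, config, column, style) {
  .need_cols(tab, c("residue_number", "status", column))
  v <- tab[[column]]
  v[is.na(v)] <- 0
  cols <- .status_colours(tab$status, config)
  is_pro <- !is.na(tab$residue_type) & tab$residue_type == "P"
  horiz <- style == "vertical"
  bp <- graphics::barplot(
    if (horiz) rev(v) else v,
    names.arg = if (horiz) rev(tab$residue_number) else tab$residue_number,
    col = if (horiz) rev(cols) else cols,
    border = NA, horiz = horiz, las = 2, cex.names = 0.5,
    xlab = if (horiz) column else "residue",
    ylab = if (horiz) "residue" else column
  )
  if (style == "compacted") {
    # shaded background over unassigned residues
    un <- which(tab$status == "unassigned")
    usr <- graphics::par("usr")
    for (i in un) {
      graphics::rect(bp[i] - 0.6, usr[3], bp[i] + 0.6, usr[4],
                     col = grDevices::adjustcolor("grey80", 0.5),
                     border = NA)
    }
  }
  if (any(is_pro)) {
    if (horiz) {
      graphics::text(0, rev(bp)[which(is_pro)], "P", cex = 0.6)
    } else {
      graphics::text(bp[which(is_pro)], 0, "P", pos = 3, cex = 0.6)
    }
  }
  if (!is.null(config$threshold)) {
    if (horiz) {
      graphics::abline(v = config$threshold, col = config$threshold_colour)
    } else {
      graphics::abline(h = config$threshold, col = config$threshold_colour)
    }
  }
  data.frame(residue_number = tab$residue_number,
             residue_type = tab$residue_type,
             value = tab[[column]], status = tab$status)
}

.plot_shift_map <- function(tab, config) {
  .need_cols(tab, c("residue_number", "delta_h", "delta_x"))
  ok <- !is.na(tab$delta_h) & !is.na(tab$delta_x)
  graphics::plot(tab$delta_x[ok], tab$delta_h[ok],
                 xlab = "delta shift F1 (ppm)",
                 ylab = "delta shift 1H (ppm)", pch = 19, cex = 0.6,
                 col = .status_colours(tab$status[ok], config))
  graphics::abline(h = 0, v = 0, col = "grey80")
  data.frame(residue_number = tab$residue_number[ok],
             delta_h = tab$delta_h[ok], delta_x = tab$delta_x[ok],
             status = tab$status[ok])
}

.plot_trajectory <- function(series, config) {
  stopifnot(inherits(series, "nmr_series"))
  long <- do.call(rbind, lapply(seq_along(series$tables), function(j) {
    t <- series$tables[[j]]
    data.frame(residue_number = t$residue_number, point = series$labels[j],
               shift_f2 = t$shift_f2, shift_f1 = t$shift_f1,
               status = t$status)
  }))
  ok <- stats::complete.cases(long[, c("shift_f2", "shift_f1")])
  graphics::plot(long$shift_f2[ok], long$shift_f1[ok], type = "n",
                 xlim = rev(range(long$shift_f2[ok])),
                 ylim = rev(range(long$shift_f1[ok])),
                 xlab = "1H (ppm)", ylab = "F1 (ppm)")
  for (r in unique(long$residue_number)) {
    seg <- long[long$residue_number == r & ok, , drop = FALSE]
    if (nrow(seg) > 1) {
      graphics::lines(seg$shift_f2, seg$shift_f1, col = "grey60")
    }
    graphics::points(seg$shift_f2, seg$shift_f1, pch = 19, cex = 0.4,
                     col = .status_colours(seg$status, config))
  }
  long[ok, , drop = FALSE]
}

.plot_heatmap <- function(ct, config) {
  stopifnot(inherits(ct, "comparative_table"))
  m <- ct$matrix
  residues <- as.integer(rownames(m))
  z <- m
  z[is.na(z)] <- 0
  graphics::image(x = residues, y = seq_len(ncol(m)), z = z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "residue", ylab = ct$presented_along, yaxt = "n",
                  main = ct$parameter)
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  data.frame(residue_number = residues, m, check.names = FALSE)
}

.plot_dpre_profile <- function(df, config) {
  .need_cols(df, "residue_number")
  series_cols <- intersect(c("predicted", "observed", "dpre",
                             "smoothed_dpre"), names(df))
  if (!length(series_cols)) {
    stop("missing required column(s): one of predicted/observed/dpre/",
         "smoothed_dpre")
  }
  pal <- c(predicted = "grey40", observed = "black", dpre = "steelblue",
           smoothed_dpre = "red")
  rng <- range(unlist(df[series_cols]), na.rm = TRUE)
  graphics::plot(NA, xlim = range(df$residue_number), ylim = rng,
                 xlab = "residue", ylab = "intensity ratio / delta-PRE")
  for (cc in series_cols) {
    graphics::lines(df$residue_number, df[[cc]], col = pal[[cc]],
                    lwd = if (cc == "smoothed_dpre") 2 else 1)
  }
  graphics::legend("topright", legend = series_cols, col = pal[series_cols],
                   lwd = 1, cex = 0.7, bty = "n")
  df[, c("residue_number", series_cols), drop = FALSE]
}

.plot_residue_evolution <- function(series, config, column, fits) {
  stopifnot(inherits(series, "nmr_series"))
  universe <- series$tables[[1]]$residue_number
  xv <- if (!anyNA(series$values)) series$values else
    seq_along(series$labels)
  mat <- vapply(series$tables, function(t) t[[column]],
                numeric(length(universe)))
  keep <- rowSums(!is.na(mat)) > 0
  rows <- which(keep)
  n <- length(rows)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  graphics::par(mfrow = c(nr, nc), mar = c(1.5, 1.5, 1, 0.5), mgp = c(1, 0.3, 0))
  for (i in rows) {
    graphics::plot(xv, mat[i, ], type = "b", pch = 19, cex = 0.5,
                   xlab = "", ylab = "", cex.axis = 0.5,
                   ylim = range(c(0, mat[i, ]), na.rm = TRUE))
    graphics::mtext(paste0(universe[i],
                           series$tables[[1]]$residue_type[i]),
                    cex = 0.5, line = 0)
    if (!is.null(fits) && nrow(fits$curves)) {
      cv <- fits$curves[fits$curves$residue_number == universe[i], ,
                        drop = FALSE]
      if (nrow(cv)) graphics::lines(cv$x, cv$fitted, col = "red")
    }
  }
  long <- do.call(rbind, lapply(seq_along(series$tables), function(j) {
    data.frame(residue_number = universe, point = series$labels[j],
               value = mat[, j])
  }))
  long[long$residue_number %in% universe[keep], , drop = FALSE]
}

#' Render a set of templates for a set of series
#'
#' Walks every requested (series, template) pair, renders the figure into
#' `dir` and logs the produced count; per-figure failures are logged and
#' the run continues.
#'
#' @param series_results list of series with observables computed.
#' @param templates character vector of template names (may be empty).
#' @param dir output directory.
#' @param config a [plot_config()].
#' @param column derived column for bar/evolution templates.
#' @return data.frame of produced files (`file`, `series`, `template`).
#' @export
render_all <- function(series_results, templates, dir,
                       config = plot_config(), column = "csp") {
  if (!length(templates)) {
    nc_log("no plot templates selected; zero figures produced")
    return(data.frame(file = character(0), series = character(0),
                      template = character(0)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (si in seq_along(series_results)) {
    s <- series_results[[si]]
    sid <- paste(names(s$fixed), s$fixed, sep = "", collapse = "_")
    for (tmpl in templates) {
      fig <- file.path(dir, sprintf("%s_%s.%s", tmpl, sid, config$format))
      data <- switch(tmpl,
        bar_extended = , bar_compacted = , bar_vertical = ,
        scatter_shift_map = s$tables[[length(s$tables)]],
        s
      )
      res <- tryCatch(
        render(tmpl, data, config, fig, column = column),
        error = function(e) {
          nc_log("figure ", basename(fig), " failed: ",
                 conditionMessage(e), level = "warn")
          NULL
        }
      )
      if (!is.null(res)) {
        out[[length(out) + 1]] <- data.frame(file = fig, series = sid,
                                             template = tmpl)
      }
    }
  }
  produced <- if (length(out)) do.call(rbind, out) else
    data.frame(file = character(0), series = character(0),
               template = character(0))
  nc_log(nrow(produced), " figure(s) written to ", dir)
  produced
}
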