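# Comparative/stacking analysis: parameters computed along one axis are
# regrouped so their dependence on another axis can be tabulated and
# plotted (e.g. delta-PRE computed along z for every sequence variant,
# presented as a residues x variants matrix).

#' Stack one parameter across series
#'
#' Pure re-indexing: takes the per-residue values of a parameter computed
#' along axis A for each label of axis B and places them side by side as
#' a residues x B-labels matrix.  Values are copied, never recomputed, so
#' every cell is traceable to exactly one source cell with an identical
#' value.  Residue sets that differ between columns (different sequences
#' along y) are outer-joined with empties and the mismatch is logged.
#'
#' @param values_by_label named list (names = presented-axis labels, in
#'   axis order) of data.frames with columns `residue_number` and `value`.
#' @param parameter name of the stacked parameter.
#' @param computed_along axis the parameter was computed along.
#' @param presented_along axis whose labels become columns.
#' @param provenance optional named character: source series coordinate
#'   per column.
#' @return a `comparative_table`: list with `parameter`,
#'   `computed_along`, `presented_along`, `matrix` (rownames = residues),
#'   `provenance`.
#' @export
stack_series <- function(values_by_label, parameter,
                         computed_along, presented_along,
                         provenance = NULL) {
  stopifnot(length(values_by_label) >= 1, !is.null(names(values_by_label)))
  residues <- sort(unique(unlist(lapply(values_by_label,
                                        `[[`, "residue_number"))))
  in_all <- Reduce(intersect, lapply(values_by_label, `[[`, "residue_number"))
  partial <- setdiff(residues, in_all)
  if (length(partial)) {
    nc_log("residue(s) present in fewer than all columns: ",
           paste(partial, collapse = ", "), level = "warn")
  }
  mat <- vapply(values_by_label, function(df) {
    df$value[match(residues, df$residue_number)]
  }, numeric(length(residues)))
  mat <- matrix(mat, nrow = length(residues),
                dimnames = list(residues, names(values_by_label)))
  structure(
    list(parameter = parameter, computed_along = computed_along,
         presented_along = presented_along, matrix = mat,
         provenance = provenance %||%
           stats::setNames(names(values_by_label),
                           names(values_by_label))),
    class = "comparative_table"
  )
}

#' Recover the source columns of a comparative table
#'
#' Inverse of [stack_series()]: returns the per-label data.frames
#' (residues with empty cells dropped), so stacking is invertible given
#' the provenance.
#'
#' @param ct a `comparative_table`.
#' @return named list of data.frames `residue_number`, `value`.
#' @export
unstack_series <- function(ct) {
  stopifnot(inherits(ct, "comparative_table"))
  residues <- as.integer(rownames(ct$matrix))
  lapply(stats::setNames(colnames(ct$matrix), colnames(ct$matrix)),
         function(lab) {
    v <- ct$matrix[, lab]
    keep <- !is.na(v)
    data.frame(residue_number = residues[keep], value = unname(v[keep]))
  })
}

#' @export
print.comparative_table <- function(x, ...) {
  cat(sprintf(
    "<comparative_table: %s computed along %s, presented along %s (%d x %d)>\n",
    x$parameter, x$computed_along, x$presented_along,
    nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write a comparative table as CSV
#' @param ct a `comparative_table`.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_comparative_csv <- function(ct, dir) {
  path <- file.path(dir, sprintf("%s_stacked_%s.csv", ct$parameter,
                                 ct$presented_along))
  df <- data.frame(residue_number = as.integer(rownames(ct$matrix)),
                   ct$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Regroup computed results across axes
#'
#' For a parameter computed along axis A on every series, produces one
#' comparative table per label of the remaining axis C, with columns
#' indexed by axis B.  Series are identified by their fixed coordinates.
#' A cube with |B| = 1 and |C| = 1 makes the comparison a no-op (one
#' single-column table) and logs a notice.
#'
#' @param series_results list of result series (observables computed),
#'   all along the same axis.
#' @param parameter derived column to regroup.
#' @param present_along axis B whose labels become columns.
#' @param at_point which point of each series to read the parameter from:
#'   `"last"` (default) or an index.
#' @return named list of `comparative_table`s, one per remaining-axis
#'   label.
#' @export
compare_across <- function(series_results, parameter, present_along,
                           at_point = "last") {
  stopifnot(length(series_results) >= 1)
  along <- series_results[[1]]$along
  if (present_along == along) {
    stop("cannot present along the axis the parameter was computed along")
  }
  other <- setdiff(c("x", "y", "z"), c(along, present_along))
  other_labels <- unique(vapply(series_results,
                                function(s) s$fixed[[other]], character(1)))
  if (length(other_labels) == 1 &&
      length(unique(vapply(series_results,
                           function(s) s$fixed[[present_along]],
                           character(1)))) == 1) {
    nc_log("single series; comparative step is a no-op")
  }
  out <- list()
  for (oc in other_labels) {
    sel <- Filter(function(s) s$fixed[[other]] == oc, series_results)
    vals <- list()
    prov <- character(0)
    for (s in sel) {
      j <- if (identical(at_point, "last")) length(s$tables) else at_point
      tab <- s$tables[[j]]
      if (!parameter %in% names(tab)) {
        stop("parameter '", parameter, "' not computed for series at ",
             paste(names(s$fixed), s$fixed, sep = "=", collapse = ", "))
      }
      lab <- s$fixed[[present_along]]
      vals[[lab]] <- data.frame(residue_number = tab$residue_number,
                                value = tab[[parameter]])
      prov[lab] <- paste0(along, "-series at ",
                          paste(names(s$fixed), s$fixed, sep = "=",
                                collapse = ","), ", point ", s$labels[j])
    }
    out[[oc]] <- stack_series(vals, parameter, along, present_along,
                              provenance = prov)
  }
  out
}
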