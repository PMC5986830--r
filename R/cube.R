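# The three-axis experimental data structure: every cell of the (z, y, x)
# grid holds exactly one peaklist; series are ordered slices along one axis
# at fixed coordinates of the other two.

#' Define one experimental axis
#'
#' Each axis of the data cube represents one experimental variable: the x
#' axis typically holds a continuous perturbation (ligand concentration,
#' temperature), the y axis different protein constructs or sequence
#' variants, and the z axis a spectroscopic toggle such as
#' diamagnetic/paramagnetic.  Labels are stored as text; when every label
#' parses as a number the axis carries numeric values usable for fitting.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param labels ordered, unique condition labels (length >= 1).
#' @return an `axis_spec` object.
#' @export
axis_spec <- function(axis = c("x", "y", "z"), labels) {
  axis <- match.arg(axis)
  labels <- as.character(labels)
  if (length(labels) < 1) stop("axis ", axis, " needs at least one label")
  if (anyDuplicated(labels)) {
    stop("axis ", axis, " labels must be unique: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  }
  values <- suppressWarnings(as.numeric(labels))
  numeric_ok <- !anyNA(values)
  if (axis == "x" && numeric_ok && is.unsorted(values, strictly = TRUE) &&
      is.unsorted(rev(values), strictly = TRUE)) {
    stop("numeric x-axis labels must be monotonic (needed for fitting)")
  }
  structure(
    list(axis = axis, labels = labels,
         values = if (numeric_ok) values else rep(NA_real_, length(labels))),
    class = "axis_spec"
  )
}

.cube_key <- function(z, y, x) paste(z, y, x, sep = "\r")

#' Assemble the data cube
#'
#' Places one peaklist at every (z, y, x) coordinate.  The cube is dense:
#' a missing or duplicated coordinate is an error naming the offending
#' cell.  Input order is irrelevant; cells are addressed by coordinate.
#'
#' @param peaklists list of `nmr_peaklist`s, each with its `coordinate`
#'   attribute set to `c(z, y, x)` (or a named list with elements
#'   `table`, `z`, `y`, `x`).
#' @param axes list with elements `x`, `y`, `z`, each an [axis_spec()].
#' @return an `nmr_cube`.
#' @export
build_cube <- function(peaklists, axes) {
  stopifnot(all(c("x", "y", "z") %in% names(axes)))
  for (a in c("x", "y", "z")) stopifnot(inherits(axes[[a]], "axis_spec"))
  cells <- list()
  for (pl in peaklists) {
    if (is.list(pl) && !inherits(pl, "nmr_peaklist")) {
      coord <- c(pl$z, pl$y, pl$x)
      tab <- pl$table
    } else {
      coord <- attr(pl, "coordinate")
      tab <- pl
    }
    if (is.null(coord) || length(coord) != 3) {
      stop("every peaklist needs a (z, y, x) coordinate")
    }
    key <- .cube_key(coord[1], coord[2], coord[3])
    if (!is.null(cells[[key]])) {
      stop(sprintf("duplicate peaklist for coordinate (z=%s, y=%s, x=%s)",
                   coord[1], coord[2], coord[3]))
    }
    attr(tab, "coordinate") <- as.character(coord)
    cells[[key]] <- tab
  }
  for (z in axes$z$labels) for (y in axes$y$labels) for (x in axes$x$labels) {
    if (is.null(cells[[.cube_key(z, y, x)]])) {
      stop(sprintf("no peaklist for coordinate (z=%s, y=%s, x=%s)", z, y, x))
    }
  }
  n_expected <- length(axes$x$labels) * length(axes$y$labels) *
    length(axes$z$labels)
  if (length(cells) != n_expected) {
    extra <- setdiff(
      names(cells),
      as.vector(outer(axes$z$labels,
                      as.vector(outer(axes$y$labels, axes$x$labels,
                                      function(y, x) paste(y, x, sep = "\r"))),
                      function(z, yx) paste(z, yx, sep = "\r")))
    )
    stop("peaklist(s) at coordinates outside the declared axes: ",
         paste(gsub("\r", "/", extra), collapse = "; "))
  }
  structure(list(axes = axes, cells = cells), class = "nmr_cube")
}

#' @export
print.nmr_cube <- function(x, ...) {
  cat(sprintf("<nmr_cube: |x|=%d |y|=%d |z|=%d (%d peaklists)>\n",
              length(x$axes$x$labels), length(x$axes$y$labels),
              length(x$axes$z$labels), length(x$cells)))
  invisible(x)
}

#' Fetch one cell of the cube
#' @param cube an `nmr_cube`.
#' @param z,y,x coordinate labels.
#' @return the `nmr_peaklist` at that coordinate.
#' @export
cube_cell <- function(cube, z, y, x) {
  cube$cells[[.cube_key(z, y, x)]]
}

#' Extract all series along one axis
#'
#' A series is the ordered sequence of peaklists along the chosen axis at
#' fixed labels of the other two; its first element is the reference
#' experiment for all derived parameters.  Enumeration walks every
#' combination of the fixed axes, so each cell appears in exactly one
#' series (a partition of the cube).
#'
#' @param cube an `nmr_cube`.
#' @param along `"x"`, `"y"` or `"z"`.
#' @return list of `nmr_series` objects.
#' @export
enumerate_series <- function(cube, along = c("x", "y", "z")) {
  along <- match.arg(along)
  fixed_axes <- setdiff(c("z", "y", "x"), along)
  if (length(cube$axes[[along]]$labels) == 1) {
    nc_log("axis ", along, " has a single point; series of length 1 ",
           "(nothing to compare)")
  }
  grid <- expand.grid(
    b = cube$axes[[fixed_axes[2]]]$labels,
    a = cube$axes[[fixed_axes[1]]]$labels,
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    fixed <- stats::setNames(c(grid$a[i], grid$b[i]), fixed_axes)
    labels <- cube$axes[[along]]$labels
    tables <- lapply(labels, function(lab) {
      coord <- c(z = unname(fixed["z"]), y = unname(fixed["y"]),
                 x = unname(fixed["x"]))
      coord[along] <- lab
      cube_cell(cube, coord[["z"]], coord[["y"]], coord[["x"]])
    })
    structure(
      list(along = along, fixed = fixed, labels = labels,
           values = cube$axes[[along]]$values, tables = tables),
      class = "nmr_series"
    )
  })
}

#' @export
print.nmr_series <- function(x, ...) {
  cat(sprintf("<nmr_series along %s (%d points) at %s>\n", x$along,
              length(x$tables),
              paste(names(x$fixed), x$fixed, sep = "=", collapse = ", ")))
  invisible(x)
}

# Analyses and the axes they are allowed on.  Paramagnetic comparisons run
# along z only, continuous-data fitting along x only; sequence variation is
# legal along y only.
.axis_policy <- list(
  csp = c("x", "y", "z"),
  height_ratio = c("x", "y", "z"),
  volume_ratio = c("x", "y", "z"),
  dpre = "z",
  fitting = "x"
)

#' Validate requested analyses against the axis policy
#'
#' Enforces the axis restrictions before any computation: paramagnetic
#' (delta-PRE) analysis only along z, fitting of continuous data only
#' along x (and only when the x labels are numeric), and differing residue
#' sequences only across y labels.  Returns the validated plan; any
#' violation aborts with a message quoting the policy.
#'
#' @param cube an `nmr_cube`.
#' @param analyses data.frame (or list of lists) with columns `analysis`
#'   and `axis`.
#' @return data.frame of permitted (analysis, axis) pairs.
#' @export
axis_policy_check <- function(cube, analyses) {
  if (is.data.frame(analyses)) {
    plan <- analyses
  } else {
    plan <- do.call(rbind, lapply(analyses, function(a) {
      data.frame(analysis = a$analysis, axis = a$axis,
                 stringsAsFactors = FALSE)
    }))
  }
  for (i in seq_len(nrow(plan))) {
    an <- plan$analysis[i]
    ax <- plan$axis[i]
    allowed <- .axis_policy[[an]]
    if (is.null(allowed)) stop("unknown analysis: ", an)
    if (!ax %in% allowed) {
      stop(sprintf(
        paste0("analysis '%s' requested along axis %s, but it is only ",
               "permitted along %s (paramagnetic analysis only along z, ",
               "fitting of continuous data only along x)"),
        an, ax, paste(allowed, collapse = "/")))
    }
    if (an == "fitting" && anyNA(cube$axes$x$values)) {
      stop("fitting requires numeric x-axis labels; got: ",
           paste(cube$axes$x$labels, collapse = ", "))
    }
  }
  # Differing sequences are legal across y only.  Peak disappearance along
  # a titration is expected, so residue *sets* may shrink within a y slice;
  # what is forbidden is a conflicting residue *type* at the same number,
  # which indicates different sequences mixed along x or z.
  for (y in cube$axes$y$labels) {
    typed <- list()
    for (z in cube$axes$z$labels) for (x in cube$axes$x$labels) {
      tab <- cube_cell(cube, z, y, x)
      for (r in seq_len(nrow(tab))) {
        key <- as.character(tab$residue_number[r])
        tp <- tab$residue_type[r]
        if (is.na(tp)) next
        if (!is.null(typed[[key]]) && !identical(typed[[key]], tp)) {
          stop(sprintf(
            paste0("residue %s has conflicting residue types ('%s' vs ",
                   "'%s') within y=%s; differing protein sequences are ",
                   "only permitted along the y axis"),
            key, typed[[key]], tp, y))
        }
        typed[[key]] <- tp
      }
    }
  }
  plan
}
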