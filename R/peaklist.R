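#' Construct a peaklist table
#'
#' A peaklist holds one row per peak of a 2D heteronuclear correlation
#' spectrum (typically an HSQC): the residue it is assigned to, the two
#' chemical shifts (F1 = heteronucleus, F2 = 1H), peak height and volume,
#' optional linewidths and the free-text annotations users keep in their
#' spectral analysis program (merit, details, fit method).  Each row also
#' carries a `status`: `"measured"` for peaks read from a spectrum,
#' `"missing"` for assigned peaks that have disappeared at this series
#' point, and `"unassigned"` for placeholder rows of residues never
#' observed.
#'
#' @param df data.frame with any subset of the canonical columns; absent
#'   columns are created empty.
#' @param source_path file the table was read from, if any.
#' @param source_format one of `"sparky"`, `"nmrpipe"`, `"ccpnv2"`,
#'   `"nmrview"`, `"ansig"`, `"canonical"`, or `NA`.
#' @param coordinate optional `(z, y, x)` label triple assigned at cube
#'   assembly.
#' @return object of class `nmr_peaklist` (a data.frame).
#' @export
peaklist <- function(df = NULL, source_path = NA_character_,
                     source_format = NA_character_, coordinate = NULL) {
  if (is.null(df)) df <- data.frame()
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  out <- data.frame(
    residue_number = rep(NA_integer_, n),
    residue_type = rep(NA_character_, n),
    atom_f1 = rep(NA_character_, n),
    atom_f2 = rep(NA_character_, n),
    shift_f1 = rep(NA_real_, n),
    shift_f2 = rep(NA_real_, n),
    height = rep(NA_real_, n),
    volume = rep(NA_real_, n),
    linewidth_f1 = rep(NA_real_, n),
    linewidth_f2 = rep(NA_real_, n),
    merit = rep(NA_character_, n),
    details = rep(NA_character_, n),
    fit_method = rep(NA_character_, n),
    status = rep("measured", n),
    stringsAsFactors = FALSE
  )
  for (col in intersect(names(df), c(.canonical_cols, .derived_cols))) {
    out[[col]] <- df[[col]]
  }
  out$residue_number <- as.integer(out$residue_number)
  for (col in c("shift_f1", "shift_f2", "height", "volume",
                "linewidth_f1", "linewidth_f2")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  if (n > 0) out <- out[order(out$residue_number, out$atom_f1), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("nmr_peaklist", "data.frame"),
    source_path = source_path,
    source_format = source_format,
    coordinate = coordinate
  )
}

#' Validate a peaklist table
#'
#' Checks the container invariants: residue numbers are positive, statuses
#' are one of the three recognised values, measured rows carry finite
#' chemical shifts, and residue types are canonical one-letter codes (or
#' blank on unassigned placeholders).
#'
#' @param x an `nmr_peaklist`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_peaklist <- function(x) {
  stopifnot(inherits(x, "nmr_peaklist"))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.na(x$residue_number) & x$residue_number < 1)) {
    stop("peaklist invariant violated: residue_number must be >= 1")
  }
  bad <- !x$status %in% c("measured", "missing", "unassigned")
  if (any(bad)) {
    stop("peaklist invariant violated: unknown status ",
         paste(unique(x$status[bad]), collapse = ", "))
  }
  meas <- x$status == "measured"
  if (any(meas & (!is.finite(x$shift_f1) | !is.finite(x$shift_f2)))) {
    stop("peaklist invariant violated: measured rows need finite shifts")
  }
  typed <- !is.na(x$residue_type) & nzchar(x$residue_type)
  if (any(typed & !x$residue_type %in% names(.aa3))) {
    stop("peaklist invariant violated: non-canonical residue type ",
         paste(unique(x$residue_type[typed & !x$residue_type %in% names(.aa3)]),
               collapse = ", "))
  }
  invisible(x)
}

#' @export
print.nmr_peaklist <- function(x, ...) {
  cat(sprintf("<nmr_peaklist: %d rows, format=%s, source=%s>\n",
              nrow(x), attr(x, "source_format"), attr(x, "source_path")))
  print(as.data.frame(x), ...)
  invisible(x)
}

# Backbone amide rows: F1 atom exactly "N" (sidechain NH2 atoms carry
# suffixed names such as ND2a/ND2b).
is_backbone_row <- function(x) {
  is.na(x$atom_f1) | x$atom_f1 %in% c("N", "")
}

#' Identify amide sidechain rows
#'
#' NH2 sidechain peaks of Asn/Gln appear as doublets whose atom names end
#' in `a`/`b` (e.g. ND2a/HD2a, NE2b/HE2b).  These rows must not enter
#' backbone analyses.  With `keep = TRUE` they are returned as a parallel
#' table; with `keep = FALSE` they are dropped and the count logged.
#'
#' @param table an `nmr_peaklist`.
#' @param keep retain sidechain rows in a separate table?
#' @return list with elements `backbone` and (if `keep`) `sidechain`,
#'   both `nmr_peaklist`s; the backbone table gains a logical
#'   `sidechain` marker column set to `FALSE`.
#' @export
tag_sidechains <- function(table, keep = TRUE) {
  stopifnot(inherits(table, "nmr_peaklist"))
  sc <- grepl("[ab]$", table$atom_f1 %||% character(0)) &
    !is.na(table$atom_f1)
  backbone <- table[!sc, , drop = FALSE]
  attributes(backbone)[c("source_path", "source_format", "coordinate")] <-
    attributes(table)[c("source_path", "source_format", "coordinate")]
  class(backbone) <- class(table)
  rownames(backbone) <- NULL
  if (keep) {
    side <- table[sc, , drop = FALSE]
    class(side) <- class(table)
    rownames(side) <- NULL
    list(backbone = backbone, sidechain = side)
  } else {
    if (any(sc)) nc_log(sum(sc), " sidechain row(s) dropped")
    list(backbone = backbone)
  }
}
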