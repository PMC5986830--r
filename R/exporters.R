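# Molecular-viewer attribute files and the hierarchical output tree.

#' Write a UCSF Chimera attribute file
#'
#' Produces the "Define attribute" text format: three header lines
#' (`attribute:`, `match mode:`, `recipient:`) followed by one
#' tab-indented line per residue with a value
#' (`<TAB>:<resnum><TAB><value>`).  Residues with empty values are
#' omitted.  Values are printed as shortest-round-trip decimals with at
#' most six significant digits.
#'
#' @param residue_numbers integer residue numbers.
#' @param values per-residue values (NA omitted).
#' @param attribute attribute name; must match
#'   `^[a-z][A-Za-z0-9_]*$` or the viewer rejects it.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chimera_attributes <- function(residue_numbers, values, attribute,
                                     path) {
  if (!grepl("^[a-z][A-Za-z0-9_]*$", attribute)) {
    stop("invalid Chimera attribute name: '", attribute,
         "' (must start with a lowercase letter, then alphanumerics/_)")
  }
  keep <- !is.na(values)
  if (!any(keep)) stop("nothing to export: all values are empty")
  lines <- c(
    paste0("attribute: ", attribute),
    "match mode: 1-to-1",
    "recipient: residues",
    sprintf("\t:%d\t%s", residue_numbers[keep], nc_fmt6(values[keep]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a Chimera attribute file back into (residue, value) pairs
#' @param path attribute file.
#' @return data.frame `residue_number`, `value`.
#' @export
read_chimera_attributes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- grep("^\t:", lines, value = TRUE)
  parts <- strsplit(sub("^\t:", "", body), "\t", fixed = TRUE)
  data.frame(
    residue_number = as.integer(vapply(parts, `[[`, character(1), 1)),
    value = as.numeric(vapply(parts, `[[`, character(1), 2))
  )
}

# ---- output tree -----------------------------------------------------------

#' Prepare the hierarchical output root
#'
#' Results are laid out as `output_root/<z>/<y>/<analysis>/`, outermost
#' to innermost coordinate.  A pre-existing non-empty root is refused
#' unless `overwrite = TRUE`.
#'
#' @param root output directory.
#' @param overwrite allow writing into a non-empty root.
#' @return `root`, invisibly.
#' @export
prepare_output_root <- function(root, overwrite = FALSE) {
  if (dir.exists(root) && length(list.files(root, all.files = FALSE)) > 0 &&
      !overwrite) {
    stop("output root ", root, " exists and is not empty; ",
         "use overwrite = TRUE to proceed")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  invisible(root)
}

output_dir <- function(root, z, y, analysis) {
  d <- file.path(root, z, y, analysis)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Write the run manifest
#'
#' One row per produced file with its cube coordinate and file type, so a
#' run's outputs are auditable and two runs can be compared.
#'
#' @param entries data.frame with columns `file`, `z`, `y`, `analysis`,
#'   `type`.
#' @param root output root.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(entries, root) {
  path <- file.path(root, "manifest.csv")
  entries <- entries[order(entries$file), , drop = FALSE]
  utils::write.csv(entries, path, row.names = FALSE)
  invisible(path)
}
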