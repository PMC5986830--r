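# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Canonical column order of a peaklist table.  Derived columns are appended
# after `status` and never reordered.
.canonical_cols <- c(
  "residue_number", "residue_type", "atom_f1", "atom_f2",
  "shift_f1", "shift_f2", "height", "volume",
  "linewidth_f1", "linewidth_f2", "merit", "details", "fit_method", "status"
)

.derived_cols <- c(
  "delta_h", "delta_x", "csp", "height_ratio", "volume_ratio",
  "dpre", "smoothed_dpre"
)

# Three-letter <-> one-letter amino-acid codes (canonical 20).
.aa3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)
.aa1 <- stats::setNames(names(.aa3), .aa3)

# Simple condition-logged messaging.  Warnings never abort; errors do.
nc_log <- function(..., level = "info") {
  msg <- paste0("[nmrcube] ", paste0(..., collapse = ""))
  if (identical(level, "warn")) warning(msg, call. = FALSE) else message(msg)
  invisible(msg)
}

# Parse numbers in C locale; empty strings and "NA" become NA without noise.
nc_num <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", "None", "-")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

# Shortest round-trip decimal, at most 6 significant digits.
nc_fmt6 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(signif(v, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
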