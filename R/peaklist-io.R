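# Peaklist readers for the supported text dialects and the canonical CSV
# writer.  Dialect details (column order, separators, comment markers) are
# frozen by the golden files under tests/testthat/fixtures; parsers are
# intentionally strict and fail loudly with line numbers rather than guess.

.dialects <- c("sparky", "nmrpipe", "ccpnv2", "nmrview", "ansig")

#' Detect the dialect of a peaklist file
#'
#' Inspects raw text content for the signature tokens of each supported
#' peaklist export: Sparky list files carry an `Assignment`/`w1` header,
#' NMRPipe `.tab` files start their header with `VARS ... X_PPM`, CCPN
#' Analysis v2 exports name columns `Position F1`/`Assign F1`, NmrView
#' `.xpk` files carry `label dataset` and per-dimension `.L`/`.P` column
#' names, and Ansig exports are flagged by an `ANSIG` marker.
#'
#' @param text character: raw file content (single string or lines).
#' @return one of `"sparky"`, `"nmrpipe"`, `"ccpnv2"`, `"nmrview"`,
#'   `"ansig"`.
#' @export
detect_format <- function(text) {
  txt <- paste(text, collapse = "\n")
  if (!nzchar(trimws(txt))) stop("cannot detect format of empty content")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (any(grepl("ANSIG", lines, fixed = TRUE))) return("ansig")
  if (any(grepl("^\\s*VARS\\b", lines) & grepl("X_PPM", lines))) {
    return("nmrpipe")
  }
  if (any(grepl("Position F1", lines, fixed = TRUE) &
          grepl("Assign F1", lines, fixed = TRUE))) {
    return("ccpnv2")
  }
  if (any(grepl("\\blabel\\b", lines) & grepl("\\bdataset\\b", lines)) ||
      any(grepl("\\.L\\b", lines) & grepl("\\.P\\b", lines))) {
    return("nmrview")
  }
  if (any(grepl("\\bAssignment\\b", lines) & grepl("\\bw1\\b", lines))) {
    return("sparky")
  }
  # Nothing matched: name the closest candidate by signature-token count.
  score <- c(
    sparky  = sum(grepl("Assignment|w1|w2", lines)),
    nmrpipe = sum(grepl("VARS|FORMAT|PPM", lines)),
    ccpnv2  = sum(grepl("Position|Assign|Merit|Details", lines)),
    nmrview = sum(grepl("label|dataset|\\.L|\\.P", lines)),
    ansig   = 0
  )
  stop(sprintf("unrecognized format (closest candidate: %s)",
               names(which.max(score))))
}

# ---- assignment-string grammar ---------------------------------------------
# Accepted forms:
#   "T103N-H"    one-letter type, residue number, F1 atom, "-", F2 atom
#   "Gly45HN"    three-letter type, residue number, atom(s)
#   "Thr103N"    three-letter per-dimension form (CCPN v2)
#   "T103N"      one-letter per-dimension form
# Anything else is a parse error naming the offending token.
parse_assignment <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec(
    "^([A-Z][a-z]{2}|[A-Z])([0-9]+)([A-Za-z][A-Za-z0-9]*)?(?:-([A-Za-z][A-Za-z0-9]*))?$",
    s))[[1]]
  if (length(m) == 0) {
    stop(sprintf("cannot parse assignment token '%s'", s), call. = FALSE)
  }
  type <- m[2]
  if (nchar(type) == 3) {
    if (!type %in% .aa3) {
      stop(sprintf("unknown residue type in assignment token '%s'", s),
           call. = FALSE)
    }
    type <- .aa1[[type]]
  } else if (!type %in% names(.aa3)) {
    stop(sprintf("unknown residue type in assignment token '%s'", s),
         call. = FALSE)
  }
  list(
    residue_type = type,
    residue_number = as.integer(m[3]),
    atom_f1 = if (nzchar(m[4])) m[4] else NA_character_,
    atom_f2 = if (length(m) >= 5 && nzchar(m[5])) m[5] else NA_character_
  )
}

#' Parse a peaklist file into the canonical table
#'
#' Reads one of the supported peaklist dialects and returns an
#' [peaklist()] with one row per peak, the assignment string decomposed
#' into residue number, one-letter residue type and the two atom names.
#' All parsed rows have `status = "measured"`.  Optional columns a dialect
#' does not carry are left empty, never fabricated.
#'
#' @param path file to read.
#' @param format dialect identifier; auto-detected when `NULL`.
#' @return an `nmr_peaklist`.
#' @export
parse_peaklist <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such peaklist file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) {
    nc_log("empty peaklist file: ", path, level = "warn")
    return(peaklist(source_path = path,
                    source_format = format %||% NA_character_))
  }
  format <- format %||% detect_format(lines)
  format <- match.arg(format, c(.dialects, "canonical"))
  tab <- switch(format,
    sparky = .parse_sparky(lines, path),
    nmrpipe = .parse_nmrpipe(lines, path),
    ccpnv2 = .parse_ccpnv2(lines, path),
    nmrview = .parse_nmrview(lines, path),
    canonical = .parse_canonical(lines, path),
    ansig = stop("unsupported dialect: ansig (fixed-width Ansig exports ",
                 "are not implemented)")
  )
  attr(tab, "source_path") <- path
  attr(tab, "source_format") <- format
  validate_peaklist(tab)
  tab
}

.data_lines <- function(lines) {
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*(#|REMARK)", lines)
  which(keep)
}

.line_error <- function(path, lineno, why) {
  stop(sprintf("malformed peak line %d in %s: %s", lineno, path, why),
       call. = FALSE)
}

# Sparky list file: whitespace columns Assignment w1 w2 [Height [Volume]];
# w1 is the heteronucleus (F1), w2 the 1H (F2).
.parse_sparky <- function(lines, path) {
  idx <- .data_lines(lines)
  hdr <- idx[grepl("Assignment", lines[idx])][1]
  body <- setdiff(idx, hdr)
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3) .line_error(path, i, "need Assignment w1 w2")
    a <- tryCatch(parse_assignment(f[1]),
                  error = function(e) .line_error(path, i, conditionMessage(e)))
    data.frame(
      residue_number = a$residue_number, residue_type = a$residue_type,
      atom_f1 = a$atom_f1 %||% NA_character_,
      atom_f2 = a$atom_f2 %||% NA_character_,
      shift_f1 = nc_num(f[2]), shift_f2 = nc_num(f[3]),
      height = if (length(f) >= 4) nc_num(f[4]) else NA_real_,
      volume = if (length(f) >= 5) nc_num(f[5]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  peaklist(do.call(rbind, rows), source_format = "sparky")
}

# NMRPipe .tab: VARS/FORMAT header; X_PPM is the direct 1H dimension (F2),
# Y_PPM the heteronucleus (F1); XW_HZ/YW_HZ likewise.
.parse_nmrpipe <- function(lines, path) {
  idx <- .data_lines(lines)
  vars_i <- idx[grepl("^\\s*VARS\\b", lines[idx])][1]
  if (is.na(vars_i)) stop("nmrpipe table lacks a VARS header: ", path)
  vars <- strsplit(trimws(lines[vars_i]), "\\s+")[[1]][-1]
  body <- idx[!grepl("^\\s*(VARS|FORMAT|DATA|NULLVALUE|NULLSTRING)\\b",
                     lines[idx])]
  col <- function(f, name) {
    j <- match(name, vars)
    if (is.na(j) || j > length(f)) NA_character_ else f[j]
  }
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < length(vars)) {
      .line_error(path, i, sprintf("expected %d fields, got %d",
                                   length(vars), length(f)))
    }
    ass <- col(f, "ASS")
    a <- tryCatch(parse_assignment(ass),
                  error = function(e) .line_error(path, i, conditionMessage(e)))
    data.frame(
      residue_number = a$residue_number, residue_type = a$residue_type,
      atom_f1 = a$atom_f1 %||% NA_character_,
      atom_f2 = a$atom_f2 %||% NA_character_,
      shift_f1 = nc_num(col(f, "Y_PPM")), shift_f2 = nc_num(col(f, "X_PPM")),
      height = nc_num(col(f, "HEIGHT")), volume = nc_num(col(f, "VOL")),
      linewidth_f1 = nc_num(col(f, "YW_HZ")),
      linewidth_f2 = nc_num(col(f, "XW_HZ")),
      stringsAsFactors = FALSE
    )
  })
  peaklist(do.call(rbind, rows), source_format = "nmrpipe")
}

# CCPN Analysis v2 tabular export: comma-separated with quoted free text.
.parse_ccpnv2 <- function(lines, path) {
  idx <- .data_lines(lines)
  txt <- lines[idx]
  df <- utils::read.csv(text = txt, check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("Position F1", "Position F2", "Assign F1", "Assign F2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("ccpnv2 export lacks column(s): ",
         paste(missing_cols, collapse = ", "), " in ", path)
  }
  opt <- function(name) {
    if (name %in% names(df)) df[[name]] else rep(NA_character_, nrow(df))
  }
  rows <- lapply(seq_len(nrow(df)), function(r) {
    a1 <- tryCatch(parse_assignment(df[["Assign F1"]][r]),
                   error = function(e)
                     .line_error(path, idx[r + 1], conditionMessage(e)))
    a2 <- tryCatch(parse_assignment(df[["Assign F2"]][r]),
                   error = function(e)
                     .line_error(path, idx[r + 1], conditionMessage(e)))
    if (!identical(a1$residue_number, a2$residue_number)) {
      .line_error(path, idx[r + 1], "F1/F2 assigned to different residues")
    }
    data.frame(
      residue_number = a1$residue_number, residue_type = a1$residue_type,
      atom_f1 = a1$atom_f1 %||% NA_character_,
      atom_f2 = a2$atom_f1 %||% NA_character_,
      shift_f1 = nc_num(df[["Position F1"]][r]),
      shift_f2 = nc_num(df[["Position F2"]][r]),
      height = nc_num(opt("Height")[r]), volume = nc_num(opt("Volume")[r]),
      linewidth_f1 = nc_num(opt("Line Width F1 (Hz)")[r]),
      linewidth_f2 = nc_num(opt("Line Width F2 (Hz)")[r]),
      merit = opt("Merit")[r], details = opt("Details")[r],
      fit_method = opt("Fit Method")[r],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  for (col in c("merit", "details", "fit_method")) {
    tab[[col]][!is.na(tab[[col]]) & !nzchar(tab[[col]])] <- NA_character_
  }
  peaklist(tab, source_format = "ccpnv2")
}

# NmrView .xpk: header block (label/dataset lines) then one row per peak
# with {}-delimited labels "{<res>.<type>.<atom>}"; F1 columns first.
.parse_nmrview <- function(lines, path) {
  idx <- .data_lines(lines)
  hdr_i <- idx[grepl("\\.L\\b", lines[idx])][1]
  if (is.na(hdr_i)) stop("nmrview .xpk lacks a column-name row: ", path)
  body <- idx[idx > hdr_i]
  hdr <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1]]
  tok_split <- function(s) {
    # split on whitespace but keep {...} groups intact
    m <- gregexpr("\\{[^}]*\\}|[^\\s{}]+", s, perl = TRUE)
    regmatches(s, m)[[1]]
  }
  lab_parse <- function(tok, i) {
    inner <- sub("^\\{", "", sub("\\}$", "", tok))
    p <- strsplit(inner, ".", fixed = TRUE)[[1]]
    if (length(p) != 3) .line_error(path, i, paste0("bad label ", tok))
    list(residue_number = as.integer(p[1]), residue_type = p[2], atom = p[3])
  }
  coln <- function(name) match(name, hdr) + 1L  # +1: leading peak index
  dims <- unique(sub("\\..*$", "", hdr[grepl("\\.L$", hdr)]))
  if (length(dims) != 2) stop("nmrview .xpk must have two dimensions: ", path)
  rows <- lapply(body, function(i) {
    f <- tok_split(trimws(lines[i]))
    if (length(f) < length(hdr) + 1) {
      .line_error(path, i, sprintf("expected %d fields, got %d",
                                   length(hdr) + 1, length(f)))
    }
    l1 <- lab_parse(f[coln(paste0(dims[1], ".L"))], i)
    l2 <- lab_parse(f[coln(paste0(dims[2], ".L"))], i)
    if (!identical(l1$residue_number, l2$residue_number)) {
      .line_error(path, i, "dimensions assigned to different residues")
    }
    data.frame(
      residue_number = l1$residue_number, residue_type = l1$residue_type,
      atom_f1 = l1$atom, atom_f2 = l2$atom,
      shift_f1 = nc_num(f[coln(paste0(dims[1], ".P"))]),
      shift_f2 = nc_num(f[coln(paste0(dims[2], ".P"))]),
      height = nc_num(f[coln("int")]),
      volume = nc_num(f[coln("vol")]),
      stringsAsFactors = FALSE
    )
  })
  peaklist(do.call(rbind, rows), source_format = "nmrview")
}

.parse_canonical <- function(lines, path) {
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE,
                        colClasses = "character")
  num_cols <- c("shift_f1", "shift_f2", "height", "volume",
                "linewidth_f1", "linewidth_f2", .derived_cols)
  for (col in intersect(num_cols, names(df))) df[[col]] <- nc_num(df[[col]])
  for (col in intersect(c("merit", "details", "fit_method"), names(df))) {
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  for (col in intersect(c("residue_type", "atom_f1", "atom_f2"), names(df))) {
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  peaklist(df, source_format = "canonical")
}

#' Write a peaklist (or result table) as canonical CSV
#'
#' The canonical export uses a fixed header order (the fourteen base
#' columns, then any derived columns present) with RFC-4180 quoting.
#' Re-reading the file through [parse_peaklist()] with
#' `format = "canonical"` reproduces the table field for field.
#'
#' @param table an `nmr_peaklist` (possibly with derived columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_canonical_csv <- function(table, path) {
  stopifnot(inherits(table, "nmr_peaklist"))
  cols <- c(.canonical_cols, intersect(.derived_cols, names(table)))
  df <- as.data.frame(table)[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write canonical CSV to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
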