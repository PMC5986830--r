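# Writers for the supported peaklist dialects.  Used by the fixture
# generator so every dialect has a programmatic golden; round-tripping
# write -> parse must preserve all fields a dialect carries.

fmt_shift <- function(x) sprintf("%.3f", x)
fmt_int <- function(x) ifelse(is.na(x), "", sprintf("%.6e", x))

one2three <- function(code) unname(.aa3[code])

#' Write a peaklist in a spectrometer-software dialect
#'
#' Only measured rows are written (the dialects have no notion of
#' missing/unassigned placeholders).  Fields a dialect does not carry are
#' silently omitted.
#'
#' @param table an `nmr_peaklist`.
#' @param path output file.
#' @param dialect one of `"sparky"`, `"nmrpipe"`, `"ccpnv2"`, `"nmrview"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(table, path,
                           dialect = c("sparky", "nmrpipe", "ccpnv2",
                                       "nmrview")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "nmr_peaklist"))
  tab <- table[table$status == "measured", , drop = FALSE]
  lines <- switch(dialect,
    sparky = .write_sparky(tab),
    nmrpipe = .write_nmrpipe(tab),
    ccpnv2 = .write_ccpnv2(tab),
    nmrview = .write_nmrview(tab)
  )
  writeLines(lines, path)
  invisible(path)
}

.assignment_string <- function(tab) {
  paste0(tab$residue_type, tab$residue_number, tab$atom_f1, "-", tab$atom_f2)
}

.write_sparky <- function(tab) {
  hdr <- sprintf("%17s %10s %10s %13s %13s",
                 "Assignment", "w1", "w2", "Height", "Volume")
  body <- sprintf("%17s %10s %10s %13s %13s",
                  .assignment_string(tab),
                  fmt_shift(tab$shift_f1), fmt_shift(tab$shift_f2),
                  fmt_int(tab$height), fmt_int(tab$volume))
  c(hdr, "", body)
}

.write_nmrpipe <- function(tab) {
  hdr <- c(
    "REMARK 2D peak table",
    "VARS   INDEX X_PPM Y_PPM XW_HZ YW_HZ HEIGHT VOL ASS",
    "FORMAT %5d %9.3f %9.3f %8.2f %8.2f %+e %+e %s"
  )
  lw <- function(v) ifelse(is.na(v), "0.00", sprintf("%.2f", v))
  body <- sprintf("%5d %9s %9s %8s %8s %s %s %s",
                  seq_len(nrow(tab)),
                  fmt_shift(tab$shift_f2), fmt_shift(tab$shift_f1),
                  lw(tab$linewidth_f2), lw(tab$linewidth_f1),
                  ifelse(is.na(tab$height), "+0.000000e+00",
                         sprintf("%+e", tab$height)),
                  ifelse(is.na(tab$volume), "+0.000000e+00",
                         sprintf("%+e", tab$volume)),
                  .assignment_string(tab))
  c(hdr, body)
}

.write_ccpnv2 <- function(tab) {
  df <- data.frame(
    Number = seq_len(nrow(tab)),
    `Position F1` = fmt_shift(tab$shift_f1),
    `Position F2` = fmt_shift(tab$shift_f2),
    `Assign F1` = paste0(one2three(tab$residue_type), tab$residue_number,
                         tab$atom_f1),
    `Assign F2` = paste0(one2three(tab$residue_type), tab$residue_number,
                         tab$atom_f2),
    `Line Width F1 (Hz)` = ifelse(is.na(tab$linewidth_f1), "",
                                  sprintf("%.2f", tab$linewidth_f1)),
    `Line Width F2 (Hz)` = ifelse(is.na(tab$linewidth_f2), "",
                                  sprintf("%.2f", tab$linewidth_f2)),
    Height = fmt_int(tab$height),
    Volume = fmt_int(tab$volume),
    Merit = ifelse(is.na(tab$merit), "", tab$merit),
    Details = ifelse(is.na(tab$details), "", tab$details),
    `Fit Method` = ifelse(is.na(tab$fit_method), "", tab$fit_method),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  out
}

.write_nmrview <- function(tab) {
  hdr <- c(
    "label dataset sw sf",
    "15N 1H",
    "synthetic.nv",
    "{2000.0 8000.0}",
    "{60.8 600.1}",
    paste(" 15N.L 15N.P 15N.W 15N.B 1H.L 1H.P 1H.W 1H.B",
          "vol int stat comment flag0")
  )
  lab <- function(atom) sprintf("{%d.%s.%s}", tab$residue_number,
                                tab$residue_type, atom)
  num0 <- function(v) ifelse(is.na(v), "0.0", sprintf("%.6e", v))
  body <- sprintf("%d %s %s 0.050 0.050 %s %s 0.010 0.010 %s %s 0 {?} 0",
                  seq_len(nrow(tab)) - 1L,
                  lab(tab$atom_f1), fmt_shift(tab$shift_f1),
                  lab(tab$atom_f2), fmt_shift(tab$shift_f2),
                  num0(tab$volume), num0(tab$height))
  c(hdr, body)
}
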