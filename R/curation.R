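# Series curation: every residue of the series' universe gets a status in
# every table, and all tables are padded to a common residue index so that
# downstream arithmetic can align rows positionally.

#' Scan a series for missing and unassigned residues
#'
#' The residue universe is a supplied sequence range (or one-letter
#' sequence) or, absent that, the union of residue numbers observed over
#' the series.  At each series point a residue is `measured` when its peak
#' is present, `missing` when it has been observed at an earlier point but
#' has disappeared (exchange broadening; the last point where it was
#' measured is recorded), and `unassigned` when it has never been observed
#' up to that point.
#'
#' @param series an `nmr_series`.
#' @param sequence optional: either a length-2 integer vector
#'   `c(first, last)` of residue numbers, or a list with `first` and
#'   `seq` (one-letter amino-acid string) defining numbering and types.
#' @return object of class `series_status`: list with `universe`
#'   (residue numbers), `types` (named one-letter codes, NA if unknown),
#'   `status` (residues x points character matrix) and `filled_from`
#'   (residues x points; x-label of the last measured point, NA
#'   elsewhere).
#' @export
scan_series <- function(series, sequence = NULL) {
  stopifnot(inherits(series, "nmr_series"))
  tabs <- lapply(series$tables, function(t) tag_sidechains(t)$backbone)
  types <- character(0)
  if (!is.null(sequence)) {
    if (is.list(sequence)) {
      aa <- strsplit(sequence$seq, "")[[1]]
      universe <- seq(sequence$first, sequence$first + length(aa) - 1L)
      types <- stats::setNames(aa, universe)
    } else {
      universe <- seq(sequence[1], sequence[2])
      types <- stats::setNames(rep(NA_character_, length(universe)), universe)
    }
  } else {
    universe <- sort(unique(unlist(lapply(tabs, `[[`, "residue_number"))))
    types <- stats::setNames(rep(NA_character_, length(universe)), universe)
  }
  # fill in observed residue types
  for (tab in tabs) {
    for (r in seq_len(nrow(tab))) {
      key <- as.character(tab$residue_number[r])
      if (key %in% names(types) && is.na(types[[key]]) &&
          !is.na(tab$residue_type[r])) {
        types[[key]] <- tab$residue_type[r]
      }
    }
  }
  npt <- length(tabs)
  status <- matrix("unassigned", nrow = length(universe), ncol = npt,
                   dimnames = list(universe, series$labels))
  filled <- matrix(NA_character_, nrow = length(universe), ncol = npt,
                   dimnames = list(universe, series$labels))
  for (j in seq_len(npt)) {
    tab <- tabs[[j]]
    dup <- tab$residue_number[duplicated(tab$residue_number)]
    if (length(dup)) {
      stop(sprintf(
        "residue %s has conflicting backbone rows in %s",
        paste(unique(dup), collapse = ", "),
        attr(series$tables[[j]], "source_path") %||% series$labels[j]))
    }
    present <- as.character(tab$residue_number[tab$status == "measured"])
    status[present[present %in% rownames(status)], j] <- "measured"
  }
  for (i in seq_along(universe)) {
    last_seen <- NA_integer_
    for (j in seq_len(npt)) {
      if (status[i, j] == "measured") {
        last_seen <- j
      } else if (!is.na(last_seen)) {
        status[i, j] <- "missing"
        filled[i, j] <- series$labels[last_seen]
      }
    }
  }
  structure(list(universe = universe, types = types, status = status,
                 filled_from = filled),
            class = "series_status")
}

#' Pad all tables of a series to a common residue index
#'
#' After padding, every table holds exactly one backbone row per residue
#' of the universe, sorted by residue number, with a `status` column.
#' Under `fill_policy = "carry_last"` a missing residue's row copies the
#' observables from the last point where it was measured (the filled
#' values are causal: they never come from a later point).  Under
#' `"blank"` missing rows keep empty observables, which then propagate as
#' empty through every derived parameter.  Unassigned rows are always
#' empty.  The operation is idempotent.
#'
#' @param series an `nmr_series`.
#' @param status a `series_status` from [scan_series()]; recomputed when
#'   `NULL`.
#' @param fill_policy `"carry_last"` (default) or `"blank"`.
#' @param sequence forwarded to [scan_series()] when `status` is `NULL`.
#' @return the series with normalized tables (class `nmr_series`,
#'   attribute `status` attached).
#' @export
pad_tables <- function(series, status = NULL,
                       fill_policy = c("carry_last", "blank"),
                       sequence = NULL) {
  fill_policy <- match.arg(fill_policy)
  if (is.null(status)) status <- scan_series(series, sequence = sequence)
  tabs <- lapply(series$tables, function(t) tag_sidechains(t)$backbone)
  universe <- status$universe
  out_tables <- vector("list", length(tabs))
  for (j in seq_along(tabs)) {
    tab <- as.data.frame(tabs[[j]])
    rows <- vector("list", length(universe))
    for (i in seq_along(universe)) {
      res <- universe[i]
      st <- status$status[i, j]
      if (st == "measured") {
        rows[[i]] <- tab[tab$residue_number == res, , drop = FALSE]
        rows[[i]]$status <- "measured"
      } else if (st == "missing" && fill_policy == "carry_last") {
        src_j <- match(status$filled_from[i, j], series$labels)
        src <- as.data.frame(tabs[[src_j]])
        row <- src[src$residue_number == res, , drop = FALSE]
        row$status <- "missing"
        rows[[i]] <- row
      } else {
        rows[[i]] <- data.frame(
          residue_number = res,
          residue_type = unname(status$types[as.character(res)]),
          status = st, stringsAsFactors = FALSE
        )
      }
    }
    merged <- do.call(rbind, lapply(rows, function(r) {
      miss <- setdiff(.canonical_cols, names(r))
      for (m in miss) r[[m]] <- NA
      r[, .canonical_cols, drop = FALSE]
    }))
    pl <- peaklist(merged,
                   source_path = attr(series$tables[[j]], "source_path"),
                   source_format = attr(series$tables[[j]], "source_format"),
                   coordinate = attr(series$tables[[j]], "coordinate"))
    out_tables[[j]] <- pl
  }
  out <- series
  out$tables <- out_tables
  attr(out, "status") <- status
  attr(out, "fill_policy") <- fill_policy
  out
}
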