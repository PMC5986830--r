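# End-to-end pipeline: parse -> curate -> cube -> per-axis analyses ->
# fitting -> comparative -> plots -> exports, fully driven by one run
# configuration.  The pipeline is deterministic: re-running the same
# configuration yields identical tables, sidecars and manifest.

.cfg_sequence <- function(config) {
  s <- config$sequence
  if (is.null(s)) return(NULL)
  if (is.list(s) && !is.null(s$seq)) {
    list(first = s$first %||% 1L, seq = s$seq)
  } else {
    c(as.integer(s[[1]]), as.integer(s[[2]]))
  }
}

.cfg_obs <- function(config) {
  o <- config$observables
  alpha_l <- o$alpha
  alpha <- stats::setNames(as.numeric(unlist(alpha_l)), names(alpha_l))
  observable_config(
    alpha = alpha,
    ratio_kind = "height",
    smoothing_sigma = o$smoothing$sigma %||% 3,
    smoothing_halfwidth = o$smoothing$halfwidth,
    dpre_sign = o$dpre_sign %||% 1,
    significance_threshold = o$threshold
  )
}

#' Execute a full analysis run
#'
#' Runs the validated pipeline end to end and populates the hierarchical
#' output tree `output_root/<z>/<y>/<analysis>/` with curated peaklist
#' CSVs, fit tables, comparative matrices, figures with their sidecar
#' tables and molecular-viewer attribute files, plus `manifest.csv`
#' listing every produced file with its coordinate, and a normalized copy
#' of the configuration.  Stage warnings never abort; stage errors do.
#'
#' @param config a `run_config` from [load_config()], or a path to one.
#' @param output_root overrides `config$output$root`.
#' @param overwrite overrides `config$output$overwrite`.
#' @return invisibly, a list with `root`, `manifest` (data.frame), `log`
#'   (named counts) and `results` (the analysed series).
#' @export
run_pipeline <- function(config, output_root = NULL, overwrite = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  base_dir <- attr(config, "base_dir") %||% "."
  root <- output_root %||% config$output$root
  if (!grepl("^(/|[A-Za-z]:)", root)) root <- file.path(base_dir, root)
  prepare_output_root(root, overwrite %||%
                        isTRUE(config$output$overwrite))
  manifest <- list()
  note <- function(file, z, y, analysis, type) {
    rel <- if (startsWith(file, paste0(root, "/"))) {
      substring(file, nchar(root) + 2)
    } else {
      file
    }
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = rel, z = z, y = y,
      analysis = analysis, type = type, stringsAsFactors = FALSE)
  }
  runlog <- c(peaklists_read = 0, residues_missing = 0,
              residues_unassigned = 0, series_analysed = 0,
              figures_written = 0)

  # ---- 1. parse ------------------------------------------------------------
  keep_sc <- identical(config$curation$sidechains, "keep")
  peaklists <- lapply(config$peaklists, function(p) {
    path <- p$path
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base_dir, path)
    tab <- parse_peaklist(path, format = p$format)
    attr(tab, "coordinate") <- c(p$z, p$y, p$x)
    tab
  })
  runlog["peaklists_read"] <- length(peaklists)

  # ---- 2. cube + policy ----------------------------------------------------
  axes <- list(x = axis_spec("x", config$axes$x),
               y = axis_spec("y", config$axes$y),
               z = axis_spec("z", config$axes$z))
  cube <- build_cube(peaklists, axes)
  plan <- data.frame(analysis = "csp", axis = "x",
                     stringsAsFactors = FALSE)
  if (isTRUE(config$observables$dpre)) {
    plan <- rbind(plan, data.frame(analysis = "dpre", axis = "z"))
  }
  if (isTRUE(config$fitting$enabled)) {
    plan <- rbind(plan, data.frame(analysis = "fitting", axis = "x"))
  }
  axis_policy_check(cube, plan)

  # ---- 3. curation along x -------------------------------------------------
  seq_in <- .cfg_sequence(config)
  x_series <- enumerate_series(cube, "x")
  x_norm <- lapply(x_series, function(s) {
    s$tables <- lapply(s$tables, function(t) {
      tag_sidechains(t, keep = keep_sc)$backbone
    })
    st <- scan_series(s, sequence = seq_in)
    runlog["residues_missing"] <<- runlog["residues_missing"] +
      sum(st$status == "missing")
    runlog["residues_unassigned"] <<- runlog["residues_unassigned"] +
      sum(st$status == "unassigned")
    pad_tables(s, st, fill_policy = config$curation$fill_policy)
  })
  # write padded tables back so z/y series reuse the normalized data
  for (s in x_norm) {
    for (j in seq_along(s$labels)) {
      coord <- c(z = unname(s$fixed[["z"]]), y = unname(s$fixed[["y"]]))
      cube$cells[[.cube_key(coord[["z"]], coord[["y"]], s$labels[j])]] <-
        s$tables[[j]]
    }
  }

  obs_cfg <- .cfg_obs(config)

  # ---- 4. x-axis observables ----------------------------------------------
  what <- c(if (isTRUE(config$observables$csp)) "csp",
            if (isTRUE(config$observables$height_ratio)) "height_ratio",
            if (isTRUE(config$observables$volume_ratio)) "volume_ratio")
  x_results <- lapply(x_norm, function(s) {
    if (!is.null(config$observables$shift_normalize)) {
      s <- shift_normalize(s, config$observables$shift_normalize)
    }
    if (length(what)) s <- compute_observables(s, obs_cfg, what = what)
    s
  })
  runlog["series_analysed"] <- length(x_results)
  for (s in x_results) {
    d <- output_dir(root, s$fixed[["z"]], s$fixed[["y"]], "peaklists")
    for (j in seq_along(s$labels)) {
      f <- file.path(d, paste0("x_", s$labels[j], ".csv"))
      write_canonical_csv(s$tables[[j]], f)
      note(f, s$fixed[["z"]], s$fixed[["y"]], "peaklists", "csv")
    }
  }

  # ---- 5. fitting ----------------------------------------------------------
  fits_by_series <- list()
  if (isTRUE(config$fitting$enabled)) {
    for (s in x_results) {
      fs <- fit_series(s, observable = config$fitting$observable %||% "csp",
                       model = config$fitting$model %||% "hill",
                       p0 = config$fitting$p0)
      sid <- paste0("z", s$fixed[["z"]], "_y", s$fixed[["y"]])
      fits_by_series[[sid]] <- fs
      d <- output_dir(root, s$fixed[["z"]], s$fixed[["y"]], "fits")
      f <- file.path(d, "fits.csv")
      utils::write.csv(fs$fits, f, row.names = FALSE, na = "")
      note(f, s$fixed[["z"]], s$fixed[["y"]], "fits", "csv")
      fc <- file.path(d, "fit_curves.csv")
      utils::write.csv(fs$curves, fc, row.names = FALSE, na = "")
      note(fc, s$fixed[["z"]], s$fixed[["y"]], "fits", "csv")
    }
  }

  # ---- 6. z-axis delta-PRE -------------------------------------------------
  z_results <- list()
  if (isTRUE(config$observables$dpre)) {
    pre_path <- config$observables$predicted_pre
    if (!grepl("^(/|[A-Za-z]:)", pre_path)) {
      pre_path <- file.path(base_dir, pre_path)
    }
    predicted <- read_predicted_pre(pre_path)
    z_series <- enumerate_series(cube, "z")
    z_results <- lapply(z_series, function(s) {
      compute_observables(s, obs_cfg, what = "dpre",
                          predicted_pre = predicted)
    })
    for (s in z_results) {
      d <- output_dir(root, "z_series", s$fixed[["y"]], "dpre")
      last <- s$tables[[length(s$tables)]]
      f <- file.path(d, paste0("dpre_x", s$fixed[["x"]], ".csv"))
      write_canonical_csv(last, f)
      note(f, "z_series", s$fixed[["y"]], "dpre", "csv")
    }
  }

  # ---- 7. comparative ------------------------------------------------------
  comparatives <- list()
  if (isTRUE(config$comparative$enabled) && length(z_results)) {
    comparatives <- compare_across(
      z_results, config$comparative$parameter %||% "dpre",
      config$comparative$present_along %||% "y")
    for (oc in names(comparatives)) {
      d <- output_dir(root, "comparative", oc,
                      comparatives[[oc]]$parameter)
      f <- write_comparative_csv(comparatives[[oc]], d)
      note(f, "comparative", oc, comparatives[[oc]]$parameter, "csv")
    }
  }

  # ---- 8. plots ------------------------------------------------------------
  templates <- unlist(config$plotting$templates)
  pc <- plot_config(threshold = config$observables$threshold,
                    format = config$plotting$format %||% "pdf",
                    dpi = config$plotting$dpi %||% 300)
  for (s in x_results) {
    d <- output_dir(root, s$fixed[["z"]], s$fixed[["y"]], "plots")
    produced <- render_all(list(s), templates, d, pc)
    runlog["figures_written"] <- runlog["figures_written"] + nrow(produced)
    for (i in seq_len(nrow(produced))) {
      note(produced$file[i], s$fixed[["z"]], s$fixed[["y"]], "plots",
           "figure")
      note(paste0(tools::file_path_sans_ext(produced$file[i]), "_data.csv"),
           s$fixed[["z"]], s$fixed[["y"]], "plots", "sidecar")
    }
  }

  # ---- 9. attribute files --------------------------------------------------
  for (attr_col in unlist(config$export$chimera)) {
    for (s in x_results) {
      last <- s$tables[[length(s$tables)]]
      if (!attr_col %in% names(last)) next
      d <- output_dir(root, s$fixed[["z"]], s$fixed[["y"]], "attributes")
      f <- file.path(d, paste0(attr_col, ".attr"))
      ok <- tryCatch({
        write_chimera_attributes(last$residue_number, last[[attr_col]],
                                 attr_col, f)
        TRUE
      }, error = function(e) {
        nc_log("attribute export skipped: ", conditionMessage(e),
               level = "warn")
        FALSE
      })
      if (ok) note(f, s$fixed[["z"]], s$fixed[["y"]], "attributes",
                   "chimera")
    }
  }

  # ---- 10. manifest + saved-back config ------------------------------------
  cfg_out <- file.path(root, "run_config.json")
  save_config(config, cfg_out)
  note(cfg_out, "", "", "config", "json")
  mdf <- do.call(rbind, manifest)
  write_manifest(mdf, root)
  nc_log("run complete: ", nrow(mdf), " file(s) in ", root)
  invisible(list(root = root, manifest = mdf, log = runlog,
                 results = list(x = x_results, z = z_results,
                                fits = fits_by_series,
                                comparative = comparatives)))
}
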