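# Synthetic dataset generators.  Every stage of the pipeline is testable
# against these: a fast-exchange ligand titration of a 100-residue protein
# (seven points, responding residues, a disappearing peak, unassigned
# prolines) and paramagnetic/diamagnetic experiment pairs with a known
# departure from a random-coil PRE profile.  All generators are
# seed-deterministic: the same spec yields byte-identical files.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic ligand titration
#'
#' Defaults emulate a seven-point titration (0 to 800 uM ligand) of a
#' 100-residue protein observed by HSQC: 30 responding residues in fast
#' exchange, residue 22 (a phenylalanine) disappearing from point 4
#' onward, and five prolines that are never observed.  Two Asn/Gln
#' sidechain NH2 rows are included to exercise sidechain tagging.
#'
#' @param n_residues protein length.
#' @param first_residue numbering offset.
#' @param x_points ligand concentrations, uM, increasing.
#' @param n_responders how many residues respond to ligand.
#' @param kd_range,csp_max_h_range,csp_max_x_range ranges the responder
#'   parameters are drawn from (uM / ppm / ppm).
#' @param disappearing residue number that vanishes, or `NULL`.
#' @param vanish_at 1-based series point at which it vanishes.
#' @param n_prolines number of unassigned prolines.
#' @param noise_sd_h,noise_sd_x Gaussian shift noise, ppm (1H / 15N).
#' @param noise_height_frac log-normal height noise (fractional sd).
#' @param seed RNG seed.
#' @return list of class `titration_spec`.
#' @export
titration_spec <- function(n_residues = 100, first_residue = 1,
                           x_points = c(0, 25, 50, 100, 200, 400, 800),
                           n_responders = 30,
                           kd_range = c(50, 300),
                           csp_max_h_range = c(0.05, 0.30),
                           csp_max_x_range = c(0.3, 1.5),
                           disappearing = 22, vanish_at = 4,
                           n_prolines = 5,
                           noise_sd_h = 0.002, noise_sd_x = 0.02,
                           noise_height_frac = 0.02,
                           seed = 1) {
  stopifnot(all(diff(x_points) > 0), all(x_points >= 0), n_residues >= 10)
  structure(as.list(environment()), class = "titration_spec")
}

#' Simulate a ligand titration dataset
#'
#' Chemical shifts follow the fast-exchange population-weighted average
#' `delta(x) = delta_free + fb(x) * delta_max` with
#' `fb(x) = x / (Kd + x)`.  The disappearing residue is absent from the
#' tables at and after its vanish point; unassigned residues (the
#' prolines) are absent from every table.  The returned ground truth
#' holds every drawn parameter so closed-loop recovery can be tested.
#'
#' @param spec a [titration_spec()].
#' @return list with `tables` (named list of `nmr_peaklist`, one per x
#'   point), `ground_truth` (data.frame), `sequence` (one-letter string),
#'   `x_points`, and `spec`.
#' @export
simulate_titration <- function(spec = titration_spec()) {
  stopifnot(inherits(spec, "titration_spec"))
  with_seed(spec$seed, {
    res <- seq(spec$first_residue, length.out = spec$n_residues)
    aa_pool <- setdiff(names(.aa3), "P")
    seq_aa <- sample(aa_pool, spec$n_residues, replace = TRUE)
    # place prolines away from the disappearing residue and termini
    candidates <- setdiff(seq_along(res)[-c(1, length(res))],
                          match(spec$disappearing, res))
    pro_idx <- sort(sample(candidates, spec$n_prolines))
    seq_aa[pro_idx] <- "P"
    if (!is.null(spec$disappearing)) {
      seq_aa[match(spec$disappearing, res)] <- "F"
    }
    observable <- setdiff(res, res[pro_idx])
    resp <- sort(sample(setdiff(observable, spec$disappearing),
                        spec$n_responders))
    kd <- stats::runif(spec$n_responders, spec$kd_range[1], spec$kd_range[2])
    dmax_h <- stats::runif(spec$n_responders, spec$csp_max_h_range[1],
                           spec$csp_max_h_range[2]) *
      sample(c(-1, 1), spec$n_responders, replace = TRUE)
    dmax_x <- stats::runif(spec$n_responders, spec$csp_max_x_range[1],
                           spec$csp_max_x_range[2]) *
      sample(c(-1, 1), spec$n_responders, replace = TRUE)
    h_free <- stats::rnorm(spec$n_residues, 8.25, 0.45)
    x_free <- stats::rnorm(spec$n_residues, 118, 4)
    base_height <- stats::rlnorm(spec$n_residues, log(1e7), 0.2)
    gt <- data.frame(
      residue_number = res, residue_type = seq_aa,
      responder = res %in% resp,
      kd = NA_real_, csp_max_h = NA_real_, csp_max_x = NA_real_,
      vanish_at = ifelse(res %in% spec$disappearing, spec$vanish_at,
                         NA_integer_),
      unassigned = res %in% res[pro_idx]
    )
    gt$kd[match(resp, res)] <- kd
    gt$csp_max_h[match(resp, res)] <- dmax_h
    gt$csp_max_x[match(resp, res)] <- dmax_x
    tables <- list()
    for (j in seq_along(spec$x_points)) {
      x <- spec$x_points[j]
      fb <- rep(0, spec$n_residues)
      ri <- match(resp, res)
      fb[ri] <- x / (kd + x)
      keep <- res %in% observable
      if (!is.null(spec$disappearing) && j >= spec$vanish_at) {
        keep <- keep & !(res %in% spec$disappearing)
      }
      n_keep <- sum(keep)
      dh <- rep(0, spec$n_residues)
      dx <- rep(0, spec$n_residues)
      dh[ri] <- fb[ri] * dmax_h
      dx[ri] <- fb[ri] * dmax_x
      tab <- data.frame(
        residue_number = res[keep],
        residue_type = seq_aa[keep],
        atom_f1 = "N", atom_f2 = "H",
        shift_f1 = x_free[keep] + dx[keep] +
          stats::rnorm(n_keep, 0, spec$noise_sd_x),
        shift_f2 = h_free[keep] + dh[keep] +
          stats::rnorm(n_keep, 0, spec$noise_sd_h),
        height = base_height[keep] *
          stats::rlnorm(n_keep, 0, spec$noise_height_frac),
        stringsAsFactors = FALSE
      )
      tab$volume <- tab$height * 2.5
      # two Asn/Gln sidechain NH2 rows, when such residues exist
      nq <- res[seq_aa %in% c("N", "Q") & res %in% observable][1:2]
      nq <- nq[!is.na(nq)]
      if (length(nq)) {
        sc <- data.frame(
          residue_number = nq,
          residue_type = seq_aa[match(nq, res)],
          atom_f1 = ifelse(seq_aa[match(nq, res)] == "N", "ND2a", "NE2a"),
          atom_f2 = ifelse(seq_aa[match(nq, res)] == "N", "HD2a", "HE2a"),
          shift_f1 = 112.5 + 0.01 * seq_along(nq),
          shift_f2 = 7.1 + 0.01 * seq_along(nq),
          height = 5e6, volume = 1.25e7,
          stringsAsFactors = FALSE
        )
        tab <- rbind(tab, sc)
      }
      tables[[as.character(x)]] <- peaklist(tab, source_format = "sparky")
    }
    list(tables = tables, ground_truth = gt,
         sequence = paste(seq_aa, collapse = ""),
         x_points = spec$x_points, spec = spec)
  })
}

#' Specification of a synthetic paramagnetic/diamagnetic pair
#'
#' Defaults emulate a spin label at residue 10 of a 100-residue
#' disordered chain: the random-coil part of the intensity-ratio profile
#' is a Gaussian broadening well around the probe site, and
#' `deviation_regions` add extra broadening (transient contacts) the
#' random-coil prediction does not contain — that extra signal is the
#' delta-PRE ground truth.
#'
#' @param n_residues chain length.
#' @param first_residue numbering offset.
#' @param probe_site residue carrying the paramagnetic centre.
#' @param broadening_width Gaussian width of the probe well, residues.
#' @param depth ratio reduction at the probe site (0..1).
#' @param baseline_ratio para/dia ratio far from the probe.
#' @param deviation_regions list of `list(range = c(lo, hi),
#'   depth = d)`: extra ratio reduction over a residue range.
#' @param noise_height_frac log-normal height noise (fractional sd).
#' @param seed RNG seed.
#' @return list of class `pre_spec`.
#' @export
pre_spec <- function(n_residues = 100, first_residue = 1,
                     probe_site = 10, broadening_width = 8,
                     depth = 0.9, baseline_ratio = 0.95,
                     deviation_regions = list(),
                     noise_height_frac = 0.02,
                     seed = 1) {
  stopifnot(depth >= 0, depth <= 1, baseline_ratio >= 0, baseline_ratio <= 1)
  structure(as.list(environment()), class = "pre_spec")
}

#' Simulate one paramagnetic/diamagnetic experiment pair
#'
#' @param spec a [pre_spec()].
#' @return list with `dia` and `para` (`nmr_peaklist`s), `predicted`
#'   (data.frame `residue_number`, `ratio`: the random-coil part only),
#'   `true_ratio` (observed, noiseless), `ground_truth` (data.frame with
#'   the deviation signal = expected delta-PRE) and `spec`.
#' @export
simulate_pre_pair <- function(spec = pre_spec()) {
  stopifnot(inherits(spec, "pre_spec"))
  with_seed(spec$seed, {
    res <- seq(spec$first_residue, length.out = spec$n_residues)
    rc <- spec$baseline_ratio *
      (1 - spec$depth * exp(-(res - spec$probe_site)^2 /
                              (2 * spec$broadening_width^2)))
    deviation <- rep(0, spec$n_residues)
    for (reg in spec$deviation_regions) {
      inside <- res >= reg$range[1] & res <= reg$range[2]
      deviation[inside] <- deviation[inside] + reg$depth
    }
    true_ratio <- pmin(pmax(rc - deviation, 0), 1)
    aa <- sample(setdiff(names(.aa3), "P"), spec$n_residues, replace = TRUE)
    h <- stats::rnorm(spec$n_residues, 8.25, 0.45)
    x <- stats::rnorm(spec$n_residues, 118, 4)
    base_height <- stats::rlnorm(spec$n_residues, log(1e7), 0.2)
    mk <- function(height) {
      peaklist(data.frame(
        residue_number = res, residue_type = aa,
        atom_f1 = "N", atom_f2 = "H",
        shift_f1 = x, shift_f2 = h,
        height = height, volume = height * 2.5,
        stringsAsFactors = FALSE
      ), source_format = "sparky")
    }
    dia <- mk(base_height *
                stats::rlnorm(spec$n_residues, 0, spec$noise_height_frac))
    para <- mk(base_height * true_ratio *
                 stats::rlnorm(spec$n_residues, 0, spec$noise_height_frac))
    list(
      dia = dia, para = para,
      predicted = data.frame(residue_number = res, ratio = rc),
      true_ratio = data.frame(residue_number = res, ratio = true_ratio),
      ground_truth = data.frame(residue_number = res, deviation = deviation),
      spec = spec
    )
  })
}

#' Write a simulated titration to disk in a chosen dialect
#'
#' Emits one peaklist file per titration point plus `ground_truth.csv`
#' and a ready-to-run JSON configuration, so the full pipeline can be
#' exercised from files alone.
#'
#' @param sim result of [simulate_titration()].
#' @param dir output directory (created).
#' @param dialect peaklist dialect to write.
#' @return invisible list with `paths`, `config_path`.
#' @export
write_titration_fixture <- function(sim, dir, dialect = "sparky") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- c(sparky = "list", nmrpipe = "tab", ccpnv2 = "csv",
           nmrview = "xpk")[[dialect]]
  paths <- character(0)
  manifest <- list()
  for (lab in names(sim$tables)) {
    p <- file.path(dir, sprintf("titration_%s.%s", lab, ext))
    write_peaklist(sim$tables[[lab]], p, dialect = dialect)
    paths[lab] <- p
    manifest[[length(manifest) + 1]] <-
      list(z = "A", y = "prot", x = lab, path = basename(p))
  }
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, na = "")
  config <- list(
    axes = list(x = names(sim$tables), y = "prot", z = "A"),
    peaklists = manifest,
    sequence = list(first = sim$spec$first_residue, seq = sim$sequence),
    curation = list(fill_policy = "carry_last", sidechains = "drop"),
    observables = list(csp = TRUE, height_ratio = TRUE),
    fitting = list(enabled = TRUE, model = "hill"),
    plotting = list(templates = list("bar_extended"), format = "pdf"),
    output = list(root = "output")
  )
  config_path <- file.path(dir, "run_config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, config_path = config_path))
}
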