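# Figure templates: the test surface is the sidecar tables plus figure
# existence/non-emptiness; pixel content is never asserted.

obs_series <- function() {
  sim <- small_titration()
  compute_observables(series_from_sim(sim), what = c("csp", "height_ratio"))
}

test_that("bar templates plot one bar per residue with status colours", {
  s <- obs_series()
  last <- s$tables[[7]]
  d <- withr::local_tempdir()
  for (tmpl in c("bar_extended", "bar_compacted", "bar_vertical")) {
    fig <- file.path(d, paste0(tmpl, ".pdf"))
    out <- render(tmpl, last, plot_config(threshold = 0.05), fig)
    expect_true(file.exists(out$figure) && file.size(out$figure) > 0)
    side <- utils::read.csv(out$sidecar)
    expect_equal(nrow(side), nrow(last))           # bar count = universe
    expect_equal(side$residue_number, last$residue_number)
    expect_identical(side$status, last$status)
    expect_equal(side$value, last$csp)
  }
})

test_that("scatter and trajectory templates export exactly what they draw", {
  s <- obs_series()
  d <- withr::local_tempdir()
  out <- render("scatter_shift_map", s$tables[[7]], plot_config(),
                file.path(d, "map.pdf"))
  side <- utils::read.csv(out$sidecar)
  last <- s$tables[[7]]
  ok <- !is.na(last$delta_h)
  expect_equal(side$delta_h, last$delta_h[ok])

  out2 <- render("scatter_trajectory", s, plot_config(),
                 file.path(d, "traj.pdf"))
  side2 <- utils::read.csv(out2$sidecar)
  expect_equal(sort(unique(side2$point)), sort(as.integer(s$labels)))
})

test_that("heat map sidecar equals the comparative matrix cell for cell", {
  a <- data.frame(residue_number = 1:6, value = c(1, 2, NA, 4, 5, 6) / 10)
  b <- data.frame(residue_number = 1:6, value = 6:1 / 10)
  ct <- stack_series(list(v1 = a, v2 = b), "dpre", "z", "y")
  d <- withr::local_tempdir()
  out <- render("heat_map", ct, plot_config(), file.path(d, "hm.pdf"))
  side <- utils::read.csv(out$sidecar, check.names = FALSE)
  expect_equal(side$v1, unname(ct$matrix[, "v1"]))
  expect_equal(side$v2, unname(ct$matrix[, "v2"]))
})

test_that("dpre profile overlays predicted, observed and smoothed traces", {
  pair <- simulate_pre_pair(pre_spec(
    n_residues = 60, deviation_regions = list(list(range = c(30, 40),
                                                   depth = 0.4))))
  obs <- intensity_ratio(pair$dia, pair$para, "height")
  dp <- dpre(obs, pair$predicted)
  df <- data.frame(residue_number = pair$predicted$residue_number,
                   predicted = pair$predicted$ratio,
                   observed = obs$ratio,
                   dpre = dp$dpre,
                   smoothed_dpre = gaussian_smooth(dp$dpre,
                                                   dp$residue_number))
  d <- withr::local_tempdir()
  out <- render("dpre_profile", df, plot_config(), file.path(d, "pre.pdf"))
  side <- utils::read.csv(out$sidecar)
  expect_equal(names(side), c("residue_number", "predicted", "observed",
                              "dpre", "smoothed_dpre"))
  expect_equal(side$smoothed_dpre, df$smoothed_dpre)
})

test_that("residue evolution renders one trace per residue with data", {
  s <- obs_series()
  d <- withr::local_tempdir()
  out <- render("residue_evolution", s,
                plot_config(width = 12, height = 12),
                file.path(d, "evo.pdf"))
  side <- utils::read.csv(out$sidecar)
  with_data <- unique(side$residue_number)
  expect_equal(length(unique(side$point)), 7)
  expect_true(all(table(side$residue_number) == 7))
  # prolines (never any data) are excluded
  st <- attr(s, "status")
  pro <- as.integer(names(which(st$types == "P")))
  expect_false(any(pro %in% with_data))
})

test_that("render errors cleanly on empty or incomplete data", {
  expect_error(render("bar_extended", peaklist(), plot_config(), "x.pdf"),
               "nothing to plot")
  s <- obs_series()
  t <- s$tables[[7]]
  t$csp <- NULL
  d <- withr::local_tempdir()
  expect_error(render("bar_extended", t, plot_config(),
                      file.path(d, "f.pdf")), "csp")
})

test_that("render_all produces the requested figure count and sidecars", {
  s <- obs_series()
  d <- withr::local_tempdir()
  produced <- suppressMessages(render_all(
    list(s), c("bar_extended", "scatter_shift_map"), d, plot_config()))
  expect_equal(nrow(produced), 2)
  expect_true(all(file.exists(produced$file)))
  # sidecar re-read reproduces the rendered values
  for (f in produced$file) {
    sc <- paste0(tools::file_path_sans_ext(f), "_data.csv")
    expect_true(file.exists(sc))
    expect_gt(nrow(utils::read.csv(sc)), 0)
  }
  expect_message(none <- render_all(list(s), character(0), d),
                 "zero figures")
  expect_equal(nrow(none), 0)
  # png output works too
  produced_png <- suppressMessages(render_all(
    list(s), "bar_extended", d, plot_config(format = "png")))
  expect_true(file.size(produced_png$file[1]) > 0)
})

test_that("sidecar tables are identical across repeated renders", {
  s <- obs_series()
  d <- withr::local_tempdir()
  r1 <- render("bar_extended", s$tables[[7]], plot_config(),
               file.path(d, "a.pdf"))
  r2 <- render("bar_extended", s$tables[[7]], plot_config(),
               file.path(d, "b.pdf"))
  expect_identical(readLines(r1$sidecar), readLines(r2$sidecar))
})
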