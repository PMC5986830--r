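# Derived parameters: shift deltas, combined CSP, intensity ratios,
# delta-PRE, Gaussian smoothing, shift normalization.

test_that("delta_shifts subtracts the reference per nucleus", {
  ref <- mini_peaklist()
  tgt <- mini_peaklist(shift_f1 = c(110.1, 108.5, 112.3) + 0.5,
                       shift_f2 = c(8.30, 8.90, 7.75))
  d <- delta_shifts(ref, tgt)
  expect_equal(d$delta_h, c(0.10, 0, 0))
  expect_equal(d$delta_x, c(0.5, 0.5, 0.5))
  expect_equal(delta_shifts(ref, ref)$delta_h, c(0, 0, 0))
  bad <- mini_peaklist(residues = c(10L, 11L, 13L))
  expect_error(delta_shifts(ref, bad), "curation contract")
})

test_that("combined_csp matches the closed form and its reductions", {
  # hand arithmetic: sqrt(0.5*(0.10^2 + (0.14*1.00)^2))
  expect_equal(combined_csp(0.10, 1.00, 0.14),
               0.121655250605964, tolerance = 1e-12)
  expect_equal(combined_csp(0, 0), 0)
  d <- 0.37
  expect_equal(combined_csp(d, 0), abs(d) / sqrt(2), tolerance = 1e-14)
  expect_equal(combined_csp(0, d, 0.2), 0.2 * abs(d) / sqrt(2),
               tolerance = 1e-14)
})

test_that("csp is non-decreasing in |delta_h| and |delta_x|", {
  set.seed(42)
  for (i in 1:200) {
    dh <- stats::rnorm(1, 0, 0.1); dx <- stats::rnorm(1, 0, 1)
    a <- stats::runif(1, 0.05, 0.3)
    base <- combined_csp(dh, dx, a)
    expect_gte(combined_csp(dh * 1.5, dx, a), base)
    expect_gte(combined_csp(dh, dx * 1.5, a), base)
  }
})

test_that("glycine gets its own alpha through the per-type map", {
  tab <- mini_peaklist()  # types A, G, T
  a <- nmrcube:::.alpha_for(tab$residue_type, c(default = 0.14, G = 0.2))
  expect_equal(a, c(0.14, 0.2, 0.14))
})

test_that("intensity ratios guard against zero/absent references", {
  ref <- mini_peaklist(height = c(2e6, 0, NA))
  tgt <- mini_peaklist(height = c(1e6, 5e5, 1e6))
  expect_warning(r <- intensity_ratio(ref, tgt, "height"), "zero reference")
  expect_equal(r$ratio, c(0.5, NA, NA))
  same <- intensity_ratio(mini_peaklist(), mini_peaklist(), "height")
  expect_equal(same$ratio, c(1, 1, 1))
  expect_false(any(is.infinite(r$ratio), na.rm = TRUE))
})

test_that("dpre follows the predicted-minus-observed convention", {
  prof <- function(r) data.frame(residue_number = 1:5, ratio = r)
  p <- prof(c(0.3, 0.5, 0.9, 0.95, 0.95))
  expect_equal(dpre(p, p)$dpre, rep(0, 5))
  obs <- prof(c(0.5, 0.5, 0.9, 0.95, 0.95))
  d <- dpre(obs, p)
  expect_equal(d$dpre[1], -0.2)   # predicted 0.3, observed 0.5
  # antisymmetry under swapping the two profiles
  expect_equal(dpre(p, obs)$dpre, -d$dpre)
  # sign flip
  expect_equal(dpre(obs, p, sign = -1)$dpre, -d$dpre)
  # residue in one profile only -> empty with warning
  obs2 <- obs[-3, ]
  expect_warning(d2 <- dpre(obs2, p), "only one")
  expect_true(is.na(d2$dpre[d2$residue_number == 3]))
})

test_that("gaussian_smooth matches the impulse closed form", {
  # impulse [0,0,1,0,0], sigma = 1, halfwidth = 2:
  # centre = 1 / (1 + 2 exp(-1/2) + 2 exp(-2))
  out <- gaussian_smooth(c(0, 0, 1, 0, 0), sigma = 1, halfwidth = 2)
  S <- 1 + 2 * exp(-0.5) + 2 * exp(-2)
  expect_equal(out[3], 1 / S, tolerance = 1e-14)
  # edge cell renormalizes over the available window
  expect_equal(out[1], exp(-2) / (1 + exp(-0.5) + exp(-2)),
               tolerance = 1e-14)
})

test_that("gaussian_smooth conserves constants and is the identity at hw->0", {
  v <- rep(3.7, 20)
  expect_equal(gaussian_smooth(v, sigma = 3), v)
  x <- stats::rnorm(15)
  expect_equal(gaussian_smooth(x, sigma = 1e-9, halfwidth = 1), x,
               tolerance = 1e-12)
})

test_that("gaussian_smooth is linear and range-bounded", {
  set.seed(7)
  res <- sort(sample(1:40, 25))
  u <- stats::rnorm(25); v <- stats::rnorm(25)
  a <- 2.5; b <- -1.2
  lhs <- gaussian_smooth(a * u + b * v, res, sigma = 2)
  rhs <- a * gaussian_smooth(u, res, sigma = 2) +
    b * gaussian_smooth(v, res, sigma = 2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  s <- gaussian_smooth(u, res, sigma = 2)
  expect_true(all(s >= min(u) - 1e-12 & s <= max(u) + 1e-12))
})

test_that("gaussian_smooth agrees with a brute-force kernel sum over gaps", {
  brute <- function(values, residues, sigma, hw) {
    out <- rep(NA_real_, length(values))
    for (i in seq_along(values)) {
      if (is.na(values[i])) next
      num <- 0; den <- 0
      for (j in -hw:hw) {
        k <- match(residues[i] + j, residues)
        if (!is.na(k) && !is.na(values[k])) {
          w <- exp(-j^2 / (2 * sigma^2))
          num <- num + w * values[k]
          den <- den + w
        }
      }
      out[i] <- num / den
    }
    out
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    residues <- sort(sample(1:60, n))
    values <- stats::rnorm(n)
    values[sample(n, ceiling(n / 6))] <- NA
    sigma <- stats::runif(1, 0.5, 4)
    hw <- sample(1:8, 1)
    expect_equal(gaussian_smooth(values, residues, sigma, hw),
                 brute(values, residues, sigma, hw), tolerance = 1e-12)
  }
})

test_that("shift_normalize removes a global per-spectrum offset", {
  sim <- simulate_titration(titration_spec(
    n_residues = 20, n_responders = 4, n_prolines = 0, disappearing = NULL,
    noise_sd_h = 0, noise_sd_x = 0, seed = 5))
  s <- series_from_sim(sim)
  ref_res <- setdiff(s$tables[[1]]$residue_number,
                     sim$ground_truth$residue_number[
                       sim$ground_truth$responder])[1]
  clean <- compute_observables(s, what = "csp")
  # inject a per-spectrum artefact
  art <- s
  for (j in 2:length(art$tables)) {
    art$tables[[j]]$shift_f2 <- art$tables[[j]]$shift_f2 + 0.02
    art$tables[[j]]$shift_f1 <- art$tables[[j]]$shift_f1 + 0.1
  }
  fixed <- compute_observables(shift_normalize(art, ref_res), what = "csp")
  for (j in seq_along(clean$tables)) {
    expect_equal(fixed$tables[[j]]$csp, clean$tables[[j]]$csp,
                 tolerance = 1e-10)
  }
  # reference residue CSP is exactly zero at every point
  for (j in seq_along(fixed$tables)) {
    t <- fixed$tables[[j]]
    expect_equal(t$csp[t$residue_number == ref_res], 0)
  }
  # idempotence
  twice <- shift_normalize(shift_normalize(art, ref_res), ref_res)
  once <- shift_normalize(art, ref_res)
  for (j in seq_along(once$tables)) {
    expect_equal(twice$tables[[j]]$shift_f2, once$tables[[j]]$shift_f2)
  }
  # missing reference residue -> error listing points
  s2 <- s
  t4 <- s2$tables[[4]]
  s2$tables[[4]] <- t4[t4$residue_number != ref_res, , drop = FALSE]
  expect_error(shift_normalize(s2, ref_res), as.character(s$labels[4]))
})

test_that("compute_observables appends columns and blanks unassigned rows", {
  sim <- small_titration()
  s <- series_from_sim(sim)
  so <- compute_observables(s, what = c("csp", "height_ratio"))
  last <- so$tables[[7]]
  expect_true(all(c("delta_h", "delta_x", "csp", "height_ratio") %in%
                    names(last)))
  expect_true(all(is.na(last$csp[last$status == "unassigned"])))
  expect_true(all(last$csp[last$status == "measured"] >= 0))
  # reference table: zero deltas, unit ratios on measured rows
  first <- so$tables[[1]]
  meas <- first$status == "measured"
  expect_equal(first$csp[meas], rep(0, sum(meas)))
  expect_equal(first$height_ratio[meas], rep(1, sum(meas)))
})

test_that("csp grows monotonically along a saturating titration (noiseless)", {
  sim <- simulate_titration(titration_spec(
    n_residues = 30, n_responders = 10, n_prolines = 0, disappearing = NULL,
    noise_sd_h = 0, noise_sd_x = 0, seed = 8))
  so <- compute_observables(series_from_sim(sim), what = "csp")
  mat <- vapply(so$tables, `[[`, numeric(30), "csp")
  for (i in seq_len(nrow(mat))) {
    expect_true(all(diff(mat[i, ]) >= -1e-12))
  }
})
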