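# Missing/unassigned scanning, padding, sidechain tagging.

test_that("scan_series classifies measured, missing and unassigned", {
  sim <- small_titration()
  s <- series_from_sim(sim, pad = FALSE)
  st <- scan_series(s, sequence = list(first = 1, seq = sim$sequence))
  gt <- sim$ground_truth
  pro <- gt$residue_number[gt$unassigned]
  expect_equal(length(st$universe), 40)
  # disappearing residue: measured 1..3, missing 4..7
  expect_equal(unname(st$status["22", ]),
               c(rep("measured", 3), rep("missing", 4)))
  expect_equal(unname(st$filled_from["22", 4:7]), rep(s$labels[3], 4))
  # prolines unassigned everywhere
  for (p in pro) {
    expect_true(all(st$status[as.character(p), ] == "unassigned"))
  }
  # statuses partition the universe in every table
  counts <- apply(st$status, 2, function(col) table(factor(
    col, levels = c("measured", "missing", "unassigned"))))
  expect_true(all(colSums(counts) == length(st$universe)))
})

test_that("without a sequence the universe is the union over the series", {
  sim <- small_titration()
  s <- series_from_sim(sim, pad = FALSE)
  st <- scan_series(s)
  expect_equal(length(st$universe), 40 - sum(sim$ground_truth$unassigned))
  expect_false(any(st$status == "unassigned"))
})

test_that("conflicting backbone rows raise a curation error", {
  dup <- peaklist(data.frame(
    residue_number = c(10L, 10L), residue_type = "A",
    atom_f1 = "N", atom_f2 = "H",
    shift_f1 = c(110, 111), shift_f2 = c(8.1, 8.2), height = 1e6))
  s <- series_from_sim(small_titration(), pad = FALSE)
  s$tables[[2]] <- dup
  expect_error(scan_series(s), "conflicting backbone rows")
})

test_that("pad_tables yields identical residue indices and carries last values", {
  sim <- small_titration()
  s <- series_from_sim(sim, pad = FALSE)
  st <- scan_series(s, sequence = list(first = 1, seq = sim$sequence))
  sn <- pad_tables(s, st)
  counts <- vapply(sn$tables, nrow, integer(1))
  expect_true(all(counts == length(st$universe)))
  idx <- lapply(sn$tables, `[[`, "residue_number")
  for (j in 2:7) expect_identical(idx[[j]], idx[[1]])
  # carry_last: the missing residue's row copies its last measured shifts
  t3 <- sn$tables[[3]]; t5 <- sn$tables[[5]]
  expect_identical(t5$status[t5$residue_number == 22], "missing")
  expect_equal(t5$shift_f2[t5$residue_number == 22],
               t3$shift_f2[t3$residue_number == 22])
  expect_equal(t5$height[t5$residue_number == 22],
               t3$height[t3$residue_number == 22])
  # unassigned rows have empty observables but typed "P"
  pro <- sim$ground_truth$residue_number[sim$ground_truth$unassigned][1]
  r <- t5[t5$residue_number == pro, ]
  expect_identical(r$status, "unassigned")
  expect_identical(r$residue_type, "P")
  expect_true(is.na(r$shift_f1) && is.na(r$height))
})

test_that("blank fill policy leaves missing observables empty", {
  sim <- small_titration()
  s <- series_from_sim(sim, pad = FALSE)
  sn <- pad_tables(s, fill_policy = "blank",
                   sequence = list(first = 1, seq = sim$sequence))
  t5 <- sn$tables[[5]]
  expect_identical(t5$status[t5$residue_number == 22], "missing")
  expect_true(is.na(t5$shift_f2[t5$residue_number == 22]))
})

test_that("carry-last fill is causal", {
  # residue absent at point 2 only: filled from point 1, not point 3
  mk <- function(res, sh, x) {
    t <- peaklist(data.frame(
      residue_number = res, residue_type = "A", atom_f1 = "N", atom_f2 = "H",
      shift_f1 = 110 + sh, shift_f2 = 8 + sh, height = 1e6))
    attr(t, "coordinate") <- c("z", "y", x)
    t
  }
  pls <- list(mk(c(1L, 2L), 0.0, "a"), mk(1L, 0.1, "b"),
              mk(c(1L, 2L), 0.2, "c"))
  cube <- build_cube(pls, list(x = axis_spec("x", c("a", "b", "c")),
                               y = axis_spec("y", "y"),
                               z = axis_spec("z", "z")))
  s <- enumerate_series(cube, "x")[[1]]
  sn <- pad_tables(s)
  t2 <- sn$tables[[2]]
  expect_equal(t2$shift_f2[t2$residue_number == 2], 8.0)  # from point 1
})

test_that("pad_tables is idempotent and a no-op on uniform series", {
  sim <- small_titration()
  s <- series_from_sim(sim, pad = FALSE)
  sn1 <- pad_tables(s, sequence = list(first = 1, seq = sim$sequence))
  sn2 <- pad_tables(sn1, sequence = list(first = 1, seq = sim$sequence))
  for (j in seq_along(sn1$tables)) {
    expect_equal(as.data.frame(sn2$tables[[j]]),
                 as.data.frame(sn1$tables[[j]]), ignore_attr = TRUE)
  }
  # uniform series: padding only adds the (all-measured) status column
  uni <- series_from_sim(simulate_titration(titration_spec(
    n_residues = 20, n_responders = 4, n_prolines = 0, disappearing = NULL,
    seed = 3)), pad = FALSE)
  un <- pad_tables(uni)
  for (j in seq_along(un$tables)) {
    expect_true(all(un$tables[[j]]$status == "measured"))
    expect_equal(un$tables[[j]]$shift_f1, uni$tables[[j]]$shift_f1)
  }
})

test_that("tag_sidechains flags NH2 rows and drop mode logs the count", {
  sim <- small_titration()
  tab <- sim$tables[[1]]
  parts <- tag_sidechains(tab, keep = TRUE)
  expect_equal(nrow(parts$sidechain), 2)
  expect_true(all(grepl("[ab]$", parts$sidechain$atom_f1)))
  expect_false(any(grepl("[ab]$", parts$backbone$atom_f1)))
  expect_message(tag_sidechains(tab, keep = FALSE), "2 sidechain")
  # backbone N/H rows are never flagged
  bb <- mini_peaklist()
  expect_equal(nrow(tag_sidechains(bb)$sidechain), 0)
})
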