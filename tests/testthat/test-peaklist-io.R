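# Parsing of the supported peaklist dialects and canonical CSV round trips.

test_that("detect_format recognises every dialect golden", {
  expect_identical(detect_format(readLines(fixture_path("golden.list"))),
                   "sparky")
  expect_identical(detect_format(readLines(fixture_path("golden.tab"))),
                   "nmrpipe")
  expect_identical(detect_format(readLines(fixture_path("golden_ccpn.csv"))),
                   "ccpnv2")
  expect_identical(detect_format(readLines(fixture_path("golden.xpk"))),
                   "nmrview")
  expect_identical(detect_format(readLines(fixture_path("golden.ansig"))),
                   "ansig")
})

test_that("detect_format rejects unknown content naming a candidate", {
  expect_error(detect_format("some random text\n1 2 3"),
               "unrecognized format")
  expect_error(detect_format("w1 w2 but nothing else"),
               "closest candidate: sparky")
  expect_error(detect_format("   \n"), "empty")
})

test_that("sparky golden parses to hand-checked values", {
  t <- parse_peaklist(fixture_path("golden.list"))
  expect_s3_class(t, "nmr_peaklist")
  expect_equal(nrow(t), 3)
  r <- t[t$residue_number == 103, ]
  expect_identical(r$residue_type, "T")
  expect_identical(r$atom_f1, "N")
  expect_identical(r$atom_f2, "H")
  expect_equal(r$shift_f1, 110.112)
  expect_equal(r$shift_f2, 8.221)
  expect_equal(r$height, 1.2e7)
  expect_equal(r$volume, 3.4e7)
  expect_true(all(t$status == "measured"))
  # sidechain NH2 row kept with its suffixed atom names
  sc <- t[t$residue_number == 57, ]
  expect_identical(sc$atom_f1, "ND2a")
  expect_identical(sc$atom_f2, "HD2a")
})

test_that("nmrpipe golden maps X to 1H and Y to the heteronucleus", {
  t <- parse_peaklist(fixture_path("golden.tab"))
  expect_equal(nrow(t), 2)
  r <- t[t$residue_number == 103, ]
  expect_equal(r$shift_f1, 110.112)  # Y_PPM
  expect_equal(r$shift_f2, 8.221)    # X_PPM
  expect_equal(r$linewidth_f1, 18.00)
  expect_equal(r$linewidth_f2, 20.50)
  expect_equal(r$height, 1.2e7)
})

test_that("ccpnv2 golden preserves annotations verbatim and empty optionals", {
  t <- parse_peaklist(fixture_path("golden_ccpn.csv"))
  r103 <- t[t$residue_number == 103, ]
  expect_identical(r103$merit, "1.0")
  expect_identical(r103$details, "alt assignment 48R")
  expect_identical(r103$fit_method, "parabolic")
  expect_equal(r103$linewidth_f1, 18.0)
  r45 <- t[t$residue_number == 45, ]
  expect_identical(r45$residue_type, "G")
  expect_true(is.na(r45$linewidth_f1))  # empty column stays empty
  expect_true(is.na(r45$details))
})

test_that("nmrview golden parses labels, shifts and intensities", {
  t <- parse_peaklist(fixture_path("golden.xpk"))
  expect_equal(t$residue_number, c(45L, 103L))
  expect_equal(t$residue_type, c("G", "T"))
  expect_equal(t$shift_f1, c(108.5, 110.112))
  expect_equal(t$height, c(9.0e6, 1.2e7))
  expect_equal(t$volume, c(2.1e7, 3.4e7))
  expect_true(all(is.na(t$linewidth_f1)))  # not carried by this dialect
})

test_that("ansig is a stub that raises 'unsupported dialect'", {
  expect_error(parse_peaklist(fixture_path("golden.ansig")),
               "unsupported dialect")
})

test_that("empty and malformed inputs fail informatively", {
  p <- withr::local_tempfile(fileext = ".list")
  writeLines("", p)
  expect_warning(t0 <- parse_peaklist(p, format = "sparky"), "empty")
  expect_equal(nrow(t0), 0)

  writeLines(c("Assignment w1 w2", "XYZ999N-H 1.0 2.0"), p)
  expect_error(parse_peaklist(p, format = "sparky"), "line 2")
  writeLines(c("Assignment w1 w2", "T103N-H 110.1"), p)
  expect_error(parse_peaklist(p, format = "sparky"), "line 2")
})

test_that("assignment grammar accepts documented forms and rejects others", {
  a <- nmrcube:::parse_assignment("T103N-H")
  expect_equal(a$residue_number, 103L)
  expect_identical(a$residue_type, "T")
  b <- nmrcube:::parse_assignment("Gly45HN")
  expect_identical(b$residue_type, "G")
  expect_identical(b$atom_f1, "HN")
  expect_error(nmrcube:::parse_assignment("45Gly"), "45Gly")
  expect_error(nmrcube:::parse_assignment("Xyz9N"), "Xyz9N")
  expect_error(nmrcube:::parse_assignment("B12N-H"), "B12N-H")  # not an AA
})

test_that("canonical CSV round-trips every dialect golden exactly", {
  goldens <- c("golden.list", "golden.tab", "golden_ccpn.csv", "golden.xpk")
  for (g in goldens) {
    t1 <- parse_peaklist(fixture_path(g))
    p <- withr::local_tempfile(fileext = ".csv")
    write_canonical_csv(t1, p)
    t2 <- parse_peaklist(p, format = "canonical")
    expect_equal(as.data.frame(t2), as.data.frame(t1), ignore_attr = TRUE,
                 info = g)
  }
})

test_that("derived columns survive the canonical round trip", {
  t <- parse_peaklist(fixture_path("golden.tab"))
  t$csp <- c(0.01, 0.25)
  p <- withr::local_tempfile(fileext = ".csv")
  write_canonical_csv(t, p)
  hdr <- strsplit(readLines(p, n = 1), ",")[[1]]
  expect_true("\"csp\"" %in% hdr || "csp" %in% hdr)
  t2 <- parse_peaklist(p, format = "canonical")
  expect_equal(t2$csp, t$csp)
})

test_that("parsing is insensitive to input peak-line order", {
  lines <- readLines(fixture_path("golden.list"))
  p <- withr::local_tempfile(fileext = ".list")
  writeLines(c(lines[1:2], rev(lines[-(1:2)])), p)
  shuffled <- parse_peaklist(p, format = "sparky")
  original <- parse_peaklist(fixture_path("golden.list"))
  expect_equal(as.data.frame(shuffled), as.data.frame(original),
               ignore_attr = TRUE)
})

test_that("dialect writers round-trip a synthetic table through each parser", {
  sim <- small_titration()
  src <- sim$tables[[3]]
  for (d in c("sparky", "nmrpipe", "ccpnv2", "nmrview")) {
    p <- withr::local_tempfile()
    write_peaklist(src, p, dialect = d)
    back <- parse_peaklist(p)
    expect_identical(attr(back, "source_format"), d)
    expect_equal(back$residue_number, src$residue_number, info = d)
    expect_equal(back$shift_f1, src$shift_f1, tolerance = 1e-3, info = d)
    expect_equal(back$height, src$height, tolerance = 1e-6, info = d)
  }
})

test_that("status column distinguishes measured/missing/unassigned on export", {
  sim <- small_titration()
  s <- series_from_sim(sim)
  tab <- s$tables[[5]]
  p <- withr::local_tempfile(fileext = ".csv")
  write_canonical_csv(tab, p)
  back <- parse_peaklist(p, format = "canonical")
  expect_setequal(unique(back$status),
                  c("measured", "missing", "unassigned"))
  expect_equal(back$status, tab$status)
})
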