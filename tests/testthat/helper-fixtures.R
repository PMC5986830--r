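# Shared helpers: tiny in-code peaklists and cubes.

mini_peaklist <- function(residues = c(10L, 11L, 12L),
                          types = c("A", "G", "T"),
                          shift_f1 = c(110.1, 108.5, 112.3),
                          shift_f2 = c(8.20, 8.90, 7.75),
                          height = c(2e6, 1.5e6, 3e6)) {
  peaklist(data.frame(
    residue_number = residues, residue_type = types,
    atom_f1 = "N", atom_f2 = "H",
    shift_f1 = shift_f1, shift_f2 = shift_f2,
    height = height, volume = height * 2,
    stringsAsFactors = FALSE
  ))
}

# dense cube of n x m x k trivial tables
mini_cube <- function(nx, ny, nz, table = mini_peaklist()) {
  xs <- paste0("x", seq_len(nx))
  ys <- paste0("y", seq_len(ny))
  zs <- paste0("z", seq_len(nz))
  pls <- list()
  for (z in zs) for (y in ys) for (x in xs) {
    t <- table
    attr(t, "coordinate") <- c(z, y, x)
    pls[[length(pls) + 1]] <- t
  }
  build_cube(pls, list(x = axis_spec("x", xs), y = axis_spec("y", ys),
                       z = axis_spec("z", zs)))
}

# a small titration series (quiet generator defaults scaled down)
small_titration <- function(seed = 11, ...) {
  simulate_titration(titration_spec(
    n_residues = 40, n_responders = 8, n_prolines = 2,
    disappearing = 22, vanish_at = 4, seed = seed, ...))
}

series_from_sim <- function(sim, pad = TRUE, drop_sidechains = TRUE) {
  labs <- names(sim$tables)
  pls <- lapply(labs, function(l) {
    t <- sim$tables[[l]]
    attr(t, "coordinate") <- c("z0", "y0", l)
    t
  })
  cube <- build_cube(pls, list(x = axis_spec("x", labs),
                               y = axis_spec("y", "y0"),
                               z = axis_spec("z", "z0")))
  s <- enumerate_series(cube, "x")[[1]]
  if (drop_sidechains) {
    s$tables <- lapply(s$tables, function(t) {
      suppressMessages(tag_sidechains(t, keep = FALSE)$backbone)
    })
  }
  if (pad) {
    s <- pad_tables(s, sequence = list(first = sim$spec$first_residue,
                                       seq = sim$sequence))
  }
  s
}

fixture_path <- function(name) testthat::test_path("fixtures", name)
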