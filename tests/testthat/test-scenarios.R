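test_that("planted configurations build exact states", {
  st <- make_planted_configuration(list(c("A", .5, .5), c("B", .51, .5)))
  expect_equal(nrow(st), 2L)
  expect_equal(st$species, c("A", "B"))
  expect_equal(nrow(make_planted_configuration(list())), 0L)
  dup <- make_planted_configuration(list(c("A", .3, .3), c("B", .3, .3)))
  expect_equal(nrow(dup), 2L)
  expect_equal(dup$id, c(1L, 2L))
  expect_error(make_planted_configuration(list(c("X", .1, .1))), "labels")
})

test_that("sinusoid fixtures carry their planted tone", {
  clean <- make_sinusoid_fixture(12, n_g = 600, amplitude = 0.05)
  expect_equal(peak_frequency(ensemble_power_spectrum(clean)), 12L)
  expect_true(all(clean >= 0 & clean <= 1))

  # amplitude 0: flat noise, the peak is not reproducible across seeds
  peaks <- vapply(1:6, function(s) {
    flat <- make_sinusoid_fixture(12, n_g = 600, amplitude = 0,
                                  noise_sd = 0.02, seed = s)
    peak_frequency(ensemble_power_spectrum(flat))
  }, integer(1))
  expect_gt(length(unique(peaks)), 1)

  expect_warning(make_sinusoid_fixture(12, n_g = 600, amplitude = 0.4),
                 "clipping")
  expect_error(make_sinusoid_fixture(400, n_g = 600), "k < n_g/2")
})

test_that("snapshot and series files round-trip", {
  dir <- withr::local_tempdir()
  p <- sim_params(box_length = 0.25, init_per_species = 40L, capacity = 8L,
                  relax_steps = 10L, measure_steps = 25L, seed = 6L)
  sim <- run_simulation(p)

  snap <- file.path(dir, "snap.csv")
  write_snapshot(sim, snap)
  back <- read_snapshot(snap, box_length = 0.25)
  expect_equal(nrow(back), nrow(sim$final_state))
  expect_equal(back$species, sim$final_state$species)
  expect_equal(back$x, sim$final_state$x, tolerance = 1e-12)
  expect_equal(readLines(snap)[1], "species,x,y")

  ser <- file.path(dir, "series.csv")
  write_counts_series(sim, ser)
  expect_equal(readLines(ser)[1], "t,nA,nB,nC,N")
  expect_equal(read_counts_series(ser), sim$series)
})

test_that("the empty-space metric matches area calculations on planted states", {
  lone <- make_planted_configuration(list(c("A", .5, .5)))
  f <- empty_space_fraction(lone, range = 0.1, probes = 200)
  expect_equal(f, 1 - pi * 0.1^2, tolerance = 5e-3)

  expect_equal(empty_space_fraction(make_planted_configuration(list()),
                                    range = 0.1), 1)

  # a lattice of individuals spaced closer than the range covers everything
  lattice <- expand.grid(x = seq(0.05, 0.95, by = 0.1),
                         y = seq(0.05, 0.95, by = 0.1))
  covered <- population_state(rep("A", nrow(lattice)), lattice$x, lattice$y)
  expect_equal(empty_space_fraction(covered, range = 0.1), 0)
})

test_that("coarse interaction ranges keep the population sparse", {
  sc <- scenario_coarse_ranges(M_values = c(30L, 240L), box_length = 0.5,
                               relax_steps = 300, measure_steps = 100,
                               seed = 3)
  expect_equal(sc$summary$M, c(30L, 240L))
  # at l_p = l_r = 0.1 even M = 30 maintains only a stunted population,
  # far below the reference-radius stationary level (~6500 in this box)
  expect_lt(sc$summary$mean_N[1], 1500)
  # richer environments fill in more of the deserted area
  expect_lt(sc$summary$empty_fraction[2], sc$summary$empty_fraction[1])
  # snapshot export parses back to exactly N rows
  snap <- withr::local_tempfile(fileext = ".csv")
  write_snapshot(sc$snapshots[["240"]], snap)
  expect_equal(nrow(read_snapshot(snap, box_length = 0.5)),
               nrow(sc$snapshots[["240"]]))
})

test_that("manifests record parameters and provenance keys", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "manifest.txt")
  write_manifest(sim_params(capacity = 12L), path,
                 extra = list(command = "run"))
  lines <- readLines(path)
  expect_true(any(grepl("^capacity: 12", lines)))
  expect_true(any(grepl("^seed: ", lines)))
  expect_true(any(grepl("^version: ", lines)))
  expect_true(any(grepl("^command: run", lines)))
})

test_that("the CLI runs, is deterministic, and rejects bad flags", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  flags <- c("run", "--box-length", "0.25", "--init-per-species", "50",
             "--capacity", "5", "--relax-steps", "10",
             "--measure-steps", "50", "--seed", "1")
  expect_equal(suppressMessages(cli_run(c(flags, "--out-dir", dir1))), 0L)
  series <- file.path(dir1, "series.csv")
  expect_true(file.exists(series))
  expect_true(file.exists(file.path(dir1, "manifest.txt")))
  expect_equal(nrow(readr::read_csv(series, show_col_types = FALSE)), 50L)

  expect_equal(suppressMessages(cli_run(c(flags, "--out-dir", dir2))), 0L)
  expect_identical(readLines(series), readLines(file.path(dir2, "series.csv")))

  expect_equal(suppressMessages(
    cli_run(c("run", "--capacity", "0", "--out-dir", dir1))), 1L)
  expect_equal(suppressMessages(cli_run("no-such-command")), 1L)
})

test_that("the CLI writes fixtures and spectrum tables", {
  dir <- withr::local_tempdir()
  expect_equal(suppressMessages(cli_run(c(
    "fixtures", "--k", "9", "--ng", "400", "--noise-sd", "0",
    "--out-dir", dir))), 0L)
  fx <- readr::read_csv(file.path(dir, "sinusoid.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(fx), 400L)
  expect_equal(peak_frequency(ensemble_power_spectrum(fx$rho)), 9L)

  expect_equal(suppressMessages(cli_run(c(
    "spectrum", "--m-values", "8", "--ng", "256", "--replicates", "2",
    "--box-length", "0.25", "--relax-steps", "50", "--smoothing", "0",
    "--seed", "2", "--out-dir", dir))), 0L)
  expect_true(file.exists(file.path(dir, "spectrum_M8.csv")))
  peaks <- readr::read_csv(file.path(dir, "peaks.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(peaks), 1L)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
})
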