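test_that("the prey map is the 3-cycle A->B->C->A", {
  expect_equal(prey_species("A"), "B")
  expect_equal(prey_species("B"), "C")
  expect_equal(prey_species("C"), "A")
  expect_equal(prey_species(prey_species(prey_species(c("A", "B", "C")))),
               c("A", "B", "C"))
  expect_error(prey_species("D"), "unknown species")
})

test_that("random initialisation is uniform, balanced and seed-reproducible", {
  p <- sim_params(init_per_species = 100L, relax_steps = 0L,
                  measure_steps = 1L, seed = 5L)
  st <- init_population(p)
  expect_equal(nrow(st), 300L)
  expect_equal(unname(table(st$species)), rep(100L, 3),
               ignore_attr = TRUE)
  expect_true(all(st$x >= 0 & st$x < 1 & st$y >= 0 & st$y < 1))
  expect_identical(init_population(p), st)
  tiny <- init_population(sim_params(init_per_species = 1L))
  expect_equal(sort(tiny$species), c("A", "B", "C"))
})

test_that("predation removes exactly the closest in-range prey", {
  p <- sim_params()
  st <- make_planted_configuration(list(c("A", .5, .5), c("B", .51, .5)))
  out <- attempt_predation(st, 1L, p)
  expect_equal(nrow(out), 1L)
  expect_equal(out$species, "A")

  far <- make_planted_configuration(list(c("A", .5, .5), c("B", .55, .5)))
  expect_identical(attempt_predation(far, 1L, p), far)

  two <- make_planted_configuration(list(
    c("A", .5, .5), c("B", .5, .518), c("B", .512, .5)
  ))
  out2 <- attempt_predation(two, 1L, p)
  expect_equal(nrow(out2), 2L)
  expect_false(3L %in% out2$id)   # nearer prey (0.012) died, 0.018 survived

  # range is evaluated with minimum-image distances across the seam
  seam <- make_planted_configuration(list(c("A", .005, .5), c("B", .995, .5)))
  expect_equal(nrow(attempt_predation(seam, 1L, p)), 1L)
})

test_that("reproduction is gated by the capacity count, actor included", {
  p <- sim_params(capacity = 2L)
  lone <- make_planted_configuration(list(c("A", .5, .5)))
  set.seed(1)
  out <- attempt_reproduction(lone, 1L, p)
  expect_equal(nrow(out), 2L)
  expect_equal(out$species, c("A", "A"))
  d <- torus_distance(out$x[2], out$y[2], .5, .5, 1)
  expect_lte(d, p$offspring_radius)

  # count == capacity blocks the birth (condition is strictly < M)
  pM3 <- sim_params(capacity = 3L)
  crowded <- make_planted_configuration(list(
    c("A", .5, .5), c("B", .505, .5), c("C", .5, .505)
  ))
  expect_identical(attempt_reproduction(crowded, 1L, pM3), crowded)

  # M = 1: the actor alone saturates its own neighbourhood
  p1 <- sim_params(capacity = 1L)
  set.seed(2)
  expect_identical(attempt_reproduction(lone, 1L, p1), lone)
})

test_that("movement jumps by exactly the movement length and wraps", {
  p <- sim_params(move_length = 0.01)
  st <- make_planted_configuration(list(c("A", .005, .5)))
  set.seed(3)
  wrapped <- FALSE
  for (i in 1:50) {
    out <- move_individual(st, 1L, p)
    expect_equal(torus_distance(out$x, out$y, .005, .5, 1), 0.01,
                 tolerance = 1e-12)
    if (out$x > 0.9) wrapped <- TRUE
  }
  expect_true(wrapped)  # left-going jumps crossed the seam to x near 0.995
})

test_that("movement directions are uniform on the circle", {
  p <- sim_params(move_length = 0.01)
  st <- make_planted_configuration(list(c("A", .5, .5)))
  set.seed(4)
  ang <- replicate(10000, {
    out <- move_individual(st, 1L, p)
    atan2(out$y - .5, out$x - .5) %% (2 * pi)
  })
  bins <- table(cut(ang, breaks = seq(0, 2 * pi, length.out = 37)))
  expect_gt(stats::chisq.test(bins)$p.value, 0.001)
})

test_that("elementary steps change N by -1, 0 or +1 and respect forced actions", {
  # forced predation: every individual's prey is in range, so N must drop
  pp <- sim_params(prob_move = 0, prob_predate = 1, prob_reproduce = 0)
  st <- make_planted_configuration(list(
    c("A", .5, .5), c("B", .51, .5), c("C", .5, .51)
  ))
  set.seed(5)
  expect_equal(nrow(elementary_step(st, pp)), 2L)

  # movement only conserves N over a full MC step
  pm <- sim_params(prob_move = 1, prob_predate = 0, prob_reproduce = 0)
  st100 <- random_state(100, seed = 8)
  set.seed(6)
  after <- mc_step(st100, pm)
  expect_equal(nrow(after), 100L)
  expect_equal(sort(after$id), sort(st100$id))
  expect_error(elementary_step(after[0, ], pm), "empty")
})

test_that("action frequencies follow (m, p, r) on a reference single-actor state", {
  # lone individual, roomy capacity: +1 <=> reproduction, a changed position
  # with constant N <=> movement, no change <=> (necessarily failed) predation
  p <- sim_params(capacity = 5L)
  st <- make_planted_configuration(list(c("A", .5, .5)))
  set.seed(7)
  n <- 4000
  kind <- replicate(n, {
    out <- elementary_step(st, p)
    if (nrow(out) == 2) "reproduce"
    else if (out$x != .5 || out$y != .5) "move"
    else "predate"
  })
  counts <- table(factor(kind, levels = c("move", "predate", "reproduce")))
  expect_equal(unname(counts["move"]) / n, 0.5,
               tolerance = 3 * sqrt(0.25 / n) / 0.5)
  for (a in c("predate", "reproduce")) {
    expect_equal(unname(counts[a]) / n, 0.25,
                 tolerance = 3 * sqrt(0.25 * 0.75 / n) / 0.25)
  }
})

test_that("reference mc_step is deterministic under a fixed seed", {
  p <- sim_params(capacity = 4L, init_per_species = 10L)
  st <- random_state(30, seed = 10)
  set.seed(11); a <- mc_step(st, p)
  set.seed(11); b <- mc_step(st, p)
  expect_identical(a, b)
})

test_that("the compiled engine is reproducible and backend-invariant", {
  p <- sim_params(box_length = 0.25, capacity = 10L, init_per_species = 167L,
                  relax_steps = 0L, measure_steps = 100L, seed = 33L)
  cell <- run_simulation(p, backend = "cell")
  cell2 <- run_simulation(p, backend = "cell")
  brute <- run_simulation(p, backend = "brute")
  expect_identical(cell$series, cell2$series)
  expect_identical(cell$series, brute$series)
  expect_identical(cell$final_state, brute$final_state)
  expect_equal(nrow(cell$series), 100L)
  # recorded counts always sum to N, and the final state tallies match
  expect_equal(cell$series$n_A + cell$series$n_B + cell$series$n_C,
               cell$series$N)
  last <- cell$series[nrow(cell$series), ]
  expect_equal(unname(c(table(factor(cell$final_state$species,
                                     levels = c("A", "B", "C"))))),
               c(last$n_A, last$n_B, last$n_C))
})

test_that("population size moves monotonically when a process is switched off", {
  base <- list(box_length = 0.25, init_per_species = 100L, capacity = 8L,
               relax_steps = 0L, measure_steps = 200L, seed = 2L)
  # no reproduction: N non-increasing
  pr0 <- do.call(sim_params, c(base, list(prob_move = 0.5, prob_predate = 0.5,
                                          prob_reproduce = 0)))
  sr0 <- run_simulation(pr0, return_state = FALSE)
  expect_true(all(diff(sr0$series$N) <= 0))
  # no predation: N non-decreasing and bounded by the packing limit
  pp0 <- do.call(sim_params, c(base, list(prob_move = 0.5, prob_predate = 0,
                                          prob_reproduce = 0.5)))
  sp0 <- run_simulation(pp0, return_state = FALSE)
  expect_true(all(diff(sp0$series$N) >= 0))
  # cover the box with cells of side l_r/sqrt(2) (diameter l_r): any cell
  # holding >= M individuals blocks further births from inside it, so the
  # population saturates near M per cell
  packing_cells <- pp0$capacity * 2 * pp0$box_length^2 / pp0$repro_radius^2
  expect_lte(max(sp0$series$N), packing_cells)
  # and the growth has essentially saturated by the end of the run
  expect_lt(sum(diff(tail(sp0$series$N, 50))),
            sum(diff(head(sp0$series$N, 50))) / 2)
  # movement only: N constant at the initial value
  pm <- do.call(sim_params, c(base, list(prob_move = 1, prob_predate = 0,
                                         prob_reproduce = 0)))
  sm <- run_simulation(pm, return_state = FALSE)
  expect_true(all(sm$series$N == 300L))
})

test_that("compiled engine and reference dynamics agree statistically", {
  # same model, two implementations, independent RNGs: stationary mean N
  # from the compiled engine must sit inside the spread of the slow
  # reference engine (tibble-level mc_step loop)
  p <- sim_params(box_length = 0.2, capacity = 5L, init_per_species = 30L,
                  relax_steps = 0L, measure_steps = 100L, seed = 1L)
  ref_means <- vapply(1:3, function(s) {
    set.seed(s)
    st <- init_population(p, seed = 100 + s)
    n <- numeric(100)
    for (i in 1:100) {
      st <- mc_step(st, p)
      n[i] <- nrow(st)
    }
    mean(n[51:100])
  }, numeric(1))
  eng_means <- vapply(1:6, function(s) {
    ps <- validate_sim_params(modifyList(unclass(p), list(seed = 200 + s)))
    mean(run_simulation(ps, return_state = FALSE)$series$N[51:100])
  }, numeric(1))
  expect_lt(abs(mean(eng_means) - mean(ref_means)),
            4 * sd(c(ref_means, eng_means)))
})

test_that("per-elementary-step population changes are -1, 0 or +1", {
  p <- sim_params(box_length = 0.25, capacity = 10L, init_per_species = 60L,
                  relax_steps = 0L, measure_steps = 30L, seed = 12L)
  sim <- run_simulation(p, record_elementary = TRUE)
  dN <- diff(c(180L, sim$elementary_N))
  expect_true(all(dN %in% c(-1L, 0L, 1L)))
})
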