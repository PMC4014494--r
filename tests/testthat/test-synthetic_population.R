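test_that("reproduction inhibition follows the log-logistic form", {
  dr <- dose_response(ec50_repro = 10, hill_slope = 2)
  expect_identical(reproduction_inhibition(0, dr), 0)
  expect_equal(reproduction_inhibition(10, dr), 0.5)
  expect_equal(reproduction_inhibition(20, dr), 0.8)   # 400 / (400 + 100)
  expect_error(reproduction_inhibition(-1, dr), "non-negative")
  cc <- seq(0, 100, by = 0.5)
  inh <- reproduction_inhibition(cc, dose_response())
  expect_true(all(diff(inh) > 0))
  expect_true(all(inh < 1))
})

test_that("length classification uses left-closed upper boundaries", {
  expect_identical(unname(classify_by_length(c(1.0, 1.4, 2.6))),
                   c(1L, 1L, 1L))
  expect_identical(unname(classify_by_length(numeric(0))), c(0L, 0L, 0L))
  expect_identical(unname(classify_by_length(c(1.39, 1.40, 2.59, 2.60))),
                   c(1L, 2L, 1L))
  expect_error(classify_by_length(c(1, 0)), "positive")
})

test_that("an extinct population is an absorbing state with food still input", {
  cfg <- treatment_config(0, n_runs = 2)
  st <- structure(list(day = 3L,
                       individuals = popchaos:::empty_individuals(),
                       food = 1),
                  class = "population_state")
  nxt <- step_day(st, cfg)
  expect_identical(nrow(nxt$individuals), 0L)
  expect_identical(nxt$day, 4L)
  lh <- cfg$life_history
  expect_equal(nxt$food, 1 * (1 - lh$food_decay) + lh$food_input)
})

test_that("a well-fed adult reproduces at the configured brood rate", {
  lh <- life_history_params(init_food = 1e6, food_input = 1e6)
  cfg <- treatment_config(0, n_runs = 2, life_history = lh)
  set.seed(1)
  ind <- data.frame(age = 10L, length = 3.0, max_lifetime = 60L,
                    days_since_brood = 0L, starve = 0L, eggs = 0)
  st <- structure(list(day = 0L, individuals = ind, food = lh$init_food),
                  class = "population_state")
  # seven days of accrual at (nearly) full ration provisions
  # 7 * brood_max / brood_interval eggs; the integer release loses at
  # most one egg per brood date to the carried remainder.  Offspring
  # cannot themselves mature within a week, so all non-mother
  # individuals are this adult's births.
  for (i in 1:7) st <- step_day(st, cfg)
  births <- nrow(st$individuals) - 1L
  rate <- lh$brood_max / lh$brood_interval
  expect_gte(births, floor(7 * rate) - 2)
  expect_lte(births, ceiling(7 * rate))
})

test_that("individuals are removed when their lifetime is exhausted", {
  cfg <- treatment_config(0, n_runs = 2)
  ind <- data.frame(age = 30L, length = 3.0, max_lifetime = 30L,
                    days_since_brood = 0L, starve = 0L, eggs = 0)
  st <- structure(list(day = 0L, individuals = ind,
                       food = cfg$life_history$init_food),
                  class = "population_state")
  set.seed(1)
  nxt <- step_day(st, cfg)
  expect_identical(nrow(nxt$individuals), 0L)
})

test_that("simulated runs start from 5 neonates + 3 adults and are reproducible", {
  cfg <- treatment_config(0, n_days = 120, n_runs = 2)
  s1 <- run_simulation(cfg, seed = 11)
  expect_identical(unlist(s1[1, c("neonates", "juveniles", "adults")],
                          use.names = FALSE), c(5L, 0L, 3L))
  expect_identical(nrow(s1), 121L)
  s2 <- run_simulation(cfg, seed = 11)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("without food input the population dies out within a year", {
  lh <- life_history_params(food_input = 0, init_food = 0.5)
  cfg <- treatment_config(0, n_days = 365, n_runs = 2, life_history = lh)
  s <- run_simulation(cfg, seed = 3)
  expect_identical(s$total[nrow(s)], 0L)
})

test_that("class counts always sum to total and stay non-negative", {
  for (conc in c(0, 20)) {
    cfg <- treatment_config(conc, n_days = 150, n_runs = 2, base_seed = 8)
    for (s in run_ensemble(cfg)) {
      expect_true(all(s$neonates + s$juveniles + s$adults == s$total))
      expect_true(all(s$total >= 0))
    }
  }
})

test_that("with reproduction and mortality disabled abundance is constant", {
  lh <- life_history_params(brood_max = 0, lifetime_range = c(1000L, 1000L),
                            starve_coef = 0, food_input = 1e4,
                            init_food = 1e4)
  cfg <- treatment_config(0, n_days = 60, n_runs = 2, life_history = lh)
  s <- run_simulation(cfg, seed = 5)
  expect_true(all(s$total == 8L))
})

test_that("ensembles are seed-paired across concentrations and need n >= 2", {
  lh <- life_history_params()
  cfg0 <- treatment_config(0, n_days = 80, n_runs = 3, base_seed = 77,
                           life_history = lh)
  cfg40 <- treatment_config(40, n_days = 80, n_runs = 3, base_seed = 77,
                            life_history = lh)
  e0 <- run_ensemble(cfg0)
  e40 <- run_ensemble(cfg40)
  # identical seeds run-by-run => identical initial lifetime draws
  for (i in 1:3) {
    expect_identical(attr(e0[[i]], "seed"), attr(e40[[i]], "seed"))
    set.seed(attr(e0[[i]], "seed"))
    init_a <- initial_state(lh)$individuals$max_lifetime
    set.seed(attr(e40[[i]], "seed"))
    init_b <- initial_state(lh)$individuals$max_lifetime
    expect_identical(init_a, init_b)
  }
  # distinct lifetime draws make distinct trajectories
  expect_false(identical(e0[[1]]$total, e0[[2]]$total))
  expect_error(run_ensemble(treatment_config(0, n_runs = 1)), "n_runs")
})

test_that("the control ensemble persists, stays bounded and fluctuates", {
  cfg <- treatment_config(0, n_runs = 8, base_seed = 42)
  ens <- run_ensemble(cfg)
  finals <- vapply(ens, function(s) s$total[nrow(s)], integer(1))
  expect_gte(mean(finals > 0), 0.95)
  ceiling_ <- cfg$life_history$carrying_ceiling
  for (s in ens) {
    post <- s$total[-(1:50)]
    expect_lt(max(post), ceiling_)
    expect_gt(stats::sd(post), 0)
  }
})

test_that("stress monotonically depresses late-season abundance", {
  mean_late <- vapply(c(0, 5, 40), function(conc) {
    cfg <- treatment_config(conc, n_runs = 20, base_seed = 100)
    mean(vapply(run_ensemble(cfg),
                function(s) mean(s$total[201:366]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_late) < 0))
})
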