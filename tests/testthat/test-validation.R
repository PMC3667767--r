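test_that("mean-activity refit reproduces a single duplicated member", {
  m <- sphingo_core_model()
  truth <- make_truth(m, seed = 2)
  tg <- exact_targets(m, truth)
  cand <- structure(list(schedule = truth,
                         trajectory = simulate_model(m, truth, times = 0:30),
                         sse = NA, aicc = NA, seed = 1, converged = TRUE),
                    class = "candidate_solution")
  cand$sse <- compute_sse(cand, tg)
  ens <- structure(list(candidates = list(cand, cand), seeds = c(1, 1),
                        n_requested = 2, errors = character(), base_seed = 0),
                   class = "gma_ensemble")
  s <- summarize_ensemble(ens)
  refit <- refit_with_means(m, s, tg, ensemble = ens)
  expect_equal(refit$sse, cand$sse, tolerance = 1e-6)
  expect_lt(refit$sse, 1e-10)  # noise-free ground-truth schedule refits itself
  expect_true(refit$pass)
})

test_that("complex sphingolipid flatness measures max fold deviation", {
  m <- sphingo_core_model()
  tc <- simulate_model(m, baseline_schedule(m), times = 0:30)
  fl <- complex_lipid_flatness(tc)
  expect_equal(unname(fl$deviation), c(0, 0, 0), tolerance = 1e-7)
  expect_true(fl$pass)

  # fold range [0.9, 1.1] -> deviation 0.1
  tc2 <- tc
  mfold <- timecourse_matrix(tc)
  mfold[, "IPC"] <- seq(0.9, 1.1, length.out = 31)
  attr(tc2, "matrix") <- mfold
  fl2 <- complex_lipid_flatness(tc2)
  expect_equal(fl2$deviation[["IPC"]], 0.1, tolerance = 1e-12)
  expect_error(complex_lipid_flatness(tc, species = "NOPE"), "not in")
})

test_that("flat-complex-lipid truth keeps the refit flat within bounds", {
  m <- sphingo_core_model()
  # mildly modulating the phosphorylation cycle (kinase, phosphatase,
  # lyase) perturbs the sphingoid bases while the complex pools stay
  # nearly constant
  shape <- list(archetype = "spike_decay", peak = 1.5, tau = 3,
                floor = 0.85)
  movers <- c("X36", "X41", "X50")
  truth <- make_truth(m, stats::setNames(rep(list(shape), 3), movers),
                      seed = 3)
  clean <- simulate_model(m, truth, times = 0:30)
  fl_truth <- complex_lipid_flatness(clean)
  expect_true(fl_truth$pass)

  # infer the moving enzymes back and check the refit stays flat too
  tg <- exact_targets(m, truth)
  cfg <- inverse_config(m, free = movers, maxit = 60)
  ens <- run_ensemble(m, tg, n_runs = 8, cfg, seed = 4)
  sel <- select_top(ens, 4, "sse")
  refit <- refit_with_means(m, summarize_ensemble(sel), tg, ensemble = sel)
  fl <- complex_lipid_flatness(refit$trajectory)
  expect_true(fl$pass)
})

test_that("an empty clamp reproduces the unconstrained ensemble exactly", {
  m <- sphingo_core_model()
  truth <- make_truth(m, seed = 5)
  tg <- exact_targets(m, truth)
  nc <- negative_control(m, tg, clamp = character(0), n_runs = 3,
                         config = inverse_config(m, maxit = 25), seed = 8)
  expect_equal(nc$best_sse_constrained, nc$best_sse_unconstrained)
  expect_false(nc$pass)  # equality, not strictly worse
})

test_that("clamping an enzyme the truth never moves costs nothing on the toy", {
  toy <- toy_enzyme_model()
  # truth moves only E2; E1 stays at baseline
  truth <- const_schedule(c("E1", "E2"), c(1, 1), times = 0:6)
  truth$folds[, "E2"] <- seq(1, 2.2, length.out = 7)
  fm <- timecourse_matrix(simulate_model(toy, truth, times = 0:6),
                          fold = TRUE)
  av <- tibble::tibble(species = rep(c("A", "B"), each = 7),
                       time_min = rep(0:6, 2),
                       fold = c(fm[, "A"], fm[, "B"]))
  tg <- smooth_targets(av, grid = 0:6, method = "interpolate")
  cfg <- toy_config(toy, maxit = 120)
  nc <- negative_control(toy, tg, clamp = "E1", n_runs = 3,
                         config = cfg, seed = 5)
  expect_lt(nc$best_sse_constrained, 1e-4)

  # clamping the only changing enzyme is strictly worse
  nc2 <- negative_control(toy, tg, clamp = "E2", n_runs = 3,
                          config = cfg, seed = 5)
  expect_gt(nc2$best_sse_constrained, 10 * nc2$best_sse_unconstrained)
  expect_true(nc2$pass)
})

test_that("cumulative production integrates producing fluxes only", {
  m <- sphingo_core_model()
  cp <- cumulative_production(m, species = "KDHS")
  # constant production rate p -> curve p * t (p = 1 in the core model)
  expect_equal(cp$production, 1 * (0:30), tolerance = 1e-8)
  fit <- stats::lm(production ~ time, data = cp)
  expect_gte(suppressWarnings(summary(fit))$r.squared, 1 - 1e-9)

  # flux bookkeeping: baseline + production - consumption = concentration
  err <- max(abs(1 + cp$production - cp$consumption - cp$concentration))
  expect_lt(err, 1e-7)

  # shutting the producing enzyme yields (essentially) zero production
  sch <- baseline_schedule(m, c(0, 30))
  sch$folds[, "X57"] <- 0
  cp0 <- cumulative_production(m, sch, species = "KDHS")
  expect_lt(max(cp0$production), 1e-9)
  expect_error(cumulative_production(m, species = "NOPE"), "unknown species")
})

test_that("heat-stress schedules accelerate then stall 3-KDHS production", {
  m <- sphingo_core_model()
  truth <- make_truth(m, seed = 1)
  cp_base <- cumulative_production(m, species = "KDHS")
  cp_heat <- cumulative_production(m, truth, species = "KDHS")
  # steeper than baseline over the first minutes, flat later
  expect_gt(cp_heat$production[4], cp_base$production[4])
  late_rate <- diff(cp_heat$production)[25:30]
  expect_lt(max(late_rate), 0.1)

  # bookkeeping identity also holds under the dynamic schedule
  err <- max(abs(1 + cp_heat$production - cp_heat$consumption -
                   cp_heat$concentration))
  expect_lt(err, 1e-6)
})

test_that("Q10 estimates follow the closed-form exponent", {
  sch <- activity_schedule(
    matrix(c(rep(1, 31), rep(2, 31),
             archetype_profile("spike_decay", 0:30, peak = 4,
                               peak_time = 1)),
           ncol = 3, dimnames = list(NULL, c("flat", "double", "spike"))),
    0:30)
  q <- estimate_q10(sch)
  expect_equal(q$q10[q$enzyme == "flat"], 1)
  expect_equal(q$q10[q$enzyme == "double"], 2^(10 / 9), tolerance = 1e-12)
  expect_equal(q$q10[q$enzyme == "spike"], 4^(10 / 9), tolerance = 1e-6)
  expect_equal(q$q10[q$enzyme == "double"], 2.16, tolerance = 0.01)
  expect_equal(q$q10[q$enzyme == "spike"], 4.67, tolerance = 0.01)
})
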