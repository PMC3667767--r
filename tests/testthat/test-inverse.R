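test_that("interval optimizer recovers generating folds on the toy chain", {
  toy <- toy_enzyme_model()
  cfg <- toy_config(toy, maxit = 200)
  true_folds <- c(E1 = 1.6, E2 = 0.7)
  sch <- const_schedule(c("E1", "E2"), true_folds)
  target <- timecourse_matrix(simulate_model(toy, sch, times = c(0, 1)),
                              fold = TRUE)[2, c("A", "B")]
  res <- optimize_interval(toy, c(A = 1, B = 1), target, c(E1 = 1, E2 = 1),
                           cfg)
  expect_lt(max(abs(res$folds - true_folds)), 1e-3)
  expect_lt(res$value, 1e-8)  # objective ~ 0 at the generating folds
  expect_true(res$converged)
})

test_that("interval optimizer matches an exhaustive grid-search oracle", {
  toy <- toy_enzyme_model()
  cfg <- toy_config(toy, maxit = 200)
  true_folds <- c(E1 = 2.3, E2 = 0.45)
  sch <- const_schedule(c("E1", "E2"), true_folds)
  target <- timecourse_matrix(simulate_model(toy, sch, times = c(0, 1)),
                              fold = TRUE)[2, c("A", "B")]

  # brute-force oracle: coarse scan then local refinement
  mm <- attr(toy, "matrices")
  ws_eval <- function(e1, e2) {
    ind <- c(E1 = e1, E2 = e2)
    lg <- mm$log_gamma + as.numeric(mm$KOi %*% log(pmax(ind, 1e-12)))
    y1 <- sphingodyn:::cpp_gma_step(c(1, 1), mm$KOd, mm$S, lg, 1, 10)
    sum((as.numeric(y1) - target)^2)
  }
  best <- c(NA, NA); bestv <- Inf
  for (e1 in seq(0.25, 4, by = 0.05)) for (e2 in seq(0.25, 4, by = 0.05)) {
    v <- ws_eval(e1, e2)
    if (v < bestv) { bestv <- v; best <- c(e1, e2) }
  }
  for (e1 in seq(best[1] - 0.05, best[1] + 0.05, by = 0.002)) {
    for (e2 in seq(best[2] - 0.05, best[2] + 0.05, by = 0.002)) {
      v <- ws_eval(e1, e2)
      if (v < bestv) { bestv <- v; best <- c(e1, e2) }
    }
  }

  fit <- optimize_interval(toy, c(A = 1, B = 1), target, c(E1 = 1, E2 = 1),
                           toy_config(toy, maxit = 200))
  expect_lt(max(abs(fit$folds - best)), 1e-3)
  # warm-start must not change the optimum, only the path to it
  fit2 <- optimize_interval(toy, c(A = 1, B = 1), target,
                            c(E1 = 3.5, E2 = 3.5),
                            toy_config(toy, maxit = 500))
  expect_lt(max(abs(fit2$folds - best)), 1e-3)
})

test_that("baseline targets on the toy chain infer unit folds", {
  toy <- toy_enzyme_model()
  # identical-to-baseline targets; determined system, so folds pin at 1
  av <- tibble::tibble(species = rep(c("A", "B"), each = 11),
                       time_min = rep(0:10, 2), fold = 1)
  tg <- smooth_targets(av, grid = 0:10, method = "interpolate")
  cand <- infer_trajectory(toy, tg, toy_config(toy, maxit = 100), seed = 5)
  expect_lt(max(abs(cand$schedule$folds[-1, ] - 1)), 0.05)
  expect_lt(cand$sse, 1e-6)
})

test_that("inference is deterministic under a fixed seed", {
  toy <- toy_enzyme_model()
  truth <- const_schedule(c("E1", "E2"), c(1.8, 0.6), times = 0:10)
  truth$folds[, "E1"] <- seq(1.8, 0.4, length.out = 11)
  fm <- timecourse_matrix(simulate_model(toy, truth, times = 0:10),
                          fold = TRUE)
  av <- tibble::tibble(species = rep(c("A", "B"), each = 11),
                       time_min = rep(0:10, 2),
                       fold = c(fm[, "A"], fm[, "B"]))
  tg <- smooth_targets(av, grid = 0:10, method = "interpolate")
  cfg <- toy_config(toy, maxit = 60)
  c1 <- infer_trajectory(toy, tg, cfg, seed = 99)
  c2 <- infer_trajectory(toy, tg, cfg, seed = 99)
  expect_identical(c1$schedule$folds, c2$schedule$folds)
  expect_identical(c1$sse, c2$sse)
  # and recovers the generating profile on this determined system
  expect_gt(stats::cor(c1$schedule$folds[, "E1"], truth$folds[, "E1"]), 0.99)
})

test_that("SSE follows its definition", {
  toy <- toy_enzyme_model()
  truth <- const_schedule(c("E1", "E2"), c(1, 1), times = 0:5)
  tc <- simulate_model(toy, truth, times = 0:5)
  cand <- list(trajectory = tc)
  av <- tibble::tibble(species = rep(c("A", "B"), each = 6),
                       time_min = rep(0:5, 2), fold = 1)
  tg <- smooth_targets(av, grid = 0:5, method = "interpolate")
  expect_equal(compute_sse(cand, tg), 0, tolerance = 1e-12)
  # residuals all equal r over m points -> SSE = m r^2
  tg2 <- tg
  attr(tg2, "matrix") <- attr(tg, "matrix") + 0.2
  expect_equal(compute_sse(cand, tg2), 10 * 0.04, tolerance = 1e-10)
})

test_that("AICc is the stated small-sample formula and fails when undefined", {
  expect_equal(compute_aicc(2, n = 20, k = 3),
               20 * log(2 / 20) + 6 + 24 / 16)
  expect_error(compute_aicc(1, n = 5, k = 4), "undefined")
  # equal k: AICc ordering equals SSE ordering
  sse <- c(3, 1, 2, 5)
  aicc <- vapply(sse, compute_aicc, numeric(1), n = 30, k = 4)
  expect_identical(order(aicc), order(sse))
})

test_that("ensembles are reproducible and reduce to single runs", {
  toy <- toy_enzyme_model()
  fm <- timecourse_matrix(simulate_model(
    toy, const_schedule(c("E1", "E2"), c(2, 0.5), times = 0:6),
    times = 0:6), fold = TRUE)
  av <- tibble::tibble(species = rep(c("A", "B"), each = 7),
                       time_min = rep(0:6, 2),
                       fold = c(fm[, "A"], fm[, "B"]))
  tg <- smooth_targets(av, grid = 0:6, method = "interpolate")
  cfg <- toy_config(toy, maxit = 40)
  e1 <- run_ensemble(toy, tg, n_runs = 5, cfg, seed = 7)
  e2 <- run_ensemble(toy, tg, n_runs = 5, cfg, seed = 7)
  expect_identical(tidy(e1)$sse, tidy(e2)$sse)
  expect_equal(nrow(tidy(e1)), 5)

  single <- run_ensemble(toy, tg, n_runs = 1, cfg, seed = 11)
  direct <- infer_trajectory(toy, tg, cfg, seed = single$seeds[1])
  expect_identical(single$candidates[[1]]$sse, direct$sse)
})

test_that("top-N selection is stable and criterion agreement behaves", {
  toy <- toy_enzyme_model()
  fm <- timecourse_matrix(simulate_model(
    toy, const_schedule(c("E1", "E2"), c(2, 0.5), times = 0:6),
    times = 0:6), fold = TRUE)
  av <- tibble::tibble(species = rep(c("A", "B"), each = 7),
                       time_min = rep(0:6, 2),
                       fold = c(fm[, "A"], fm[, "B"]))
  tg <- smooth_targets(av, grid = 0:6, method = "interpolate")
  ens <- run_ensemble(toy, tg, n_runs = 6, toy_config(toy, maxit = 30),
                      seed = 3)
  top <- select_top(ens, 3, "sse")
  sse <- tidy(ens)$sse
  expect_equal(sort(tidy(top)$sse), sort(sse)[1:3])
  # equal k across candidates: SSE and AICc selections coincide
  expect_equal(criterion_agreement(ens, 3), 100)
  expect_equal(criterion_agreement(ens, length(ens$candidates)), 100)
  expect_error(select_top(ens, 10), "exceeds")
  ens0 <- ens; ens0$candidates <- list()
  expect_error(select_top(ens0, 1), "empty")
})

test_that("objective is invariant under common baseline rescaling", {
  # scaled-residual SSE: scaling all baselines by c leaves fold residuals
  # unchanged because targets and simulations rescale together
  scale <- 3.7
  toyA <- toy_enzyme_model()
  v <- toyA$variables; v$baseline[v$id %in% c("A", "B")] <- scale
  toyB <- gma_model(v, list(
    power_law_flux("in", scale, c(E1 = 1), produces = c(A = 1),
                   catalyst = "E1"),
    power_law_flux("ab", 1, c(A = 1, E2 = 1), consumes = c(A = 1),
                   produces = c(B = 1), catalyst = "E2"),
    power_law_flux("bo", 1, c(B = 1), consumes = c(B = 1))
  ))
  sch <- const_schedule(c("E1", "E2"), c(1.5, 0.8), times = 0:4)
  fmA <- timecourse_matrix(simulate_model(toyA, sch, times = 0:4),
                           fold = TRUE)
  fmB <- timecourse_matrix(simulate_model(toyB, sch, times = 0:4),
                           fold = TRUE)
  expect_equal(fmA, fmB, tolerance = 1e-7)
})
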