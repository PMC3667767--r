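test_that("power-law flux evaluation follows gamma * prod(x^f)", {
  f <- power_law_flux("v", 2, c(A = 0.5), consumes = c(A = 1))
  expect_equal(evaluate_flux(f, c(A = 4)), 4)

  f0 <- power_law_flux("v", 3, c(A = 0), consumes = c(A = 1))
  expect_equal(evaluate_flux(f0, c(A = 17.3)), 3)

  f2 <- power_law_flux("v", 1, c(A = 1, E = 1), consumes = c(A = 1))
  expect_equal(evaluate_flux(f2, c(A = 2, E = 0.5)), 1)

  expect_error(evaluate_flux(f2, c(A = 2)), "missing")
  expect_error(evaluate_flux(f2, c(A = -1, E = 1)), "negative")
  fneg <- power_law_flux("v", 1, c(A = -0.5), consumes = c(A = 1))
  expect_error(evaluate_flux(fneg, c(A = 0)), "zero state")
})

test_that("flux terms respond monotonically to their kinetic orders", {
  fpos <- power_law_flux("v", 1.3, c(A = 0.7), consumes = c(A = 1))
  fneg <- power_law_flux("v", 1.3, c(A = -0.4), consumes = c(A = 1))
  x <- seq(0.2, 5, length.out = 20)
  vpos <- vapply(x, function(a) evaluate_flux(fpos, c(A = a)), numeric(1))
  vneg <- vapply(x, function(a) evaluate_flux(fneg, c(A = a)), numeric(1))
  expect_true(all(diff(vpos) > 0))
  expect_true(all(diff(vneg) < 0))
})

test_that("model construction validates references and baselines", {
  vars <- data.frame(id = c("A", "E"),
                     role = c("dependent", "independent"), baseline = 1)
  expect_error(
    gma_model(vars, list(power_law_flux("v", 1, c(Z = 1),
                                        consumes = c(A = 1)))),
    "unknown variable"
  )
  expect_error(
    gma_model(vars, list(power_law_flux("v", 1, c(E = 1),
                                        produces = c(E = 1)))),
    "non-dependent"
  )
  vars0 <- data.frame(id = "A", role = "dependent", baseline = 0)
  expect_error(
    gma_model(vars0, list(power_law_flux("v", 1, c(A = 1),
                                         consumes = c(A = 1)))),
    "non-positive baseline"
  )
  expect_error(power_law_flux("v", 1, c(A = 1)), "at least one")
  expect_error(power_law_flux("v", -1, c(A = 1), consumes = c(A = 1)),
               "positive")
})

test_that("assembled derivatives are stoichiometry-weighted flux sums", {
  m <- one_species_model(with_efflux = FALSE)
  d <- gma_derivatives(m)
  expect_equal(d(c(A = 1)), c(A = 1))
  expect_equal(d(c(A = 42)), c(A = 1))

  m2 <- one_species_model(with_efflux = TRUE)
  d2 <- gma_derivatives(m2)
  expect_equal(d2(c(A = 1)), c(A = 0))
  expect_lt(d2(c(A = 2))[["A"]], 0)
})

test_that("baseline steady-state residual behaves as a norm", {
  m <- sphingo_core_model()
  expect_lt(steady_state_residual(m), 1e-8)

  # perturb one rate constant -> residual leaves zero
  m2 <- m
  m2$fluxes$spt$rate_constant <- m2$fluxes$spt$rate_constant * 1.1
  m2 <- gma_model(m2$variables, m2$fluxes)
  expect_gt(steady_state_residual(m2), 1e-3)

  # invariant under relabeling of flux ids
  fx <- m$fluxes
  names(fx) <- NULL
  fx <- lapply(rev(seq_along(fx)), function(i) {
    f <- fx[[i]]; f$id <- paste0("relabel_", i); f
  })
  m3 <- gma_model(m$variables, fx)
  expect_equal(steady_state_residual(m3), steady_state_residual(m))
})

test_that("simulation at steady state stays at baseline", {
  m <- sphingo_core_model()
  tc <- simulate_model(m, times = 0:30)
  expect_lt(max(abs(timecourse_matrix(tc, fold = TRUE) - 1)), 1e-6)
})

test_that("constant influx without efflux accumulates linearly", {
  m <- one_species_model(with_efflux = FALSE)
  tc <- simulate_model(m, times = 0:10)
  expect_equal(timecourse_matrix(tc)[, "A"], 1 + 0:10, tolerance = 1e-8)
})

test_that("doubling a first-order catalyst doubles the flux", {
  m <- toy_enzyme_model()
  f <- m$fluxes$ab
  v1 <- evaluate_flux(f, c(A = 1.7, E2 = 1))
  v2 <- evaluate_flux(f, c(A = 1.7, E2 = 2))
  expect_equal(v2, 2 * v1)
})

test_that("linear all-orders-1 case matches the matrix exponential", {
  k <- 0.8
  m <- linear_two_species_model(k)
  A <- rbind(c(-k, 0), c(k, -k))
  b <- c(1, 0)
  x0 <- c(2, 0.5)
  xinf <- -solve(A, b)
  for (t in c(1, 4, 7)) {
    oracle <- as.numeric(Matrix::expm(A * t) %*% (x0 - xinf)) + xinf
    sim <- timecourse_matrix(
      simulate_model(m, times = c(0, t), init = c(A = 2, B = 0.5)))[2, ]
    expect_lt(max(abs(sim - oracle) / abs(oracle)), 1e-6)
  }
})

test_that("piecewise reset logic is a no-op for constant activities", {
  m <- toy_enzyme_model()
  sch1 <- const_schedule(c("E1", "E2"), c(1.7, 0.6), times = c(0, 10))
  sch2 <- const_schedule(c("E1", "E2"), c(1.7, 0.6), times = 0:10)
  tc1 <- simulate_model(m, sch1, times = 0:10)
  tc2 <- simulate_model(m, sch2, times = 0:10)
  expect_equal(timecourse_matrix(tc1), timecourse_matrix(tc2),
               tolerance = 1e-8)
})

test_that("closed subnetworks conserve stoichiometry-weighted mass", {
  m <- sphingo_core_model()
  # shutting the entry and both exits closes the sphingoid network
  sch <- baseline_schedule(m, times = c(0, 30))
  sch$folds[, c("X57", "X50", "X43")] <- 0
  tc <- simulate_model(m, sch, times = seq(0, 30, 5))
  tot <- rowSums(timecourse_matrix(tc))
  expect_lt(max(abs(tot - tot[1])), 1e-6)
})

test_that("rk4 and lsoda integrators agree on smooth dynamics", {
  m <- sphingo_core_model()
  truth <- make_truth(m, seed = 3)
  t1 <- timecourse_matrix(simulate_model(m, truth, times = 0:30))
  t2 <- timecourse_matrix(simulate_model(m, truth, times = 0:30,
                                         method = "rk4", nstep = 20))
  expect_lt(max(abs(t1 - t2)), 1e-5)
})

test_that("timecourse tibble carries fold and absolute units coherently", {
  m <- sphingo_core_model()
  tc <- simulate_model(m, make_truth(m), times = 0:5)
  expect_s3_class(tc, "gma_timecourse")
  expect_equal(tc$value / 1, tc$fold)  # unit baselines
  path <- tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tc))
  expect_true(all(c("time", "species", "value", "fold", "unit") %in%
                    names(back)))
})
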