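# Small fixture models built in code.

# one species, constant influx, optional efflux
one_species_model <- function(with_efflux = FALSE) {
  fx <- list(power_law_flux("in", 1, numeric(), produces = c(A = 1)))
  if (with_efflux) {
    fx <- c(fx, list(power_law_flux("out", 1, c(A = 1), consumes = c(A = 1))))
  }
  gma_model(data.frame(id = "A", role = "dependent", baseline = 1), fx)
}

# two species, all kinetic orders 1, one dependent per flux -> linear ODE
linear_two_species_model <- function(k = 0.8) {
  gma_model(
    data.frame(id = c("A", "B"), role = "dependent", baseline = 1),
    list(
      power_law_flux("in", 1, numeric(), produces = c(A = 1)),
      power_law_flux("ab", k, c(A = 1), consumes = c(A = 1),
                     produces = c(B = 1)),
      power_law_flux("bo", k, c(B = 1), consumes = c(B = 1))
    )
  )
}

# two-species chain with two enzyme activities (determined inverse problem)
toy_enzyme_model <- function() {
  gma_model(
    data.frame(
      id = c("A", "B", "E1", "E2"),
      role = c("dependent", "dependent", "independent", "independent"),
      baseline = 1
    ),
    list(
      power_law_flux("in", 1, c(E1 = 1), produces = c(A = 1),
                     catalyst = "E1"),
      power_law_flux("ab", 1, c(A = 1, E2 = 1), consumes = c(A = 1),
                     produces = c(B = 1), catalyst = "E2"),
      power_law_flux("bo", 1, c(B = 1), consumes = c(B = 1))
    ),
    name = "toy enzyme chain"
  )
}

toy_config <- function(model = toy_enzyme_model(), ...) {
  inverse_config(model, measured = c("A", "B"), ...)
}

# constant-fold schedule over a grid
const_schedule <- function(ids, folds, times = c(0, 1)) {
  activity_schedule(
    matrix(rep(folds, each = length(times)), length(times),
           dimnames = list(NULL, ids)),
    times
  )
}

# observation tibble with identical replicates at given fold values
flat_observations <- function(fold = 1, times = seq(0, 30, 5),
                              species = measured_species()) {
  obs <- tidyr::expand_grid(species = species, time_min = times,
                            replicate = 1:2)
  obs$fold_change <- fold
  as_observation_set(obs)
}

# exact 31-point targets taken from a clean simulated trajectory
exact_targets <- function(model, schedule, grid = 0:30) {
  fm <- timecourse_matrix(simulate_model(model, schedule, times = grid),
                          fold = TRUE)
  species <- intersect(measured_species(), colnames(fm))
  obs <- tidyr::expand_grid(species = species, time_min = grid,
                            replicate = 1)
  obs$fold_change <- fm[cbind(match(obs$time_min, grid),
                              match(obs$species, colnames(fm)))]
  smooth_targets(average_replicates(as_observation_set(obs)), grid = grid,
                 method = "interpolate")
}
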