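#' Refit the model with ensemble-mean activities
#'
#' Simulates the pathway model under the ensemble-mean activity schedule
#' and reports the resulting metabolite fold curves and SSE against the
#' smoothed targets. Averages of good fits are not guaranteed to be good
#' fits themselves, so the refit is judged against the spread of the
#' member SSEs: it passes when its SSE is at most `factor` times the
#' median member SSE.
#'
#' @param model A [gma_model()].
#' @param summary An [summarize_ensemble()] result.
#' @param targets The [smooth_targets()] the ensemble was fitted to.
#' @param ensemble Optional selected `gma_ensemble`; supplies the member
#'   SSEs for the pass criterion.
#' @param factor Pass multiplier on the median member SSE (default 2).
#' @return List with `trajectory` (a `gma_timecourse`), `sse`,
#'   `median_member_sse` (or `NA`), and `pass`.
#' @export
refit_with_means <- function(model, summary, targets, ensemble = NULL,
                             factor = 2) {
  sch <- mean_activity_schedule(summary)
  tc <- simulate_model(model, sch, times = target_times(targets))
  cand <- list(trajectory = tc)
  sse <- compute_sse(cand, targets)
  med <- NA_real_
  if (!is.null(ensemble)) {
    med <- stats::median(vapply(ensemble$candidates,
                                function(c) c$sse, numeric(1)))
  }
  list(trajectory = tc, sse = sse, median_member_sse = med,
       pass = if (is.na(med)) NA else sse <= factor * med)
}

#' Flatness of the complex sphingolipids
#'
#' The complex sphingolipids IPC, MIPC and M(IP)2C stay almost constant
#' during the heat-stress response even though they were not fitted; this
#' is the out-of-sample check of an inferred activity profile. Returns
#' the maximum absolute fold-change deviation from baseline per species.
#'
#' @param tc A `gma_timecourse` (e.g. the refit trajectory).
#' @param species Complex-lipid species ids.
#' @param tol Pass threshold on the deviation (default 0.25).
#' @return List with `deviation` (named vector of max |fold - 1|) and
#'   `pass`.
#' @export
complex_lipid_flatness <- function(tc, species = c("IPC", "MIPC", "MIP2C"),
                                   tol = 0.25) {
  m <- timecourse_matrix(tc, fold = TRUE)
  miss <- setdiff(species, colnames(m))
  if (length(miss)) stop("species not in trajectory: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dev <- apply(abs(m[, species, drop = FALSE] - 1), 2, max)
  list(deviation = dev, pass = all(dev <= tol))
}

#' Clamped-enzyme negative control
#'
#' Re-runs the ensemble inference with a set of enzymes clamped at their
#' nominal steady-state activity (fold 1) while all others remain free,
#' using the same base seed and scale as the unconstrained ensemble.
#' When the clamped set contains the enzymes that actually drive the
#' dynamics, the constrained fit must be distinctly worse.
#'
#' @param model A [gma_model()].
#' @param targets A [smooth_targets()] result.
#' @param clamp Enzyme ids to fix at fold 1. An empty clamp reproduces
#'   the unconstrained ensemble exactly.
#' @param n_runs Ensemble size for both arms.
#' @param config Unconstrained [inverse_config()]; the constrained arm
#'   drops `clamp` from its free set.
#' @param seed Common base seed.
#' @return List with the two ensembles, their best SSEs, and `pass`
#'   (constrained best SSE strictly worse).
#' @export
negative_control <- function(model, targets, clamp, n_runs = 20,
                             config = inverse_config(model), seed = 1L) {
  free_con <- setdiff(config$free, clamp)
  if (!length(free_con)) stop("clamping removes every free enzyme", call. = FALSE)
  config_con <- config
  config_con$free <- free_con
  unconstrained <- run_ensemble(model, targets, n_runs, config, seed = seed)
  constrained <- run_ensemble(model, targets, n_runs, config_con, seed = seed)
  best <- function(e) min(vapply(e$candidates, function(c) c$sse, numeric(1)))
  b_u <- best(unconstrained); b_c <- best(constrained)
  list(unconstrained = unconstrained, constrained = constrained,
       best_sse_unconstrained = b_u, best_sse_constrained = b_c,
       pass = b_c > b_u)
}

#' Cumulative production of a species
#'
#' Integrates the producing and consuming fluxes of one species along a
#' simulation, so that production can be examined with degradation
#' computationally omitted: the `production` column is the accumulation
#' the species would show if none of it were consumed. Under baseline
#' activities with constant influx this accumulation is exactly linear;
#' under a heat-stress schedule it is initially steeper and then
#' flattens. The identity `baseline + production - consumption =
#' concentration` holds to integrator tolerance.
#'
#' @param model A [gma_model()].
#' @param schedule An [activity_schedule()] or `NULL` for baseline.
#' @param species Species id (default `"KDHS"`, the first committed
#'   metabolite of de novo sphingolipid biosynthesis).
#' @param times Output grid.
#' @param rtol,atol Integration tolerances.
#' @return A tibble with columns `time`, `production`, `consumption`,
#'   `concentration`.
#' @export
cumulative_production <- function(model, schedule = NULL, species = "KDHS",
                                  times = 0:30, rtol = 1e-10, atol = 1e-12) {
  mm <- gma_matrices(model)
  if (!species %in% mm$dep_ids) stop("unknown species: ", species, call. = FALSE)
  if (sum(mm$Sprod[species, ] > 0) < 1) {
    stop("species '", species, "' has no producing flux", call. = FALSE)
  }
  if (is.null(schedule)) schedule <- baseline_schedule(model, range(times))
  wp <- mm$Sprod[species, ]
  wc <- mm$Scons[species, ]
  nd <- length(mm$dep_ids)

  rhs <- function(t, y, parms) {
    v <- gma_flux_values(mm, y[seq_len(nd)], parms)
    list(c(as.numeric(mm$S %*% v), sum(wp * v), sum(wc * v)))
  }

  out <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, c("concentration", "production",
                                        "consumption")))
  y <- c(mm$dep_baseline, P = 0, C = 0)
  out[1, ] <- c(y[[species]], 0, 0)
  brk <- sort(unique(c(times, schedule$times[
    schedule$times > min(times) & schedule$times < max(times)])))
  for (i in seq_len(length(brk) - 1)) {
    k <- findInterval(brk[i], schedule$times)
    folds <- schedule_interval_folds(schedule, k)
    ind <- mm$indep_baseline
    ind[names(folds)] <- ind[names(folds)] * folds
    sol <- deSolve::lsoda(y, c(brk[i], brk[i + 1]), rhs, parms = ind,
                          rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    j <- match(brk[i + 1], times)
    if (!is.na(j)) out[j, ] <- c(y[[species]], y[["P"]], y[["C"]])
  }
  tibble::tibble(time = times,
                 production = out[, "production"],
                 consumption = out[, "consumption"],
                 concentration = out[, "concentration"])
}

#' Estimate Q10 temperature coefficients from early activity rises
#'
#' The immediate rise of an enzyme's inferred activity after the
#' temperature shift reflects the Arrhenius (Q10) effect. For a shift of
#' `delta_T` degrees, `Q10 = peak^(10 / delta_T)` where `peak` is the
#' maximum mean fold over the early window `[0, t_early]` (the rise
#' precedes the deactivation phase that sets in after a few minutes).
#'
#' @param summary An [summarize_ensemble()] result or an
#'   [activity_schedule()] (mean profiles).
#' @param delta_T Temperature shift in degrees C (default 9, the 30 to 39
#'   degree step).
#' @param t_early Early-window length in minutes (default 3).
#' @return A tibble with columns `enzyme`, `peak_fold`, `q10`.
#' @export
estimate_q10 <- function(summary, delta_T = 9, t_early = 3) {
  if (inherits(summary, "ensemble_summary")) {
    m <- attr(summary, "mean"); times <- attr(summary, "times")
  } else if (inherits(summary, "activity_schedule")) {
    m <- summary$folds; times <- summary$times
  } else stop("summary must be an ensemble_summary or activity_schedule",
              call. = FALSE)
  w <- times <= t_early
  peak <- apply(m[w, , drop = FALSE], 2, max)
  if (any(peak <= 0)) stop("non-positive fold in early window", call. = FALSE)
  tibble::tibble(enzyme = colnames(m), peak_fold = unname(peak),
                 q10 = unname(peak^(10 / delta_T)))
}
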