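#' Configuration for piecewise activity inference
#'
#' Collects the choices of the dynamic inverse problem: which enzymes are
#' free to move, box bounds on the activity folds, the random
#' initialization used at t = 0, optimizer effort per interval, and
#' whether the metabolite state carries forward from the simulation
#' (default) or is reset to the data at each interval start.
#'
#' @param model A [gma_model()].
#' @param free Character vector of independent-variable ids optimized per
#'   interval; defaults to all enzymes of the model. Everything else is
#'   held at baseline (fold 1).
#' @param measured Dependent species entering the objective; defaults to
#'   the six core sphingolipids present in the model.
#' @param bounds Length-2 fold bounds `[lo, hi]`, `lo >= 0`.
#' @param init_range Range of the log-uniform random initialization of
#'   the folds at t = 0 (spanning the plausible Q10 amplification range).
#' @param maxit Maximum L-BFGS-B iterations per interval.
#' @param max_eval Cap on objective evaluations per interval (reported;
#'   optimization stops via `maxit`).
#' @param nstep Fixed RK4 steps per 1-minute interval in the objective.
#' @param reset_state If `TRUE`, the measured species are reset to the
#'   target values at each interval start instead of carrying the
#'   simulated state forward.
#' @return A list of class `inverse_config`.
#' @export
inverse_config <- function(model, free = NULL, measured = NULL,
                           bounds = c(0, 10), init_range = c(0.25, 4),
                           maxit = 60, max_eval = 2000, nstep = 10,
                           reset_state = FALSE) {
  free <- free %||% enzyme_ids(model)
  bad <- setdiff(free, independent_ids(model))
  if (length(bad)) stop("free variables not independent in the model: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!length(free)) stop("no free variables to optimize", call. = FALSE)
  measured <- measured %||% intersect(measured_species(), dependent_ids(model))
  bad <- setdiff(measured, dependent_ids(model))
  if (length(bad)) stop("measured species not in the model: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!length(measured)) stop("no measured species", call. = FALSE)
  stopifnot(length(bounds) == 2, bounds[1] >= 0, bounds[2] > bounds[1],
            length(init_range) == 2, init_range[1] > 0,
            init_range[2] >= init_range[1])
  structure(list(free = free, measured = measured, bounds = bounds,
                 init_range = init_range, maxit = maxit,
                 max_eval = max_eval, nstep = nstep,
                 reset_state = reset_state),
            class = "inverse_config")
}

# Precomputed quantities shared by all interval optimizations.
inverse_workspace <- function(model, config) {
  mm <- gma_matrices(model)
  free <- config$free
  fixed <- setdiff(mm$indep_ids, free)
  off_fixed <- mm$log_gamma +
    as.numeric(mm$KOi[, fixed, drop = FALSE] %*%
                 log(pmax(mm$indep_baseline[fixed], 1e-12)))
  list(
    mm = mm, free = free,
    KOi_free = mm$KOi[, free, drop = FALSE],
    base_free = mm$indep_baseline[free],
    off_fixed = off_fixed,
    meas = config$measured,
    meas_idx = match(config$measured, mm$dep_ids),
    meas_base = mm$dep_baseline[config$measured]
  )
}

interval_offset <- function(ws, folds) {
  ws$off_fixed + as.numeric(ws$KOi_free %*%
                              log(pmax(folds * ws$base_free, 1e-12)))
}

#' Optimize enzyme folds over one interval
#'
#' Finds the fold vector for the free enzymes that, held constant over
#' `[t, t + dt)`, carries the current metabolite state as close as
#' possible to the target at the end of the interval. The objective is
#' the sum over measured species of squared baseline-scaled residuals
#' (i.e. fold-change residuals). Bound-constrained L-BFGS-B, warm-started
#' from the previous interval's folds; non-convergence is reported, not
#' fatal, and a simulation failure inside the objective returns a large
#' penalty.
#'
#' @param model A [gma_model()].
#' @param state Named dependent state (absolute units) at interval start.
#' @param target Named fold-change targets for the measured species at
#'   interval end.
#' @param folds_prev Named warm-start folds for the free enzymes.
#' @param config An [inverse_config()].
#' @param dt Interval length (minutes).
#' @return List with `folds`, `value` (objective at optimum),
#'   `converged`, `evals`.
#' @export
optimize_interval <- function(model, state, target, folds_prev, config,
                              dt = 1) {
  ws <- inverse_workspace(model, config)
  optimize_interval_ws(ws, state[ws$mm$dep_ids],
                       target[ws$meas], folds_prev[ws$free], config, dt)
}

optimize_interval_ws <- function(ws, y0, target_fold, par0, config, dt = 1) {
  n_eval <- 0L
  fn <- function(p) {
    n_eval <<- n_eval + 1L
    y1 <- tryCatch(
      cpp_gma_step(y0, ws$mm$KOd, ws$mm$S, interval_offset(ws, p),
                   dt, config$nstep),
      error = function(e) NULL
    )
    if (is.null(y1) || any(!is.finite(y1))) return(1e10)
    r <- y1[ws$meas_idx] / ws$meas_base - target_fold
    sum(r * r)
  }
  fit <- stats::optim(
    par0, fn, method = "L-BFGS-B",
    lower = config$bounds[1], upper = config$bounds[2],
    control = list(maxit = config$maxit, factr = 1e8)
  )
  list(folds = stats::setNames(pmin(pmax(fit$par, config$bounds[1]),
                                    config$bounds[2]), ws$free),
       value = fit$value,
       converged = fit$convergence == 0 && fit$value < 1e10,
       evals = n_eval)
}

#' Infer a dynamic enzyme-activity profile from smoothed targets
#'
#' Chains [optimize_interval()] over the consecutive 1-minute intervals
#' of the target grid. The dependent state is carried forward from the
#' simulation between intervals (activities are reset, concentrations are
#' not), unless the configuration requests data resets. The folds for the
#' first interval are warm-started from a random log-uniform draw, which
#' is what differentiates the ensemble members.
#'
#' @param model A [gma_model()].
#' @param targets A [smooth_targets()] result covering the measured
#'   species on the inference grid.
#' @param config An [inverse_config()].
#' @param seed Integer seed; recorded in the result.
#' @return An object of class `candidate_solution`: the inferred
#'   [activity_schedule()], the chained trajectory, `sse`, `aicc`, and
#'   per-interval convergence flags.
#' @export
infer_trajectory <- function(model, targets, config = inverse_config(model),
                             seed = 1L) {
  ws <- inverse_workspace(model, config)
  grid <- target_times(targets)
  tm <- target_matrix(targets)
  miss <- setdiff(ws$meas, colnames(tm))
  if (length(miss)) stop("targets missing measured species: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tm <- tm[, ws$meas, drop = FALSE]
  n_int <- length(grid) - 1L

  set.seed(seed)
  par <- stats::setNames(
    exp(stats::runif(length(ws$free), log(config$init_range[1]),
                     log(config$init_range[2]))),
    ws$free)
  par <- pmin(pmax(par, config$bounds[1]), config$bounds[2])

  folds <- matrix(NA_real_, length(grid), length(ws$free),
                  dimnames = list(NULL, ws$free))
  traj <- matrix(NA_real_, length(grid), length(ws$mm$dep_ids),
                 dimnames = list(NULL, ws$mm$dep_ids))
  y <- ws$mm$dep_baseline
  traj[1, ] <- y
  converged <- logical(n_int)
  evals <- integer(n_int)

  for (k in seq_len(n_int)) {
    dt <- grid[k + 1] - grid[k]
    res <- optimize_interval_ws(ws, y, tm[k + 1, ], par, config, dt)
    folds[k, ] <- res$folds
    converged[k] <- res$converged
    evals[k] <- res$evals
    par <- res$folds
    y <- as.numeric(cpp_gma_step(y, ws$mm$KOd, ws$mm$S,
                                 interval_offset(ws, res$folds),
                                 dt, config$nstep))
    y <- stats::setNames(pmax(y, 0), ws$mm$dep_ids)
    if (config$reset_state) {
      y[ws$meas] <- tm[k + 1, ] * ws$meas_base
    }
    traj[k + 1, ] <- y
  }
  folds[length(grid), ] <- folds[n_int, ]

  tc <- new_gma_timecourse(traj, grid, ws$mm$dep_baseline,
                           paste0("inferred (seed ", seed, ")"))
  sse <- sum((timecourse_matrix(tc, fold = TRUE)[-1, ws$meas, drop = FALSE] -
                tm[-1, , drop = FALSE])^2)
  n <- length(ws$meas) * n_int
  k_par <- length(ws$free)
  structure(
    list(schedule = activity_schedule(folds, grid, seed = seed),
         trajectory = tc,
         sse = sse,
         aicc = compute_aicc(sse, n, k_par),
         converged = converged, evals = evals, seed = seed,
         n_residuals = n, k = k_par),
    class = "candidate_solution")
}

#' @export
print.candidate_solution <- function(x, ...) {
  cat("<candidate_solution> seed ", x$seed, ": SSE = ",
      format(x$sse, digits = 4), ", AICc = ", format(x$aicc, digits = 4),
      ", ", sum(x$converged), "/", length(x$converged),
      " intervals converged\n", sep = "")
  invisible(x)
}

#' Residual error of a candidate against smoothed targets
#'
#' Sum over the measured species and all post-baseline grid points of
#' squared baseline-scaled (fold-change) residuals.
#'
#' @param candidate A `candidate_solution`.
#' @param targets A [smooth_targets()] result on the same grid.
#' @return Non-negative scalar.
#' @export
compute_sse <- function(candidate, targets) {
  tm <- target_matrix(targets)
  sim <- timecourse_matrix(candidate$trajectory, fold = TRUE)
  species <- intersect(colnames(tm), colnames(sim))
  if (!length(species)) stop("no common species", call. = FALSE)
  if (nrow(tm) != nrow(sim)) stop("trajectory and targets have different grids",
                                  call. = FALSE)
  sum((sim[-1, species, drop = FALSE] - tm[-1, species, drop = FALSE])^2)
}

#' Small-sample corrected Akaike criterion
#'
#' `AICc = n log(SSE / n) + 2k + 2k(k + 1) / (n - k - 1)`, with `n` the
#' number of residuals and `k` the number of free parameters (here: the
#' number of optimized enzymes; see the methods vignette for why the
#' per-interval fold values are not each counted as a parameter).
#'
#' @param sse Residual sum of squares.
#' @param n Number of residuals.
#' @param k Number of free parameters.
#' @return Scalar AICc; errors if `n - k - 1 <= 0`.
#' @export
compute_aicc <- function(sse, n, k) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0", call. = FALSE)
  n * log(max(sse, .Machine$double.xmin) / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}

#' Run a Monte-Carlo ensemble of inference candidates
#'
#' Repeats [infer_trajectory()] from independent random initializations
#' with seeds derived reproducibly from a base seed. Individual failures
#' are recorded and skipped, not fatal.
#'
#' @param model A [gma_model()].
#' @param targets A [smooth_targets()] result.
#' @param n_runs Number of candidates.
#' @param config An [inverse_config()].
#' @param seed Base seed from which the per-run seeds are derived.
#' @return A `gma_ensemble`: list of `candidate_solution`s plus run
#'   metadata; see [tidy.gma_ensemble()].
#' @export
run_ensemble <- function(model, targets, n_runs = 100,
                         config = inverse_config(model), seed = 1L) {
  stopifnot(n_runs >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  out <- vector("list", n_runs)
  errors <- character()
  for (i in seq_len(n_runs)) {
    out[[i]] <- tryCatch(
      infer_trajectory(model, targets, config, seed = seeds[i]),
      error = function(e) {
        errors[[length(errors) + 1]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(out, is.null, logical(1))
  structure(list(candidates = out[ok], seeds = seeds[ok],
                 n_requested = n_runs, errors = errors,
                 config = config, base_seed = seed),
            class = "gma_ensemble")
}

#' @export
print.gma_ensemble <- function(x, ...) {
  sse <- vapply(x$candidates, function(c) c$sse, numeric(1))
  cat("<gma_ensemble> ", length(x$candidates), "/", x$n_requested,
      " candidates (base seed ", x$base_seed, ")\n", sep = "")
  if (length(sse)) {
    cat("  SSE: best ", format(min(sse), digits = 4), ", median ",
        format(stats::median(sse), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy and glance methods for inference ensembles
#'
#' @param x A `gma_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return `tidy()`: one row per candidate with `run`, `seed`, `sse`,
#'   `aicc`, `converged_frac`. `glance()`: a one-row summary.
#' @export
tidy.gma_ensemble <- function(x, ...) {
  tibble::tibble(
    run = seq_along(x$candidates),
    seed = x$seeds,
    sse = vapply(x$candidates, function(c) c$sse, numeric(1)),
    aicc = vapply(x$candidates, function(c) c$aicc, numeric(1)),
    converged_frac = vapply(x$candidates,
                            function(c) mean(c$converged), numeric(1))
  )
}

#' @rdname tidy.gma_ensemble
#' @export
glance.gma_ensemble <- function(x, ...) {
  d <- tidy.gma_ensemble(x)
  tibble::tibble(
    n_runs = x$n_requested, n_ok = nrow(d), n_failed = length(x$errors),
    best_sse = min(d$sse), median_sse = stats::median(d$sse),
    best_aicc = min(d$aicc)
  )
}

#' Select the best candidates of an ensemble
#'
#' Top-N by ascending SSE or AICc; ties are broken by run order (seed
#' order), so selection is deterministic.
#'
#' @param ensemble A `gma_ensemble`.
#' @param n Number of candidates to keep.
#' @param criterion `"sse"` or `"aicc"`.
#' @return A `gma_ensemble` containing the selected candidates.
#' @export
select_top <- function(ensemble, n, criterion = c("sse", "aicc")) {
  criterion <- match.arg(criterion)
  if (!length(ensemble$candidates)) stop("empty ensemble", call. = FALSE)
  if (n > length(ensemble$candidates)) {
    stop("n exceeds the number of candidates", call. = FALSE)
  }
  v <- vapply(ensemble$candidates, function(c) c[[criterion]], numeric(1))
  idx <- order(v)[seq_len(n)]
  out <- ensemble
  out$candidates <- ensemble$candidates[idx]
  out$seeds <- ensemble$seeds[idx]
  out$n_requested <- n
  out$selection <- list(criterion = criterion, n = n)
  out
}

#' Agreement between SSE- and AICc-based selection
#'
#' Percentage of the top-N candidates by SSE that also appear in the
#' top-N by AICc. With a common parameter count across candidates the
#' two rankings coincide and the agreement is 100%.
#'
#' @param ensemble A `gma_ensemble`.
#' @param n Selection size.
#' @return Percentage in `[0, 100]`.
#' @export
criterion_agreement <- function(ensemble, n) {
  top_sse <- select_top(ensemble, n, "sse")$seeds
  top_aicc <- select_top(ensemble, n, "aicc")$seeds
  100 * length(intersect(top_sse, top_aicc)) / n
}
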