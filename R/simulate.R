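#' Simulate a GMA model under a piecewise-constant activity schedule
#'
#' Integrates the model ODEs interval by interval. Within each interval of
#' the schedule grid the independent variables are held constant at the
#' schedule's fold values times their baselines; the dependent state
#' carries over continuously across interval boundaries (activities are
#' reset, concentrations are not). With `schedule = NULL` all independent
#' variables stay at baseline throughout.
#'
#' The default integrator is the stiff-capable `deSolve::lsoda` with tight
#' tolerances; `method = "rk4"` uses the package's compiled fixed-step
#' integrator (the one used inside the inference objective).
#'
#' @param model A [gma_model()].
#' @param schedule An [activity_schedule()] covering `times`, or `NULL`.
#' @param times Output grid (minutes); must lie within the schedule grid.
#' @param init Named initial dependent state (absolute units); defaults to
#'   the model baselines.
#' @param method `"lsoda"` (default) or `"rk4"`.
#' @param rtol,atol Integration tolerances for `lsoda`.
#' @param nstep RK4 steps per unit time for `method = "rk4"`.
#' @return A `gma_timecourse`: a tibble with columns `time`, `species`,
#'   `value` (absolute model units) and `fold` (value over baseline),
#'   carrying the trajectory matrix as an attribute.
#' @export
simulate_model <- function(model, schedule = NULL, times = 0:30, init = NULL,
                           method = c("lsoda", "rk4"),
                           rtol = 1e-8, atol = 1e-10, nstep = 20) {
  method <- match.arg(method)
  mm <- gma_matrices(model)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)

  y0 <- mm$dep_baseline
  if (!is.null(init)) {
    bad <- setdiff(names(init), mm$dep_ids)
    if (length(bad)) stop("unknown species in init: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    y0[names(init)] <- init
  }

  if (is.null(schedule)) {
    schedule <- baseline_schedule(model, times = range(times))
  }
  bad <- setdiff(colnames(schedule$folds), mm$indep_ids)
  if (length(bad)) stop("schedule covers unknown independent variable(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (min(times) < min(schedule$times) || max(times) > max(schedule$times)) {
    stop("schedule grid does not cover the requested times", call. = FALSE)
  }

  # breakpoints: schedule grid points that fall inside the requested span
  brk <- sort(unique(c(times, schedule$times[
    schedule$times > min(times) & schedule$times < max(times)
  ])))

  traj <- matrix(NA_real_, length(times), length(mm$dep_ids),
                 dimnames = list(NULL, mm$dep_ids))
  if (times[1] %in% brk) traj[1, ] <- y0

  rhs <- function(t, y, parms) {
    list(as.numeric(mm$S %*% gma_flux_values(mm, y, parms)))
  }

  y <- y0
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    # schedule interval containing [t0, t1)
    k <- findInterval(t0, schedule$times)
    folds <- schedule_interval_folds(schedule, k)
    ind <- mm$indep_baseline
    ind[names(folds)] <- ind[names(folds)] * folds
    if (method == "lsoda") {
      sol <- deSolve::lsoda(y, c(t0, t1), rhs, parms = ind,
                            rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0 || anyNA(sol[nrow(sol), -1])) {
        cond <- structure(
          class = c("sphingodyn_simulation_error", "error", "condition"),
          list(message = sprintf(
            "integration failed on interval [%g, %g]", t0, t1),
            call = sys.call(-1), interval = c(t0, t1))
        )
        stop(cond)
      }
      y <- sol[nrow(sol), -1]
    } else {
      lg_off <- mm$log_gamma + as.numeric(mm$KOi %*% log(pmax(ind, 1e-12)))
      y <- as.numeric(cpp_gma_step(y, mm$KOd, mm$S, lg_off,
                                   t1 - t0, max(1L, ceiling(nstep * (t1 - t0)))))
    }
    y <- stats::setNames(pmax(as.numeric(y), 0), mm$dep_ids)
    j <- match(t1, times)
    if (!is.na(j)) traj[j, ] <- y
  }

  new_gma_timecourse(traj, times, mm$dep_baseline, model$name)
}

new_gma_timecourse <- function(traj, times, baseline, model_name) {
  out <- tibble::tibble(
    time = rep(times, ncol(traj)),
    species = rep(colnames(traj), each = length(times)),
    value = as.vector(traj),
    fold = as.vector(sweep(traj, 2, baseline, "/"))
  )
  structure(out, class = c("gma_timecourse", class(out)),
            matrix = traj, times = times, baseline = baseline,
            model = model_name)
}

#' Extract the trajectory matrix of a time course
#'
#' @param tc A `gma_timecourse` from [simulate_model()].
#' @param fold If `TRUE`, values are scaled by the species baselines.
#' @return Numeric matrix, times by species.
#' @export
timecourse_matrix <- function(tc, fold = FALSE) {
  m <- attr(tc, "matrix")
  if (fold) m <- sweep(m, 2, attr(tc, "baseline"), "/")
  m
}

#' @export
print.gma_timecourse <- function(x, ...) {
  cat("<gma_timecourse> ", length(attr(x, "times")), " times x ",
      ncol(attr(x, "matrix")), " species (", attr(x, "model"), ")\n", sep = "")
  NextMethod()
}

#' Write a time course as tidy CSV
#'
#' Columns `time`, `species`, `value`, `fold`, `unit`.
#'
#' @param tc A `gma_timecourse`.
#' @param path Output file.
#' @param unit Unit label stored with absolute values.
#' @export
write_timecourse <- function(tc, path, unit = "model units") {
  df <- as.data.frame(tc[, c("time", "species", "value", "fold")])
  df$unit <- unit
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
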