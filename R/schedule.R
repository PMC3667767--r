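#' Piecewise-constant enzyme-activity schedules
#'
#' An activity schedule holds, for each scheduled independent variable, a
#' fold-change multiplier at every grid time; the value at grid point
#' \eqn{t_i} applies over the interval \eqn{[t_i, t_{i+1})}. Absolute
#' activity is fold times the variable's baseline. Independent variables
#' not covered by the schedule stay at fold 1.
#'
#' @param folds A numeric matrix with `length(times)` rows and one named
#'   column per scheduled variable, or a named list of numeric vectors.
#' @param times Strictly increasing numeric grid (minutes).
#' @param seed Optional provenance seed recorded with the schedule.
#' @return An object of class `activity_schedule`.
#' @export
activity_schedule <- function(folds, times, seed = NULL) {
  if (is.list(folds) && !is.matrix(folds)) {
    folds <- do.call(cbind, folds)
  }
  if (is.null(dim(folds))) folds <- matrix(folds, ncol = 1)
  if (ncol(folds) > 0 && is.null(colnames(folds))) {
    stop("schedule folds must have named columns (one per variable)",
         call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with length >= 2", call. = FALSE)
  }
  if (nrow(folds) != length(times)) {
    stop("folds must have one row per grid time", call. = FALSE)
  }
  if (any(!is.finite(folds)) || any(folds < 0)) {
    stop("folds must be finite and >= 0", call. = FALSE)
  }
  structure(list(times = times, folds = folds, seed = seed),
            class = "activity_schedule")
}

#' @rdname activity_schedule
#' @param model A [gma_model()]; scheduled variables default to its enzymes.
#' @param value Constant fold applied everywhere (default 1, the baseline).
#' @export
baseline_schedule <- function(model, times = 0:30, value = 1) {
  ids <- enzyme_ids(model)
  activity_schedule(
    matrix(value, length(times), length(ids), dimnames = list(NULL, ids)),
    times
  )
}

#' @export
print.activity_schedule <- function(x, ...) {
  cat("<activity_schedule> ", ncol(x$folds), " variables on t = [",
      min(x$times), ", ", max(x$times), "] (", length(x$times),
      " grid points)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.activity_schedule <- function(x, ...) {
  as.data.frame(tidy.activity_schedule(x))
}

#' Tidy an activity schedule into long format
#'
#' @param x An [activity_schedule()].
#' @param ... Unused.
#' @return A tibble with columns `enzyme`, `time`, `fold`.
#' @export
tidy.activity_schedule <- function(x, ...) {
  tibble::tibble(
    enzyme = rep(colnames(x$folds), each = length(x$times)),
    time = rep(x$times, ncol(x$folds)),
    fold = as.vector(x$folds)
  )
}

# folds for the interval starting at grid index i (piecewise-constant rule)
schedule_interval_folds <- function(schedule, i) {
  schedule$folds[min(i, nrow(schedule$folds)), , drop = TRUE]
}
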