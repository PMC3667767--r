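#' Read and validate an observation set
#'
#' Observations are duplicate fold-change measurements of the six core
#' sphingolipids at the sampling design times (0, 5, ..., 30 min), with
#' baseline defined as fold 1 at t = 0.
#'
#' @param path CSV file with columns `species`, `time_min`, `replicate`,
#'   `fold_change`.
#' @return A tibble of class `observation_set`.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_observation_set(df)
}

#' @rdname read_observations
#' @param df A data frame with the observation columns.
#' @export
as_observation_set <- function(df) {
  need <- c("species", "time_min", "replicate", "fold_change")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!is.finite(df$fold_change)) || any(df$fold_change <= 0)) {
    stop("fold changes must be positive and finite", call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  class(out) <- c("observation_set", class(out))
  out
}

#' Average replicate measurements
#'
#' Arithmetic mean of the replicate fold changes per species and time.
#' Replicate scatter is retained in `sd` (used by the synthetic-data
#' noise calibration, not by the inference objective).
#'
#' @param obs An observation set (see [read_observations()]).
#' @return A tibble with columns `species`, `time_min`, `fold`, `sd`, `n`.
#' @export
average_replicates <- function(obs) {
  obs <- as_observation_set(obs)
  out <- dplyr::summarise(
    dplyr::group_by(obs, .data$species, .data$time_min),
    fold = mean(.data$fold_change),
    sd = stats::sd(.data$fold_change),
    n = dplyr::n(),
    .groups = "drop"
  )
  full <- tidyr::expand_grid(species = unique(out$species),
                             time_min = unique(out$time_min))
  gap <- dplyr::anti_join(full, out, by = c("species", "time_min"))
  if (nrow(gap)) {
    stop("missing observation(s): ",
         paste(sprintf("%s@t=%g", gap$species, gap$time_min), collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(out, .data$species, .data$time_min)
}

#' Smooth sparse fold-change series onto a dense grid
#'
#' Fits a cubic smoothing spline per species to the replicate-averaged
#' fold changes and evaluates it on a dense grid (by default the 31
#' points 0, 1, ..., 30 min). The smoothing level is chosen by
#' generalized cross-validation unless `spar` or `df` is given;
#' `method = "interpolate"` uses an exact cubic interpolation spline
#' instead (the zero-smoothing limit). Curves are floor-clipped at a
#' small positive `eps` so downstream power laws stay defined.
#'
#' @param means Output of [average_replicates()] (columns `species`,
#'   `time_min`, `fold`).
#' @param grid Output grid in minutes.
#' @param method `"gcv"` (smoothing spline, GCV) or `"interpolate"`.
#' @param spar,df Optional smoothing parameter / equivalent degrees of
#'   freedom passed to [stats::smooth.spline()].
#' @param eps Positive floor for the smoothed fold curves.
#' @return A tibble of class `smoothed_targets` with columns `species`,
#'   `time`, `fold`, carrying the curve matrix as an attribute.
#' @export
smooth_targets <- function(means, grid = 0:30, method = c("gcv", "interpolate"),
                           spar = NULL, df = NULL, eps = 1e-6) {
  method <- match.arg(method)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  species <- unique(means$species)
  curves <- matrix(NA_real_, length(grid), length(species),
                   dimnames = list(NULL, species))
  for (s in species) {
    d <- means[means$species == s, ]
    d <- d[order(d$time_min), ]
    if (nrow(d) < 4) stop("species '", s, "' has fewer than 4 time points",
                          call. = FALSE)
    if (method == "interpolate") {
      y <- stats::spline(d$time_min, d$fold, xout = grid, method = "natural")$y
    } else {
      fit <- if (!is.null(spar)) {
        stats::smooth.spline(d$time_min, d$fold, spar = spar)
      } else if (!is.null(df)) {
        stats::smooth.spline(d$time_min, d$fold, df = df)
      } else {
        stats::smooth.spline(d$time_min, d$fold, cv = FALSE)
      }
      y <- stats::predict(fit, grid)$y
    }
    curves[, s] <- pmax(y, eps)
  }
  out <- tibble::tibble(
    species = rep(species, each = length(grid)),
    time = rep(grid, times = length(unique(means$species))),
    fold = as.vector(curves)
  )
  structure(out, class = c("smoothed_targets", class(out)),
            matrix = curves, times = grid)
}

#' @rdname smooth_targets
#' @param targets A `smoothed_targets` object.
#' @export
target_matrix <- function(targets) attr(targets, "matrix")

#' @rdname smooth_targets
#' @export
target_times <- function(targets) attr(targets, "times")

#' Convert between fold-change and absolute concentration curves
#'
#' Absolute concentration = fold change times the species' steady-state
#' baseline; the two functions are exact inverses.
#'
#' @param curves A tibble with columns `species` and `fold` (or `value`
#'   for the inverse direction).
#' @param baselines Named positive vector of steady-state concentrations.
#' @return The input tibble with the converted column added.
#' @export
fold_to_absolute <- function(curves, baselines) {
  check_baselines(baselines, unique(curves$species))
  dplyr::mutate(curves, value = .data$fold * unname(baselines[.data$species]))
}

#' @rdname fold_to_absolute
#' @export
absolute_to_fold <- function(curves, baselines) {
  check_baselines(baselines, unique(curves$species))
  dplyr::mutate(curves, fold = .data$value / unname(baselines[.data$species]))
}

check_baselines <- function(baselines, species) {
  miss <- setdiff(species, names(baselines))
  if (length(miss)) stop("no baseline for: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(baselines[species] <= 0) || any(!is.finite(baselines[species]))) {
    stop("baselines must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}
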