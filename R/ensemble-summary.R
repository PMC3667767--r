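#' Summarize a selected ensemble of activity profiles
#'
#' Per enzyme and grid point: the pointwise arithmetic mean of the member
#' fold values and the pointwise 2.5%/97.5% quantile envelope (the band
#' enclosing 95% of the member trajectories). The relative band width —
#' the grid average of `(upper - lower) / max(mean, eps)` — is the
#' identifiability statistic used by [classify_identifiability()].
#'
#' @param ensemble A `gma_ensemble` (usually after [select_top()]) with
#'   at least 2 candidates.
#' @param coverage Envelope coverage (default 0.95).
#' @param eps Floor protecting the relative band width near zero means.
#' @return An `ensemble_summary`: a tibble with columns `enzyme`, `time`,
#'   `mean`, `lower`, `upper` and attributes `band_width` (named vector)
#'   and `coverage`.
#' @export
summarize_ensemble <- function(ensemble, coverage = 0.95, eps = 0.05) {
  if (length(ensemble$candidates) < 2) {
    stop("need at least 2 candidates to summarize", call. = FALSE)
  }
  sch <- lapply(ensemble$candidates, function(c) c$schedule$folds)
  enzymes <- colnames(sch[[1]])
  times <- ensemble$candidates[[1]]$schedule$times
  arr <- array(unlist(sch), dim = c(length(times), length(enzymes),
                                    length(sch)))
  a <- (1 - coverage) / 2
  mean_m <- apply(arr, c(1, 2), mean)
  lo_m <- apply(arr, c(1, 2), stats::quantile, probs = a, names = FALSE)
  hi_m <- apply(arr, c(1, 2), stats::quantile, probs = 1 - a, names = FALSE)
  dimnames(mean_m) <- dimnames(lo_m) <- dimnames(hi_m) <-
    list(NULL, enzymes)
  bw <- colMeans((hi_m - lo_m) / pmax(mean_m, eps))
  out <- tibble::tibble(
    enzyme = rep(enzymes, each = length(times)),
    time = rep(times, length(enzymes)),
    mean = as.vector(mean_m),
    lower = as.vector(lo_m),
    upper = as.vector(hi_m)
  )
  structure(out, class = c("ensemble_summary", class(out)),
            mean = mean_m, lower = lo_m, upper = hi_m,
            times = times, band_width = bw, coverage = coverage,
            n_members = length(sch))
}

#' Classify enzyme identifiability from envelope width
#'
#' An enzyme is `tight` when its mean relative envelope width is below
#' the threshold, `loose` otherwise. Tight bands mean the measured data
#' pin the enzyme's activity profile regardless of the random
#' initialization; loose bands mean the profile is not identifiable.
#'
#' @param summary An [summarize_ensemble()] result.
#' @param threshold Relative band-width threshold (default 0.75).
#' @return A tibble with columns `enzyme`, `band_width`, `class`, and
#'   `zone` where the enzyme is in the pathway registry.
#' @export
classify_identifiability <- function(summary, threshold = 0.75) {
  bw <- attr(summary, "band_width")
  reg <- sphingo_registry()
  tibble::tibble(
    enzyme = names(bw),
    band_width = unname(bw),
    class = ifelse(bw < threshold, "tight", "loose"),
    zone = reg$zone[match(names(bw), reg$index)]
  )
}

#' Ensemble-mean activity schedule
#'
#' The schedule whose folds are the pointwise ensemble means — the object
#' entered into the pathway model for the averaged-model refit. Note that
#' averages of good fits need not themselves be good fits; the refit
#' reports its own SSE.
#'
#' @param summary An [summarize_ensemble()] result.
#' @return An [activity_schedule()].
#' @export
mean_activity_schedule <- function(summary) {
  activity_schedule(attr(summary, "mean"), attr(summary, "times"))
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> ", length(attr(x, "band_width")), " enzymes, ",
      attr(x, "n_members"), " members, ",
      100 * attr(x, "coverage"), "% envelopes\n", sep = "")
  NextMethod()
}

#' Zone-level report of an ensemble summary
#'
#' Groups the identifiability classification by pathway zone.
#'
#' @param summary An [summarize_ensemble()] result.
#' @param threshold Passed to [classify_identifiability()].
#' @return A tibble with one row per zone: enzyme count, tight count,
#'   median band width.
#' @export
zone_report <- function(summary, threshold = 0.75) {
  cls <- classify_identifiability(summary, threshold)
  dplyr::summarise(
    dplyr::group_by(cls, .data$zone),
    n_enzymes = dplyr::n(),
    n_tight = sum(.data$class == "tight"),
    median_band_width = stats::median(.data$band_width),
    .groups = "drop"
  )
}
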