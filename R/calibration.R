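#' Care-stage interval specification
#'
#' A printed median/IQR summary for one care stage, the calibration unit the
#' duration distributions are fitted from.
#'
#' @param stage stage identifier (character scalar).
#' @param median,q1,q3 minutes; `q1 <= median <= q3`, all nonnegative, and
#'   strictly positive unless the stage is zero-inflated.
#' @param zero_inflated logical; `TRUE` for stages whose printed median (or
#'   lower quartile) is 0 minutes, which require a point-mass-at-zero fit.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(stage, median, q1, q3, zero_inflated = (median == 0 || q1 == 0)) {
  stopifnot(is.character(stage), length(stage) == 1L)
  if (any(c(median, q1, q3) < 0)) stop("stage quantiles must be nonnegative")
  if (!(q1 <= median && median <= q3))
    stop(sprintf("stage '%s': need q1 <= median <= q3", stage))
  if (!zero_inflated && q1 <= 0)
    stop(sprintf("stage '%s': zero quantile requires zero_inflated = TRUE", stage))
  structure(list(stage = stage, median = median, q1 = q1, q3 = q3,
                 zero_inflated = isTRUE(zero_inflated)),
            class = "stage_spec")
}

#' Fit the duration distribution for one stage spec
#'
#' Dispatches to [fit_zero_inflated()] for zero-inflated stages and to
#' [fit_lognormal_from_quantiles()] otherwise.
#'
#' @param spec a [stage_spec()].
#' @return A [lognormal_params()] object.
#' @export
fit_stage <- function(spec) {
  stopifnot(inherits(spec, "stage_spec"))
  if (spec$zero_inflated) {
    fit_zero_inflated(spec$median, spec$q1, spec$q3)
  } else {
    fit_lognormal_from_quantiles(spec$median, spec$q1, spec$q3)
  }
}

path_extdata <- function(file) {
  p <- system.file("extdata", file, package = "pedflow")
  if (!nzchar(p)) stop(sprintf("calibration file '%s' not found", file))
  p
}

#' Default care-stage interval specs for one trial arm
#'
#' Reads the versioned calibration table shipped with the package: the 11
#' care-stage intervals (minutes, median and IQR) for the requested arm of
#' the day-randomized trial.  Zero-median stages are flagged for the
#' zero-inflated fit.
#'
#' @param arm `"control"` (standard dashboard days) or `"optimum"`
#'   (secondary-triage prioritizer days).
#' @param path optional override of the shipped calibration file.
#' @return Named list of [stage_spec()] objects, one per stage.
#' @export
default_stage_specs <- function(arm = c("control", "optimum"), path = NULL) {
  arm <- match.arg(arm)
  if (is.null(path)) path <- path_extdata("stage_intervals.csv")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("stage", "arm", "median", "q1", "q3", "zero_inflated")
  if (!all(need %in% names(tab))) stop("malformed stage-interval calibration file")
  tab <- tab[tab$arm == arm, , drop = FALSE]
  if (nrow(tab) == 0L) stop(sprintf("unknown arm '%s' in calibration file", arm))
  specs <- lapply(seq_len(nrow(tab)), function(i)
    stage_spec(tab$stage[i], tab$median[i], tab$q1[i], tab$q3[i],
               zero_inflated = tab$zero_inflated[i] == 1))
  names(specs) <- tab$stage
  specs
}

#' Fitted duration distributions for all stages of one arm
#'
#' @inheritParams default_stage_specs
#' @param specs optionally, a list of [stage_spec()] as returned by
#'   [default_stage_specs()].
#' @return Named list of [lognormal_params()].
#' @export
fit_stage_distributions <- function(arm = c("control", "optimum"), specs = NULL) {
  if (is.null(specs)) specs <- default_stage_specs(arm)
  lapply(specs, fit_stage)
}

#' Case-mix distribution over patient attributes
#'
#' Categorical marginals over admission reason, simplified 3-level triage
#' priority, care-plan item counts (blood tests, imaging, specialist
#' consults, treatment lines, senior evaluations), disposition, and sex.
#' Probabilities are renormalized to sum to exactly 1 per attribute.
#'
#' @param probs named list; each element a named nonnegative numeric vector
#'   of category probabilities (or percentages).
#' @return An object of class `case_mix`: the list with each element
#'   renormalized.
#' @export
case_mix <- function(probs) {
  stopifnot(is.list(probs), length(names(probs)) == length(probs))
  out <- lapply(names(probs), function(a) {
    p <- probs[[a]]
    if (is.null(names(p)) || any(p < 0) || sum(p) <= 0)
      stop(sprintf("attribute '%s': probabilities must be named, nonnegative, with positive sum", a))
    p / sum(p)
  })
  names(out) <- names(probs)
  structure(out, class = "case_mix")
}

#' Default case mix
#'
#' The whole-cohort attribute percentages shipped with the package,
#' renormalized per attribute (printed columns sum to 99.9--100.1% because
#' of rounding).  High/moderate/low triage priority is the simplified
#' 3-level acuity scale (5-level PaedCTAS collapsed as 1--2 / 3--4 / 5).
#'
#' @param path optional override of the shipped calibration file.
#' @return A [case_mix()] object.
#' @examples
#' cm <- default_case_mix()
#' cm$priority["high"]  # ~0.131
#' @export
default_case_mix <- function(path = NULL) {
  if (is.null(path)) path <- path_extdata("case_mix.csv")
  tab <- utils::read.csv(path, comment.char = "#",
                         colClasses = c("character", "character", "numeric"))
  if (!all(c("attribute", "category", "pct") %in% names(tab)))
    stop("malformed case-mix calibration file")
  probs <- split(tab, tab$attribute)
  probs <- lapply(probs, function(d) stats::setNames(d$pct, d$category))
  # keep file order of attributes
  probs <- probs[unique(tab$attribute)]
  case_mix(probs)
}

#' Reference LOS percentile table
#'
#' Builds the reason-specific 50th/75th/95th length-of-stay percentiles the
#' status colors are computed against, from a set of completed visits.
#' Quantiles use linear interpolation between order statistics (R's type-7
#' convention, the fixed rule used throughout the package).  Reason
#' categories with fewer than `min_n` completed visits fall back to the
#' pooled all-reason percentiles.
#'
#' @param completed_visits data frame with columns `reason` and `los`
#'   (total length of stay, minutes).
#' @param min_n minimum completed visits per reason before the pooled
#'   fallback applies (default 20).
#' @param reasons reason categories the table must cover; defaults to the
#'   categories present in the input.
#' @return An object of class `los_reference`: a data frame with columns
#'   `reason`, `p50`, `p75`, `p95`, `n`, plus a `pooled` attribute.
#' @export
build_los_reference <- function(completed_visits, min_n = 20,
                                reasons = unique(completed_visits$reason)) {
  if (!is.data.frame(completed_visits) ||
      !all(c("reason", "los") %in% names(completed_visits)))
    stop("'completed_visits' must be a data frame with columns 'reason' and 'los'")
  if (nrow(completed_visits) == 0L) stop("no completed visits to build a reference from")
  if (any(completed_visits$los < 0)) stop("negative LOS in completed visits")
  if (!all(completed_visits$reason %in% reasons))
    stop("unknown reason category in completed visits")
  qs <- function(x) stats::quantile(x, c(0.5, 0.75, 0.95), type = 7, names = FALSE)
  pooled <- qs(completed_visits$los)
  rows <- lapply(reasons, function(r) {
    x <- completed_visits$los[completed_visits$reason == r]
    p <- if (length(x) >= min_n) qs(x) else pooled
    data.frame(reason = r, p50 = p[1], p75 = p[2], p95 = p[3], n = length(x))
  })
  out <- do.call(rbind, rows)
  structure(out, pooled = pooled, class = c("los_reference", "data.frame"))
}

#' Look up the LOS percentiles for a reason category
#'
#' @param reference a [build_los_reference()] table.
#' @param reason reason category; unknown categories fall back to the pooled
#'   percentiles.
#' @return Numeric vector `c(p50, p75, p95)` in minutes.
#' @export
los_percentiles <- function(reference, reason) {
  stopifnot(inherits(reference, "los_reference"))
  i <- match(reason, reference$reason)
  if (is.na(i)) return(attr(reference, "pooled"))
  c(reference$p50[i], reference$p75[i], reference$p95[i])
}

#' Default synthetic LOS reference table
#'
#' The original prioritizer drew its percentiles from a historical reference
#' database that is not available; the package substitutes a synthetic
#' reference built by simulating completed visits from the control-arm stage
#' calibration and the default case mix.  Granularity is the 5 published
#' reason categories.
#'
#' @param n_visits completed visits to simulate (default 2000).
#' @param seed RNG seed for the reference simulation.
#' @return A [build_los_reference()] table.
#' @export
default_los_reference <- function(n_visits = 2000, seed = 20210315) {
  cm <- default_case_mix()
  fits <- fit_stage_distributions("control")
  set.seed(seed %% .Machine$integer.max)
  profiles <- sample_patients(n_visits, cm)
  profiles$arrival_time <- 0
  los <- simulate_trajectory_los(profiles, fits)
  keep <- !is.na(los)
  build_los_reference(data.frame(reason = profiles$reason[keep], los = los[keep]),
                      reasons = names(cm$reason))
}
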