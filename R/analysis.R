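# from-event -> to-event per named interval; first occurrences are used.
INTERVAL_DEFS <- list(
  admission_to_triage                = c("arrival", "triage"),
  triage_to_first_eval               = c("triage", "first_eval"),
  first_eval_to_junior               = c("first_eval", "junior_eval"),
  admission_to_senior                = c("arrival", "senior_eval"),
  blood_prescription_to_sampling     = c("blood_prescription", "blood_sampling"),
  blood_sampling_to_results          = c("blood_sampling", "blood_results_review"),
  imaging_prescription_to_results    = c("imaging_prescription", "imaging_results_review"),
  specialist_prescription_to_consult = c("specialist_prescription", "specialist_consult"),
  treatment_prescription_to_admin    = c("treatment_prescription", "treatment_admin"),
  final_decision_to_end_of_care      = c("final_decision", "end_of_care"),
  end_of_care_to_discharge           = c("end_of_care", "discharge"),
  total_los                          = c("arrival", "discharge")
)

#' Extract per-patient care intervals from an event log
#'
#' Computes the 11 named care-stage intervals plus the total length of stay
#' (arrival to discharge) for every patient, using each milestone's first
#' occurrence.  An interval is missing (`NA`) when either milestone is
#' absent (stage not applicable, or stay incomplete).  The log is linted
#' against the stage graph first.
#'
#' @param log a [event_log()].
#' @return Data frame (`interval_table`) with columns `patient_id`, `arm`,
#'   `priority`, `interval`, `value` (minutes, `NA` when undefined).
#' @export
extract_intervals <- function(log) {
  lint_event_log(log)
  profiles <- attr(log, "profiles")
  # first occurrence of each event per patient
  key <- paste(log$patient_id, log$event, sep = "\r")
  first <- tapply(log$t_minutes, key, min)
  ids <- unique(log$patient_id)
  rows <- lapply(names(INTERVAL_DEFS), function(iv) {
    from <- INTERVAL_DEFS[[iv]][1]; to <- INTERVAL_DEFS[[iv]][2]
    a <- first[paste(ids, from, sep = "\r")]
    b <- first[paste(ids, to, sep = "\r")]
    data.frame(patient_id = ids, interval = iv,
               value = unname(b - a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- match(out$patient_id, profiles$patient_id)
  out$arm <- log$arm[match(out$patient_id, log$patient_id)]
  out$priority <- profiles$priority[m]
  if (any(out$value < 0, na.rm = TRUE)) {
    bad <- out$patient_id[which(out$value < 0)][1]
    stop(sprintf("negative interval for patient %s", bad))
  }
  structure(out[c("patient_id", "arm", "priority", "interval", "value")],
            class = c("interval_table", "data.frame"))
}

#' Median and interquartile range of a sample
#'
#' Uses the same fixed order-statistic interpolation rule (type 7) as the
#' LOS reference table so summaries and reference percentiles agree.
#'
#' @param values nonempty numeric vector; `NA`s are dropped.
#' @return List with `n`, `median`, `q1`, `q3`.
#' @export
summarize_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
}

#' Mean census curve over the time of day
#'
#' For each time-of-day bin, the average (across days) number of patients
#' simultaneously present in the department.  Presence runs from arrival to
#' discharge (or walk-out); occupancy is bin-averaged (overlap of the
#' presence interval with the bin, divided by the bin width), so the
#' conservation identity `sum(mean_count) * step * n_days = total
#' patient-minutes within the horizon` holds exactly.
#'
#' @param log a [event_log()].
#' @param grid_step bin width in minutes (default 15; must divide 1440).
#' @return Data frame (`census_curve`) with `t` (bin start, minutes of day)
#'   and `mean_count`, plus attributes `n_days` and `grid_step`.
#' @export
census_curve <- function(log, grid_step = 15) {
  if (1440 %% grid_step != 0) stop("'grid_step' must divide 1440")
  days <- sort(unique(log$day))
  n_days <- length(days)
  if (n_days == 0L) stop("empty log")
  pres <- presence_intervals(log)
  # absolute time within the multi-day horizon; day labels need not start
  # at 1 (e.g. one-day subsets of a trial log), so re-index by rank
  day_idx <- match(pres$day, days)
  abs_start <- (day_idx - 1) * 1440 + pres$start
  abs_end <- pmin((day_idx - 1) * 1440 + pres$end, n_days * 1440)
  breaks <- seq(0, n_days * 1440, by = grid_step)
  occ <- numeric(length(breaks) - 1L)
  for (i in seq_along(abs_start)) {
    lo <- abs_start[i]; hi <- abs_end[i]
    if (hi <= lo) next
    b0 <- max(floor(lo / grid_step) + 1L, 1L)
    b1 <- min(ceiling(hi / grid_step), length(occ))
    for (b in b0:b1) {
      occ[b] <- occ[b] + max(0, min(hi, breaks[b + 1L]) - max(lo, breaks[b]))
    }
  }
  bin_of_day <- ((seq_along(occ) - 1L) %% (1440 %/% grid_step)) + 1L
  mean_count <- as.numeric(tapply(occ, bin_of_day, sum)) / (grid_step * n_days)
  structure(data.frame(t = seq(0, 1440 - grid_step, by = grid_step),
                       mean_count = mean_count),
            n_days = n_days, grid_step = grid_step,
            class = c("census_curve", "data.frame"))
}

# presence interval (arrival -> discharge/walk-out) per patient; open stays
# extend to +Inf and are clipped by the caller
presence_intervals <- function(log) {
  arr <- log[log$event == "arrival", ]
  dep <- log[log$event %in% c("discharge", "lwbs"), ]
  end <- dep$t_minutes[match(arr$patient_id, dep$patient_id)]
  data.frame(patient_id = arr$patient_id, day = arr$day,
             start = arr$t_minutes,
             end = ifelse(is.na(end), Inf, end), stringsAsFactors = FALSE)
}

#' Permutation test for a census-curve difference between arms
#'
#' The published comparison used a functional analysis of variance; that
#' method is underspecified, so the package tests the same null with a
#' permutation test: the statistic is the integrated squared difference
#' between arm-mean curves, and the null distribution comes from permuting
#' day-to-arm labels within weekday/weekend strata.
#'
#' @param log a pooled two-arm [event_log()] (e.g. from [run_trial()]).
#' @param assignment data frame with `day`, `stratum`, `arm` (from
#'   [run_trial()]).
#' @param n_permutations number of label permutations (default 999).
#' @param grid_step census bin width, minutes.
#' @return List with `statistic`, `p_value`, `n_permutations`.
#' @export
compare_census_curves <- function(log, assignment, n_permutations = 999,
                                  grid_step = 30) {
  if (length(unique(assignment$arm)) < 2L ||
      min(table(assignment$arm)) < 2L)
    stop("need at least 2 days per arm")
  # per-day time-of-day occupancy matrix
  days <- assignment$day
  curves <- lapply(days, function(d) {
    sub <- log[log$day == d, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(rep(0, 1440 %/% grid_step))
    census_curve(sub, grid_step)$mean_count
  })
  M <- do.call(rbind, curves)
  stat <- function(arm) {
    a <- colMeans(M[arm == "optimum", , drop = FALSE])
    b <- colMeans(M[arm == "control", , drop = FALSE])
    sum((a - b)^2) * grid_step
  }
  obs <- stat(assignment$arm)
  perm <- replicate(n_permutations, {
    arm <- assignment$arm
    for (s in unique(assignment$stratum)) {
      idx <- which(assignment$stratum == s)
      arm[idx] <- sample(arm[idx])
    }
    stat(arm)
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' ANCOVA comparison of one interval between arms
#'
#' Linear model of the transformed interval on arm plus a binary triage
#' priority covariate (low vs. moderate/high), mirroring the trial's
#' analysis.  The transform is `log1p` (log of value + 1, so zero-valued
#' intervals are defined) or within-sample ranks, used in the trial for the
#' two zero-heavy intervals.  Optionally adds an arm-by-priority
#' interaction and reports its heterogeneity p-value.
#'
#' @param intervals an [extract_intervals()] table.
#' @param interval_name which interval to compare.
#' @param transform `"log"` (log1p) or `"rank"`.
#' @param interaction add an arm-by-priority interaction term.
#' @return List (`comparison_result`) with the arm p-value, standardized
#'   difference with 95% CI on the transformed scale, and optionally the
#'   interaction p-value.
#' @export
ancova_compare <- function(intervals, interval_name,
                           transform = c("log", "rank"), interaction = FALSE) {
  transform <- match.arg(transform)
  d <- intervals[intervals$interval == interval_name & !is.na(intervals$value), ]
  if (length(unique(d$arm)) < 2L)
    stop("both arms must be present to compare")
  y <- if (transform == "log") log1p(d$value) else rank(d$value)
  arm <- factor(d$arm, levels = c("control", "optimum"))
  low <- factor(d$priority == "low", levels = c(FALSE, TRUE))
  fit <- if (length(unique(low)) > 1L) {
    if (interaction) stats::lm(y ~ arm + low + arm:low) else stats::lm(y ~ arm + low)
  } else {
    stats::lm(y ~ arm)
  }
  coefs <- summary(fit)$coefficients
  p_arm <- coefs["armoptimum", "Pr(>|t|)"]
  interaction_p <- if (interaction && "armoptimum:lowTRUE" %in% rownames(coefs))
    coefs["armoptimum:lowTRUE", "Pr(>|t|)"] else NA_real_
  sd_res <- standardized_difference(y, as.character(d$arm))
  structure(list(interval = interval_name, transform = transform,
                 n = nrow(d), p_value = unname(p_arm),
                 interaction_p = unname(interaction_p),
                 std_difference = sd_res$estimate,
                 std_difference_ci = sd_res$ci,
                 effect_label = sd_res$label),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s transform, n = %d): arm p = %.4g; std diff = %.3f (95%% CI %.3f to %.3f, %s)\n",
              x$interval, x$transform, x$n, x$p_value, x$std_difference,
              x$std_difference_ci[1], x$std_difference_ci[2], x$effect_label))
  if (!is.na(x$interaction_p))
    cat(sprintf("  arm x priority interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}

#' Standardized difference between two arms
#'
#' Difference of arm means divided by the pooled standard deviation
#' (a Cohen's-d-type effect size), computed on the transformed scale, with
#' a 95% CI from the standard large-sample variance of d.  Magnitudes of
#' 0.2, 0.5 and 0.8 are read as small, moderate and large.
#'
#' @param values numeric (already transformed if desired).
#' @param arms character vector of arm labels, two distinct values; the
#'   difference is first level minus second in sorted label order.
#' @return List with `estimate`, `ci` (length 2), `label`.
#' @export
standardized_difference <- function(values, arms) {
  lv <- sort(unique(arms))
  if (length(lv) != 2L) stop("exactly two arms required")
  x <- values[arms == lv[1]]; y <- values[arms == lv[2]]
  if (!length(x) || !length(y)) stop("both arms must be nonempty")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) stop("zero pooled variance")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(estimate = d, ci = d + c(-1, 1) * stats::qnorm(0.975) * se,
       label = effect_size_label(d))
}

#' @rdname standardized_difference
#' @param d standardized difference.
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  if (a < 0.2) "negligible" else if (a < 0.5) "small"
  else if (a < 0.8) "moderate" else "large"
}

#' Little's-law census effect of a LOS change
#'
#' Time-average census equals arrival rate times mean time in system, so a
#' LOS change of `delta_los_minutes` at `arrivals_per_day` arrivals shifts
#' the mean number of patients present by
#' `arrivals_per_day / 1440 * delta_los_minutes`.
#'
#' @param arrivals_per_day mean daily arrivals (`>= 0`).
#' @param delta_los_minutes LOS change in minutes.
#' @param round_patients round the result to a whole patient count
#'   (presentation flag; default `FALSE`).
#' @return Mean census change in patients.
#' @examples
#' littles_law_delta(78, 15)        # 0.8125
#' littles_law_delta(78, 15, TRUE)  # 1
#' @export
littles_law_delta <- function(arrivals_per_day, delta_los_minutes,
                              round_patients = FALSE) {
  if (arrivals_per_day < 0) stop("'arrivals_per_day' must be >= 0")
  out <- arrivals_per_day / 1440 * delta_los_minutes
  if (round_patients) round(out) else out
}

#' Daily arrival volume from an annual count
#'
#' @param annual_visits visits per year.
#' @param days_per_year denominator (default 365).
#' @param round_daily round to a whole patient count (default `TRUE`).
#' @return Arrivals per day.
#' @examples
#' arrivals_per_day_from_annual(28500)  # 78
#' @export
arrivals_per_day_from_annual <- function(annual_visits, days_per_year = 365,
                                         round_daily = TRUE) {
  out <- annual_visits / days_per_year
  if (round_daily) round(out) else out
}
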