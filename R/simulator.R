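#' Simulation configuration
#'
#' Bundles everything a run needs.  Defaults are the published calibration:
#' 78 arrivals/day (about 28,500 visits/year), 23% of arrivals between
#' midnight and 10:00, the printed case mix, and stage intervals of the
#' requested arm.
#'
#' Two execution modes exist.  In `"passthrough"` mode (the default, used
#' for calibration checks) each printed stage interval is sampled directly
#' from its fitted distribution and milestones are stacked along the stage
#' graph, so recovered interval distributions equal the fitted inputs; no
#' resource contention occurs.  In `"mechanistic"` mode staff roles are a
#' finite resource, tasks take `task_fraction` of a sampled stage interval,
#' result turnarounds take the remaining fraction without consuming staff,
#' and waits emerge from load and the prioritization policy.
#'
#' @param arm `"control"` or `"optimum"`; picks the stage calibration and
#'   the default policy (standard dashboard vs. secondary-triage).
#' @param n_days number of simulated days.
#' @param arrivals_per_day mean daily arrival count.
#' @param overnight_fraction expected share of arrivals in `[00:00, 10:00)`.
#' @param resources named integer vector of staff per role
#'   (mechanistic mode).
#' @param mode `"passthrough"` or `"mechanistic"`.
#' @param policy prioritization policy; defaults to `"optimum"` on the
#'   optimum arm and `"standard"` on the control arm.
#' @param task_fraction fraction of a sampled stage interval spent as
#'   staff-consuming task time in mechanistic mode.
#' @param lwbs_patience minutes an eventual leaver waits for the first
#'   medical evaluation before walking out.
#' @param latency_params transfer-latency distribution for the optimum arm
#'   (record visibility delay); defaults to [fit_latency_model()] with the
#'   published 83%/94% within-5/10-minute shares.
#' @param case_mix a [case_mix()]; defaults to [default_case_mix()].
#' @param stage_specs named list of [stage_spec()]; defaults to
#'   [default_stage_specs()] for `arm`.
#' @param seed mandatory integer seed.
#' @param horizon optional cutoff in minutes per day (mechanistic mode);
#'   patients still in progress at the cutoff are flagged as present.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(arm = c("control", "optimum"), n_days = 1,
                       arrivals_per_day = 78, overnight_fraction = 0.23,
                       resources = c(nurse = 2L, junior = 2L, senior = 2L, specialist = 1L),
                       mode = c("passthrough", "mechanistic"),
                       policy = NULL, task_fraction = 0.3, lwbs_patience = 120,
                       latency_params = fit_latency_model(0.83, 0.94),
                       case_mix = default_case_mix(), stage_specs = NULL,
                       seed, horizon = Inf) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed)) stop("'seed' is mandatory")
  if (is.null(policy)) policy <- if (arm == "optimum") "optimum" else "standard"
  policy <- match.arg(policy, c("optimum", "standard"))
  if (is.null(stage_specs)) stage_specs <- default_stage_specs(arm)
  if (n_days < 1) stop("'n_days' must be >= 1")
  if (arrivals_per_day < 0) stop("'arrivals_per_day' must be >= 0")
  if (overnight_fraction <= 0 || overnight_fraction >= 1)
    stop("'overnight_fraction' must be in (0, 1)")
  if (!all(ROLES %in% names(resources)) || any(resources < 1))
    stop("'resources' must name every role with a count >= 1")
  if (task_fraction <= 0 || task_fraction >= 1)
    stop("'task_fraction' must be in (0, 1)")
  structure(list(arm = arm, n_days = as.integer(n_days),
                 arrivals_per_day = arrivals_per_day,
                 overnight_fraction = overnight_fraction,
                 resources = resources, mode = mode, policy = policy,
                 task_fraction = task_fraction, lwbs_patience = lwbs_patience,
                 latency_params = latency_params, case_mix = case_mix,
                 stage_specs = stage_specs, seed = as.integer(seed),
                 horizon = horizon),
            class = "sim_config")
}

#' Sample one day of arrival times
#'
#' Piecewise-constant-intensity Poisson process on `[0, 1440)` minutes: the
#' daily count is Poisson with the configured mean, and each arrival falls
#' in the overnight window `[0, night_end)` with probability
#' `overnight_fraction`, uniformly within its window.
#'
#' @param arrivals_per_day mean daily count (default 78).
#' @param overnight_fraction expected overnight share (default 0.23).
#' @param night_end end of the overnight window, minutes (default 600,
#'   i.e. 10:00).
#' @return Sorted arrival times in minutes since midnight.
#' @export
sample_arrival_times <- function(arrivals_per_day = 78, overnight_fraction = 0.23,
                                 night_end = 600) {
  n <- stats::rpois(1L, arrivals_per_day)
  if (n == 0L) return(numeric(0))
  night <- stats::runif(n) < overnight_fraction
  t <- ifelse(night, stats::runif(n, 0, night_end),
              stats::runif(n, night_end, 1440))
  sort(t)
}

AGE_MONTHS_SPEC <- c(median = 34, q1 = 12, q3 = 100)

sample_categorical <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Sample patient profiles from a case mix
#'
#' Each attribute is drawn independently from its categorical marginal (the
#' published characteristics are marginals only; any real correlation
#' between, say, priority and blood tests is not reproduced --- a documented
#' fidelity limitation).  Age in months is drawn from a log-normal
#' quantile-matched to the published median 34 [12--100].
#'
#' @param n number of patients.
#' @param case_mix a [case_mix()] object.
#' @param ids optional character ids (default `"p1"`..`"pn"`).
#' @return Data frame with one row per patient: id, demographics, reason,
#'   priority, care-plan counts and disposition.  `arrival_time` is `NA`
#'   until assigned by the simulator.
#' @export
sample_patients <- function(n, case_mix = default_case_mix(),
                            ids = paste0("p", seq_len(n))) {
  stopifnot(inherits(case_mix, "case_mix"))
  age_fit <- fit_lognormal_from_quantiles(AGE_MONTHS_SPEC["median"],
                                          AGE_MONTHS_SPEC["q1"], AGE_MONTHS_SPEC["q3"])
  data.frame(
    patient_id = ids,
    arrival_time = rep(NA_real_, n),
    age_months = rdur(n, age_fit),
    sex = sample_categorical(n, case_mix$sex),
    reason = sample_categorical(n, case_mix$reason),
    priority = sample_categorical(n, case_mix$priority),
    n_blood_tests = as.integer(sample_categorical(n, case_mix$blood_tests)),
    n_imaging = as.integer(sample_categorical(n, case_mix$imaging)),
    n_specialist = as.integer(sample_categorical(n, case_mix$specialist)),
    n_treatment_lines = as.integer(sample_categorical(n, case_mix$treatment)),
    n_senior_evals = as.integer(sample_categorical(n, case_mix$senior_evals)),
    disposition = sample_categorical(n, case_mix$disposition),
    stringsAsFactors = FALSE)
}

#' Sample one patient profile
#'
#' Convenience wrapper around [sample_patients()] for a single draw.
#'
#' @inheritParams sample_patients
#' @return One-row data frame.
#' @export
sample_patient <- function(case_mix = default_case_mix()) {
  sample_patients(1L, case_mix)
}

#' Sample a stage duration
#'
#' @param stage stage name (a row of the stage calibration table).
#' @param fits named list of fitted [lognormal_params()], e.g. from
#'   [fit_stage_distributions()].
#' @param n number of draws.
#' @return Durations in minutes.
#' @export
sample_stage_duration <- function(stage, fits, n = 1L) {
  if (!stage %in% names(fits)) stop(sprintf("unknown stage '%s'", stage))
  rdur(n, fits[[stage]])
}

#' Sample dashboard-transfer latencies
#'
#' Minutes between a record appearing on the standard dashboard and its
#' transfer to the prioritizer; added to the arrival time to set record
#' visibility under the optimum arm (the standard arm sees records
#' immediately).
#'
#' @param latency_params a [fit_latency_model()] fit.
#' @param n number of draws.
#' @return Latencies in minutes.
#' @export
sample_transfer_latency <- function(latency_params, n = 1L) {
  rdur(n, latency_params)
}

EVENT_NAMES <- c("arrival", "triage", "first_eval", "junior_eval", "senior_eval",
                 "blood_prescription", "blood_sampling", "blood_results_review",
                 "imaging_prescription", "imaging_results_review",
                 "specialist_prescription", "specialist_consult",
                 "treatment_prescription", "treatment_admin",
                 "final_decision", "end_of_care", "discharge", "lwbs")

#' Event-log container
#'
#' The interchange format between simulator and analysis: one row per
#' milestone with `patient_id`, `day`, `arm`, `event`, `t_minutes` (minutes
#' since the day's midnight; stays may run past 1440), plus the per-patient
#' profile sidecar as the `profiles` attribute.
#'
#' @param events data frame with the five log columns.
#' @param profiles profile data frame as from [sample_patients()].
#' @param validate lint the stage-graph ordering (default `TRUE`).
#' @return An object of class `ped_event_log` (a data frame).
#' @export
event_log <- function(events, profiles, validate = TRUE) {
  need <- c("patient_id", "day", "arm", "event", "t_minutes")
  if (!all(need %in% names(events))) stop("event log lacks columns: ",
    paste(setdiff(need, names(events)), collapse = ", "))
  events <- events[need]
  events <- events[order(events$day, events$patient_id, events$t_minutes,
                         match(events$event, EVENT_NAMES)), , drop = FALSE]
  rownames(events) <- NULL
  out <- structure(events, profiles = profiles,
                   class = c("ped_event_log", "data.frame"))
  if (validate) lint_event_log(out)
  out
}

#' @export
print.ped_event_log <- function(x, ...) {
  cat(sprintf("PED event log: %d events, %d patients, %d day(s)\n",
              nrow(x), length(unique(x$patient_id)), length(unique(x$day))))
  NextMethod()
}

#' Stage-graph linter for event logs
#'
#' Checks every patient's trajectory against the stage graph: timestamps
#' nondecreasing along each path (arrival -> triage -> first evaluation ->
#' ... -> final decision -> end of care -> discharge), prescriptions no
#' earlier than the first evaluation, results after sampling/prescription,
#' at most one discharge, and no discharge for leavers.  Uses each event's
#' first occurrence except `discharge`, which must be unique.
#'
#' @param log a [event_log()] data frame.
#' @return Invisibly `TRUE`; stops with the offending patient id otherwise.
#' @export
lint_event_log <- function(log) {
  bad <- setdiff(unique(log$event), EVENT_NAMES)
  if (length(bad)) stop("unknown event name(s): ", paste(bad, collapse = ", "))
  prec <- list(
    c("arrival", "triage"), c("triage", "first_eval"),
    c("first_eval", "junior_eval"),
    c("arrival", "senior_eval"),
    c("first_eval", "blood_prescription"),
    c("blood_prescription", "blood_sampling"),
    c("blood_sampling", "blood_results_review"),
    c("first_eval", "imaging_prescription"),
    c("imaging_prescription", "imaging_results_review"),
    c("first_eval", "specialist_prescription"),
    c("specialist_prescription", "specialist_consult"),
    c("first_eval", "treatment_prescription"),
    c("treatment_prescription", "treatment_admin"),
    c("first_eval", "final_decision"),
    c("final_decision", "end_of_care"),
    c("end_of_care", "discharge"),
    c("arrival", "lwbs"))
  for (key in split(seq_len(nrow(log)), paste(log$day, log$patient_id))) {
    ev <- log$event[key]; tt <- log$t_minutes[key]
    id <- log$patient_id[key][1]
    if (!"arrival" %in% ev) stop(sprintf("patient %s: no arrival event", id))
    if (sum(ev == "discharge") > 1L) stop(sprintf("patient %s: multiple discharges", id))
    if ("lwbs" %in% ev && "discharge" %in% ev)
      stop(sprintf("patient %s: both left-without-being-seen and discharged", id))
    first_t <- function(e) if (e %in% ev) min(tt[ev == e]) else NA_real_
    for (pr in prec) {
      a <- first_t(pr[1]); b <- first_t(pr[2])
      if (!is.na(b) && (is.na(a) || b < a - 1e-9))
        stop(sprintf("patient %s: '%s' at %.3f precedes '%s'", id, pr[2], b, pr[1]))
    }
  }
  invisible(TRUE)
}

# ---- passthrough trajectory sampler -------------------------------------

# Draws every applicable stage interval directly from its fitted
# distribution and stacks milestones along the stage graph.  Returns a long
# event data frame (without day/arm columns).
simulate_trajectories <- function(profiles, fits, lwbs_patience = 120) {
  n <- nrow(profiles)
  if (n == 0L)
    return(data.frame(patient_id = character(0), event = character(0),
                      t_minutes = numeric(0), stringsAsFactors = FALSE))
  d <- function(stage) sample_stage_duration(stage, fits, n)
  arr <- profiles$arrival_time
  t_triage <- arr + d("admission_to_triage")
  t_first <- t_triage + d("triage_to_first_eval")
  t_junior <- t_first + d("first_eval_to_junior")
  t_senior <- pmax(t_first, arr + d("admission_to_senior"))
  t_blood_samp <- t_first + d("blood_prescription_to_sampling")
  t_blood_rev <- t_blood_samp + d("blood_sampling_to_results")
  t_imaging <- t_first + d("imaging_prescription_to_results")
  t_spec <- t_first + d("specialist_prescription_to_consult")
  t_treat <- t_first + d("treatment_prescription_to_admin")
  d_eoc <- d("final_decision_to_end_of_care")
  d_dis <- d("end_of_care_to_discharge")

  has_senior <- profiles$n_senior_evals > 0
  has_blood <- profiles$n_blood_tests > 0
  has_imaging <- profiles$n_imaging > 0
  has_spec <- profiles$n_specialist > 0
  has_treat <- profiles$n_treatment_lines > 0
  lwbs <- profiles$disposition == "lwbs"

  t_final <- pmax(t_junior,
                  ifelse(has_senior, t_senior, -Inf),
                  ifelse(has_blood, t_blood_rev, -Inf),
                  ifelse(has_imaging, t_imaging, -Inf),
                  ifelse(has_spec, t_spec, -Inf),
                  ifelse(has_treat, t_treat, -Inf))
  t_eoc <- t_final + d_eoc
  t_dis <- t_eoc + d_dis

  add <- function(keep, event, t) {
    if (!any(keep)) return(NULL)
    data.frame(patient_id = profiles$patient_id[keep], event = event,
               t_minutes = t[keep], stringsAsFactors = FALSE)
  }
  ok <- !lwbs
  out <- rbind(
    add(rep(TRUE, n), "arrival", arr),
    add(rep(TRUE, n), "triage", t_triage),
    add(lwbs, "lwbs", t_triage + lwbs_patience),
    add(ok, "first_eval", t_first),
    add(ok, "junior_eval", t_junior),
    add(ok & has_senior, "senior_eval", t_senior),
    add(ok & has_blood, "blood_prescription", t_first),
    add(ok & has_blood, "blood_sampling", t_blood_samp),
    add(ok & has_blood, "blood_results_review", t_blood_rev),
    add(ok & has_imaging, "imaging_prescription", t_first),
    add(ok & has_imaging, "imaging_results_review", t_imaging),
    add(ok & has_spec, "specialist_prescription", t_first),
    add(ok & has_spec, "specialist_consult", t_spec),
    add(ok & has_treat, "treatment_prescription", t_first),
    add(ok & has_treat, "treatment_admin", t_treat),
    add(ok, "final_decision", t_final),
    add(ok, "end_of_care", t_eoc),
    add(ok, "discharge", t_dis))
  out
}

# Total LOS (discharge - arrival) per profile under passthrough sampling;
# NA for leavers.  Used to bootstrap the synthetic LOS reference table.
simulate_trajectory_los <- function(profiles, fits) {
  ev <- simulate_trajectories(profiles, fits)
  dis <- ev[ev$event == "discharge", ]
  los <- dis$t_minutes[match(profiles$patient_id, dis$patient_id)] -
    profiles$arrival_time
  los
}

# ---- mechanistic discrete-event engine ----------------------------------

ACTION_STAGE <- c(
  TRIAGE              = "admission_to_triage",
  FIRST_MEDICAL_EVAL  = "triage_to_first_eval",
  SENIOR_EVAL         = "admission_to_senior",
  BLOOD_DRAW          = "blood_prescription_to_sampling",
  BLOOD_RESULT_REVIEW = "blood_sampling_to_results",
  IMAGING_REVIEW      = "imaging_prescription_to_results",
  SPECIALIST_REVIEW   = "specialist_prescription_to_consult",
  TREATMENT_ADMIN     = "treatment_prescription_to_admin",
  FINAL_DECISION      = "first_eval_to_junior",
  DISCHARGE_PROCESS   = "end_of_care_to_discharge"
)

simulate_day_mechanistic <- function(profiles, fits, config, reference) {
  n <- nrow(profiles)
  events <- list()
  log_event <- function(id, event, t)
    events[[length(events) + 1L]] <<- list(patient_id = id, event = event, t_minutes = t)

  patients <- list()
  idle <- config$resources
  # pending simulation events: arrivals, task/turnaround completions, ...
  q_time <- numeric(0); q_type <- character(0); q_pid <- character(0); q_info <- character(0)
  push <- function(time, type, pid, info = "") {
    q_time <<- c(q_time, time); q_type <<- c(q_type, type)
    q_pid <<- c(q_pid, pid); q_info <<- c(q_info, info)
  }
  pop <- function() {
    i <- which.min(q_time)
    ev <- list(time = q_time[i], type = q_type[i], pid = q_pid[i], info = q_info[i])
    q_time <<- q_time[-i]; q_type <<- q_type[-i]; q_pid <<- q_pid[-i]; q_info <<- q_info[-i]
    ev
  }
  for (i in seq_len(n)) push(profiles$arrival_time[i], "arrival", profiles$patient_id[i])

  tf <- config$task_fraction
  task_time <- function(action_type)
    tf * sample_stage_duration(ACTION_STAGE[[action_type]], fits, 1L)
  turnaround <- function(stage) (1 - tf) * sample_stage_duration(stage, fits, 1L)

  snapshot <- function(clock)
    dept_state(clock, patients, reference, idle_roles = idle)

  dispatch <- function(clock) {
    repeat {
      started <- FALSE
      for (role in ROLES) {
        if (idle[[role]] < 1L) next
        a <- next_action(role, snapshot(clock), config$policy)
        if (is.null(a)) next
        idle[[role]] <<- idle[[role]] - 1L
        patients[[a$patient_id]]$in_service <<- TRUE
        push(clock + task_time(a$action_type), "task_done", a$patient_id, a$action_type)
        started <- TRUE
      }
      if (!started) break
    }
  }

  while (length(q_time)) {
    ev <- pop()
    t <- ev$time
    if (t > config$horizon) break
    id <- ev$pid
    if (ev$type == "arrival") {
      i <- match(id, profiles$patient_id)
      lat <- if (config$arm == "optimum") sample_transfer_latency(config$latency_params) else 0
      st <- patient_state(profiles[i, ], visible_since = t + lat)
      patients[[id]] <- st
      log_event(id, "arrival", t)
      if (config$arm == "optimum") push(t + lat, "visible", id)
    } else if (ev$type == "visible") {
      # no state change needed; the event exists so the clock stops here
      # and newly visible records get dispatched
    } else if (ev$type == "renege") {
      st <- patients[[id]]
      if (!has_milestone(st, "first_eval") && !st$discharged && !st$reneged &&
          !isTRUE(st$in_service)) {
        patients[[id]]$reneged <- TRUE
        log_event(id, "lwbs", t)
      }
    } else if (ev$type == "turnaround_done") {
      st <- patients[[id]]
      if (ev$info == "blood") {
        st$blood_ready <- st$blood_ready + 1L
        st$blood_result_times <- c(st$blood_result_times, t)
      } else {
        st$imaging_ready <- st$imaging_ready + 1L
        st$imaging_result_times <- c(st$imaging_result_times, t)
      }
      patients[[id]] <- st
    } else if (ev$type == "end_of_care") {
      patients[[id]] <- set_milestone(patients[[id]], "end_of_care", t)
      log_event(id, "end_of_care", t)
    } else if (ev$type == "task_done") {
      at <- ev$info
      st <- patients[[id]]
      st$in_service <- FALSE
      idle[[ACTION_ROLES[[at]]]] <- idle[[ACTION_ROLES[[at]]]] + 1L
      if (at == "TRIAGE") {
        st <- set_milestone(st, "triage", t)
        log_event(id, "triage", t)
        if (st$profile$disposition == "lwbs")
          push(t + config$lwbs_patience, "renege", id)
      } else if (at == "FIRST_MEDICAL_EVAL") {
        st <- set_milestone(st, "first_eval", t)
        log_event(id, "first_eval", t)
        p <- st$profile
        if (p$n_blood_tests > 0) log_event(id, "blood_prescription", t)
        if (p$n_imaging > 0) {
          log_event(id, "imaging_prescription", t)
          for (k in seq_len(p$n_imaging))
            push(t + turnaround("imaging_prescription_to_results"), "turnaround_done", id, "imaging")
        }
        if (p$n_specialist > 0) log_event(id, "specialist_prescription", t)
        if (p$n_treatment_lines > 0) log_event(id, "treatment_prescription", t)
      } else if (at == "BLOOD_DRAW") {
        st$blood_drawn <- st$blood_drawn + 1L
        log_event(id, "blood_sampling", t)
        push(t + turnaround("blood_sampling_to_results"), "turnaround_done", id, "blood")
      } else if (at == "BLOOD_RESULT_REVIEW") {
        st$blood_reviewed <- st$blood_reviewed + 1L
        log_event(id, "blood_results_review", t)
      } else if (at == "IMAGING_REVIEW") {
        st$imaging_reviewed <- st$imaging_reviewed + 1L
        log_event(id, "imaging_results_review", t)
      } else if (at == "SPECIALIST_REVIEW") {
        st$specialist_done <- st$specialist_done + 1L
        log_event(id, "specialist_consult", t)
      } else if (at == "TREATMENT_ADMIN") {
        st$treatment_done <- st$treatment_done + 1L
        log_event(id, "treatment_admin", t)
      } else if (at == "SENIOR_EVAL") {
        st$senior_done <- st$senior_done + 1L
        log_event(id, "senior_eval", t)
      } else if (at == "FINAL_DECISION") {
        st <- set_milestone(st, "final_decision", t)
        log_event(id, "final_decision", t)
        push(t + sample_stage_duration("final_decision_to_end_of_care", fits, 1L),
             "end_of_care", id)
      } else if (at == "DISCHARGE_PROCESS") {
        st <- set_milestone(st, "discharge", t)
        st$discharged <- TRUE
        log_event(id, "discharge", t)
      }
      patients[[id]] <- st
    }
    # serve whoever can be served at the current clock
    dispatch(t)
  }
  do.call(rbind, lapply(events, function(e)
    data.frame(patient_id = e$patient_id, event = e$event,
               t_minutes = e$t_minutes, stringsAsFactors = FALSE)))
}

#' Run a simulation
#'
#' Simulates `n_days` days of PED operation under one arm and returns the
#' milestone event log with the patient-profile sidecar.  Seeded and fully
#' deterministic: the same configuration reproduces the identical log.
#'
#' @param config a [sim_config()].
#' @param reference LOS reference table for the prioritization policy
#'   (mechanistic mode); defaults to [default_los_reference()].
#' @return A [event_log()] object.
#' @export
run_simulation <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode == "mechanistic" && is.null(reference))
    reference <- default_los_reference()
  fits <- lapply(config$stage_specs, fit_stage)
  set.seed(config$seed)
  day_logs <- vector("list", config$n_days)
  all_profiles <- vector("list", config$n_days)
  for (day in seq_len(config$n_days)) {
    arr <- sample_arrival_times(config$arrivals_per_day, config$overnight_fraction)
    profiles <- sample_patients(length(arr), config$case_mix,
                                ids = sprintf("d%03d_p%03d", day, seq_along(arr)))
    profiles$arrival_time <- arr
    ev <- if (config$mode == "passthrough") {
      simulate_trajectories(profiles, fits, config$lwbs_patience)
    } else {
      simulate_day_mechanistic(profiles, fits, config, reference)
    }
    if (is.null(ev) || nrow(ev) == 0L) next
    ev$day <- day
    ev$arm <- config$arm
    day_logs[[day]] <- ev
    all_profiles[[day]] <- profiles
  }
  events <- do.call(rbind, day_logs)
  if (is.null(events))
    events <- data.frame(patient_id = character(0), day = integer(0),
                         arm = character(0), event = character(0),
                         t_minutes = numeric(0))
  event_log(events, do.call(rbind, all_profiles))
}

#' Randomize calendar days to trial arms within weekday/weekend strata
#'
#' Each day is labeled weekday or weekend from its day of week, then days
#' are randomized to the optimum vs. control arm separately within each
#' stratum, balanced to within one day (an odd stratum's extra day lands on
#' either arm with equal probability).  Uses the session RNG.
#'
#' @param n_days number of calendar days.
#' @param start_dow day of week of day 1 (1 = Monday ... 7 = Sunday).
#' @return Data frame with `day`, `stratum`, `arm`.
#' @export
randomize_days <- function(n_days, start_dow = 1L) {
  dow <- ((start_dow - 1L + seq_len(n_days) - 1L) %% 7L) + 1L
  stratum <- ifelse(dow >= 6L, "weekend", "weekday")
  arm <- character(n_days)
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    n_opt <- length(idx) %/% 2L
    if (length(idx) %% 2L == 1L) n_opt <- n_opt + stats::rbinom(1L, 1L, 0.5)
    arm[idx] <- "control"
    arm[idx[sample.int(length(idx), n_opt)]] <- "optimum"
  }
  data.frame(day = seq_len(n_days), stratum = stratum, arm = arm,
             stringsAsFactors = FALSE)
}

#' Day-randomized two-arm trial
#'
#' Labels each calendar day weekday or weekend, randomizes days to the
#' optimum vs. control arm separately within each stratum (balanced to
#' within one day per stratum), simulates every day under its arm's stage
#' calibration and policy, and returns the pooled log plus the assignment.
#'
#' @param n_days number of calendar days (`>= 2`).
#' @param seed integer seed driving both the randomization and every
#'   simulated day.
#' @param start_dow day of week of day 1 (1 = Monday ... 7 = Sunday);
#'   days 6--7 of each week are the weekend stratum.
#' @param mode,arrivals_per_day,overnight_fraction,... passed to
#'   [sim_config()] for each day.
#' @return An object of class `ped_trial`: list with `log` (a pooled
#'   [event_log()]) and `assignment` (data frame day/stratum/arm).
#' @export
run_trial <- function(n_days, seed, start_dow = 1L, mode = "passthrough",
                      arrivals_per_day = 78, overnight_fraction = 0.23, ...) {
  if (n_days < 2) stop("'n_days' must be >= 2")
  set.seed(seed)
  assignment <- randomize_days(n_days, start_dow)
  day_logs <- vector("list", n_days)
  day_profiles <- vector("list", n_days)
  for (day in seq_len(n_days)) {
    day_seed <- (seed %% 1000000L) * 2000L + day
    cfg <- sim_config(arm = assignment$arm[day], n_days = 1L, mode = mode,
                      arrivals_per_day = arrivals_per_day,
                      overnight_fraction = overnight_fraction,
                      seed = day_seed, ...)
    lg <- run_simulation(cfg)
    if (nrow(lg) == 0L) next
    ev <- as.data.frame(lg)
    ev$day <- day
    # re-key single-day ids (d001_*) so they are unique across trial days
    rekey <- function(x) sub("^d001", sprintf("d%03d", day), x)
    ev$patient_id <- rekey(ev$patient_id)
    pf <- attr(lg, "profiles")
    pf$patient_id <- rekey(pf$patient_id)
    day_logs[[day]] <- ev
    day_profiles[[day]] <- pf
  }
  events <- do.call(rbind, day_logs)
  profiles <- do.call(rbind, day_profiles)
  structure(list(log = event_log(events, profiles), assignment = assignment),
            class = "ped_trial")
}

#' Restrict a log to the trial's analysis window
#'
#' Keeps patients whose arrival falls inside the daily inclusion window
#' (default 10:00--24:00, since overnight arrivals were few and excluded)
#' and drops excludable dispositions (leavers by default; short-stay
#' admissions optionally, reflecting the ambiguity between the stated
#' exclusion and the published cohort table).
#'
#' @param log a [event_log()].
#' @param window_start,window_end minutes of day; default `c(600, 1440)`.
#' @param exclude_dispositions dispositions to drop (default `"lwbs"`).
#' @return A filtered [event_log()].
#' @export
filter_analysis_window <- function(log, window_start = 600, window_end = 1440,
                                   exclude_dispositions = "lwbs") {
  profiles <- attr(log, "profiles")
  arrivals <- log[log$event == "arrival", ]
  keep_ids <- arrivals$patient_id[arrivals$t_minutes >= window_start &
                                  arrivals$t_minutes < window_end]
  drop_ids <- profiles$patient_id[profiles$disposition %in% exclude_dispositions]
  keep_ids <- setdiff(keep_ids, drop_ids)
  event_log(log[log$patient_id %in% keep_ids, , drop = FALSE],
            profiles[profiles$patient_id %in% keep_ids, , drop = FALSE],
            validate = FALSE)
}
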