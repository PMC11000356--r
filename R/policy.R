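#' Status color of a patient's length of stay
#'
#' The four-level flag at the heart of the secondary-triage policy: a
#' patient's running LOS is compared with the reference percentiles of
#' patients admitted for the same reason.  Bands are lower-inclusive:
#' green below the 50th percentile, yellow from the 50th up to the 75th,
#' red from the 75th through the 95th, dark red strictly above the 95th
#' (the overcrowding color).
#'
#' @param los current length of stay, minutes, `>= 0`.
#' @param percentiles numeric `c(p50, p75, p95)`, nondecreasing.
#' @return One of `"green"`, `"yellow"`, `"red"`, `"dark_red"`.
#' @export
status_color <- function(los, percentiles) {
  if (length(percentiles) != 3L || is.unsorted(percentiles))
    stop("'percentiles' must be nondecreasing c(p50, p75, p95)")
  if (any(los < 0)) stop("'los' must be nonnegative")
  ifelse(los > percentiles[3], "dark_red",
         ifelse(los >= percentiles[2], "red",
                ifelse(los >= percentiles[1], "yellow", "green")))
}

#' @rdname status_color
#' @format Character vector of the four colors in increasing urgency.
#' @export
STATUS_COLORS <- c("green", "yellow", "red", "dark_red")

patient_color <- function(state, dept) {
  los <- max(dept$clock - state$profile$arrival_time, 0)
  status_color(los, los_percentiles(dept$reference, state$profile$reason))
}

#' Is the final senior decision awaited?
#'
#' `TRUE` when everything except the senior physician's final decision is
#' done: the patient is triaged and has had the first medical evaluation,
#' every blood result and imaging study has been reviewed, every specialist
#' consult, treatment line and intermediate senior evaluation is complete,
#' and no final decision has been recorded.  Discharged or reneged patients
#' are never awaiting.
#'
#' @param state a [patient_state()].
#' @return Logical scalar.
#' @export
awaiting_senior <- function(state) {
  p <- state$profile
  !state$discharged && !state$reneged &&
    has_milestone(state, "triage") && has_milestone(state, "first_eval") &&
    state$blood_reviewed >= p$n_blood_tests &&
    state$imaging_reviewed >= p$n_imaging &&
    state$specialist_done >= p$n_specialist &&
    state$treatment_done >= p$n_treatment_lines &&
    state$senior_done >= n_intermediate_senior(state) &&
    !has_milestone(state, "final_decision")
}

#' Enabled actions for one patient
#'
#' Walks the stage graph: triage precedes everything; the first medical
#' evaluation follows triage; care-plan items (blood draws, result and
#' imaging reviews, specialist consults, treatments, intermediate senior
#' evaluations) open up after the first evaluation; the final decision is
#' enabled exactly when [awaiting_senior()]; the discharge process follows
#' the end of care.  One action per enabled type is returned (the next
#' outstanding unit).
#'
#' @param state a [patient_state()].
#' @param clock current time in minutes.
#' @return List of actions (each with `action_type`, `patient_id`,
#'   `required_role`, `ready_time`); empty for discharged/reneged patients.
#' @export
pending_actions <- function(state, clock) {
  if (state$discharged || state$reneged) return(list())
  p <- state$profile
  id <- p$patient_id
  if (has_milestone(state, "first_eval") && !has_milestone(state, "triage"))
    stop(sprintf("patient %s: first evaluation recorded before triage", id))
  if (has_milestone(state, "discharge") && !has_milestone(state, "final_decision"))
    stop(sprintf("patient %s: discharge recorded before the final decision", id))

  if (!has_milestone(state, "triage"))
    return(list(new_action("TRIAGE", id, p$arrival_time)))
  if (!has_milestone(state, "first_eval"))
    return(list(new_action("FIRST_MEDICAL_EVAL", id, milestone(state, "triage"))))

  acts <- list()
  t_plan <- milestone(state, "first_eval")
  if (state$blood_drawn < p$n_blood_tests)
    acts <- c(acts, list(new_action("BLOOD_DRAW", id, t_plan)))
  if (state$blood_reviewed < state$blood_ready)
    acts <- c(acts, list(new_action("BLOOD_RESULT_REVIEW", id,
      state$blood_result_times[state$blood_reviewed + 1L])))
  if (state$imaging_reviewed < state$imaging_ready)
    acts <- c(acts, list(new_action("IMAGING_REVIEW", id,
      state$imaging_result_times[state$imaging_reviewed + 1L])))
  if (state$specialist_done < p$n_specialist)
    acts <- c(acts, list(new_action("SPECIALIST_REVIEW", id, t_plan)))
  if (state$treatment_done < p$n_treatment_lines)
    acts <- c(acts, list(new_action("TREATMENT_ADMIN", id, t_plan)))
  if (state$senior_done < n_intermediate_senior(state))
    acts <- c(acts, list(new_action("SENIOR_EVAL", id, t_plan)))
  if (awaiting_senior(state)) {
    ready <- max(c(t_plan, state$blood_result_times, state$imaging_result_times,
                   milestone(state, "last_plan_item")), na.rm = TRUE)
    acts <- c(acts, list(new_action("FINAL_DECISION", id, ready)))
  }
  if (has_milestone(state, "end_of_care") && !has_milestone(state, "discharge"))
    acts <- c(acts, list(new_action("DISCHARGE_PROCESS", id, milestone(state, "end_of_care"))))
  acts
}

#' Department overcrowding indicator
#'
#' The department is overcrowded as soon as at least one present
#' (non-discharged, non-reneged) patient's status color is dark red, i.e.
#' their LOS exceeds the 95th reference percentile for their admission
#' reason.  In that mode the policy flips to prioritizing discharges over
#' new patients.
#'
#' @param dept a [dept_state()].
#' @return Logical scalar.
#' @export
is_overcrowded <- function(dept) {
  for (p in dept$patients) {
    if (p$discharged || p$reneged) next
    if (patient_color(p, dept) == "dark_red") return(TRUE)
  }
  FALSE
}

PRIORITY_LEVELS <- c("high", "moderate", "low")

# action-class tiers; smaller ranks first
tier_of <- function(action_type, overcrowded) {
  front <- c("TRIAGE", "FIRST_MEDICAL_EVAL")
  back  <- c("FINAL_DECISION", "DISCHARGE_PROCESS")
  if (action_type %in% front) t <- if (overcrowded) 3 else 1
  else if (action_type %in% back) t <- if (overcrowded) 1 else 3
  else t <- 2
  t
}

rank_key <- function(action, dept, policy, overcrowded = NULL) {
  st <- dept$patients[[as.character(action$patient_id)]]
  if (is.null(st)) stop("action references a patient not present in the department")
  pr <- match(st$profile$priority, PRIORITY_LEVELS)
  pid_key <- match(as.character(action$patient_id), sort(names(dept$patients)))
  act_key <- match(action$action_type, names(ACTION_ROLES))
  if (policy == "standard") {
    return(c(priority = pr, arrival = st$profile$arrival_time,
             ready = action$ready_time, pid = pid_key, act = act_key))
  }
  if (is.null(overcrowded)) overcrowded <- is_overcrowded(dept)
  color <- patient_color(st, dept)
  # low-priority patients are lifted by their color only once dark red
  if (st$profile$priority == "low" && color != "dark_red") color <- "green"
  c(tier = tier_of(action$action_type, overcrowded),
    color = -match(color, STATUS_COLORS),
    priority = pr, ready = action$ready_time, pid = pid_key, act = act_key)
}

check_enabled <- function(action, dept) {
  st <- dept$patients[[as.character(action$patient_id)]]
  if (is.null(st)) stop("action references a patient not present in the department")
  enabled <- pending_actions(st, dept$clock)
  ok <- any(vapply(enabled, function(a) a$action_type == action$action_type, TRUE))
  if (!ok) stop(sprintf("action %s is not enabled for patient %s",
                        action$action_type, action$patient_id))
  invisible(TRUE)
}

#' Ranking key of the secondary-triage (optimum) policy
#'
#' Lexicographic sort key, smaller first: (1) action-class tier --- under
#' normal load triage/first evaluations, then nurse care and physician
#' reviews, then the final senior step; once the department is overcrowded
#' the order of the first and last tiers flips so that final decisions and
#' discharges outrank seeing new patients; (2) patient status color, darker
#' first, except that low-priority patients are lifted by their color only
#' when it is dark red; (3) triage priority, high first; (4) action ready
#' time, earliest first; (5) patient id and action-type enum order as
#' deterministic tie-breaks.
#'
#' @param action an enabled action as produced by [pending_actions()].
#' @param dept a [dept_state()].
#' @return Named numeric vector; compare element-wise, smaller sorts first.
#' @export
optimum_rank <- function(action, dept) {
  check_enabled(action, dept)
  rank_key(action, dept, "optimum")
}

#' Ranking key of the standard-dashboard baseline policy
#'
#' Acuity first, then order of arrival: (triage priority high-first,
#' patient arrival time, action ready time, patient id).  No percentile
#' logic and no overcrowding mode.
#'
#' @inheritParams optimum_rank
#' @return Named numeric vector; compare element-wise, smaller sorts first.
#' @export
standard_rank <- function(action, dept) {
  check_enabled(action, dept)
  rank_key(action, dept, "standard")
}

#' Best next action for a role
#'
#' Enumerates the enabled actions of all patients visible to the policy
#' (`visible_since <= clock`), keeps those requiring `role`, and returns the
#' best-ranked one under the chosen policy.  Deterministic given the
#' department state.
#'
#' @param role one of `"nurse"`, `"junior"`, `"senior"`, `"specialist"`.
#' @param dept a [dept_state()].
#' @param policy `"optimum"` or `"standard"`.
#' @return An action (list), or `NULL` when nothing is enabled for the role.
#' @export
next_action <- function(role, dept, policy = c("optimum", "standard")) {
  policy <- match.arg(policy)
  role <- match.arg(role, ROLES)
  overcrowded <- if (policy == "optimum") is_overcrowded(dept) else FALSE
  cand <- list()
  for (st in dept$patients) {
    if (st$visible_since > dept$clock) next
    if (isTRUE(st$in_service)) next
    for (a in pending_actions(st, dept$clock)) {
      if (a$required_role == role && a$ready_time <= dept$clock)
        cand <- c(cand, list(a))
    }
  }
  if (!length(cand)) return(NULL)
  keys <- t(vapply(cand, rank_key, numeric(if (policy == "standard") 5 else 6),
                   dept = dept, policy = policy, overcrowded = overcrowded))
  ord <- do.call(order, as.data.frame(keys))
  cand[[ord[1L]]]
}
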