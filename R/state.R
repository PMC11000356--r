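#' Action types and the fixed role map
#'
#' The unit of work a policy ranks: each action type is performed by exactly
#' one staff role.  Triage, blood draws, treatment administration and the
#' discharge process are nursing work; the first medical evaluation and
#' result reviews belong to the junior physician/student; intermediate and
#' final senior evaluations to the senior physician; specialist consults to
#' the on-call specialist.
#'
#' @format Named character vector mapping action type to role.
#' @export
ACTION_ROLES <- c(
  TRIAGE              = "nurse",
  FIRST_MEDICAL_EVAL  = "junior",
  SENIOR_EVAL         = "senior",
  BLOOD_DRAW          = "nurse",
  BLOOD_RESULT_REVIEW = "junior",
  IMAGING_REVIEW      = "junior",
  SPECIALIST_REVIEW   = "specialist",
  TREATMENT_ADMIN     = "nurse",
  FINAL_DECISION      = "senior",
  DISCHARGE_PROCESS   = "nurse"
)

#' @rdname ACTION_ROLES
#' @export
ROLES <- c("nurse", "junior", "senior", "specialist")

new_action <- function(action_type, patient_id, ready_time) {
  list(action_type = action_type, patient_id = patient_id,
       required_role = unname(ACTION_ROLES[[action_type]]),
       ready_time = ready_time)
}

#' Construct a patient's dynamic state
#'
#' Tracks a patient's milestones and outstanding care-plan items as they
#' move through the stage graph.  Progress counters start at zero; the
#' simulation engine (or a test fixture) advances them.
#'
#' @param profile a single-row data frame or named list with at least
#'   `patient_id`, `arrival_time`, `reason`, `priority` and the care-plan
#'   counts `n_blood_tests`, `n_imaging`, `n_specialist`,
#'   `n_treatment_lines`, `n_senior_evals`.
#' @param visible_since time (minutes) the record becomes visible to the
#'   prioritization policy; under the optimum arm this is arrival plus the
#'   sampled dashboard-transfer latency, under the standard arm it equals
#'   the arrival time.
#' @return An object of class `patient_state`.
#' @export
patient_state <- function(profile, visible_since = profile$arrival_time) {
  profile <- as.list(profile)
  need <- c("patient_id", "arrival_time", "reason", "priority",
            "n_blood_tests", "n_imaging", "n_specialist",
            "n_treatment_lines", "n_senior_evals")
  missing <- setdiff(need, names(profile))
  if (length(missing)) stop("profile lacks fields: ", paste(missing, collapse = ", "))
  structure(list(
    profile = profile,
    milestones = c(arrival = as.numeric(profile$arrival_time)),
    visible_since = as.numeric(visible_since),
    # progress counters
    blood_drawn = 0L, blood_ready = 0L, blood_reviewed = 0L,
    imaging_ready = 0L, imaging_reviewed = 0L,
    specialist_done = 0L, treatment_done = 0L, senior_done = 0L,
    # times pending results became available (engine-filled)
    blood_result_times = numeric(0), imaging_result_times = numeric(0),
    discharged = FALSE, reneged = FALSE, in_service = FALSE
  ), class = "patient_state")
}

has_milestone <- function(state, name) name %in% names(state$milestones)

milestone <- function(state, name) {
  if (!has_milestone(state, name)) return(NA_real_)
  unname(state$milestones[[name]])
}

set_milestone <- function(state, name, t) {
  state$milestones[name] <- t
  state
}

# intermediate senior evaluations in the care plan; the final decision
# stands in for the last senior evaluation, so a patient with k printed
# senior evaluations carries max(k - 1, 0) intermediate SENIOR_EVAL items
n_intermediate_senior <- function(state) max(state$profile$n_senior_evals - 1L, 0L)

#' Construct a department-wide state snapshot
#'
#' The object a prioritization policy ranks over: the clock, all patient
#' states, the idle-staff multiset and the LOS reference percentile table.
#'
#' @param clock minutes since simulation start.
#' @param patients list of [patient_state()] objects.
#' @param reference a [build_los_reference()] table.
#' @param idle_roles named integer vector of idle staff per role.
#' @return An object of class `dept_state`.
#' @export
dept_state <- function(clock, patients, reference,
                       idle_roles = c(nurse = 1L, junior = 1L, senior = 1L, specialist = 1L)) {
  stopifnot(inherits(reference, "los_reference"))
  ids <- vapply(patients, function(p) as.character(p$profile$patient_id), "")
  if (anyDuplicated(ids)) stop("duplicate patient ids in department state")
  names(patients) <- ids
  structure(list(clock = clock, patients = patients,
                 idle_roles = idle_roles, reference = reference),
            class = "dept_state")
}
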