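# Shared fixtures: profiles, patient states, department snapshots, and a
# tiny reference table with round percentiles.

make_profile <- function(patient_id = "p1", arrival_time = 0,
                         reason = "fever", priority = "moderate",
                         n_blood_tests = 0L, n_imaging = 0L, n_specialist = 0L,
                         n_treatment_lines = 0L, n_senior_evals = 1L,
                         disposition = "home", age_months = 36, sex = "male") {
  list(patient_id = patient_id, arrival_time = arrival_time,
       age_months = age_months, sex = sex, reason = reason,
       priority = priority, n_blood_tests = n_blood_tests,
       n_imaging = n_imaging, n_specialist = n_specialist,
       n_treatment_lines = n_treatment_lines, n_senior_evals = n_senior_evals,
       disposition = disposition)
}

flat_reference <- function(p50 = 100, p75 = 200, p95 = 400) {
  # same percentiles for every reason: quantiles of a known sample
  reasons <- c("fever", "respiratory", "digestive", "trauma", "other")
  tab <- do.call(rbind, lapply(reasons, function(r)
    data.frame(reason = r, p50 = p50, p75 = p75, p95 = p95, n = 100L)))
  structure(tab, pooled = c(p50, p75, p95),
            class = c("los_reference", "data.frame"))
}

# a patient state advanced to a given point in the stage graph
advanced_state <- function(profile, triage = NA, first_eval = NA,
                           visible_since = profile$arrival_time) {
  st <- patient_state(profile, visible_since = visible_since)
  if (!is.na(triage)) st$milestones["triage"] <- triage
  if (!is.na(first_eval)) st$milestones["first_eval"] <- first_eval
  st
}

# fully served patient awaiting only the senior's final decision
awaiting_state <- function(profile, t = 60) {
  st <- advanced_state(profile, triage = 10, first_eval = 20)
  st$blood_drawn <- st$blood_ready <- st$blood_reviewed <- profile$n_blood_tests
  st$imaging_ready <- st$imaging_reviewed <- profile$n_imaging
  st$specialist_done <- profile$n_specialist
  st$treatment_done <- profile$n_treatment_lines
  st$senior_done <- max(profile$n_senior_evals - 1L, 0L)
  st$blood_result_times <- rep(t, profile$n_blood_tests)
  st$imaging_result_times <- rep(t, profile$n_imaging)
  st
}

# random consistent patient state for the brute-force policy oracle
random_state <- function(id, clock, rng_priority = c("high", "moderate", "low")) {
  prof <- make_profile(
    patient_id = id,
    arrival_time = stats::runif(1, 0, clock),
    reason = sample(c("fever", "respiratory", "digestive", "trauma", "other"), 1),
    priority = sample(rng_priority, 1),
    n_blood_tests = sample(0:2, 1), n_imaging = sample(0:2, 1),
    n_specialist = sample(0:1, 1), n_treatment_lines = sample(0:1, 1),
    n_senior_evals = sample(0:2, 1))
  st <- patient_state(prof, visible_since = prof$arrival_time)
  stage <- sample(c("new", "triaged", "in_plan", "awaiting", "end_of_care"), 1)
  if (stage == "new") return(st)
  t0 <- prof$arrival_time
  st$milestones["triage"] <- t0 + 1
  if (stage == "triaged") return(st)
  st$milestones["first_eval"] <- t0 + 2
  if (stage == "in_plan") {
    st$blood_drawn <- sample(0:prof$n_blood_tests, 1)
    st$blood_ready <- sample(0:st$blood_drawn, 1)
    st$blood_reviewed <- sample(0:st$blood_ready, 1)
    st$blood_result_times <- rep(t0 + 3, st$blood_ready)
    st$imaging_ready <- sample(0:prof$n_imaging, 1)
    st$imaging_reviewed <- sample(0:st$imaging_ready, 1)
    st$imaging_result_times <- rep(t0 + 3, st$imaging_ready)
    st$specialist_done <- sample(0:prof$n_specialist, 1)
    st$treatment_done <- sample(0:prof$n_treatment_lines, 1)
    st$senior_done <- sample(0:max(prof$n_senior_evals - 1L, 0L), 1)
    return(st)
  }
  st <- awaiting_state(prof, t = t0 + 3)
  if (stage == "awaiting") return(st)
  st$milestones["final_decision"] <- t0 + 4
  st$milestones["end_of_care"] <- t0 + 5
  st
}

random_dept <- function(n_patients, clock = 300, reference = flat_reference()) {
  pats <- lapply(seq_len(n_patients), function(i)
    random_state(sprintf("p%02d", i), clock))
  dept_state(clock, pats, reference)
}

# hand-written three-patient log used by the interval-extraction tests
handcrafted_log <- function() {
  rows <- rbind(
    # p1: plain visit, no plan items
    data.frame(patient_id = "p1", event = c("arrival", "triage", "first_eval",
                                            "junior_eval", "final_decision",
                                            "end_of_care", "discharge"),
               t_minutes = c(0, 15, 40, 70, 70, 90, 120)),
    # p2: blood + imaging, senior involved
    data.frame(patient_id = "p2",
               event = c("arrival", "triage", "first_eval", "junior_eval",
                         "senior_eval", "blood_prescription", "blood_sampling",
                         "blood_results_review", "imaging_prescription",
                         "imaging_results_review", "final_decision",
                         "end_of_care", "discharge"),
               t_minutes = c(10, 20, 45, 80, 81, 45, 85, 200, 45, 130,
                             200, 200, 240)),
    # p3: walked out before the first evaluation
    data.frame(patient_id = "p3", event = c("arrival", "triage", "lwbs"),
               t_minutes = c(5, 30, 150)))
  rows$day <- 1L
  rows$arm <- "control"
  profiles <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    arrival_time = c(0, 10, 5), age_months = 36, sex = "male",
    reason = c("fever", "trauma", "other"),
    priority = c("moderate", "high", "low"),
    n_blood_tests = c(0L, 1L, 0L), n_imaging = c(0L, 1L, 0L),
    n_specialist = 0L, n_treatment_lines = 0L,
    n_senior_evals = c(0L, 1L, 0L),
    disposition = c("home", "ward", "lwbs"))
  event_log(rows, profiles)
}
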