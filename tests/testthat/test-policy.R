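test_that("status_color bands are lower-inclusive with dark red strictly above p95", {
  p <- c(50, 75, 95)
  eps <- 1e-9
  expect_equal(status_color(50 - eps, p), "green")
  expect_equal(status_color(50, p), "yellow")
  expect_equal(status_color(75 - eps, p), "yellow")
  expect_equal(status_color(75, p), "red")
  expect_equal(status_color(95, p), "red")     # p95 itself still red
  expect_equal(status_color(95 + eps, p), "dark_red")
  expect_equal(status_color(96, p), "dark_red")
  expect_equal(status_color(0, p), "green")
  expect_error(status_color(10, c(75, 50, 95)), "nondecreasing")
  expect_error(status_color(-1, p), "nonnegative")
})

test_that("status_color is monotone nondecreasing in LOS", {
  set.seed(5)
  for (i in 1:20) {
    p <- sort(runif(3, 0, 500))
    los <- sort(runif(50, 0, 600))
    idx <- match(status_color(los, p), STATUS_COLORS)
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("awaiting_senior flags exactly the all-done, no-decision state", {
  prof <- make_profile(n_imaging = 1L, n_senior_evals = 1L)
  st <- awaiting_state(prof)
  st$imaging_reviewed <- 0L  # one imaging review still pending
  expect_false(awaiting_senior(st))
  st$imaging_reviewed <- 1L
  expect_true(awaiting_senior(st))
  # empty care plan, first eval done
  st2 <- awaiting_state(make_profile(n_senior_evals = 0L))
  expect_true(awaiting_senior(st2))
  st2$milestones["final_decision"] <- 100
  expect_false(awaiting_senior(st2))
  st3 <- awaiting_state(make_profile())
  st3$discharged <- TRUE
  expect_false(awaiting_senior(st3))
})

test_that("pending_actions walks the stage graph", {
  prof <- make_profile(n_blood_tests = 1L)
  fresh <- patient_state(prof)
  acts <- pending_actions(fresh, 5)
  expect_length(acts, 1)
  expect_equal(acts[[1]]$action_type, "TRIAGE")
  expect_equal(acts[[1]]$required_role, "nurse")

  triaged <- advanced_state(prof, triage = 10)
  acts <- pending_actions(triaged, 15)
  expect_equal(vapply(acts, `[[`, "", "action_type"), "FIRST_MEDICAL_EVAL")

  in_plan <- advanced_state(prof, triage = 10, first_eval = 20)
  types <- vapply(pending_actions(in_plan, 30), `[[`, "", "action_type")
  expect_setequal(types, "BLOOD_DRAW")

  done <- awaiting_state(prof)
  types <- vapply(pending_actions(done, 60), `[[`, "", "action_type")
  expect_setequal(types, "FINAL_DECISION")

  # discharged patients expose nothing
  done$discharged <- TRUE
  expect_length(pending_actions(done, 70), 0)

  # inconsistent milestones rejected
  broken <- patient_state(prof)
  broken$milestones["first_eval"] <- 20
  expect_error(pending_actions(broken, 30), "before triage")
})

test_that("is_overcrowded triggers on any dark-red patient", {
  ref <- flat_reference(100, 200, 400)
  expect_false(is_overcrowded(dept_state(50, list(), ref)))
  green <- patient_state(make_profile("a", arrival_time = 0))
  late <- patient_state(make_profile("b", arrival_time = 0))
  expect_false(is_overcrowded(dept_state(300, list(green), ref)))   # LOS 300 = red
  expect_true(is_overcrowded(dept_state(401, list(green, late), ref)))
  # discharged dark-red patients do not count
  late$discharged <- TRUE
  expect_false(is_overcrowded(dept_state(401, list(late), ref)))
})

test_that("optimum ranking follows tier, color, priority, ready time", {
  ref <- flat_reference(100, 200, 400)
  mk <- function(id, priority, arrival) {
    st <- advanced_state(make_profile(id, arrival_time = arrival, priority = priority),
                         triage = arrival + 5)
    st
  }
  # same tier, same color: high priority outranks low
  d <- dept_state(60, list(mk("hi", "high", 10), mk("lo", "low", 10)), ref)
  a_hi <- pending_actions(d$patients$hi, 60)[[1]]
  a_lo <- pending_actions(d$patients$lo, 60)[[1]]
  expect_true(all(optimum_rank(a_hi, d) <= optimum_rank(a_lo, d)) &&
              any(optimum_rank(a_hi, d) < optimum_rank(a_lo, d)))
  best <- next_action("junior", d, "optimum")
  expect_equal(best$patient_id, "hi")

  # low-priority green vs moderate green, same tier: moderate first
  d2 <- dept_state(60, list(mk("mod", "moderate", 10), mk("low", "low", 10)), ref)
  expect_equal(next_action("junior", d2, "optimum")$patient_id, "mod")

  # a dark-red low-priority patient is lifted above a green patient
  d3 <- dept_state(450, list(mk("darklow", "low", 10), mk("green", "moderate", 420)), ref)
  expect_equal(next_action("junior", d3, "optimum")$patient_id, "darklow")
  # ... but a merely-red low-priority patient is not color-lifted
  d4 <- dept_state(280, list(mk("redlow", "low", 10), mk("green", "moderate", 250)), ref)
  expect_equal(next_action("junior", d4, "optimum")$patient_id, "green")

  expect_error(optimum_rank(new_action <- list(action_type = "DISCHARGE_PROCESS",
                                               patient_id = "hi",
                                               required_role = "nurse",
                                               ready_time = 0), d),
               "not enabled")
})

test_that("overcrowding flips discharges above seeing new patients", {
  ref <- flat_reference(100, 200, 400)
  # one dark-red patient awaiting the final decision + one fresh arrival
  dark <- awaiting_state(make_profile("dark", arrival_time = 0, n_senior_evals = 1L))
  dark$milestones["final_decision"] <- 410
  dark$milestones["end_of_care"] <- 420
  fresh <- patient_state(make_profile("new", arrival_time = 425))
  d <- dept_state(430, list(dark, fresh), ref)
  expect_true(is_overcrowded(d))
  # nurse work: DISCHARGE_PROCESS (tier 1 under overcrowding) beats TRIAGE
  expect_equal(next_action("nurse", d, "optimum")$action_type, "DISCHARGE_PROCESS")
  # without the dark-red patient the same comparison reverses
  ok <- awaiting_state(make_profile("ok", arrival_time = 300, n_senior_evals = 1L))
  ok$milestones["final_decision"] <- 410
  ok$milestones["end_of_care"] <- 420
  d2 <- dept_state(430, list(ok, fresh), ref)
  expect_false(is_overcrowded(d2))
  expect_equal(next_action("nurse", d2, "optimum")$action_type, "TRIAGE")
})

test_that("standard ranking is acuity first, then order of arrival", {
  ref <- flat_reference()
  mk <- function(id, priority, arrival)
    advanced_state(make_profile(id, arrival_time = arrival, priority = priority),
                   triage = arrival + 1)
  # same priority: FIFO by arrival
  d <- dept_state(700, list(mk("early", "moderate", 540), mk("late", "moderate", 600)), ref)
  expect_equal(next_action("junior", d, "standard")$patient_id, "early")
  # acuity overrides arrival order
  d2 <- dept_state(700, list(mk("lowearly", "low", 540), mk("hilate", "high", 600)), ref)
  expect_equal(next_action("junior", d2, "standard")$patient_id, "hilate")
  # identical keys: stable order by patient id
  d3 <- dept_state(700, list(mk("b", "moderate", 540), mk("a", "moderate", 540)), ref)
  expect_equal(next_action("junior", d3, "standard")$patient_id, "a")
  # no percentile logic: a dark-red low-priority patient stays behind
  d4 <- dept_state(700, list(mk("verylate", "low", 0), mk("hi", "high", 650)), ref)
  expect_equal(next_action("junior", d4, "standard")$patient_id, "hi")
})

test_that("next_action respects role, visibility and emptiness", {
  ref <- flat_reference()
  expect_null(next_action("senior", dept_state(10, list(), ref), "optimum"))
  fresh <- patient_state(make_profile("p", arrival_time = 0))
  d <- dept_state(10, list(fresh), ref)
  expect_equal(next_action("nurse", d, "optimum")$action_type, "TRIAGE")
  expect_null(next_action("junior", d, "optimum"))
  # not yet transferred to the prioritizer: invisible
  hidden <- patient_state(make_profile("h", arrival_time = 0), visible_since = 20)
  expect_null(next_action("nurse", dept_state(10, list(hidden), ref), "optimum"))
  expect_equal(next_action("nurse", dept_state(25, list(hidden), ref), "optimum")$patient_id, "h")
})

test_that("next_action agrees with the brute-force oracle on random departments", {
  set.seed(1234)
  n_checked <- 0L
  for (i in 1:250) {
    d <- random_dept(sample(2:10, 1), clock = runif(1, 50, 500))
    for (role in ROLES) {
      for (policy in c("optimum", "standard")) {
        got <- next_action(role, d, policy)
        want <- oracle_next_action(role, d, policy)
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(got$patient_id, want$patient_id)
          expect_equal(got$action_type, want$action_type)
          n_checked <- n_checked + 1L
        }
      }
    }
  }
  expect_gt(n_checked, 200)  # the generator actually produced work
})

test_that("policy decisions are pure functions of the department state", {
  set.seed(77)
  d <- random_dept(8, clock = 240)
  for (policy in c("optimum", "standard")) {
    first <- next_action("junior", d, policy)
    for (k in 1:5) expect_identical(next_action("junior", d, policy), first)
  }
})
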