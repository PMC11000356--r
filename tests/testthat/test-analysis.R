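test_that("extract_intervals matches hand-computed values on a crafted log", {
  iv <- extract_intervals(handcrafted_log())
  get <- function(id, nm) iv$value[iv$patient_id == id & iv$interval == nm]
  # p1: plain visit
  expect_equal(get("p1", "admission_to_triage"), 15)
  expect_equal(get("p1", "triage_to_first_eval"), 25)
  expect_equal(get("p1", "first_eval_to_junior"), 30)
  expect_equal(get("p1", "final_decision_to_end_of_care"), 20)
  expect_equal(get("p1", "end_of_care_to_discharge"), 30)
  expect_equal(get("p1", "total_los"), 120)
  expect_true(is.na(get("p1", "imaging_prescription_to_results")))
  expect_true(is.na(get("p1", "admission_to_senior")))
  # p2: full work-up
  expect_equal(get("p2", "admission_to_senior"), 71)
  expect_equal(get("p2", "blood_prescription_to_sampling"), 40)
  expect_equal(get("p2", "blood_sampling_to_results"), 115)
  expect_equal(get("p2", "imaging_prescription_to_results"), 85)
  expect_equal(get("p2", "total_los"), 230)
  # p3 walked out: no total LOS
  expect_true(is.na(get("p3", "total_los")))
  expect_true(is.na(get("p3", "triage_to_first_eval")))
  # priority/arm metadata carried over
  expect_equal(unique(iv$priority[iv$patient_id == "p2"]), "high")
})

test_that("extract_intervals rejects malformed logs with the offender named", {
  bad <- as.data.frame(handcrafted_log())
  bad$t_minutes[bad$patient_id == "p1" & bad$event == "discharge"] <- 80  # before end_of_care
  expect_error(event_log(bad, attr(handcrafted_log(), "profiles")), "p1")
})

test_that("summarize_median_iqr follows the fixed type-7 rule", {
  s <- summarize_median_iqr(1:100)
  expect_equal(c(s$median, s$q1, s$q3), c(50.5, 25.75, 75.25))
  expect_equal(s$n, 100)
  s1 <- summarize_median_iqr(7)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7, 7, 7))
  expect_error(summarize_median_iqr(numeric(0)), "no values")
  expect_error(summarize_median_iqr(c(NA_real_, NA_real_)), "no values")
  # round trip with the calibration fit
  set.seed(12)
  s2 <- summarize_median_iqr(rdur(1e4, fit_lognormal_from_quantiles(167, 108, 254)))
  f <- fit_lognormal_from_quantiles(167, 108, 254)
  expect_equal(s2$median, 167, tolerance = 0.03)
  expect_equal(c(s2$q1, s2$q3), qdur(c(0.25, 0.75), f), tolerance = 0.03)
})

test_that("census_curve counts presence and satisfies conservation exactly", {
  # one patient present [0, 100) on one day
  ev <- data.frame(patient_id = "p1", day = 1L, arm = "control",
                   event = c("arrival", "triage", "first_eval", "junior_eval",
                             "final_decision", "end_of_care", "discharge"),
                   t_minutes = c(0, 10, 20, 30, 40, 50, 100))
  lg <- event_log(ev, data.frame(patient_id = "p1", priority = "low"))
  cc <- census_curve(lg, grid_step = 10)
  expect_equal(cc$mean_count, c(rep(1, 10), rep(0, 134)))
  # conservation on a simulated multi-day log
  lg2 <- run_simulation(sim_config(seed = 77, n_days = 3))
  cc2 <- census_curve(lg2, grid_step = 15)
  arr <- lg2[lg2$event == "arrival", ]
  dep <- lg2[lg2$event %in% c("discharge", "lwbs"), ]
  t_in <- (arr$day - 1) * 1440 + arr$t_minutes
  t_out <- (dep$day[match(arr$patient_id, dep$patient_id)] - 1) * 1440 +
    dep$t_minutes[match(arr$patient_id, dep$patient_id)]
  total_minutes <- sum(pmin(t_out, 3 * 1440) - t_in)
  expect_equal(sum(cc2$mean_count) * 15 * 3, total_minutes, tolerance = 1e-12)
  expect_true(all(cc2$mean_count >= 0))
  expect_true(all(diff(cc2$t) > 0))
})

test_that("census permutation test is valid under the null and bounded", {
  # identical day patterns in both arms -> statistic 0 -> p = 1
  base <- data.frame(patient_id = "x", event = c("arrival", "triage", "first_eval",
                                                 "junior_eval", "final_decision",
                                                 "end_of_care", "discharge"),
                     t_minutes = c(600, 610, 620, 630, 640, 650, 700))
  days <- do.call(rbind, lapply(1:8, function(d) {
    b <- base; b$day <- d; b$patient_id <- paste0("x", d)
    b$arm <- if (d %% 2) "control" else "optimum"
    b
  }))
  prof <- data.frame(patient_id = paste0("x", 1:8), priority = "moderate",
                     disposition = "home")
  lg <- event_log(days, prof)
  assign <- data.frame(day = 1:8, stratum = "weekday",
                       arm = ifelse(1:8 %% 2 == 1, "control", "optimum"))
  res <- compare_census_curves(lg, assign, n_permutations = 99)
  expect_equal(res$p_value, 1)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_error(compare_census_curves(lg, assign[1:2, ], n_permutations = 9),
               "2 days per arm")
})

test_that("census permutation test detects a doubled arrival rate", {
  set.seed(21)
  detected <- 0L
  n_rep <- 5
  for (r in 1:n_rep) {
    lgA <- run_simulation(sim_config(seed = 1000 + r, n_days = 8, arrivals_per_day = 40,
                                     arm = "control"))
    lgB <- run_simulation(sim_config(seed = 2000 + r, n_days = 8, arrivals_per_day = 80,
                                     arm = "optimum"))
    evB <- as.data.frame(lgB); evB$day <- evB$day + 8
    evB$patient_id <- paste0("b_", evB$patient_id)
    pfB <- attr(lgB, "profiles"); pfB$patient_id <- paste0("b_", pfB$patient_id)
    lg <- event_log(rbind(as.data.frame(lgA), evB), rbind(attr(lgA, "profiles"), pfB))
    assign <- data.frame(day = 1:16, stratum = "weekday",
                         arm = rep(c("control", "optimum"), each = 8))
    res <- compare_census_curves(lg, assign, n_permutations = 199)
    if (res$p_value < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, n_rep - 1)
})

make_interval_table <- function(valA, valB, priA, priB) {
  data.frame(
    patient_id = paste0("p", seq_len(length(valA) + length(valB))),
    arm = rep(c("control", "optimum"), c(length(valA), length(valB))),
    priority = c(priA, priB), interval = "total_los",
    value = c(valA, valB), stringsAsFactors = FALSE)
}

test_that("ancova arm p-values are uniform under the null", {
  set.seed(33)
  n <- 200
  pvals <- replicate(400, {
    pri <- sample(c("low", "moderate", "high"), 2 * n, TRUE, prob = c(0.3, 0.57, 0.13))
    iv <- make_interval_table(rlnorm(n, 5, 0.6), rlnorm(n, 5, 0.6),
                              pri[1:n], pri[(n + 1):(2 * n)])
    ancova_compare(iv, "total_los", "log")$p_value
  })
  # type-I error close to nominal, and roughly uniform
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.6)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("ancova detects a 1.5x shift and honors transforms", {
  set.seed(34)
  hits <- replicate(20, {
    n <- 500
    pri <- sample(c("low", "moderate"), 2 * n, TRUE)
    iv <- make_interval_table(rlnorm(n, 5, 0.6), 1.5 * rlnorm(n, 5, 0.6),
                              pri[1:n], pri[(n + 1):(2 * n)])
    ancova_compare(iv, "total_los", "log")$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
  # rank transform also works on zero-heavy data
  set.seed(35)
  n <- 300
  z <- function(n, p) ifelse(runif(n) < p, 0, rlnorm(n, 3, 1))
  iv <- make_interval_table(z(n, 0.5), z(n, 0.2) + 20,
                            rep("moderate", n), rep("moderate", n))
  res <- ancova_compare(iv, "total_los", "rank")
  expect_lt(res$p_value, 0.01)
  expect_equal(res$transform, "rank")
})

test_that("constant priority covariate reduces to the two-sample model", {
  set.seed(36)
  n <- 100
  iv <- make_interval_table(rlnorm(n), rlnorm(n), rep("moderate", n), rep("moderate", n))
  res <- ancova_compare(iv, "total_los", "log")
  y <- log1p(iv$value)
  p_t <- t.test(y[iv$arm == "control"], y[iv$arm == "optimum"], var.equal = TRUE)$p.value
  expect_equal(res$p_value, p_t, tolerance = 1e-12)
})

test_that("ancova interaction term reports heterogeneity by priority", {
  set.seed(37)
  n <- 800
  pri <- rep(c("low", "moderate"), n)
  # effect exists only for low-priority patients
  valA <- rlnorm(n, 5, 0.5)
  valB <- rlnorm(n, 5, 0.5) * ifelse(pri[(n + 1):(2 * n)] == "low", 1.8, 1)
  iv <- make_interval_table(valA, valB, pri[1:n], pri[(n + 1):(2 * n)])
  res <- ancova_compare(iv, "total_los", "log", interaction = TRUE)
  expect_lt(res$interaction_p, 0.01)
  expect_error(ancova_compare(iv[iv$arm == "control", ], "total_los"), "both arms")
})

test_that("standardized difference recovers known effects with a valid CI", {
  set.seed(38)
  x <- rnorm(1000, 0.5, 1); y <- rnorm(1000, 0, 1)
  res <- standardized_difference(c(x, y), rep(c("a", "b"), each = 1000))
  expect_equal(res$estimate, 0.5, tolerance = 0.2)
  expect_true(res$ci[1] <= res$estimate && res$estimate <= res$ci[2])
  expect_equal(res$label, "moderate")
  # identical arms -> 0; sign flips with label order; shift-invariant
  z <- rnorm(200)
  expect_equal(standardized_difference(c(z, z), rep(c("a", "b"), each = 200))$estimate, 0)
  res2 <- standardized_difference(c(x, y) + 100, rep(c("a", "b"), each = 1000))
  expect_equal(res2$estimate, res$estimate)
  expect_error(standardized_difference(rep(1, 10), rep(c("a", "b"), 5)), "pooled variance")
  expect_equal(effect_size_label(0.2), "small")
  expect_equal(effect_size_label(-0.8), "large")
  expect_equal(effect_size_label(0.1), "negligible")
})

test_that("Little's-law planning arithmetic matches the published reasoning", {
  expect_equal(littles_law_delta(78, 15), 0.8125)
  expect_equal(littles_law_delta(78, 15, round_patients = TRUE), 1)
  expect_equal(littles_law_delta(0, 15), 0)
  expect_equal(littles_law_delta(1440, 15), 15)
  expect_error(littles_law_delta(-1, 15), ">= 0")
  expect_equal(arrivals_per_day_from_annual(28500), 78)
  expect_equal(arrivals_per_day_from_annual(28500, round_daily = FALSE),
               28500 / 365, tolerance = 1e-12)
})

test_that("interval_report summarizes a two-arm trial log end to end", {
  tr <- run_trial(8, seed = 91, arrivals_per_day = 30)
  rep <- interval_report(filter_analysis_window(tr$log))
  expect_true("total_los" %in% rep$interval)
  expect_true(all(c("control_summary", "optimum_summary", "p_value") %in% names(rep)))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1, na.rm = TRUE))
})
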