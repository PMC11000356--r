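# independent oracle: enumerate every enabled action and sort with a
# from-scratch comparator that re-derives tier/color/priority
oracle_next_action <- function(role, dept, policy) {
  acts <- list(); keys <- list()
  overcrowded <- FALSE
  for (st in dept$patients) {
    if (st$discharged || st$reneged) next
    los <- dept$clock - st$profile$arrival_time
    pct <- los_percentiles(dept$reference, st$profile$reason)
    if (los > pct[3]) overcrowded <- TRUE
  }
  for (st in dept$patients) {
    if (st$visible_since > dept$clock || isTRUE(st$in_service)) next
    for (a in pending_actions(st, dept$clock)) {
      if (a$required_role != role || a$ready_time > dept$clock) next
      los <- dept$clock - st$profile$arrival_time
      pct <- los_percentiles(dept$reference, st$profile$reason)
      color <- if (los > pct[3]) 4 else if (los >= pct[2]) 3 else if (los >= pct[1]) 2 else 1
      if (st$profile$priority == "low" && color < 4) color <- 1
      tier <- switch(a$action_type,
        TRIAGE = , FIRST_MEDICAL_EVAL = if (overcrowded && policy == "optimum") 3 else 1,
        FINAL_DECISION = , DISCHARGE_PROCESS = if (overcrowded && policy == "optimum") 1 else 3,
        2)
      pr <- c(high = 1, moderate = 2, low = 3)[[st$profile$priority]]
      key <- if (policy == "optimum") {
        c(tier, -color, pr, a$ready_time,
          match(a$patient_id, sort(names(dept$patients))),
          match(a$action_type, names(ACTION_ROLES)))
      } else {
        c(pr, st$profile$arrival_time, a$ready_time,
          match(a$patient_id, sort(names(dept$patients))),
          match(a$action_type, names(ACTION_ROLES)))
      }
      acts <- c(acts, list(a)); keys <- c(keys, list(key))
    }
  }
  if (!length(acts)) return(NULL)
  ord <- do.call(order, as.data.frame(do.call(rbind, keys)))
  acts[[ord[1]]]
}
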