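#' System Usability Scale score
#'
#' Standard SUS scoring of a 10-item questionnaire answered on a 1--5
#' Likert scale: odd (positively worded) items contribute `score - 1`,
#' even (negatively worded) items contribute `5 - score`, and the total is
#' multiplied by 2.5, giving a score in `[0, 100]` in steps of 2.5.
#'
#' @param item_scores integer vector of exactly 10 item responses in 1..5,
#'   or a data frame/matrix with 10 such columns (one row per respondent).
#' @return Numeric score(s) in `[0, 100]`.
#' @examples
#' sus_score(rep(3, 10))  # 50
#' @export
sus_score <- function(item_scores) {
  if (is.data.frame(item_scores) || is.matrix(item_scores)) {
    m <- as.matrix(item_scores)
    if (ncol(m) != 10L) stop("exactly 10 items are required")
    return(apply(m, 1L, sus_score))
  }
  if (length(item_scores) != 10L) stop("exactly 10 items are required")
  if (any(is.na(item_scores)) || any(item_scores < 1 | item_scores > 5) ||
      any(item_scores != round(item_scores)))
    stop("item scores must be integers in 1..5")
  odd <- item_scores[c(1, 3, 5, 7, 9)]
  even <- item_scores[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' Interpretation band of a SUS score
#'
#' Published interpretation bands: very poor below 51, poor from 51 up to
#' (but excluding) 68, average at exactly 68, good above 68 up to 80.3,
#' excellent above 80.3.  (The source bands overlap at 68; 68 itself is
#' classified "average".)
#'
#' @param score numeric in `[0, 100]`.
#' @return One of `"very poor"`, `"poor"`, `"average"`, `"good"`,
#'   `"excellent"`.
#' @examples
#' sus_band(68)  # "average"
#' @export
sus_band <- function(score) {
  if (length(score) > 1L) return(vapply(score, sus_band, ""))
  if (is.na(score) || score < 0 || score > 100) stop("score must be in [0, 100]")
  if (score < 51) "very poor"
  else if (score < 68) "poor"
  else if (score == 68) "average"
  else if (score <= 80.3) "good"
  else "excellent"
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Spearman's rho with average ranks for ties; the p-value uses the
#' standard large-sample t approximation (ties make exact p-values
#' unavailable anyway).  Used to relate staff SUS scores to age or
#' seniority.
#'
#' @param x,y paired numeric vectors, `n >= 3`; pairs with `NA` are dropped.
#' @return List with `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Score a table of SUS responses
#'
#' @param responses data frame with columns `respondent_id`, `q1`..`q10`,
#'   and optionally `age_years`, `seniority_months`, `occupation`.
#' @return The input with `sus` and `band` columns appended, plus the
#'   score-vs-age rank correlation (when age is present) as attributes
#'   `age_correlation`.
#' @export
score_sus_responses <- function(responses) {
  qcols <- paste0("q", 1:10)
  if (!all(qcols %in% names(responses)))
    stop("responses must have columns q1..q10")
  responses$sus <- sus_score(responses[qcols])
  responses$band <- sus_band(responses$sus)
  if ("age_years" %in% names(responses) &&
      sum(!is.na(responses$age_years)) >= 3L) {
    attr(responses, "age_correlation") <-
      rank_correlation(responses$age_years, responses$sus)
  }
  responses
}
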