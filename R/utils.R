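#' @importFrom rlang abort warn inform := .data
#' @importFrom stats pnorm qnorm plogis qlogis rbinom runif glm binomial
#'   coef vcov logLik pchisq quantile rank sd cor lm fitted anova as.formula
#'   setNames qlnorm plnorm
NULL

abort_malformed <- function(msg) abort(msg, class = "ntcppce_malformed_input")
abort_config <- function(msg) abort(msg, class = "ntcppce_config_error")
abort_domain <- function(msg) abort(msg, class = "ntcppce_domain_error")
abort_contract <- function(msg) abort(msg, class = "ntcppce_contract_error")
abort_degenerate <- function(msg) abort(msg, class = "ntcppce_degenerate_data")

# outcome selector shared by fitting/validation: "any" -> any-grade PCE,
# "symptomatic" -> grade >= 3 PCE
outcome_column <- function(outcome = c("any", "symptomatic")) {
  outcome <- match.arg(outcome)
  switch(outcome,
    any = "outcome_any_grade",
    symptomatic = "outcome_symptomatic"
  )
}

outcome_vector <- function(cohort, outcome) {
  col <- outcome_column(outcome)
  if (!col %in% names(cohort)) {
    abort_contract(sprintf("cohort has no '%s' column", col))
  }
  y <- cohort[[col]]
  if (!all(y %in% c(0, 1))) {
    abort_malformed(sprintf("'%s' must be binary 0/1", col))
  }
  as.integer(y)
}

check_fit_feasible <- function(y) {
  if (sum(y) == 0L || sum(y) == length(y)) {
    abort_degenerate("cohort must contain at least one event and one non-event")
  }
  invisible(y)
}
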