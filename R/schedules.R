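# Age-dependent learning-rate schedules.  One model year = 1,000 training
# trials; schedules are indexed by total model age since birth, never by
# time since L2 onset.

#' Learning-rate schedule
#'
#' Three schedule kinds:
#' * `"constant"` — both rates fixed at `high_rate` for life.
#' * `"stretched_z"` — a single rate for the whole network: plateau at
#'   `high_rate` through `plateau_end_year`, linear decline to `low_rate`
#'   at `decline_end_year`, constant floor thereafter.
#' * `"dual_rate"` — the syntactic rate follows the stretched-Z shape with
#'   a floor of 0 while the lexical rate stays at `lexical_rate` at all
#'   ages.
#'
#' @param kind `"constant"`, `"stretched_z"` or `"dual_rate"`.
#' @param high_rate Plateau rate (default 0.1).
#' @param low_rate Floor rate (0.025 for `"stretched_z"`, 0 for the
#'   `"dual_rate"` syntactic rate).
#' @param plateau_end_year,decline_end_year Endpoints of the linear
#'   decline (defaults 10 and 16 model years).
#' @param lexical_rate Constant lexical rate for `"dual_rate"`.
#' @return An object of class `dp_schedule`.
#' @export
learning_schedule <- function(kind = c("constant", "stretched_z", "dual_rate"),
                              high_rate = 0.1, low_rate = NULL,
                              plateau_end_year = 10, decline_end_year = 16,
                              lexical_rate = 0.1) {
  kind <- match.arg(kind)
  if (is.null(low_rate)) low_rate <- if (kind == "dual_rate") 0 else 0.025
  stopifnot(high_rate >= 0, low_rate >= 0, lexical_rate >= 0,
            plateau_end_year < decline_end_year)
  s <- list(kind = kind, high_rate = high_rate, low_rate = low_rate,
            plateau_end_year = plateau_end_year,
            decline_end_year = decline_end_year, lexical_rate = lexical_rate)
  class(s) <- "dp_schedule"
  s
}

#' Learning rates at a given model age
#'
#' @param schedule A [learning_schedule()].
#' @param age_years Non-negative model age(s) since birth.
#' @return For a scalar age, a named vector `c(syntactic=, lexical=)`; for
#'   a vector of ages, a two-column matrix.
#' @export
lr_at_age <- function(schedule, age_years) {
  stopifnot(inherits(schedule, "dp_schedule"), all(age_years >= 0))
  z <- function(age) {
    pmin(pmax((schedule$decline_end_year - age) /
                (schedule$decline_end_year - schedule$plateau_end_year),
              0), 1) * (schedule$high_rate - schedule$low_rate) +
      schedule$low_rate
  }
  res <- switch(schedule$kind,
    constant = cbind(syntactic = rep(schedule$high_rate, length(age_years)),
                     lexical = rep(schedule$high_rate, length(age_years))),
    stretched_z = cbind(syntactic = z(age_years), lexical = z(age_years)),
    dual_rate = cbind(syntactic = z(age_years),
                      lexical = rep(schedule$lexical_rate, length(age_years))))
  if (length(age_years) == 1L) res[1L, ] else res
}
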