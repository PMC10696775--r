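#' Build the model's cycle plan
#'
#' Monthly cycles for the first 4 years, annual cycles thereafter:
#' 48 one-month cycles covering months 0-47, then `horizon_years - 4`
#' twelve-month cycles.  A 10-year horizon therefore has 54 cycles
#' covering months 0-120.
#'
#' @param horizon_years Whole-year horizon, at least 5.
#' @return A data.frame of class `cycle_plan` with columns `cycle`
#'   (0-based index), `start` (months) and `length` (months).
#' @export
build_cycle_plan <- function(horizon_years = 10) {
  if (horizon_years < 5 || horizon_years != round(horizon_years)) {
    stop("horizon must be a whole number of years >= 5", call. = FALSE)
  }
  starts <- c(0:47, seq(48, horizon_years * 12 - 12, by = 12))
  lens <- c(rep(1, 48), rep(12, horizon_years - 4))
  structure(data.frame(cycle = seq_along(starts) - 1L, start = starts,
                       length = lens),
            class = c("cycle_plan", "data.frame"))
}

#' Discount factor at a time point
#'
#' \eqn{(1 + r)^{-t/12}} for annual rate `r` and time `t` in months;
#' applied at each cycle's start time.
#'
#' @param t_months Time in months (vectorised).
#' @param annual_rate Annual discount rate (>= 0), default 0.05.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(t_months, annual_rate = 0.05) {
  if (any(annual_rate < 0)) stop("discount rate must be >= 0", call. = FALSE)
  if (any(t_months < 0)) stop("t must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-t_months / 12)
}
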