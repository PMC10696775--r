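#' Scheduled follow-up visits within a cycle
#'
#' Routine visits occur every 3 months in the first 2 years, every
#' 6 months in years 3-5, and yearly thereafter.  A cycle starting at
#' `t` with length `delta` months contains the visits falling in
#' `(t, t + delta]`.
#'
#' @param t Cycle start time in months.
#' @param delta Cycle length in months (default 1).
#' @return Number of scheduled visits in the cycle.
#' @export
followup_visits <- function(t, delta = 1) {
  schedule <- c(seq(3, 24, by = 3), seq(30, 60, by = 6),
                seq(72, 1200, by = 12))
  delta <- rep_len(delta, length(t))
  vapply(seq_along(t), function(i) {
    sum(schedule > t[i] & schedule <= t[i] + delta[i])
  }, numeric(1))
}

#' Expected one-off SAE cost for a strategy's first-line month
#'
#' Sum over grade >= 3 adverse events of risk times unit treatment cost.
#'
#' @param risks Named risk vector (neutropenia, thrombocytopenia,
#'   febrile_neutropenia, hypertension).
#' @param unit_costs Named unit-cost vector over the same events.
#' @return Expected cost in USD.
#' @export
sae_expected_cost <- function(risks, unit_costs) {
  ev <- names(unit_costs)
  sum(risks[ev] * unit_costs[ev])
}

#' Expected first-cycle SAE utility decrement
#'
#' @param risks Named risk vector.
#' @param disutil Named vector of (non-negative) utility decrements.
#' @return Expected utility decrement (applied for one month).
#' @export
sae_expected_disutility <- function(risks, disutil) {
  ev <- names(disutil)
  sum(risks[ev] * disutil[ev])
}

#' Adjust a historical cost to 2022 US dollars
#'
#' Applies a health-CPI ratio and, for amounts quoted in CNY, the 2022
#' average exchange rate of 6.7261 CNY per USD.
#'
#' @param amount Cost amount.
#' @param from_year Year the amount was quoted in.
#' @param cpi Named numeric vector of health-CPI index values by year
#'   (must contain `from_year` and `2022`).
#' @param currency `"USD"` or `"CNY"`.
#' @param cny_per_usd Exchange rate (default 6.7261).
#' @return The amount in 2022 USD.
#' @export
adjust_cost <- function(amount, from_year, cpi = default_health_cpi(),
                        currency = c("USD", "CNY"), cny_per_usd = 6.7261) {
  currency <- match.arg(currency)
  y <- as.character(from_year)
  if (!y %in% names(cpi) || !"2022" %in% names(cpi)) {
    stop(sprintf("no CPI index for year %s", from_year), call. = FALSE)
  }
  out <- amount * cpi[["2022"]] / cpi[[y]]
  if (currency == "CNY") out <- out / cny_per_usd
  unname(out)
}

#' Packaged health-CPI index (China, health component; 2015 = 100)
#'
#' A small reference series used by [adjust_cost()]; replace with your
#' own series for other settings.
#'
#' @return Named numeric vector by year.
#' @export
default_health_cpi <- function() {
  c("2015" = 100.0, "2016" = 103.8, "2017" = 109.7, "2018" = 114.5,
    "2019" = 117.2, "2020" = 119.3, "2021" = 119.7, "2022" = 120.4)
}

# ---- internal accrual primitives shared by cycle_cost() and the engine ----

# First-line per-occupant cost components for a cycle starting at month t
# (time since first-line entry; for line 1 this equals model time).
# Returns components: drug (incl. LE maintenance), admin, supportive,
# hospitalization.
first_line_cost <- function(strategy, t, delta, costs) {
  months <- t + seq_len(delta) - 1  # calendar months covered by the cycle
  drug <- admin <- supportive <- hosp <- 0
  if (strategy == "IB") {
    drug <- costs$monthly[["IB"]] * delta
  } else {
    for (m in months) {
      if (m < 6) {
        # intravenous chemo-immunotherapy cycles 1-6
        drug <- drug + costs$monthly[["BE"]] + costs$monthly[["RI"]]
        # 3 infusion days (BE on days 1-2 + RI on 1 day), one drug group each
        admin <- admin + 3 * costs$iv_infusion + 3 * costs$allocation
        supportive <- supportive + costs$supportive
        hosp <- hosp + costs$hospitalization
      } else if (m == 6) {
        drug <- drug + costs$monthly[["LE"]] / 3       # 5 mg of 15 mg
      } else if (m < 12) {
        drug <- drug + costs$monthly[["LE"]] * 2 / 3   # 10 mg of 15 mg
      } else {
        drug <- drug + costs$monthly[["LE"]]           # full 15 mg
      }
    }
  }
  list(drug = drug, admin = admin, supportive = supportive, hosp = hosp)
}

# Subsequent-line drug cost per occupant for a cycle of length delta.
subsequent_line_cost <- function(drug, delta, costs) {
  costs$monthly[[drug]] * delta
}

#' Per-occupant cycle cost for a model state
#'
#' Undiscounted cost accrued over one cycle by a patient occupying the
#' given state, split into the categories used in the base-case table.
#' Transition-linked one-off costs (end-of-life, allo-HSCT entry) and the
#' first-cycle SAE lump are returned by the dedicated `state` values
#' `"death_transition"`, `"allo_entry"` and the `cycle == 0` EFS case.
#'
#' @param model A [default_model()]-style definition.
#' @param strategy `"IB"` or `"BE_RI"`.
#' @param state One of `"EFS"`, `"TF"`, `"L2"`, `"L3"`, `"allo"`,
#'   `"allo_entry"`, `"BSC"`, `"death"`, `"death_transition"`.
#' @param cycle 0-based cycle index into the model's cycle plan.
#' @param tau Months since entering the current line (defaults to the
#'   cycle start time, exact for first-line states).
#' @return Named numeric vector of cost components:
#'   `drug_first_line`, `drug_subsequent`, `ae`, `other`.
#' @export
cycle_cost <- function(model, strategy = c("IB", "BE_RI"), state, cycle,
                       tau = NULL) {
  strategy <- match.arg(strategy)
  plan <- build_cycle_plan(model$horizon_years)
  if (cycle < 0 || cycle >= nrow(plan)) stop("cycle outside plan", call. = FALSE)
  t <- plan$start[cycle + 1]; delta <- plan$length[cycle + 1]
  if (is.null(tau)) tau <- t
  costs <- model$costs
  out <- c(drug_first_line = 0, drug_subsequent = 0, ae = 0, other = 0)
  risks <- model$sae_risks[[strategy]]
  arm_lines <- model$strategies[[strategy]]$lines
  if (state == "EFS") {
    fc <- first_line_cost(strategy, tau, delta, costs)
    out["drug_first_line"] <- fc$drug + fc$admin + fc$supportive
    out["other"] <- fc$hosp + followup_visits(t, delta) * costs$followup_visit
    out["ae"] <- risks[["hypertension"]] *
      costs$hypertension_outpatient_annual * delta / 12
    if (cycle == 0) out["ae"] <- out["ae"] + sae_expected_cost(risks, costs$sae)
  } else if (state %in% c("L2", "L3")) {
    drug <- arm_lines[[if (state == "L2") 2 else 3]]$drug
    out["drug_subsequent"] <- subsequent_line_cost(drug, delta, costs)
    out["other"] <- followup_visits(t, delta) * costs$followup_visit
    out["ae"] <- risks[["hypertension"]] *
      costs$hypertension_outpatient_annual * delta / 12
  } else if (state == "allo") {
    out["other"] <- followup_visits(t, delta) * costs$followup_visit
    out["ae"] <- risks[["hypertension"]] *
      costs$hypertension_outpatient_annual * delta / 12
  } else if (state == "allo_entry") {
    out["other"] <- costs$allo_hsct
  } else if (state == "BSC") {
    out["other"] <- costs$bsc_monthly * delta
    out["ae"] <- risks[["hypertension"]] *
      costs$hypertension_outpatient_annual * delta / 12
  } else if (state == "TF") {
    out["ae"] <- risks[["hypertension"]] *
      costs$hypertension_outpatient_annual * delta / 12
  } else if (state == "death_transition") {
    out["other"] <- costs$eol
  } else if (state == "death") {
    # absorbing, no accrual
  } else {
    stop(sprintf("unknown state '%s'", state), call. = FALSE)
  }
  out
}

#' Per-occupant cycle utility (QALY increment)
#'
#' Utility weight times cycle length in years.  Event-free survival uses
#' the oral-treatment weight in the IB arm and the intravenous-treatment
#' weight in the BE+RI arm (the published utilities distinguish the two
#' first-line routes, not individual cycles).  The transient
#' treatment-failure month after first line carries the
#' progression-after-first-line weight; relapsed treatment lines
#' (2L/3L/allo-HSCT), later treatment-failure months and BSC carry the
#' relapsed-lines weight.  The first model cycle of first-line treatment
#' subtracts the expected SAE utility decrement for one month.
#'
#' @inheritParams cycle_cost
#' @param state As in [cycle_cost()], plus `"TF_1L"` (the transient
#'   month after first-line failure) versus `"TF"` (later lines).
#' @return QALY increment for one occupant over the cycle.
#' @export
cycle_utility <- function(model, strategy = c("IB", "BE_RI"), state, cycle,
                          tau = NULL) {
  strategy <- match.arg(strategy)
  plan <- build_cycle_plan(model$horizon_years)
  if (cycle < 0 || cycle >= nrow(plan)) stop("cycle outside plan", call. = FALSE)
  t <- plan$start[cycle + 1]; delta <- plan$length[cycle + 1]
  if (is.null(tau)) tau <- t
  u <- model$utilities
  w <- switch(state,
    EFS = if (strategy == "BE_RI") u$efs_iv else u$efs_oral,
    TF_1L = u$pf_after_1L,
    TF = u$pf_relapsed, BSC = u$pf_relapsed,
    L2 = u$pf_relapsed, L3 = u$pf_relapsed, allo = u$pf_relapsed,
    death = u$death,
    stop(sprintf("unknown state '%s'", state), call. = FALSE))
  q <- w * delta / 12
  if (state == "EFS" && cycle == 0) {
    q <- q - sae_expected_disutility(model$sae_risks[[strategy]],
                                     u$disutil) / 12
  }
  q
}
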