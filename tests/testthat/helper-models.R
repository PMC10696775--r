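# Shared fixtures, all generated in code.

# A model in which nothing ever happens: vanishing hazards, no background
# mortality, no one-off costs beyond treatment.
frozen_model <- function(strategy_drug_cost = NULL) {
  m <- default_model(life_table = make_life_table("flat", q = 0))
  eps <- surv_dist("exponential", rate = 1e-14)
  for (d in names(m$dists)) m$dists[[d]] <- eps
  m$allo$nrm_monthly_early <- m$allo$nrm_monthly_late <- 0
  m$allo$relapse_monthly_early <- m$allo$relapse_monthly_late <- 0
  validate_model(m)
}

# Single effective line with exponential PFS = OS (no progression, pure
# death), utility u, flat monthly drug cost, nothing else: admits an exact
# geometric-series solution.
oracle_exp_model <- function(hazard, utility = 0.71, monthly_cost = 1000,
                             discount = 0.05) {
  m <- default_model(discount_rate = discount,
                     life_table = make_life_table("flat", q = 0))
  d <- surv_dist("exponential", rate = hazard)
  for (nm in names(m$dists)) m$dists[[nm]] <- d
  m$costs$monthly[] <- monthly_cost
  m$costs$iv_infusion <- m$costs$allocation <- 0
  m$costs$supportive <- m$costs$hospitalization <- 0
  m$costs$sae[] <- 0
  m$costs$hypertension_outpatient_annual <- 0
  m$costs$followup_visit <- 0
  m$costs$bsc_monthly <- 0
  m$costs$allo_hsct <- 0
  m$costs$eol <- 0
  m$utilities$efs_oral <- m$utilities$efs_iv <- utility
  m$utilities$disutil[] <- 0
  m$sae_risks$IB[] <- 0
  m$sae_risks$BE_RI[] <- 0
  validate_model(m)
}

# Exact geometric-series totals for the oracle model above (IB arm):
# occupancy decays by e^(-h * delta) per cycle, accrual at cycle start.
oracle_exp_totals <- function(hazard, utility, monthly_cost, discount) {
  plan <- build_cycle_plan(10)
  occ <- exp(-hazard * plan$start)
  disc <- (1 + discount)^(-plan$start / 12)
  qaly <- sum(occ * disc * utility * plan$length / 12)
  cost <- sum(occ * disc * monthly_cost * plan$length)
  list(qaly = qaly, cost = cost)
}

# Minimal hand-built surv_fit stand-ins for selection tests.
fake_fit <- function(family, aic, bic, k) {
  structure(list(distribution = NULL, family = family, loglik = NA,
                 aic = aic, bic = bic, k = k, n = 10, n_events = 5),
            class = "surv_fit")
}

published <- list(
  qaly_ib = 4.48, qaly_beri = 3.30, dqaly = 1.17,
  cost_ib = 184041.53, cost_beri = 272088.31, dcost = 88046.78,
  drug1_ib = 172897.84, drug1_beri = 237779.12,
  icer = -75107.35, wtp = 38223.34)
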