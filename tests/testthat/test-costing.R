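# Cost and utility accrual rules.

test_that("follow-up visit schedule: quarterly, six-monthly, then annual", {
  # 4 visits in the first 12 months (months 3, 6, 9, 12)
  expect_equal(sum(followup_visits(0:11, 1)), 4)
  # annual cycle covering months 36-47: visits at 42 and 48
  expect_equal(followup_visits(36, 12), 2)
  # annual cycle covering months 72-83: one visit
  expect_equal(followup_visits(72, 12), 1)
  # 19 visits over the whole 10-year plan
  plan <- build_cycle_plan(10)
  expect_equal(sum(followup_visits(plan$start, plan$length)), 19)
})

test_that("expected SAE cost and disutility aggregate risk x unit values", {
  m <- default_model()
  expect_equal(sae_expected_cost(m$sae_risks$BE_RI, m$costs$sae),
               0.4034 * 815.10 + 0.1477 * 605.63 + 0.0739 * 4516.31 +
                 0.1420 * 968.52, tolerance = 1e-9)
  expect_equal(sae_expected_cost(m$sae_risks$BE_RI, m$costs$sae), 889.548,
               tolerance = 1e-5)
  expect_equal(sae_expected_disutility(m$sae_risks$IB, m$utilities$disutil),
               0.15 * 0.163 + 0.0667 * 0.108 + 0.0167 * 0.15 + 0.2944 * 0.195,
               tolerance = 1e-9)
  expect_equal(sae_expected_disutility(m$sae_risks$IB, m$utilities$disutil),
               0.0915666, tolerance = 1e-6)
})

test_that("per-state cycle costs follow the regimen rules", {
  m <- default_model()
  # IB arm, EFS, cycle 4 (month 4, no visit falls in (4, 5])
  cc <- cycle_cost(m, "IB", "EFS", 4)
  expect_equal(cc[["drug_first_line"]], 2360.36)
  expect_equal(cc[["other"]], 0)
  expect_equal(cc[["ae"]], 0.2944 * 129.48 / 12, tolerance = 1e-9)
  # month 5 cycle contains the month-6 visit
  expect_equal(cycle_cost(m, "IB", "EFS", 5)[["other"]], 48.80)
  # BE+RI chemo month: drugs + admin + supportive as first-line drug cost,
  # hospitalization as other
  cc0 <- cycle_cost(m, "BE_RI", "EFS", 1)
  expect_equal(cc0[["drug_first_line"]],
               1543.10 + 1797.48 + 3 * 0.22 + 3 * 0.90 + 2703.17,
               tolerance = 1e-9)
  expect_equal(cc0[["other"]], 1454.95)
  # first cycle adds the SAE lump
  expect_equal(cycle_cost(m, "BE_RI", "EFS", 0)[["ae"]],
               889.548 + 0.1420 * 129.48 / 12, tolerance = 1e-3)
  # lenalidomide maintenance dose escalation: 1/3, 2/3, then full
  expect_equal(cycle_cost(m, "BE_RI", "EFS", 6)[["drug_first_line"]],
               5069.89 / 3, tolerance = 1e-9)
  expect_equal(cycle_cost(m, "BE_RI", "EFS", 9)[["drug_first_line"]],
               5069.89 * 2 / 3, tolerance = 1e-9)
  expect_equal(cycle_cost(m, "BE_RI", "EFS", 20)[["drug_first_line"]],
               5069.89, tolerance = 1e-9)
  # annual cycle: 12 months of full-dose maintenance
  expect_equal(cycle_cost(m, "BE_RI", "EFS", 50)[["drug_first_line"]],
               12 * 5069.89, tolerance = 1e-9)
  # subsequent lines draw the right drug price
  expect_equal(cycle_cost(m, "IB", "L2", 10)[["drug_subsequent"]], 2940.04)
  expect_equal(cycle_cost(m, "BE_RI", "L2", 10)[["drug_subsequent"]], 2360.36)
  # one-off states and absorbing death
  expect_equal(cycle_cost(m, "IB", "allo_entry", 30)[["other"]], 59621.17)
  expect_equal(cycle_cost(m, "IB", "death_transition", 30)[["other"]],
               12455.19)
  expect_equal(sum(cycle_cost(m, "IB", "death", 30)), 0)
  expect_equal(cycle_cost(m, "IB", "BSC", 50)[["other"]], 12 * 299.95)
  expect_error(cycle_cost(m, "IB", "nonsense", 3), "unknown state")
})

test_that("per-state cycle utilities follow the published weights", {
  m <- default_model()
  expect_equal(cycle_utility(m, "IB", "EFS", 5), 0.71 / 12, tolerance = 1e-12)
  expect_equal(cycle_utility(m, "BE_RI", "EFS", 5), 0.67 / 12,
               tolerance = 1e-12)
  expect_equal(cycle_utility(m, "IB", "TF_1L", 10), 0.66 / 12)
  expect_equal(cycle_utility(m, "IB", "L2", 10), 0.42 / 12)
  expect_equal(cycle_utility(m, "IB", "BSC", 50), 0.42)
  expect_equal(cycle_utility(m, "IB", "death", 10), 0)
  # first-cycle SAE decrement
  dis <- sae_expected_disutility(m$sae_risks$IB, m$utilities$disutil)
  expect_equal(cycle_utility(m, "IB", "EFS", 0), 0.71 / 12 - dis / 12,
               tolerance = 1e-12)
})

test_that("historical costs adjust by CPI ratio and exchange rate", {
  expect_equal(adjust_cost(100, 2022), 100)
  expect_equal(adjust_cost(672.61, 2022, currency = "CNY"), 100,
               tolerance = 1e-9)
  cpi <- c("2018" = 100, "2022" = 110)
  expect_equal(adjust_cost(100, 2018, cpi = cpi), 110)
  expect_error(adjust_cost(100, 1999), "CPI")
})

test_that("zero unit costs zero the totals without touching QALYs", {
  m <- default_model()
  m0 <- m
  m0$costs$monthly[] <- 0; m0$costs$per_mg[] <- 0
  m0$costs$iv_infusion <- m0$costs$allocation <- 0
  m0$costs$supportive <- m0$costs$hospitalization <- 0
  m0$costs$sae[] <- 0; m0$costs$hypertension_outpatient_annual <- 0
  m0$costs$followup_visit <- 0; m0$costs$bsc_monthly <- 0
  m0$costs$allo_hsct <- 0; m0$costs$eol <- 0
  for (s in c("IB", "BE_RI")) {
    t0 <- run_cohort(m0, s); t1 <- run_cohort(m, s)
    expect_equal(t0$total_cost, 0)
    expect_equal(t0$total_qaly, t1$total_qaly, tolerance = 1e-12)
  }
})

test_that("raising a unit cost weakly raises the owning strategy's total", {
  m <- default_model()
  base <- run_cohort(m, "IB")$total_cost
  m$costs$monthly[["IB"]] <- m$costs$monthly[["IB"]] * 1.2
  expect_gt(run_cohort(m, "IB")$total_cost, base)
  m2 <- default_model()
  base2 <- run_cohort(m2, "BE_RI")$total_cost
  m2$costs$bsc_monthly <- m2$costs$bsc_monthly * 2
  expect_gte(run_cohort(m2, "BE_RI")$total_cost, base2)
})

test_that("cost categories partition the total exactly", {
  m <- default_model()
  for (s in c("IB", "BE_RI")) {
    tr <- run_cohort(m, s)
    expect_equal(sum(tr$categories), tr$total_cost, tolerance = 1e-9)
    expect_equal(sum(tr$trace$cost), tr$total_cost, tolerance = 1e-6)
  }
})
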