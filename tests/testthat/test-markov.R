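# Cycle plan, discounting and the cohort state-transition engine.

test_that("cycle plan has 48 monthly + annual cycles covering the horizon", {
  plan <- build_cycle_plan(10)
  expect_equal(nrow(plan), 54)
  expect_equal(sum(plan$length), 120)
  expect_equal(plan$length, c(rep(1, 48), rep(12, 6)))
  # contiguous, non-overlapping
  expect_equal(plan$start, cumsum(c(0, plan$length[-54])))
  expect_equal(nrow(build_cycle_plan(5)), 49)
  expect_error(build_cycle_plan(4), "horizon")
  expect_error(build_cycle_plan(7.5), "horizon")
})

test_that("discount factors follow (1+r)^(-t/12)", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(12, 0.05), 1 / 1.05, tolerance = 1e-12)
  expect_equal(discount_factor(c(0, 6, 600), 0), rep(1, 3))
  expect_error(discount_factor(12, -0.01), ">= 0")
})

test_that("per-line transition probabilities compose PFS, OS and background", {
  # first-line IB disease mortality over one month
  os <- surv_dist("exponential", rate = 0.00368296)
  pfs <- surv_dist("exponential", rate = 0.00592451)
  p <- line_transition_probs(pfs, os, tau = 10, delta = 1)
  expect_equal(p$die, 1 - exp(-0.00368296), tolerance = 1e-12)
  expect_equal(p$fail, exp(-0.00368296) - exp(-0.00592451), tolerance = 1e-9)
  expect_equal(p$stay + p$fail + p$die, 1, tolerance = 1e-12)
  # background flooring: q_annual = 0.02 over one month
  bg <- background_mortality(make_life_table("flat", q = 0.02), 70, 1)
  expect_equal(bg, 1 - 0.98^(1 / 12), tolerance = 1e-12)
  p2 <- line_transition_probs(pfs, surv_dist("exponential", rate = 1e-8),
                              tau = 0, delta = 1, bg = bg)
  expect_equal(p2$die, bg, tolerance = 1e-12)
  # degenerate PFS == OS: no failures, only deaths
  p3 <- line_transition_probs(os, os, tau = 5, delta = 1)
  expect_equal(p3$fail, 0)
})

test_that("frozen cohort stays in EFS and accrues the closed-form QALYs", {
  m <- frozen_model()
  tr <- run_cohort(m, "IB")
  plan <- build_cycle_plan(10)
  expect_equal(tr$trace$efs, rep(1, 54), tolerance = 1e-8)
  q_expect <- sum(0.71 * plan$length / 12 * discount_factor(plan$start, 0.05)) -
    sae_expected_disutility(m$sae_risks$IB, m$utilities$disutil) / 12
  expect_equal(tr$total_qaly, q_expect, tolerance = 1e-8)
})

test_that("immediate death truncates accrual and charges end-of-life once", {
  m <- frozen_model()
  lethal <- surv_dist("exponential", rate = 50)  # S(1 month) ~ 2e-22
  m$dists$ib1_pfs <- lethal
  m$dists$ib1_os <- lethal
  tr <- run_cohort(m, "IB")
  expect_equal(tr$trace$dead[2], 1, tolerance = 1e-9)
  q1 <- 0.71 / 12 -
    sae_expected_disutility(m$sae_risks$IB, m$utilities$disutil) / 12
  expect_equal(tr$total_qaly, q1, tolerance = 1e-6)
  # EOL charged once at full value (death in cycle 0, discount 1)
  m$costs$eol <- 12455.19
  tr2 <- run_cohort(m, "IB")
  expect_equal(tr2$categories[["other"]], 12455.19, tolerance = 1e-3)
})

test_that("traces conserve occupancy, keep death absorbing, stay valid", {
  m <- default_model()
  for (s in c("IB", "BE_RI")) {
    tr <- run_cohort(m, s)
    t <- tr$trace
    sums <- t$efs + t$tf + t$l2 + t$l3 + t$allo + t$bsc + t$dead
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(as.matrix(t[c("efs", "tf", "l2", "l3", "allo", "bsc",
                                  "dead")]) >= -1e-12))
    expect_true(all(diff(t$dead) >= -1e-12))
    expect_true(all(t$cost >= 0))
  }
})

test_that("zero discounting weakly increases totals", {
  m0 <- default_model(discount_rate = 0)
  m <- default_model()
  for (s in c("IB", "BE_RI")) {
    t0 <- run_cohort(m0, s); t1 <- run_cohort(m, s)
    expect_gte(t0$total_cost, t1$total_cost)
    expect_gte(t0$total_qaly, t1$total_qaly)
  }
})

test_that("engine matches the exponential geometric-series closed form", {
  h <- 0.01; u <- 0.71; cst <- 1000; r <- 0.05
  m <- oracle_exp_model(h, u, cst, r)
  tr <- run_cohort(m, "IB")
  o <- oracle_exp_totals(h, u, cst, r)
  expect_equal(tr$total_qaly, o$qaly, tolerance = 1e-6)
  expect_equal(tr$total_cost, o$cost, tolerance = 1e-6)
})

test_that("extending the horizon never decreases undiscounted QALYs", {
  m10 <- default_model(horizon_years = 10, discount_rate = 0)
  m20 <- default_model(horizon_years = 20, discount_rate = 0)
  for (s in c("IB", "BE_RI")) {
    expect_gte(run_cohort(m20, s)$total_qaly, run_cohort(m10, s)$total_qaly)
  }
})

test_that("background-mortality scope toggle floors EFS deaths too", {
  m <- default_model(life_table = make_life_table("flat", q = 0.30))
  m$toggles$background_scope <- "all_alive"
  tr_all <- run_cohort(m, "IB")
  m$toggles$background_scope <- "pf_only"
  tr_pf <- run_cohort(m, "IB")
  expect_gt(tr_all$trace$dead[13], tr_pf$trace$dead[13])
})

test_that("life table generator produces the advertised profiles", {
  flat <- make_life_table("flat", q = 0.02)
  expect_true(all(flat$qx == 0.02))
  aging <- make_life_table("aging")
  expect_true(all(diff(aging$qx) > 0))
  # zero-mortality table produces no background deaths in the frozen model
  expect_equal(background_mortality(make_life_table("flat", q = 0), 80, 12), 0)
})
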