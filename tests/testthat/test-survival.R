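# Closed-form survivor functions, transition probabilities and MLE fitting.

test_that("survivor functions match their closed forms", {
  # each family checked against direct arithmetic, not the same pdist call
  expect_equal(survival_at(surv_dist("exponential", rate = 0.00592451), 0), 1)
  expect_equal(survival_at(surv_dist("exponential", rate = 0.00592451), 24),
               exp(-0.00592451 * 24), tolerance = 1e-12)
  g <- surv_dist("gompertz", shape = 0.02325928, rate = 0.00943535)
  expect_equal(survival_at(g, 24),
               exp(-(0.00943535 / 0.02325928) * (exp(0.02325928 * 24) - 1)),
               tolerance = 1e-12)
  expect_equal(survival_at(g, 24), 0.7384097, tolerance = 1e-6)
  expect_equal(survival_at(surv_dist("weibull", shape = 1.3, rate = 0.02), 30),
               exp(-(0.02 * 30)^1.3), tolerance = 1e-12)
  expect_equal(survival_at(surv_dist("loglogistic", shape = 2, scale = 3), 2),
               1 / (1 + (2 / 3)^2), tolerance = 1e-12)
  expect_equal(survival_at(surv_dist("lognormal", meanlog = 3, sdlog = 0.8), 20),
               1 - pnorm((log(20) - 3) / 0.8), tolerance = 1e-12)
  expect_equal(survival_at(surv_dist("gamma", shape = 2, rate = 0.05), 10),
               (1 + 0.05 * 10) * exp(-0.05 * 10), tolerance = 1e-12)  # Erlang-2
})

test_that("all families give valid, monotone survival curves", {
  dists <- list(
    surv_dist("exponential", rate = 0.01),
    surv_dist("weibull", shape = 0.8, rate = 0.02),
    surv_dist("gompertz", shape = 0.03, rate = 0.005),
    surv_dist("gompertz", shape = -0.02, rate = 0.01),
    surv_dist("gamma", shape = 1.18, rate = 0.019),
    surv_dist("lognormal", meanlog = 3.5, sdlog = 1.1),
    surv_dist("loglogistic", shape = 1.5, scale = 40))
  grid <- seq(0, 240, by = 0.5)
  for (d in dists) {
    s <- survival_at(d, grid)
    expect_equal(s[1], 1)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
    tp <- transition_prob(d, grid[-length(grid)], 0.5)
    expect_true(all(tp >= 0 & tp <= 1))
  }
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(surv_dist("exponential", rate = -1), "must be > 0")
  expect_error(surv_dist("weibull", shape = 1), "requires parameters")
  expect_error(surv_dist("notafamily", rate = 1))
  expect_error(survival_at(surv_dist("exponential", rate = 1), -2), ">= 0")
})

test_that("transition probabilities: closed form, memorylessness, composition", {
  e <- surv_dist("exponential", rate = 0.00592451)
  expect_equal(transition_prob(e, 0, 1), 1 - exp(-0.00592451),
               tolerance = 1e-12)
  # memorylessness: identical at any t
  expect_equal(transition_prob(e, c(0, 7, 60, 119), 1),
               rep(1 - exp(-0.00592451), 4), tolerance = 1e-12)
  # increasing hazard for positive-shape gompertz
  g <- surv_dist("gompertz", shape = 0.02325928, rate = 0.00943535)
  expect_gt(transition_prob(g, 60, 1), transition_prob(g, 0, 1))
  # composition identity: two half-steps compose into one double step
  for (d in list(e, g, surv_dist("gamma", shape = 1.18, rate = 0.019),
                 surv_dist("loglogistic", shape = 1.5, scale = 40))) {
    for (t0 in c(0, 5.5, 48, 100)) {
      lhs <- 1 - (1 - transition_prob(d, t0, 1)) *
        (1 - transition_prob(d, t0 + 1, 1))
      expect_equal(lhs, transition_prob(d, t0, 2), tolerance = 1e-12)
    }
  }
  expect_error(transition_prob(e, 0, 0), "delta")
})

test_that("exponential MLE recovers the generating rate and the closed form", {
  co <- simulate_cohort(5000, surv_dist("exponential", rate = 0.006),
                        admin_censor = 240, seed = 7)
  f <- fit_parametric(co, "exponential")
  # independent oracle: censored-exponential MLE is events / total exposure
  expect_equal(f$distribution$params$rate, sum(co$event) / sum(co$time),
               tolerance = 1e-6)
  expect_lt(abs(f$distribution$params$rate - 0.006) / 0.006, 0.05)
  expect_equal(f$n, 5000)
})

test_that("information criteria match a hand-computed 3-observation example", {
  # events at 1, 2, 3: rate-hat = 3/6, ll = 3 log(1/2) - 3
  tiny <- data.frame(time = c(1, 2, 3), event = 1)
  f <- fit_parametric(tiny, "exponential")
  expect_equal(f$distribution$params$rate, 0.5, tolerance = 1e-4)
  ll <- 3 * log(0.5) - 0.5 * 6
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$aic, -2 * ll + 2, tolerance = 1e-4)
  expect_equal(f$bic, -2 * ll + log(3), tolerance = 1e-4)
})

test_that("fitting degenerate inputs errors", {
  expect_error(fit_parametric(data.frame(time = 1:5, event = 0), "exponential"),
               "at least 2 events")
  expect_error(fit_parametric(data.frame(time = numeric(), event = integer()),
                              "exponential"), "empty")
  expect_error(fit_parametric(data.frame(time = c(-1, 2), event = 1),
                              "exponential"), "> 0")
})

test_that("model selection identifies the generating family", {
  co <- simulate_cohort(800, surv_dist("exponential", rate = 0.01),
                        admin_censor = 120, seed = 11)
  fits <- suppressWarnings(fit_all_families(co))
  expect_identical(select_best(fits, "bic")$family, "exponential")
  co3 <- simulate_cohort(2000, surv_dist("gompertz", shape = 0.04, rate = 0.004),
                         admin_censor = 120, seed = 13)
  fits3 <- suppressWarnings(fit_all_families(co3))
  expect_identical(select_best(fits3, "aic")$family, "gompertz")
})

test_that("select_best handles singletons, ties and empty input", {
  f1 <- fake_fit("weibull", aic = 100, bic = 101, k = 2)
  f2 <- fake_fit("exponential", aic = 90, bic = 95, k = 1)
  expect_identical(select_best(list(f1, f2), "aic")$family, "exponential")
  expect_identical(select_best(list(f1), "aic")$family, "weibull")
  # AIC tie: fewer parameters wins
  f3 <- fake_fit("gamma", aic = 90, bic = 99, k = 2)
  expect_identical(select_best(list(f3, f2), "aic")$family, "exponential")
  # full tie: family-name order
  f4 <- fake_fit("loglogistic", aic = 90, bic = 95, k = 1)
  expect_identical(select_best(list(f4, f2), "aic")$family, "exponential")
  expect_error(select_best(list(), "aic"), "empty")
})
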