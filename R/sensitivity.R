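#' Sensitivity-analysis parameter specifications
#'
#' One `param_spec` per uncertain input: base value, one-way range
#' (published low/high bounds, else a 25% range), the probabilistic
#' sensitivity analysis (PSA) distribution family and a setter wiring
#' the value into the model definition.  PSA distributions are
#' moment-matched: the mean equals the base value and the standard
#' deviation is `(high - low) / (2 * 1.96)`, so the central 95% mass
#' approximates the one-way range.  Distribution parameters are
#' validated at construction.
#'
#' @param name Parameter label.
#' @param base,low,high Base value and one-way range (`low <= base <= high`).
#' @param dist `"gamma"` (costs), `"beta"` (utilities, probabilities,
#'   risks, disutility magnitudes), `"normal"` (body surface area) or
#'   `"fixed"` (excluded from PSA, e.g. the discount rate).
#' @param setter `function(model, value)` returning the modified model.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, base, low, high, dist, setter) {
  dist <- match.arg(dist, c("gamma", "beta", "normal", "fixed"))
  if (!(low <= base && base <= high)) {
    stop(sprintf("'%s': need low <= base <= high", name), call. = FALSE)
  }
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  par <- switch(dist,
    gamma = {
      if (base <= 0) stop(sprintf("'%s': gamma needs base > 0", name), call. = FALSE)
      if (sd == 0) list(shape = Inf, rate = Inf)
      else list(shape = (base / sd)^2, rate = base / sd^2)
    },
    beta = {
      if (base <= 0 || base >= 1) {
        stop(sprintf("'%s': beta needs base in (0, 1)", name), call. = FALSE)
      }
      if (sd == 0) list(shape1 = Inf, shape2 = Inf)
      else {
        v <- min(sd^2, base * (1 - base) * 0.999)
        nu <- base * (1 - base) / v - 1
        list(shape1 = base * nu, shape2 = (1 - base) * nu)
      }
    },
    normal = list(mean = base, sd = sd),
    fixed = list())
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, psa = par, setter = setter),
            class = "param_spec")
}

#' Draw PSA values for one parameter
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` (the base value for `"fixed"`
#'   specs or degenerate distributions).
#' @export
draw_param <- function(spec, n) {
  p <- spec$psa
  switch(spec$dist,
    fixed = rep(spec$base, n),
    gamma = if (!is.finite(p$shape)) rep(spec$base, n) else
      stats::rgamma(n, shape = p$shape, rate = p$rate),
    beta = if (!is.finite(p$shape1)) rep(spec$base, n) else
      stats::rbeta(n, shape1 = p$shape1, shape2 = p$shape2),
    normal = stats::rnorm(n, mean = p$mean, sd = p$sd))
}

#' Default sensitivity parameter set
#'
#' Builds the full list of [param_spec()]s for the packaged model:
#' monthly drug prices, per-mg prices (price levers with no base-case
#' wiring, hence zero one-way swing), administration, supportive-care,
#' hospitalization, SAE, follow-up, BSC, allo-HSCT and end-of-life
#' costs (gamma); state utilities, SAE disutility magnitudes, SAE
#' risks, the OB response rate and BSC branching probabilities (beta);
#' body surface area (normal, no base-case wiring); and the discount
#' rate (one-way range 0 to 0.08, fixed in PSA).  Survival-curve
#' parameters are fixed throughout.
#'
#' @param model A model definition supplying the base values.
#' @return Named list of `param_spec` objects.
#' @export
default_param_specs <- function(model = default_model()) {
  sp <- list()
  add <- function(name, base, low, high, dist, setter) {
    sp[[name]] <<- param_spec(name, base, low, high, dist, setter)
  }
  pm25 <- function(x) c(x * 0.75, x * 1.25)

  monthly <- model$costs$monthly
  bounds <- list(IB = c(1770.27, 2950.45), ZB = c(2205.03, 3675.05),
                 OB = c(2246.74, 3744.57), BE = c(1157.32, 1928.87),
                 RI = c(1348.11, 2246.84), LE = c(3802.42, 6337.36))
  for (drug in names(monthly)) {
    local({
      d <- drug
      add(sprintf("monthly_cost_%s", d), monthly[[d]], bounds[[d]][1],
          bounds[[d]][2], "gamma",
          function(model, v) { model$costs$monthly[[d]] <- v; model })
    })
  }
  per_mg <- model$costs$per_mg
  mg_bounds <- list(IB = c(0.15, 0.25), ZB = c(0.25, 0.41),
                    OB = c(0.53, 0.89), BE = c(6.43, 10.72),
                    RI = c(2.70, 4.49), LE = c(9.05, 15.09))
  for (drug in names(per_mg)) {
    local({
      d <- drug
      add(sprintf("per_mg_price_%s", d), per_mg[[d]], mg_bounds[[d]][1],
          mg_bounds[[d]][2], "gamma",
          function(model, v) { model$costs$per_mg[[d]] <- v; model })
    })
  }
  add("iv_infusion_fee", model$costs$iv_infusion, 0.17, 0.28, "gamma",
      function(model, v) { model$costs$iv_infusion <- v; model })
  add("drug_allocation_fee", model$costs$allocation, 0.67, 1.12, "gamma",
      function(model, v) { model$costs$allocation <- v; model })
  add("supportive_drug_cost", model$costs$supportive, 2027.38, 3378.96,
      "gamma", function(model, v) { model$costs$supportive <- v; model })
  add("hospitalization_cost", model$costs$hospitalization, 1091.21, 1818.69,
      "gamma", function(model, v) { model$costs$hospitalization <- v; model })
  sae_costs <- model$costs$sae
  for (ev in names(sae_costs)) {
    local({
      e <- ev
      add(sprintf("sae_cost_%s", e), sae_costs[[e]], 0, sae_costs[[e]],
          "gamma",
          function(model, v) { model$costs$sae[[e]] <- v; model })
    })
  }
  add("hypertension_outpatient_annual",
      model$costs$hypertension_outpatient_annual, 0, 129.48, "gamma",
      function(model, v) { model$costs$hypertension_outpatient_annual <- v; model })
  add("followup_visit_cost", model$costs$followup_visit, 36.60, 61.00,
      "gamma", function(model, v) { model$costs$followup_visit <- v; model })
  add("bsc_monthly_cost", model$costs$bsc_monthly, 224.96, 374.93, "gamma",
      function(model, v) { model$costs$bsc_monthly <- v; model })
  add("allo_hsct_cost", model$costs$allo_hsct, 44715.88, 74526.46, "gamma",
      function(model, v) { model$costs$allo_hsct <- v; model })
  add("eol_cost", model$costs$eol, 11711.66, 15682.52, "gamma",
      function(model, v) { model$costs$eol <- v; model })

  add("utility_efs_oral", model$utilities$efs_oral, 0.67, 0.75, "beta",
      function(model, v) { model$utilities$efs_oral <- v; model })
  add("utility_efs_iv", model$utilities$efs_iv, 0.63, 0.71, "beta",
      function(model, v) { model$utilities$efs_iv <- v; model })
  add("utility_pf_after_1L", model$utilities$pf_after_1L, 0.62, 0.71, "beta",
      function(model, v) { model$utilities$pf_after_1L <- v; model })
  add("utility_pf_relapsed", model$utilities$pf_relapsed, 0.37, 0.47, "beta",
      function(model, v) { model$utilities$pf_relapsed <- v; model })
  dis_bounds <- list(neutropenia = c(0.12225, 0.195),
                     thrombocytopenia = c(0.081, 0.135),
                     febrile_neutropenia = c(0.1125, 0.1875),
                     hypertension = c(0.14625, 0.195))
  for (ev in names(dis_bounds)) {
    local({
      e <- ev
      add(sprintf("disutility_%s", e), model$utilities$disutil[[e]],
          dis_bounds[[e]][1], dis_bounds[[e]][2], "beta",
          function(model, v) { model$utilities$disutil[[e]] <- v; model })
    })
  }
  risk_bounds <- list(
    BE_RI = list(neutropenia = c(0.3026, 0.5043),
                 thrombocytopenia = c(0.1108, 0.1846),
                 febrile_neutropenia = c(0.0554, 0.0924),
                 hypertension = c(0.1065, 0.1775)),
    IB = list(neutropenia = c(0.1125, 0.1875),
              thrombocytopenia = c(0.0500, 0.0834),
              febrile_neutropenia = c(0.0125, 0.0209),
              hypertension = c(0.2208, 0.3680)))
  for (arm in names(risk_bounds)) {
    for (ev in names(risk_bounds[[arm]])) {
      local({
        a <- arm; e <- ev
        add(sprintf("sae_risk_%s_%s", a, e), model$sae_risks[[a]][[e]],
            risk_bounds[[a]][[e]][1], risk_bounds[[a]][[e]][2], "beta",
            function(model, v) { model$sae_risks[[a]][[e]] <- v; model })
      })
    }
  }
  add("orr_ob", model$probs$orr_ob, 0.83, 0.96, "beta",
      function(model, v) { model$probs$orr_ob <- v; model })
  add("prob_bsc_after_1L", model$probs$bsc_after_1L, 0.11, 0.18, "beta",
      function(model, v) { model$probs$bsc_after_1L <- v; model })
  add("prob_bsc_after_2L3L", model$probs$bsc_after_2L3L, 0.14, 0.24, "beta",
      function(model, v) { model$probs$bsc_after_2L3L <- v; model })
  add("body_surface_area", model$bsa, 1.50, 1.90, "normal",
      function(model, v) { model$bsa <- v; model })
  add("discount_rate", model$discount_rate, 0, 0.08, "fixed",
      function(model, v) { model$discount_rate <- v; model })
  sp
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the base case with each parameter set to its low and
#' high bound (all others at base) and reports the resulting ICERs,
#' sorted by swing (absolute ICER difference), largest first.
#'
#' @param model A model definition.
#' @param specs List of [param_spec()]s (default [default_param_specs()]).
#' @param top Keep only the `top` largest swings (`Inf` for all).
#' @return A data.frame of class `tornado` with columns `param`,
#'   `icer_low`, `icer_high`, `swing`, plus attribute `"base_icer"`.
#' @export
one_way_dsa <- function(model, specs = default_param_specs(model),
                        top = Inf) {
  base <- run_base_case(model)
  icer_at <- function(spec, v) {
    m <- spec$setter(model, v)
    run_base_case(m)$icer
  }
  out <- data.frame(param = vapply(specs, `[[`, character(1), "name"),
                    icer_low = NA_real_, icer_high = NA_real_)
  for (i in seq_along(specs)) {
    out$icer_low[i] <- icer_at(specs[[i]], specs[[i]]$low)
    out$icer_high[i] <- icer_at(specs[[i]], specs[[i]]$high)
  }
  out$swing <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$swing), , drop = FALSE]
  if (is.finite(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` independent parameter sets (gamma for costs, beta for
#' utilities/probabilities/risks, normal for body surface area;
#' `"fixed"` specs, including survival parameters and the discount rate,
#' stay at base), evaluates both strategies per draw and records costs,
#' QALYs and increments.  Increments are oriented IB minus BE+RI, so the
#' dominant quadrant for IB is `delta_qaly > 0 & delta_cost < 0`.
#'
#' @param model A model definition.
#' @param specs List of [param_spec()]s.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; the same seed reproduces the samples
#'   bit-for-bit.
#' @return A data.frame of class `psa_samples` with columns `draw`,
#'   `cost_IB`, `qaly_IB`, `cost_BE_RI`, `qaly_BE_RI`, `delta_cost`,
#'   `delta_qaly`, plus the sampled parameter values as attribute
#'   `"draws"`.
#' @export
run_psa <- function(model, specs = default_param_specs(model),
                    n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  draws <- vapply(specs, draw_param, numeric(n_draws), n = n_draws)
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1,
                                     dimnames = list(NULL, names(specs)))
  out <- data.frame(draw = seq_len(n_draws), cost_IB = NA_real_,
                    qaly_IB = NA_real_, cost_BE_RI = NA_real_,
                    qaly_BE_RI = NA_real_)
  for (i in seq_len(n_draws)) {
    m <- model
    for (j in seq_along(specs)) {
      if (specs[[j]]$dist != "fixed") m <- specs[[j]]$setter(m, draws[i, j])
    }
    tr_ib <- run_cohort(m, "IB")
    tr_beri <- run_cohort(m, "BE_RI")
    out$cost_IB[i] <- tr_ib$total_cost
    out$qaly_IB[i] <- tr_ib$total_qaly
    out$cost_BE_RI[i] <- tr_beri$total_cost
    out$qaly_BE_RI[i] <- tr_beri$total_qaly
  }
  out$delta_cost <- out$cost_IB - out$cost_BE_RI
  out$delta_qaly <- out$qaly_IB - out$qaly_BE_RI
  attr(out, "draws") <- draws
  attr(out, "seed") <- seed
  class(out) <- c("psa_samples", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the IB strategy has positive incremental net monetary benefit.
#'
#' @param samples A [run_psa()] result.
#' @param wtp_grid Non-empty numeric grid of thresholds.
#' @return A data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 80000, by = 2000)) {
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  if (nrow(samples) == 0) stop("empty PSA sample", call. = FALSE)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Summarise a PSA run
#'
#' @param samples A [run_psa()] result.
#' @param wtp Willingness-to-pay threshold.
#' @return List with the dominant-quadrant fraction (IB cheaper and more
#'   effective), CEAC value at `wtp`, and mean costs/QALYs per arm.
#' @export
psa_summary <- function(samples, wtp = 38223.34) {
  list(
    n = nrow(samples),
    frac_dominant = mean(samples$delta_qaly > 0 & samples$delta_cost < 0),
    ceac_at_wtp = mean(wtp * samples$delta_qaly - samples$delta_cost > 0),
    mean_cost = c(IB = mean(samples$cost_IB), BE_RI = mean(samples$cost_BE_RI)),
    mean_qaly = c(IB = mean(samples$qaly_IB), BE_RI = mean(samples$qaly_BE_RI)))
}
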