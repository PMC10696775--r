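#' Per-line transition probabilities over one cycle
#'
#' Given a line's progression-free survival (PFS) and overall survival
#' (OS) curves on the line's own clock, returns the probabilities of
#' staying on the line, failing (progressing, net of death) and dying
#' during a cycle of length `delta` starting `tau` months after line
#' entry.  Death is the larger of the disease-specific OS probability
#' and the background life-table probability; failure is the PFS event
#' probability net of the OS death probability (PFS events include
#' deaths).
#'
#' @param pfs,os [surv_dist()] curves for the line.
#' @param tau Months since line entry (vectorised).
#' @param delta Cycle length in months.
#' @param bg Background mortality probability over the cycle (scalar).
#' @param orr_scale Hazard-scaling factor for the failure probability
#'   (used when a line borrows another drug's curve shape; 1 = none).
#' @return List with numeric vectors `stay`, `fail`, `die`.
#' @export
line_transition_probs <- function(pfs, os, tau, delta, bg = 0,
                                  orr_scale = 1) {
  tp_os <- transition_prob(os, tau, delta)
  tp_pfs <- transition_prob(pfs, tau, delta)
  if (orr_scale != 1) tp_pfs <- 1 - (1 - tp_pfs)^orr_scale
  if (any(!is.finite(tp_os)) || any(!is.finite(tp_pfs))) {
    stop("non-finite transition probability: PFS/OS curves inconsistent",
         call. = FALSE)
  }
  die <- pmax(tp_os, bg)
  # death takes priority over progression in the discrete step: when the
  # background floor raises deaths while the PFS event probability is near
  # one, the failure probability is capped at the residual
  fail <- pmin(pmax(0, tp_pfs - tp_os), 1 - die)
  list(stay = 1 - fail - die, fail = fail, die = die)
}

#' Run the cohort state-transition model for one strategy
#'
#' Simulates a closed cohort entering first-line treatment in the
#' event-free survival (EFS) state at time 0 through the model's cycle
#' plan (monthly cycles for 4 years, annual thereafter).  Treatment
#' failure (TF) is a transient one-cycle state; its occupants then split
#' between best supportive care (BSC) and the next treatment line.
#' Second/third-line and allo-HSCT sub-states keep their own line clocks
#' (tunnel compartments by entry cycle), so each line's survival curves
#' apply from line entry.  After allo-HSCT failure all patients enter
#' BSC.  Costs and QALYs accrue at cycle start with the cycle-start
#' discount factor (no half-cycle correction).
#'
#' @param model A validated [default_model()]-style definition.
#' @param strategy `"IB"` or `"BE_RI"`.
#' @return An object of class `cohort_trace`: list with elements
#'   `strategy`, `trace` (per-cycle data.frame with state occupancies and
#'   discounted cost/QALY increments), `total_cost`, `total_qaly` and
#'   `categories` (named cost breakdown: `drug_first_line`,
#'   `drug_subsequent`, `ae`, `other`).
#' @export
run_cohort <- function(model, strategy = c("IB", "BE_RI")) {
  strategy <- match.arg(strategy)
  model <- validate_model(model)
  plan <- build_cycle_plan(model$horizon_years)
  n_c <- nrow(plan)
  tt <- plan$start; dd <- plan$length
  disc <- discount_factor(tt, model$discount_rate)

  arm <- model$strategies[[strategy]]
  d1 <- line_dists(model, arm$lines[[1]])
  d2 <- line_dists(model, arm$lines[[2]])
  d3 <- line_dists(model, arm$lines[[3]])
  orr_scale3 <- if (isTRUE(arm$lines[[3]]$orr_scaled)) {
    model$probs$orr_ref / model$probs$orr_ob
  } else 1

  costs <- model$costs; u <- model$utilities
  risks <- model$sae_risks[[strategy]]
  lt <- model$life_table
  bg_all <- identical(model$toggles$background_scope, "all_alive")
  p_bsc1 <- model$probs$bsc_after_1L
  p_bsc23 <- model$probs$bsc_after_2L3L
  al <- model$allo

  # per-cycle, per-occupant accruals
  fl <- lapply(seq_len(n_c), function(i) {
    first_line_cost(strategy, tt[i], dd[i], costs)
  })
  fl_drug <- vapply(fl, function(x) x$drug + x$admin + x$supportive, numeric(1))
  fl_hosp <- vapply(fl, function(x) x$hosp, numeric(1))
  drug2 <- costs$monthly[[arm$lines[[2]]$drug]] * dd
  drug3 <- costs$monthly[[arm$lines[[3]]$drug]] * dd
  fu <- followup_visits(tt, dd) * costs$followup_visit
  hyp <- risks[["hypertension"]] * costs$hypertension_outpatient_annual *
    dd / 12
  bsc_cost <- costs$bsc_monthly * dd
  u_efs <- rep(if (strategy == "BE_RI") u$efs_iv else u$efs_oral,
               n_c) * dd / 12
  u_pf1 <- u$pf_after_1L * dd / 12
  u_rel <- u$pf_relapsed * dd / 12
  bg <- background_mortality(lt, model$age_entry + tt / 12, dd)

  # state occupancy at cycle start
  efs <- 1; tf1 <- tf2 <- tf3 <- tfa <- 0
  occ2 <- numeric(n_c); occ3 <- numeric(n_c); occa <- numeric(n_c)
  bsc1 <- bsc2 <- dead <- 0
  allo_new <- 0  # entrants at start of current cycle (for one-off cost)

  cat_names <- c("drug_first_line", "drug_subsequent", "ae", "other")
  categories <- stats::setNames(numeric(4), cat_names)
  trace <- data.frame(cycle = plan$cycle, start = tt, length = dd,
                      efs = 0, tf = 0, l2 = 0, l3 = 0, allo = 0, bsc = 0,
                      dead = 0, new_deaths = 0, cost = 0, qaly = 0)
  total_qaly <- 0

  for (k in seq_len(n_c)) {
    s2 <- sum(occ2); s3 <- sum(occ3); sa <- sum(occa)
    alive_pf <- s2 + s3 + sa + bsc1 + bsc2
    total <- efs + tf1 + tf2 + tf3 + tfa + alive_pf + dead
    if (abs(total - 1) > 1e-9) {
      stop(sprintf("occupancy conservation violated at cycle %d (sum = %.12f)",
                   k - 1, total), call. = FALSE)
    }
    trace$efs[k] <- efs; trace$tf[k] <- tf1 + tf2 + tf3 + tfa
    trace$l2[k] <- s2; trace$l3[k] <- s3; trace$allo[k] <- sa
    trace$bsc[k] <- bsc1 + bsc2; trace$dead[k] <- dead

    # ---- accrual at cycle start ----
    alive <- efs + tf1 + tf2 + tf3 + tfa + alive_pf
    cyc <- stats::setNames(numeric(4), cat_names)
    cyc["drug_first_line"] <- efs * fl_drug[k]
    cyc["drug_subsequent"] <- s2 * drug2[k] + s3 * drug3[k]
    cyc["ae"] <- alive * hyp[k]
    cyc["other"] <- efs * fl_hosp[k] + (efs + s2 + s3 + sa) * fu[k] +
      (bsc1 + bsc2) * bsc_cost[k] + allo_new * costs$allo_hsct
    qaly <- efs * u_efs[k] + tf1 * u_pf1[k] +
      (tf2 + tf3 + tfa + s2 + s3 + sa + bsc1 + bsc2) * u_rel[k]
    if (k == 1) {
      cyc["ae"] <- cyc["ae"] + efs * sae_expected_cost(risks, costs$sae)
      qaly <- qaly - efs * sae_expected_disutility(risks, u$disutil) / 12
    }

    # ---- transitions over cycle k ----
    new_deaths <- 0

    # first line (line clock == model clock); negligible occupancies are
    # not stepped so that fully depleted curves cannot trip S(t) = 0
    if (efs > 1e-16) {
      p1 <- line_transition_probs(d1$pfs, d1$os, tt[k], dd[k],
                                  bg = if (bg_all) bg[k] else 0)
      new_tf1 <- efs * p1$fail
      new_deaths <- new_deaths + efs * p1$die
      efs_next <- efs * p1$stay
    } else {
      new_tf1 <- 0
      efs_next <- efs
    }

    # subsequent lines on their own clocks
    step_line <- function(occ, dists, orr_scale = 1) {
      act <- which(occ > 1e-16)
      out <- list(occ = occ, fail = 0, die = 0)
      if (length(act)) {
        tau <- tt[k] - tt[act]
        p <- line_transition_probs(dists$pfs, dists$os, tau, dd[k],
                                   bg = bg[k], orr_scale = orr_scale)
        out$fail <- sum(occ[act] * p$fail)
        out$die <- sum(occ[act] * p$die)
        out$occ[act] <- occ[act] * p$stay
      }
      out
    }
    r2 <- step_line(occ2, d2)
    r3 <- step_line(occ3, d3, orr_scale3)
    occ2 <- r2$occ; occ3 <- r3$occ
    new_tf2 <- r2$fail; new_tf3 <- r3$fail
    new_deaths <- new_deaths + r2$die + r3$die

    # allo-HSCT: piecewise-constant monthly relapse / non-relapse mortality
    new_tfa <- 0
    act <- which(occa > 1e-16)
    if (length(act)) {
      tau <- tt[k] - tt[act]
      early <- tau < al$early_months
      m_nrm <- ifelse(early, al$nrm_monthly_early, al$nrm_monthly_late)
      m_rel <- ifelse(early, al$relapse_monthly_early, al$relapse_monthly_late)
      p_die <- pmax(1 - (1 - m_nrm)^dd[k], bg[k])
      p_rel <- 1 - (1 - m_rel)^dd[k]
      tot <- p_die + p_rel
      over <- tot > 1
      if (any(over)) { p_die[over] <- p_die[over] / tot[over]
                       p_rel[over] <- p_rel[over] / tot[over] }
      new_tfa <- sum(occa[act] * p_rel)
      new_deaths <- new_deaths + sum(occa[act] * p_die)
      occa[act] <- occa[act] * (1 - p_die - p_rel)
    }

    # BSC exits only to death (background mortality)
    new_deaths <- new_deaths + (bsc1 + bsc2) * bg[k]
    bsc1 <- bsc1 * (1 - bg[k]); bsc2 <- bsc2 * (1 - bg[k])

    # TF occupants move on to BSC or the next line / allo-HSCT
    allo_new <- tf3 * (1 - p_bsc23)
    bsc1 <- bsc1 + tf1 * p_bsc1
    bsc2 <- bsc2 + tf2 * p_bsc23 + tf3 * p_bsc23 + tfa
    if (k < n_c) {
      occ2[k + 1] <- occ2[k + 1] + tf1 * (1 - p_bsc1)
      occ3[k + 1] <- occ3[k + 1] + tf2 * (1 - p_bsc23)
      occa[k + 1] <- occa[k + 1] + allo_new
    } else {
      # horizon ends; keep conservation by leaving them in their new state
      occ2[n_c] <- occ2[n_c] + tf1 * (1 - p_bsc1)
      occ3[n_c] <- occ3[n_c] + tf2 * (1 - p_bsc23)
      occa[n_c] <- occa[n_c] + allo_new
    }
    tf1 <- new_tf1; tf2 <- new_tf2; tf3 <- new_tf3; tfa <- new_tfa
    efs <- efs_next
    dead <- dead + new_deaths

    cyc["other"] <- cyc["other"] + new_deaths * costs$eol
    categories <- categories + cyc * disc[k]
    trace$new_deaths[k] <- new_deaths
    trace$cost[k] <- sum(cyc) * disc[k]
    trace$qaly[k] <- qaly * disc[k]
    total_qaly <- total_qaly + qaly * disc[k]
  }

  structure(list(strategy = strategy, trace = trace,
                 total_cost = sum(categories),
                 total_qaly = total_qaly,
                 categories = categories),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> strategy %s: %d cycles\n", x$strategy,
              nrow(x$trace)))
  cat(sprintf("  discounted total cost: $%s\n",
              format(round(x$total_cost, 2), big.mark = ",", nsmall = 2)))
  cat(sprintf("  discounted total QALYs: %.4f\n", x$total_qaly))
  cat("  cost categories:\n")
  for (nm in names(x$categories)) {
    cat(sprintf("    %-16s $%s\n", nm,
                format(round(x$categories[[nm]], 2), big.mark = ",",
                       nsmall = 2)))
  }
  invisible(x)
}

#' Base-case cost-effectiveness comparison of both strategies
#'
#' Runs [run_cohort()] for both arms and computes incremental results
#' with the BE+RI arm compared against the IB arm (so that a dominant IB
#' arm yields a negative incremental cost-effectiveness ratio).
#'
#' @param model A model definition.
#' @return A `ce_result` (see [compute_icer()]) with the per-arm traces
#'   attached as attribute `"traces"`.
#' @export
run_base_case <- function(model) {
  tr_ib <- run_cohort(model, "IB")
  tr_beri <- run_cohort(model, "BE_RI")
  res <- compute_icer(cost_a = tr_beri$total_cost, qaly_a = tr_beri$total_qaly,
                      cost_b = tr_ib$total_cost, qaly_b = tr_ib$total_qaly,
                      label_a = "BE_RI", label_b = "IB", wtp = model$wtp)
  attr(res, "traces") <- list(IB = tr_ib, BE_RI = tr_beri)
  res
}
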