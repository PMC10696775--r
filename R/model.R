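#' Default model definition
#'
#' Builds the complete machine-readable model definition for the
#' comparison of first-line ibrutinib (IB) against bendamustine plus
#' rituximab (BE+RI) with lenalidomide (LE) maintenance in older,
#' previously untreated CLL patients: treatment-line sequences, fitted
#' parametric survival distributions per line, unit costs (2022 USD),
#' utilities and severe-adverse-event (SAE) inputs, best-supportive-care
#' (BSC) branching probabilities, discounting, horizon and background
#' mortality.
#'
#' Treatment pathways: the IB arm sequences IB, zanubrutinib (ZB),
#' orelabrutinib (OB), then allogeneic stem-cell transplantation
#' (allo-HSCT) and BSC; the BE+RI arm sequences BE+RI (6 intravenous
#' cycles, then LE maintenance), IB, ZB, allo-HSCT, BSC.  OB has no
#' published survival curves, so its time-to-event borrows the ZB shape
#' with the OB objective response rate acting as a hazard-scaling lever
#' (scale = `orr_ref / orr_ob`, 1 at base case).
#'
#' The second/third-line ZB overall-survival row is a lognormal with
#' `meanlog = 1.59`, `sdlog = 164.93`, reproduced exactly as published
#' even though the enormous `sdlog` yields a near-degenerate curve
#' (about half the line's entrants die within the first month, after
#' which the curve is almost flat).  Supply
#' `toggles$zb_os_override` (a [surv_dist()]) to replace it.
#'
#' @param horizon_years Model horizon in whole years (default 10).
#' @param discount_rate Annual discount rate (default 0.05).
#' @param life_table A [life_table()]; defaults to the packaged synthetic
#'   aging schedule from [make_life_table()].
#' @return A list of class `ce_model`; see the package vignette for the
#'   full field reference.
#' @export
default_model <- function(horizon_years = 10, discount_rate = 0.05,
                          life_table = make_life_table("aging")) {
  model <- list(
    strategies = list(
      IB = list(
        label = "First-line ibrutinib",
        first_line_route = "oral",
        lines = list(
          list(name = "IB_1L", drug = "IB", pfs = "ib1_pfs", os = "ib1_os"),
          list(name = "ZB_2L", drug = "ZB", pfs = "zb_pfs", os = "zb_os"),
          list(name = "OB_3L", drug = "OB", pfs = "zb_pfs", os = "zb_os",
               orr_scaled = TRUE))),
      BE_RI = list(
        label = "First-line bendamustine plus rituximab",
        first_line_route = "iv",
        lines = list(
          list(name = "BERI_1L", drug = "BE_RI_LE", pfs = "beri1_pfs",
               os = "beri1_os"),
          list(name = "IB_2L", drug = "IB", pfs = "ib2_pfs", os = "ib2_os"),
          list(name = "ZB_3L", drug = "ZB", pfs = "zb_pfs", os = "zb_os")))),
    dists = list(
      ib1_pfs   = surv_dist("exponential", rate = 0.00592451),
      ib1_os    = surv_dist("exponential", rate = 0.00368296),
      beri1_pfs = surv_dist("gompertz", shape = 0.02325928, rate = 0.00943535),
      beri1_os  = surv_dist("exponential", rate = 0.00332761),
      ib2_pfs   = surv_dist("gamma", shape = 1.1802239, rate = 0.0191373),
      ib2_os    = surv_dist("exponential", rate = 0.00100394),
      zb_pfs    = surv_dist("gompertz", shape = 0.0341335, rate = 0.00268049),
      zb_os     = surv_dist("lognormal", meanlog = 1.59, sdlog = 164.93)),
    probs = list(bsc_after_1L = 0.15, bsc_after_2L3L = 0.19,
                 orr_ob = 0.91, orr_ref = 0.91),
    costs = list(
      monthly = c(IB = 2360.36, ZB = 2940.04, OB = 2995.66, BE = 1543.10,
                  RI = 1797.48, LE = 5069.89),
      per_mg = c(IB = 0.20, ZB = 0.33, OB = 0.71, BE = 8.57, RI = 3.59,
                 LE = 12.07),
      iv_infusion = 0.22, allocation = 0.90,
      supportive = 2703.17, hospitalization = 1454.95,
      sae = c(neutropenia = 815.10, thrombocytopenia = 605.63,
              febrile_neutropenia = 4516.31, hypertension = 968.52),
      hypertension_outpatient_annual = 129.48,
      followup_visit = 48.80, bsc_monthly = 299.95,
      allo_hsct = 59621.17, eol = 12455.19),
    utilities = list(
      efs_oral = 0.71, efs_iv = 0.67, pf_after_1L = 0.66,
      pf_relapsed = 0.42, death = 0,
      disutil = c(neutropenia = 0.163, thrombocytopenia = 0.108,
                  febrile_neutropenia = 0.15, hypertension = 0.195)),
    sae_risks = list(
      BE_RI = c(neutropenia = 0.4034, thrombocytopenia = 0.1477,
                febrile_neutropenia = 0.0739, hypertension = 0.1420),
      IB = c(neutropenia = 0.1500, thrombocytopenia = 0.0667,
             febrile_neutropenia = 0.0167, hypertension = 0.2944)),
    bsa = 1.72,
    discount_rate = discount_rate,
    wtp = 38223.34,
    horizon_years = horizon_years,
    age_entry = 70,
    life_table = life_table,
    allo = list(nrm_monthly_early = 0.012, nrm_monthly_late = 0.002,
                relapse_monthly_early = 0.015, relapse_monthly_late = 0.004,
                early_months = 24),
    toggles = list(background_scope = "pf_only", half_cycle = FALSE,
                   zb_os_override = NULL, psa_cost_dist = "gamma"))
  validate_model(model)
}

#' Validate a model definition
#'
#' Checks probability/utility ranges, non-negative costs, distribution
#' references and the cycle plan before any computation.
#'
#' @param model A model definition list.
#' @return The validated model, classed `ce_model`.
#' @export
validate_model <- function(model) {
  stopifnot(is.list(model))
  req <- c("strategies", "dists", "probs", "costs", "utilities", "sae_risks",
           "discount_rate", "wtp", "horizon_years", "age_entry", "life_table",
           "allo", "toggles")
  miss <- setdiff(req, names(model))
  if (length(miss)) stop("model definition missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pr <- unlist(model$probs)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  ut <- unlist(model$utilities[c("efs_oral", "efs_iv", "pf_after_1L",
                                 "pf_relapsed", "death")])
  if (any(ut < 0 | ut > 1)) stop("state utilities must lie in [0, 1]", call. = FALSE)
  if (any(unlist(model$utilities$disutil) < 0)) {
    stop("disutilities must be stored as non-negative decrements", call. = FALSE)
  }
  cs <- unlist(model$costs[setdiff(names(model$costs), "per_mg")])
  if (any(cs < 0)) stop("costs must be >= 0", call. = FALSE)
  if (any(unlist(model$sae_risks) < 0 | unlist(model$sae_risks) > 1)) {
    stop("SAE risks must lie in [0, 1]", call. = FALSE)
  }
  if (model$discount_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (model$horizon_years < 5) stop("horizon must be >= 5 years", call. = FALSE)
  for (s in model$strategies) {
    for (ln in s$lines) {
      for (d in c(ln$pfs, ln$os)) {
        if (is.null(model$dists[[d]])) {
          stop(sprintf("line '%s' references unknown distribution '%s'",
                       ln$name, d), call. = FALSE)
        }
      }
    }
  }
  if (!inherits(model$life_table, "life_table")) {
    model$life_table <- life_table(model$life_table$age, model$life_table$qx)
  }
  if (!model$toggles$background_scope %in% c("pf_only", "all_alive")) {
    stop("background_scope must be 'pf_only' or 'all_alive'", call. = FALSE)
  }
  class(model) <- c("ce_model", "list")
  model
}

#' Resolve a line's survival distributions (with toggles applied)
#' @keywords internal
line_dists <- function(model, line) {
  pfs <- model$dists[[line$pfs]]
  os <- model$dists[[line$os]]
  if (!is.null(model$toggles$zb_os_override) && identical(line$os, "zb_os")) {
    os <- model$toggles$zb_os_override
  }
  list(pfs = pfs, os = os)
}

#' Write / read a model definition as JSON
#'
#' The config round-trips all scalar inputs, survival distributions
#' (`{family, params}` entries), the life table and toggles.
#'
#' @param model A `ce_model`.
#' @param path Output path.
#' @return `read_model_config()` returns the validated model;
#'   `write_model_config()` returns `invisible(path)`.
#' @export
write_model_config <- function(model, path) {
  x <- unclass(model)
  x$dists <- lapply(x$dists, function(d) list(family = d$family,
                                              params = d$params))
  # named vectors must become JSON objects, not bare arrays
  x$costs$monthly <- as.list(x$costs$monthly)
  x$costs$per_mg <- as.list(x$costs$per_mg)
  x$costs$sae <- as.list(x$costs$sae)
  x$utilities$disutil <- as.list(x$utilities$disutil)
  x$sae_risks <- lapply(x$sae_risks, as.list)
  zo <- x$toggles$zb_os_override
  if (!is.null(zo)) {
    x$toggles$zb_os_override <- list(family = zo$family, params = zo$params)
  }
  x$life_table <- as.data.frame(unclass(x$life_table))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$dists <- lapply(x$dists, function(d) {
    do.call(surv_dist, c(list(d$family), as.list(d$params)))
  })
  zo <- x$toggles$zb_os_override
  x$toggles$zb_os_override <- if (is.null(zo)) NULL else {
    do.call(surv_dist, c(list(zo$family), as.list(zo$params)))
  }
  x$life_table <- life_table(x$life_table$age, x$life_table$qx)
  x$costs$monthly <- unlist(x$costs$monthly)
  x$costs$per_mg <- unlist(x$costs$per_mg)
  x$costs$sae <- unlist(x$costs$sae)
  x$utilities$disutil <- unlist(x$utilities$disutil)
  x$sae_risks <- lapply(x$sae_risks, unlist)
  # json simplification turns line lists into data.frames; restore lists
  x$strategies <- lapply(x$strategies, function(s) {
    if (is.data.frame(s$lines)) {
      s$lines <- lapply(seq_len(nrow(s$lines)), function(i) {
        ln <- as.list(s$lines[i, ])
        if (!is.null(ln$orr_scaled) && is.na(ln$orr_scaled)) ln$orr_scaled <- NULL
        ln
      })
    }
    s
  })
  validate_model(x)
}
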