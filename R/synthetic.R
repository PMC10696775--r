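#' Simulate a right-censored survival cohort
#'
#' Event times are drawn from a true event-time distribution and
#' censoring times from an optional censoring distribution (plus an
#' administrative cut-off); the observed time is the minimum with the
#' corresponding event flag.  Used to exercise pseudo-IPD
#' reconstruction, fitting and the end-to-end recovery checks without
#' any external data.
#'
#' @param n Number of subjects (> 0).
#' @param event_dist A [surv_dist()] for the true event times.
#' @param censor_dist Optional [surv_dist()] for random censoring.
#' @param admin_censor Administrative censoring time in months
#'   (default `Inf`).
#' @param seed Integer seed recorded in the output's attributes.
#' @return A data.frame with columns `time`, `event`; attributes `seed`
#'   and `spec`.
#' @export
simulate_cohort <- function(n, event_dist, censor_dist = NULL,
                            admin_censor = Inf, seed = 1) {
  stopifnot(n > 0)
  set.seed(seed)
  te <- surv_rand(event_dist, n)
  tc <- if (!is.null(censor_dist)) surv_rand(censor_dist, n) else rep(Inf, n)
  tc <- pmin(tc, admin_censor)
  time <- pmin(te, tc)
  if (any(time <= 0)) time <- pmax(time, 1e-9)
  out <- data.frame(time = time, event = as.integer(te <= tc))
  attr(out, "seed") <- seed
  attr(out, "spec") <- list(n = n, event_dist = event_dist,
                            censor_dist = censor_dist,
                            admin_censor = admin_censor)
  out
}

#' Emulate digitization of a KM curve with its risk table
#'
#' Evaluates the cohort's product-limit estimate on a reporting grid
#' (default every 3 months, mimicking trial reporting cadence) together
#' with the exact numbers at risk, optionally perturbing the survival
#' coordinates by bounded jitter to emulate digitization error.
#'
#' @param ipd Data.frame with `time`, `event`.
#' @param grid_times Increasing grid of reporting times starting at 0.
#' @param jitter Maximum absolute perturbation of survival coordinates
#'   (uniform, clamped so the curve stays monotone in `[0, 1]`).
#' @param seed Seed for the jitter.
#' @return List with elements `curve` (a [digitized_curve()]) and `risk`
#'   (a [risk_table()]).
#' @export
digitize <- function(ipd, grid_times = seq(0, 48, by = 3), jitter = 0,
                     seed = 1) {
  ipd <- validate_ipd(ipd)
  if (any(diff(grid_times) <= 0)) stop("grid must be increasing", call. = FALSE)
  max_fu <- max(ipd$time)
  if (max(grid_times) > max_fu) {
    warning("grid extends beyond follow-up; truncating")
    grid_times <- grid_times[grid_times <= max_fu]
  }
  km <- km_estimate(ipd)
  s <- km_at(km, grid_times)
  if (jitter > 0) {
    set.seed(seed)
    s <- s + stats::runif(length(s), -jitter, jitter)
    s[1] <- 1
    s <- cummin(pmin(1, pmax(0, s)))
  }
  n_at <- vapply(grid_times, function(g) sum(ipd$time >= g), numeric(1))
  list(curve = digitized_curve(grid_times, s),
       risk = risk_table(grid_times, n_at))
}
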