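#' Parametric survival distributions
#'
#' A `surv_dist` bundles a distribution family with its parameters on a
#' monthly time axis.  Six standard families used for survival
#' extrapolation in decision models are supported, with the following
#' parameterizations of the survivor function \eqn{S(t)}:
#'
#' * `exponential` (`rate`): \eqn{S(t) = e^{-rate \cdot t}}
#' * `weibull` (`shape`, `rate`): \eqn{S(t) = e^{-(rate \cdot t)^{shape}}}
#' * `gompertz` (`shape`, `rate`):
#'   \eqn{S(t) = \exp\{-(rate/shape)(e^{shape \cdot t} - 1)\}}
#'   (the `flexsurv` convention; `shape` may be negative, giving a
#'   decreasing hazard)
#' * `gamma` (`shape`, `rate`): shape/rate gamma on time
#' * `lognormal` (`meanlog`, `sdlog`): normal on log-time
#' * `loglogistic` (`shape`, `scale`): \eqn{S(t) = 1/(1 + (t/scale)^{shape})}
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"gamma"`, `"lognormal"`, `"loglogistic"`.
#' @param ... Named numeric parameters for the family (see above).
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("exponential", rate = 0.00592451)
#' survival_at(d, c(0, 12, 24))
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, surv_families())
  params <- list(...)
  if (length(params) == 1L && is.list(params[[1]]) && is.null(names(params))) {
    params <- params[[1]]
  }
  params <- lapply(params, as.numeric)
  need <- surv_family_params(family)
  if (!setequal(names(params), need)) {
    stop(sprintf("family '%s' requires parameters: %s (got: %s)",
                 family, paste(need, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- params[need]
  bad <- vapply(params, function(p) !is.finite(p), logical(1))
  if (any(bad)) stop("non-finite distribution parameter", call. = FALSE)
  # strictly positive where the family requires it (gompertz shape is free)
  pos <- setdiff(need, if (family == "gompertz") "shape" else character())
  if (family == "lognormal") pos <- "sdlog"
  for (p in pos) {
    if (params[[p]] <= 0) {
      stop(sprintf("parameter '%s' of family '%s' must be > 0", p, family),
           call. = FALSE)
    }
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("<surv_dist> %s(%s)  [time in months]\n", x$family,
              paste(sprintf("%s = %g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

#' Supported survival families
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "gamma", "lognormal", "loglogistic")
}

surv_family_params <- function(family) {
  switch(family,
         exponential = "rate",
         weibull     = c("shape", "rate"),
         gompertz    = c("shape", "rate"),
         gamma       = c("shape", "rate"),
         lognormal   = c("meanlog", "sdlog"),
         loglogistic = c("shape", "scale"))
}

#' Survivor function of a parametric distribution
#'
#' @param dist A [surv_dist()].
#' @param t Vector of non-negative times in months.
#' @return \eqn{S(t)}, same length as `t`.
#' @export
survival_at <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- dist$params
  switch(dist$family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p$shape, scale = 1 / p$rate,
                                  lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate,
                                      lower.tail = FALSE),
    gamma       = stats::pgamma(t, shape = p$shape, rate = p$rate,
                                lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale,
                                    lower.tail = FALSE))
}

#' Log-density of a parametric survival distribution
#' @inheritParams survival_at
#' @return \eqn{\log f(t)}.
#' @keywords internal
surv_logdens <- function(dist, t) {
  p <- dist$params
  switch(dist$family,
    exponential = stats::dexp(t, rate = p$rate, log = TRUE),
    weibull     = stats::dweibull(t, shape = p$shape, scale = 1 / p$rate,
                                  log = TRUE),
    gompertz    = flexsurv::dgompertz(t, shape = p$shape, rate = p$rate,
                                      log = TRUE),
    gamma       = stats::dgamma(t, shape = p$shape, rate = p$rate, log = TRUE),
    lognormal   = stats::dlnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                log = TRUE),
    loglogistic = flexsurv::dllogis(t, shape = p$shape, scale = p$scale,
                                    log = TRUE))
}

#' Random event times from a parametric survival distribution
#' @param dist A [surv_dist()].
#' @param n Number of draws.
#' @return Vector of `n` event times in months.
#' @export
surv_rand <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    exponential = stats::rexp(n, rate = p$rate),
    weibull     = stats::rweibull(n, shape = p$shape, scale = 1 / p$rate),
    gompertz    = flexsurv::rgompertz(n, shape = p$shape, rate = p$rate),
    gamma       = stats::rgamma(n, shape = p$shape, rate = p$rate),
    lognormal   = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    loglogistic = flexsurv::rllogis(n, shape = p$shape, scale = p$scale))
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability that the event occurs in \eqn{(t, t + \delta]} conditional on
#' being event-free at \eqn{t}: \eqn{1 - S(t+\delta)/S(t)}.
#'
#' @param dist A [surv_dist()].
#' @param t Time at the start of the cycle (months), vectorised.
#' @param delta Cycle length in months (> 0).
#' @return Conditional event probability in `[0, 1]`.
#' @examples
#' transition_prob(surv_dist("exponential", rate = 0.00592451), 0, 1)
#' @export
transition_prob <- function(dist, t, delta) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(delta <= 0)) stop("delta must be > 0", call. = FALSE)
  s0 <- survival_at(dist, t)
  if (any(s0 == 0)) {
    stop("S(t) = 0: transition probability undefined on degenerate support",
         call. = FALSE)
  }
  pmin(1, pmax(0, 1 - survival_at(dist, t + delta) / s0))
}

#' Export a survival curve on a time grid
#'
#' @param dist A [surv_dist()].
#' @param times Time grid in months.
#' @return A data.frame with columns `t` and `S`.
#' @export
survival_curve <- function(dist, times = 0:120) {
  data.frame(t = times, S = survival_at(dist, times))
}
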