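#' Fit a parametric survival model to (pseudo) individual patient data
#'
#' Maximises the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)} for one of
#' the six supported families.  Fitting is delegated to
#' [flexsurv::flexsurvreg()]; fitted parameters are mapped back to the
#' package's parameterizations (see [surv_dist()]).
#'
#' @param ipd A data.frame with columns `time` (months, > 0) and `event`
#'   (1 = event, 0 = censored), e.g. from [reconstruct_ipd()] or
#'   [simulate_cohort()].
#' @param family A family name from [surv_families()].
#' @return An object of class `surv_fit`: list with elements
#'   `distribution` ([surv_dist()]), `loglik`, `aic`, `bic`, `n`,
#'   `n_events` and `family`.  AIC is \eqn{-2\ell + 2k} and BIC
#'   \eqn{-2\ell + k\log n} with `k` free parameters and `n` subjects.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  ipd <- validate_ipd(ipd)
  n_events <- sum(ipd$event)
  if (n_events < 2L) {
    stop("need at least 2 events to identify a survival model", call. = FALSE)
  }
  dist_fs <- switch(family,
                    exponential = "exp", weibull = "weibull",
                    gompertz = "gompertz", gamma = "gamma",
                    lognormal = "lnorm", loglogistic = "llogis")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = dist_fs),
    error = function(e) {
      stop(sprintf("fit of family '%s' failed to converge: %s",
                   family, conditionMessage(e)), call. = FALSE)
    })
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  params <- switch(family,
    exponential = list(rate = unname(est["rate"])),
    weibull     = list(shape = unname(est["shape"]),
                       rate  = 1 / unname(est["scale"])),
    gompertz    = list(shape = unname(est["shape"]),
                       rate  = unname(est["rate"])),
    gamma       = list(shape = unname(est["shape"]),
                       rate  = unname(est["rate"])),
    lognormal   = list(meanlog = unname(est["meanlog"]),
                       sdlog   = unname(est["sdlog"])),
    loglogistic = list(shape = unname(est["shape"]),
                       scale = unname(est["scale"])))
  k <- fit$npars
  n <- nrow(ipd)
  ll <- fit$loglik
  structure(list(distribution = do.call(surv_dist, c(list(family), params)),
                 family = family, loglik = ll,
                 aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(n),
                 k = k, n = n, n_events = n_events),
            class = "surv_fit")
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s: loglik = %.3f, AIC = %.3f, BIC = %.3f (n = %d, events = %d)\n",
              x$family, x$loglik, x$aic, x$bic, x$n, x$n_events))
  print(x$distribution)
  invisible(x)
}

#' Fit all six parametric families
#'
#' @inheritParams fit_parametric
#' @param families Families to fit (default all six).
#' @return A named list of `surv_fit` objects.  Families whose optimiser
#'   fails are dropped with a warning.
#' @export
fit_all_families <- function(ipd, families = surv_families()) {
  fits <- list()
  for (f in families) {
    res <- tryCatch(fit_parametric(ipd, f), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("family '%s' not fitted: %s", f,
                      conditionMessage(res)), call. = FALSE)
    } else {
      fits[[f]] <- res
    }
  }
  fits
}

#' Select the best fit by information criterion
#'
#' Ties (differences below `1e-9`) are broken by fewer free parameters,
#' then by family-name order.
#'
#' @param fits A non-empty list of `surv_fit` objects.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `surv_fit`.
#' @export
select_best <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0L) stop("empty fit list", call. = FALSE)
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  fam <- vapply(fits, function(f) f$family, character(1))
  ord <- order(round(crit / 1e-9) * 1e-9, k, fam)
  fits[[ord[1L]]]
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop("ipd must be a data.frame with columns 'time' and 'event'",
         call. = FALSE)
  }
  if (nrow(ipd) == 0L) stop("ipd is empty", call. = FALSE)
  ipd$time <- as.numeric(ipd$time)
  ipd$event <- as.integer(ipd$event)
  if (any(!is.finite(ipd$time)) || any(ipd$time <= 0)) {
    stop("ipd times must be finite and > 0", call. = FALSE)
  }
  if (!all(ipd$event %in% c(0L, 1L))) {
    stop("ipd event flags must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  ipd[c("time", "event")]
}
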