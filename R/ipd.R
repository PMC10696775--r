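#' Digitized Kaplan-Meier curve
#'
#' Ordered coordinates read off a published KM figure.  Times must be
#' strictly increasing, survival non-increasing and within `[0, 1]`, and
#' the curve is expected to start at (or very near) \eqn{(0, 1)}.
#'
#' @param time Times in months.
#' @param survival Survival probabilities at `time`.
#' @return A data.frame of class `digitized_curve` with columns `time`,
#'   `survival`.
#' @export
digitized_curve <- function(time, survival) {
  time <- as.numeric(time); survival <- as.numeric(survival)
  if (length(time) != length(survival) || length(time) < 2L) {
    stop("need matching time/survival vectors of length >= 2", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("digitized times must be strictly increasing", call. = FALSE)
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]", call. = FALSE)
  if (any(diff(survival) > 1e-8)) stop("digitized survival must be non-increasing", call. = FALSE)
  if (time[1] > 1e-6 || survival[1] < 1 - 1e-6) {
    stop("digitized curve must start at (0, 1)", call. = FALSE)
  }
  survival <- cummin(survival)  # clear tiny digitization noise
  structure(data.frame(time = time, survival = survival),
            class = c("digitized_curve", "data.frame"))
}

#' Number-at-risk table
#'
#' @param time Reporting times in months (increasing, first usually 0).
#' @param n_at_risk Non-negative, non-increasing integer counts.
#' @return A data.frame of class `risk_table` with columns `time`, `n_at_risk`.
#' @export
risk_table <- function(time, n_at_risk) {
  time <- as.numeric(time); n_at_risk <- as.integer(round(n_at_risk))
  if (length(time) != length(n_at_risk) || length(time) < 2L) {
    stop("risk table needs >= 2 (time, n) entries", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("risk-table times must be strictly increasing", call. = FALSE)
  if (any(n_at_risk < 0)) stop("n_at_risk must be >= 0", call. = FALSE)
  if (any(diff(n_at_risk) > 0)) stop("n_at_risk must be non-increasing", call. = FALSE)
  structure(data.frame(time = time, n_at_risk = n_at_risk),
            class = c("risk_table", "data.frame"))
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Implements the interval balancing equations of the Guyot-style
#' reconstruction algorithm in its risk-table-only variant (total event
#' counts unreported, as in the source trials).  Within each interval
#' between consecutive number-at-risk times the algorithm finds an integer
#' number of censorings (spread uniformly over the interval) such that,
#' after allocating events to each digitized survival drop via the running
#' product-limit identity \eqn{d_k = n_k (1 - S_k / S_{last})}, the risk
#' set remaining at the end of the interval matches the published count.
#' Fractional event counts are rounded by largest remainder within the
#' interval, preserving the interval total.  After the last risk-table
#' time, events are read from the remaining survival drops and all
#' remaining subjects are censored at the end of follow-up.
#'
#' @param curve A [digitized_curve()] spanning the risk-table time range.
#' @param risk A [risk_table()] with at least 2 entries.
#' @param total_events Optional total number of events over follow-up.
#'   When supplied, event counts in the tail interval (after the last
#'   risk-table time) are rescaled so the overall total matches.
#' @return A data.frame with columns `time` (months) and `event`
#'   (1 = event, 0 = censored); one row per reconstructed subject, in
#'   total the initial number at risk.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  if (!inherits(curve, "digitized_curve")) curve <- digitized_curve(curve$time, curve$survival)
  if (!inherits(risk, "risk_table")) risk <- risk_table(risk$time, risk$n_at_risk)
  if (max(curve$time) < max(risk$time) - 1e-8) {
    stop("digitized curve must span the risk-table time range", call. = FALSE)
  }

  tk <- curve$time; Sk <- curve$survival
  K <- length(tk)
  tr <- risk$time; nr <- risk$n_at_risk
  I <- length(tr)

  ev_time <- numeric(0); ev_n <- integer(0)     # event allocations
  cs_time <- numeric(0); cs_n <- integer(0)     # censoring allocations

  n_cur <- nr[1]
  S_run <- 1          # product-limit estimate of reconstructed data
  S_last <- 1         # value of digitized curve at last allocated event

  # indices of digitized points inside interval i: (tr[i], tr[i+1]]
  for (i in seq_len(I)) {
    lo <- tr[i]
    hi <- if (i < I) tr[i + 1] else max(tk) + 1e-9
    idx <- which(tk > lo + 1e-12 & tk <= hi + 1e-12)
    target <- if (i < I) nr[i + 1] else NA_integer_

    alloc <- function(n_cens) {
      # spread censorings uniformly, interleave with event allocation
      ct <- if (n_cens > 0) lo + (seq_len(n_cens) - 0.5) / n_cens * (hi - lo) else numeric(0)
      n <- n_cur; Sl <- S_last; Sr <- S_run
      d_real <- numeric(length(idx)); n_at <- numeric(length(idx))
      used_c <- 0
      prev_t <- lo
      for (j in seq_along(idx)) {
        k <- idx[j]
        # censorings occurring before this digitized time leave the risk set
        nc <- sum(ct > prev_t & ct <= tk[k]); used_c <- used_c + nc
        n <- n - nc
        n_at[j] <- n
        if (n > 0 && Sl > 0) {
          d <- n * (1 - Sk[k] / Sl)
          d <- min(max(d, 0), n)
        } else d <- 0
        d_real[j] <- d
        if (d > 0) Sl <- Sk[k]
        n <- n - d
        prev_t <- tk[k]
      }
      n <- n - (n_cens - used_c)  # censorings after the last digitized point
      list(d_real = d_real, n_at = n_at, n_end = n)
    }

    if (i < I) {
      # solve for integer censorings matching the published end-of-interval n
      n_cens <- 0
      best <- NULL; best_gap <- Inf
      for (iter in 1:50) {
        n_cens <- max(0L, min(n_cur, as.integer(n_cens)))
        res <- alloc(n_cens)
        d_int <- largest_remainder_round(res$d_real)
        n_end <- n_cur - n_cens - sum(d_int)
        gap <- n_end - target
        if (abs(gap) < abs(best_gap)) {
          best <- list(n_cens = n_cens, d_int = d_int); best_gap <- gap
        }
        if (gap == 0) break
        n_cens <- n_cens + gap
      }
      n_cens <- best$n_cens; d_int <- best$d_int
      if (best_gap != 0) {
        # absorb any residual into censoring at end of interval
        n_cens <- max(0L, n_cens + best_gap)
        d_int <- best$d_int
      }
    } else {
      res <- alloc(0L)
      d_int <- largest_remainder_round(res$d_real)
      if (!is.null(total_events)) {
        done <- sum(ev_n)
        tail_target <- max(0L, as.integer(total_events) - done)
        if (sum(d_int) > 0 && tail_target != sum(d_int)) {
          d_int <- largest_remainder_round(res$d_real * tail_target / sum(d_int))
        }
      }
      d_int <- pmin(d_int, n_cur)   # safety
      n_cens <- n_cur - sum(d_int)  # censor all survivors at end of follow-up
    }

    # commit allocations; recompute running KM with integer counts
    ct <- if (i < I && n_cens > 0) {
      lo + (seq_len(n_cens) - 0.5) / n_cens * (hi - lo)
    } else numeric(0)
    n <- n_cur; prev_t <- lo; used_c <- 0
    for (j in seq_along(idx)) {
      k <- idx[j]
      nc <- sum(ct > prev_t & ct <= tk[k])
      if (nc > 0) { cs_time <- c(cs_time, ct[ct > prev_t & ct <= tk[k]]); cs_n <- c(cs_n, rep(1L, nc)) }
      used_c <- used_c + nc; n <- n - nc
      d <- min(d_int[j], n)
      if (d > 0) {
        ev_time <- c(ev_time, tk[k]); ev_n <- c(ev_n, d)
        S_run <- S_run * (1 - d / n)
        S_last <- Sk[k]
        n <- n - d
      }
      prev_t <- tk[k]
    }
    if (i < I) {
      rest <- n_cens - used_c
      if (rest > 0) { cs_time <- c(cs_time, ct[ct > prev_t]); cs_n <- c(cs_n, rep(1L, length(ct[ct > prev_t]))) }
      n <- n - rest
    } else if (n > 0) {
      cs_time <- c(cs_time, rep(max(tk), n)); cs_n <- c(cs_n, rep(1L, n))
      n <- 0
    }
    n_cur <- if (i < I) nr[i + 1] else 0L
  }

  out <- rbind(
    if (length(ev_time)) data.frame(time = rep(ev_time, ev_n), event = 1L),
    if (length(cs_time)) data.frame(time = rep(cs_time, cs_n), event = 0L))
  out$time <- pmax(out$time, 1e-6)
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}

largest_remainder_round <- function(x) {
  x <- pmax(x, 0)
  total <- as.integer(round(sum(x)))
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(min(rem, length(f)))]] <- f[ord[seq_len(min(rem, length(f)))]] + 1
  }
  as.integer(f)
}

#' Product-limit (Kaplan-Meier) estimate from individual patient data
#'
#' Thin wrapper over [survival::survfit()] evaluated at event times,
#' used to validate reconstructed pseudo-IPD against the digitized input.
#'
#' @param ipd Data.frame with `time` and `event` columns.
#' @return A data.frame with columns `time` and `survival` (the step
#'   function evaluated after each distinct event time), prefixed with
#'   the (0, 1) origin.
#' @export
km_estimate <- function(ipd) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  data.frame(time = c(0, fit$time[keep]), survival = c(1, fit$surv[keep]))
}

#' Evaluate a KM step function at arbitrary times
#' @param km Data.frame with `time`, `survival` (right-continuous steps).
#' @param t Times at which to evaluate.
#' @return Survival values at `t`.
#' @export
km_at <- function(km, t) {
  stats::approx(km$time, km$survival, xout = t, method = "constant",
                yleft = 1, rule = 2)$y
}

#' Read/write helpers for curve, risk-table and IPD CSV files
#'
#' Plain CSV formats: curves as `time,survival`, risk tables as
#' `time,n_at_risk`, IPD as `time,event`.
#'
#' @param path File path.
#' @name ipd_io
#' @return The parsed object (readers) or `invisible(path)` (writers).
NULL

#' @rdname ipd_io
#' @export
read_digitized_curve <- function(path) {
  d <- utils::read.csv(path)
  digitized_curve(d$time, d$survival)
}

#' @rdname ipd_io
#' @export
read_risk_table <- function(path) {
  d <- utils::read.csv(path)
  risk_table(d$time, d$n_at_risk)
}

#' @rdname ipd_io
#' @param ipd IPD data.frame.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(validate_ipd(ipd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_ipd <- function(path) validate_ipd(utils::read.csv(path))
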