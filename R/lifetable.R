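#' Abridged all-cause life table
#'
#' Background (general-population) mortality by single year of age,
#' stored as annual death probabilities.  The packaged default is a
#' synthetic Gompertz-Makeham schedule emulating the shape of an older
#' East-Asian census life table (the source census table is not shipped);
#' any user table with the same two columns can be supplied in its place
#' through the model definition.
#'
#' @param age Vector of ages in years (contiguous, increasing).
#' @param qx Annual probability of death at each age, in `[0, 1]`.
#' @return A data.frame of class `life_table` with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  age <- as.numeric(age); qx <- as.numeric(qx)
  if (length(age) != length(qx) || length(age) < 2L) {
    stop("life table needs matching age/qx vectors", call. = FALSE)
  }
  if (any(diff(age) != 1)) stop("ages must be contiguous single years", call. = FALSE)
  if (any(qx < 0 | qx > 1)) stop("qx must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Generate a synthetic life table
#'
#' `"aging"` (default) uses a Gompertz-Makeham hazard
#' \eqn{q(a) = \min(0.7,\; 0.002 + 0.012\, e^{0.085 (a - 65)})}, giving a
#' strictly increasing schedule from about 1.4% at 65 to about 25% at 100.
#' `"flat"` applies a constant annual probability `q`.
#'
#' @param profile `"aging"` or `"flat"`.
#' @param q Annual death probability for the `"flat"` profile.
#' @param ages Age range covered (default 65 to 100).
#' @return A [life_table()].
#' @export
make_life_table <- function(profile = c("aging", "flat"), q = 0.02,
                            ages = 65:100) {
  profile <- match.arg(profile)
  qx <- switch(profile,
               aging = pmin(0.7, 0.002 + 0.012 * exp(0.085 * (ages - 65))),
               flat  = rep(q, length(ages)))
  life_table(ages, qx)
}

#' Background mortality probability over a model step
#'
#' Converts the annual probability at the cohort's current (integer) age
#' into a probability for a step of `delta` months via
#' \eqn{1 - (1 - q)^{\delta/12}}.  Ages beyond the table are held at the
#' last row.
#'
#' @param lt A [life_table()].
#' @param age Current age in years (may be fractional; floored for lookup).
#' @param delta Step length in months.
#' @return Death probability over the step.
#' @export
background_mortality <- function(lt, age, delta) {
  stopifnot(inherits(lt, "life_table"))
  a <- pmin(pmax(floor(age), min(lt$age)), max(lt$age))
  q <- lt$qx[match(a, lt$age)]
  1 - (1 - q)^(delta / 12)
}
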