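#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes increments `delta_cost = cost_a - cost_b` and
#' `delta_qaly = qaly_a - qaly_b` for the declared comparator order, the
#' ICER `delta_cost / delta_qaly` where defined, and a dominance label:
#' `"dominant"` if A is cheaper and more effective, `"dominated"` if A is
#' costlier and less effective, `"equivalent"` if both increments vanish,
#' otherwise `"cost_effective"` / `"not_cost_effective"` by comparing the
#' ICER with the willingness-to-pay threshold.
#'
#' @param cost_a,qaly_a Totals for strategy A.
#' @param cost_b,qaly_b Totals for comparator B.
#' @param label_a,label_b Strategy names used in printing.
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#' @return An object of class `ce_result`.
#' @examples
#' compute_icer(100, 2, 0, 0)  # $50/QALY
#' @export
compute_icer <- function(cost_a, qaly_a, cost_b, qaly_b,
                         label_a = "A", label_b = "B", wtp = 38223.34) {
  stopifnot(is.finite(cost_a), is.finite(qaly_a),
            is.finite(cost_b), is.finite(qaly_b))
  dc <- cost_a - cost_b
  de <- qaly_a - qaly_b
  icer <- if (de != 0) dc / de else NA_real_
  label <- if (dc < 0 && de > 0) {
    "dominant"
  } else if (dc > 0 && de < 0) {
    "dominated"
  } else if (dc == 0 && de == 0) {
    "equivalent"
  } else if (de == 0) {
    if (dc < 0) "dominant" else "dominated"  # equal effect, cost decides
  } else if (icer <= wtp && de > 0 || de < 0 && icer >= wtp) {
    "cost_effective"
  } else {
    "not_cost_effective"
  }
  structure(list(strategies = c(a = label_a, b = label_b),
                 cost = c(a = cost_a, b = cost_b),
                 qaly = c(a = qaly_a, b = qaly_b),
                 delta_cost = dc, delta_qaly = de,
                 icer = icer, wtp = wtp, dominance = label),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  fmt <- function(v) format(round(v, 2), big.mark = ",", nsmall = 2)
  cat(sprintf("<ce_result> %s vs %s (WTP $%s/QALY)\n", x$strategies["a"],
              x$strategies["b"], fmt(x$wtp)))
  cat(sprintf("  %-8s cost $%s, QALYs %.4f\n", x$strategies["a"],
              fmt(x$cost["a"]), x$qaly["a"]))
  cat(sprintf("  %-8s cost $%s, QALYs %.4f\n", x$strategies["b"],
              fmt(x$cost["b"]), x$qaly["b"]))
  cat(sprintf("  delta cost $%s, delta QALYs %.4f\n", fmt(x$delta_cost),
              x$delta_qaly))
  cat(sprintf("  ICER: %s, %s: %s\n",
              if (is.na(x$icer)) "undefined" else paste0("$", fmt(x$icer)),
              x$strategies["a"], x$dominance))
  invisible(x)
}

#' Net monetary benefit
#'
#' \eqn{NMB = \lambda \cdot QALY - cost} at willingness-to-pay
#' \eqn{\lambda}.
#'
#' @param cost Total cost.
#' @param qaly Total QALYs.
#' @param wtp Willingness-to-pay per QALY (>= 0).
#' @return NMB in USD (vectorised over any argument).
#' @export
net_monetary_benefit <- function(cost, qaly, wtp = 38223.34) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  qaly * wtp - cost
}

#' Serialize a `ce_result` to a base-case table
#'
#' @param res A `ce_result` with attached traces (from [run_base_case()]).
#' @return A data.frame shaped like the published base-case table:
#'   QALYs, cost categories, totals, ICER and dominance per strategy.
#' @export
ce_table <- function(res) {
  traces <- attr(res, "traces")
  if (is.null(traces)) stop("ce_result has no attached traces", call. = FALSE)
  ib <- traces$IB; beri <- traces$BE_RI
  rows <- c("QALYs", "Cost: first-line drugs", "Cost: subsequent drugs",
            "Cost: adverse events", "Cost: other", "Total cost",
            "ICER ($/QALY)", "Dominance")
  val <- function(tr) c(tr$total_qaly, tr$categories[["drug_first_line"]],
                        tr$categories[["drug_subsequent"]],
                        tr$categories[["ae"]], tr$categories[["other"]],
                        tr$total_cost)
  v_ib <- val(ib); v_beri <- val(beri)
  data.frame(variable = rows,
             IB = c(round(v_ib, 2), NA, NA),
             BE_RI = c(round(v_beri, 2), NA, NA),
             incremental = c(round(v_beri - v_ib, 2), round(res$icer, 2), NA),
             note = c(rep("", 7),
                      sprintf("%s %s", res$strategies[["a"]], res$dominance)),
             stringsAsFactors = FALSE)
}
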