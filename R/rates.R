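#' Correct identification rate
#'
#' Proportion of target-present lineups on which the perpetrator was
#' identified: total TP suspect IDs across confidence divided by the number
#' of TP lineups.
#'
#' @param table a \code{\link{lineup_table}}.
#' @return list of class \code{rate_result}: \code{numerator},
#'   \code{denominator}, \code{divisor_k} (1 here), \code{rate}.
#' @export
correct_id_rate <- function(table) {
  stopifnot(inherits(table, "lineup_table"))
  if (table$n_tp == 0) stop("no target-present lineups: rate undefined")
  num <- sum(tp_suspect_counts(table))
  structure(list(numerator = num, denominator = table$n_tp, divisor_k = 1,
                 rate = num / table$n_tp),
            class = "rate_result")
}

#' Estimated innocent-suspect false identification rate
#'
#' With no designated innocent suspect, the false ID rate is estimated as the
#' target-absent filler identification proportion divided by the lineup size
#' k: any of the k fillers stands in for the innocent suspect with equal
#' probability.
#'
#' @param table a \code{\link{lineup_table}}.
#' @param designated_suspect set \code{TRUE} if the design designates an
#'   innocent suspect in TA lineups; this estimator then does not apply and
#'   an error directs the caller to the direct suspect-ID rate.
#' @return a \code{rate_result} with \code{divisor_k = k}.
#' @export
estimated_false_id_rate <- function(table, designated_suspect = FALSE) {
  stopifnot(inherits(table, "lineup_table"))
  if (designated_suspect)
    stop("design has a designated innocent suspect: use the direct ",
         "TA suspect-ID rate, not the filler-based estimator")
  if (table$n_ta == 0) stop("no target-absent lineups: rate undefined")
  num <- sum(ta_filler_counts(table))
  structure(list(numerator = num, denominator = table$n_ta,
                 divisor_k = table$k,
                 rate = num / table$n_ta / table$k),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("rate = %d / %d%s = %.4f\n", x$numerator, x$denominator,
              if (x$divisor_k > 1) sprintf(" / %d", x$divisor_k) else "",
              x$rate))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' @param a,b first row (outcome count, remainder) for condition 1.
#' @param c,d second row for condition 2.
#' @return list of class \code{chisq_result}: \code{statistic}, \code{df},
#'   \code{p}, \code{table}.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal total: chi-square undefined")
  ht <- stats::chisq.test(m, correct = FALSE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = unname(ht$p.value), table = m),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.6f\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Compare two conditions on an outcome with chi-square
#'
#' Builds the 2x2 table (outcome count vs remainder, per condition) and
#' applies \code{\link{chisq_2x2}}. \code{"correct_ids"} compares TP suspect
#' identifications; \code{"ta_false_alarms"} compares total TA filler
#' identifications.
#'
#' @param table_a,table_b \code{\link{lineup_table}}s for the two conditions.
#' @param outcome \code{"correct_ids"} or \code{"ta_false_alarms"}.
#' @return a \code{chisq_result}.
#' @export
compare_conditions <- function(table_a, table_b,
                               outcome = c("correct_ids", "ta_false_alarms")) {
  outcome <- match.arg(outcome)
  pull <- function(tab) {
    if (outcome == "correct_ids") {
      if (tab$n_tp == 0) stop("empty target-present lineups")
      c(sum(tp_suspect_counts(tab)), tab$n_tp - sum(tp_suspect_counts(tab)))
    } else {
      if (tab$n_ta == 0) stop("empty target-absent lineups")
      c(sum(ta_filler_counts(tab)), tab$n_ta - sum(ta_filler_counts(tab)))
    }
  }
  x <- pull(table_a); y <- pull(table_b)
  chisq_2x2(x[1], x[2], y[1], y[2])
}
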