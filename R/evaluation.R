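# Scoring abundance estimates against a known truth.

#' Average relative error of an abundance estimate
#'
#' Mean over truth species of `|R_true - R_est| / R_true`.  Species absent
#' from the estimate contribute `R_est = 0` (a full relative error of 1).
#' The absolute value makes over- and under-estimates both count as error
#' rather than cancelling.
#'
#' @param truth named numeric vector of true read counts (names are
#'   species taxids or labels); all entries must be positive.
#' @param estimate named numeric vector of estimated read counts.
#' @return Mean relative error (a non-negative fraction).
#' @examples
#' average_relative_error(c(a = 100, b = 200), c(a = 90, b = 220))  # 0.1
#' @export
average_relative_error <- function(truth, estimate) {
  if (!length(truth)) stop("empty truth")
  if (any(truth <= 0)) stop("truth read counts must be positive")
  est <- estimate[match(names(truth), names(estimate))]
  est[is.na(est)] <- 0
  mean(abs(truth - est) / truth)
}

#' False-positive rate of an abundance estimate
#'
#' Fraction of reads assigned to species absent from the truth set.  The
#' default denominator is the total reads including unclassified; set
#' `classified_only = TRUE` to divide by classified reads instead.
#'
#' @param truth named numeric vector of true read counts.
#' @param estimate named numeric vector of estimated read counts.
#' @param total_reads total reads in the sample (classified +
#'   unclassified).
#' @param classified_reads classified reads, required when
#'   `classified_only = TRUE`.
#' @param classified_only use classified reads as the denominator.
#' @return Fraction in `[0, 1]`.
#' @export
false_positive_rate <- function(truth, estimate, total_reads,
                                classified_reads = NULL,
                                classified_only = FALSE) {
  stopifnot(total_reads > 0)
  fp <- sum(estimate[!(names(estimate) %in% names(truth))])
  den <- if (classified_only) {
    if (is.null(classified_reads))
      stop("classified_reads is required when classified_only = TRUE")
    classified_reads
  } else total_reads
  fp / den
}

#' Score an abundance table against a truth table
#'
#' @param truth data frame with columns `taxid` and a read-count column
#'   (`reads` or `expected_reads`), as produced by [make_community()] or
#'   tallied from [simulate_reads()].
#' @param est an `abundance_table` (or a data frame with `taxonomy_id`
#'   and `new_est_reads`).
#' @param total_reads total reads in the sample.
#' @return An `evaluation_result`: `n`, per-species `relative_errors`,
#'   `average_relative_error` and `false_positive_rate`.
#' @export
evaluate_estimate <- function(truth, est, total_reads) {
  rc <- if ("reads" %in% names(truth)) truth$reads else
    truth$expected_reads
  tv <- stats::setNames(rc, truth$taxid)
  ev <- stats::setNames(est$new_est_reads, est$taxonomy_id)
  rel <- abs(tv - ifelse(is.na(ev[names(tv)]), 0, ev[names(tv)])) / tv
  structure(list(n = length(tv),
                 relative_errors = stats::setNames(unname(rel), names(tv)),
                 average_relative_error = average_relative_error(tv, ev),
                 false_positive_rate =
                   false_positive_rate(tv, ev, total_reads)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result over", x$n, "truth species\n")
  cat(sprintf("  average relative error: %.4f (%.2f%%)\n",
              x$average_relative_error, 100 * x$average_relative_error))
  cat(sprintf("  false positive rate:    %.4f (%.2f%%)\n",
              x$false_positive_rate, 100 * x$false_positive_rate))
  cat(sprintf("  max relative error:     %.4f\n", max(x$relative_errors)))
  invisible(x)
}
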