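# Tolerance policy: the constants that gate a gene's contribution to a
# pathway activation score.

#' Tolerance policy for the beyond-tolerance-interval filter
#'
#' A gene's case-to-control expression ratio (ECR) contributes to a pathway
#' score only when it lies beyond the tolerance interval: the ratio must
#' exceed `fold_upper` or fall below `fold_lower`, AND the case expression
#' level must differ from the control mean by more than `sd_multiplier`
#' control standard deviations. Defaults are the method's printed constants:
#' fold bounds 3/2 and 2/3, SD multiplier 2.
#'
#' @param fold_upper upper ECR bound (default 3/2).
#' @param fold_lower lower ECR bound (default 2/3); must satisfy
#'   `0 < fold_lower < 1 < fold_upper`.
#' @param sd_multiplier positive multiplier on the control SD (default 2).
#' @param pseudocount small positive value added to both the numerator and
#'   denominator of every ECR, guarding zero expression. `NULL` (default)
#'   resolves at profiling time to `1e-8 * median(matrix)` with a floor of
#'   `1e-12`.
#' @param min_control_n minimum control-group size (default 3).
#' @return an object of class `"tolerance_policy"`.
#' @export
tolerance_policy <- function(fold_upper = 3 / 2, fold_lower = 2 / 3,
                             sd_multiplier = 2, pseudocount = NULL,
                             min_control_n = 3L) {
  assert_that(is.numeric(fold_lower) && is.numeric(fold_upper) &&
                fold_lower > 0 && fold_lower < 1 && fold_upper > 1,
              "fold bounds must satisfy 0 < fold_lower < 1 < fold_upper")
  assert_that(is.numeric(sd_multiplier) && sd_multiplier > 0,
              "'sd_multiplier' must be > 0")
  if (!is.null(pseudocount)) {
    assert_that(is.numeric(pseudocount) && pseudocount > 0,
                "'pseudocount' must be > 0")
  }
  assert_that(min_control_n >= 1, "'min_control_n' must be >= 1")
  structure(list(fold_upper = fold_upper, fold_lower = fold_lower,
                 sd_multiplier = sd_multiplier, pseudocount = pseudocount,
                 min_control_n = as.integer(min_control_n)),
            class = "tolerance_policy")
}

#' @export
print.tolerance_policy <- function(x, ...) {
  cat("tolerance_policy: ECR outside [",
      format(x$fold_lower), ", ", format(x$fold_upper),
      "] AND |case - control mean| > ", format(x$sd_multiplier),
      " x control SD\n", sep = "")
  cat("  pseudocount: ",
      if (is.null(x$pseudocount)) "auto (1e-8 x matrix median)"
      else format(x$pseudocount),
      "; min control n: ", x$min_control_n, "\n", sep = "")
  invisible(x)
}

# Resolve the ECR pseudocount against a concrete set of expression values.
resolve_pseudocount <- function(policy, values) {
  if (!is.null(policy$pseudocount)) return(policy$pseudocount)
  max(1e-8 * stats::median(values), 1e-12)
}
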