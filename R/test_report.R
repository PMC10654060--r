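#' Permutation test report
#'
#' Light container for permutation-test results. P-values use the
#' add-one rule `(r + 1) / (n + 1)`, so they are bounded below by
#' `1 / (n_permutations + 1)` and never exactly zero.
#'
#' @param statistic_name character scalar.
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @param p_value the permutation P-value.
#' @param n_permutations number of permutations.
#' @param ... extra named fields carried through.
#' @return a list of class `vm_test_report`.
#' @keywords internal
new_test_report <- function(statistic_name, observed, null, p_value,
                            n_permutations, ...) {
  structure(list(statistic_name = statistic_name, observed = observed,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 p_value = p_value, n_permutations = n_permutations, ...),
            class = "vm_test_report")
}

#' @export
print.vm_test_report <- function(x, ...) {
  cat(sprintf("%s: observed = %.4g, null = %.4g +/- %.4g (%d perms), P = %.4g\n",
              x$statistic_name, x$observed, x$null_mean, x$null_sd,
              x$n_permutations, x$p_value))
  if (!is.null(x$q_value)) cat(sprintf("  FDR q = %.4g\n", x$q_value))
  invisible(x)
}

# two-sided permutation P with the add-one floor
perm_p_two_sided <- function(observed, null) {
  n <- length(null)
  lo <- (sum(null <= observed) + 1) / (n + 1)
  hi <- (sum(null >= observed) + 1) / (n + 1)
  min(1, 2 * min(lo, hi))
}

# two-sided P on absolute deviation from the null center
perm_p_abs <- function(observed, null) {
  (sum(abs(null) >= abs(observed)) + 1) / (length(null) + 1)
}
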