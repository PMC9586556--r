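# Tolerance thresholds derived from the geometry. Fractions of each arm (or
# of the whole sample) that may be miscoded before significance is lost:
#   eps_E = |x_i| / (a+b),  eps_C = |y_i| / (c+d),  eps_A = d_min / n.
# Continuous |x_i|, |y_i| are used (integer-floored variants are reported as
# secondary fields); a missing axis crossing caps the arm's tolerance at 1
# with an explanatory flag, since no single-arm recoding can then remove
# significance.
tolerance_metrics <- function(tab, intercepts, solution) {
  flags <- character(0)
  if (solution$degenerate) {
    return(list(epsilon_E = 0, epsilon_C = 0, epsilon_A = 0,
                epsilon_E_int = 0, epsilon_C_int = 0,
                flags = "not significant: all tolerances zero"))
  }
  arm_eps <- function(intercept, size, arm) {
    if (is.na(intercept)) {
      flags <<- c(flags, sprintf(
        "%s: single-arm recoding cannot remove significance (no axis crossing); tolerance capped at 100%%",
        arm))
      c(1, 1)
    } else {
      c(abs(intercept) / size, floor(abs(intercept)) / size)
    }
  }
  eE <- arm_eps(intercepts$x_i, tab$a + tab$b, "experimental arm")
  eC <- arm_eps(intercepts$y_i, tab$c + tab$d, "control arm")
  if (!solution$feasible)
    flags <- c(flags,
               "FECKUP displacement exceeds available counts (infeasible as literal recoding)")
  list(epsilon_E = eE[1], epsilon_C = eC[1],
       epsilon_A = solution$d_min / tab$n,
       epsilon_E_int = eE[2], epsilon_C_int = eC[2],
       flags = flags)
}

#' Minimum miscoding implied by test sensitivity and specificity
#'
#' If the endpoint test used in the experimental arm has sensitivity `sn_e`
#' and specificity `sp_e`, the observed positive count relates to the true
#' count `a_o` by `a = a_o sn_e + (a + b - a_o)(1 - sp_e)`. Solving for the
#' net miscoding `x_m = a - a_o` gives
#' \deqn{x_m = \frac{b (1 - sp_e) - a (1 - sn_e)}{sn_e + sp_e - 1},}
#' and analogously for the control arm
#' \deqn{y_m = \frac{c (1 - sn_c) - d (1 - sp_c)}{sn_c + sp_c - 1}.}
#' These are the miscodings guaranteed to exist in the reported counts from
#' the test's intrinsic error rates alone; negative values mean net
#' miscoding in the opposite direction and are reported signed. When only
#' the experimental arm's test is characterised, `y_m` is 0. When one pair
#' of characteristics is supplied it is applied to both arms (the common
#' same-test-in-both-arms case).
#'
#' @param table A `contingency_table` (or coercible).
#' @param sens_exp,spec_exp Sensitivity and specificity of the
#'   experimental-arm endpoint test, each in \[0, 1\].
#' @param sens_ctl,spec_ctl Control-arm test characteristics; default to the
#'   experimental-arm values (same test used in both arms).
#' @param both_arms If `TRUE` (default when control characteristics are
#'   available), compute `y_m`; otherwise `y_m = 0`.
#' @return Object of class `"miscoding_estimate"`: list with `x_m`, `y_m`
#'   and the characteristics used.
#' @examples
#' minimum_miscoding(contingency_table(113, 887, 24, 976),
#'                   sens_exp = 0.75, spec_exp = 0.90, both_arms = FALSE)
#' @export
minimum_miscoding <- function(table, sens_exp, spec_exp,
                              sens_ctl = sens_exp, spec_ctl = spec_exp,
                              both_arms = TRUE) {
  # real-valued cells (e.g. expected counts under misclassification) are
  # allowed via a plain list, as in chi_squared()
  tab <- if (is.list(table) && !inherits(table, "contingency_table") &&
             all(c("a", "b", "c", "d") %in% names(table))) table
         else as_contingency_table(table)
  check_prob <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop(sprintf("%s must be a probability in [0, 1]", nm), call. = FALSE)
    p
  }
  sens_exp <- check_prob(sens_exp, "sens_exp")
  spec_exp <- check_prob(spec_exp, "spec_exp")
  if (abs(sens_exp + spec_exp - 1) < 1e-12)
    stop("uninformative experimental-arm test: sensitivity + specificity = 1",
         call. = FALSE)
  x_m <- (tab$b * (1 - spec_exp) - tab$a * (1 - sens_exp)) /
    (sens_exp + spec_exp - 1)
  y_m <- 0
  if (both_arms) {
    sens_ctl <- check_prob(sens_ctl, "sens_ctl")
    spec_ctl <- check_prob(spec_ctl, "spec_ctl")
    if (abs(sens_ctl + spec_ctl - 1) < 1e-12)
      stop("uninformative control-arm test: sensitivity + specificity = 1",
           call. = FALSE)
    y_m <- (tab$c * (1 - sens_ctl) - tab$d * (1 - spec_ctl)) /
      (sens_ctl + spec_ctl - 1)
  }
  structure(list(x_m = x_m, y_m = y_m,
                 sens_exp = sens_exp, spec_exp = spec_exp,
                 sens_ctl = if (both_arms) sens_ctl else NA_real_,
                 spec_ctl = if (both_arms) spec_ctl else NA_real_),
            class = "miscoding_estimate")
}

#' @export
print.miscoding_estimate <- function(x, ...) {
  cat(sprintf("minimum test-implied miscoding: x_m = %.4g, y_m = %.4g\n",
              x$x_m, x$y_m))
  invisible(x)
}

#' Robustness verdict from test-implied miscoding
#'
#' The point `(x_m, y_m)` is the miscoding guaranteed by the endpoint
#' test's sensitivity and specificity. If it lies on or within the ellipse
#' of insignificance, the reported significance cannot be trusted: the
#' test's intrinsic misclassification alone is enough to account for it.
#'
#' @param coeffs An [ellipse_coefficients()] object.
#' @param estimate A [minimum_miscoding()] result (or any list with `x_m`,
#'   `y_m`).
#' @return `"not robust"` if `(x_m, y_m)` falls inside the ellipse
#'   (boundary included), else `"robust"`.
#' @export
robustness_verdict <- function(coeffs, estimate) {
  if (is.null(estimate$x_m))
    stop("estimate must carry x_m and y_m", call. = FALSE)
  y_m <- if (is.null(estimate$y_m)) 0 else estimate$y_m
  if (eoi_contains(coeffs, estimate$x_m, y_m)) "not robust" else "robust"
}
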