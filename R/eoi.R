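#' Ellipse-of-insignificance fragility analysis of a 2x2 trial
#'
#' Fits the full analysis for a dichotomous-outcome trial reported as a 2x2
#' table: an experimental arm with `a` endpoint-positive and `b`
#' endpoint-negative participants, and a control arm with `c` positive and
#' `d` negative. The region of simultaneous recoding displacements `(x, y)`
#' (experimental positives recoded negative, control negatives recoded
#' positive) under which the Pearson chi-squared statistic falls below its
#' critical value at level `alpha` is an inclined ellipse; the analysis
#' reports
#' \itemize{
#'   \item the nearest boundary point `(x_e, y_e)` with length `f_min` and
#'     the integer bound `d_min = floor(|x_e| + |y_e|)` — the fewest
#'     simultaneous miscodings that could erase significance;
#'   \item single-arm tolerances `x_i`, `y_i` (axis intercepts);
#'   \item tolerance fractions `epsilon_E = |x_i|/(a+b)`,
#'     `epsilon_C = |y_i|/(c+d)`, `epsilon_A = d_min/n`;
#'   \item when the endpoint test's sensitivity/specificity are supplied,
#'     the guaranteed miscoding `(x_m, y_m)` and a robustness verdict: the
#'     result is "not robust" when that point already lies inside the
#'     ellipse.
#' }
#' For a table that is not significant at `alpha` the geometry is degenerate
#' (the origin is already in the insignificance region) and all tolerances
#' are zero.
#'
#' @param a Either the endpoint-positive experimental count, or a complete
#'   table (`contingency_table`, 2x2 matrix, or length-4 vector) in which
#'   case `b`, `c`, `d` are omitted.
#' @param b,c,d Remaining cell counts (see [contingency_table()]).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param sens_exp,spec_exp Optional sensitivity/specificity of the
#'   experimental-arm endpoint test.
#' @param sens_ctl,spec_ctl Optional control-arm test characteristics;
#'   default to the experimental-arm values when those are given. Supply
#'   `sens_exp`/`spec_exp` alone with `sens_ctl = NA` to characterise only
#'   the experimental arm (then `y_m = 0`).
#' @param invert If `TRUE`, analyse the transposed table
#'   (see [invert_table()]) to probe experimental/control arm misallocation
#'   instead of endpoint miscoding.
#' @return An object of class `"eoi"`; see Details. Key components:
#'   `table`, `alpha`, `nu_c`, `statistic`, `significant`, `coefficients`
#'   (class `eoi_coefficients`), `feckup` (class `feckup`), `intercepts`
#'   (`x_i`, `y_i`), `epsilon` (fractions `E`, `C`, `A` plus integer-floored
#'   variants), `flags`, and — when test characteristics were supplied —
#'   `miscoding` and `verdict`.
#' @examples
#' fit <- eoi(164, 530, 36, 183)
#' fit
#' summary(fit)
#'
#' # screening comparison with a known test:
#' eoi(113, 887, 24, 976, sens_exp = 0.75, spec_exp = 0.90, sens_ctl = NA)
#' @seealso [feckup_point()], [axis_intercepts()], [minimum_miscoding()],
#'   [polygon_of_insignificance()], [classic_fragility_index()]
#' @export
eoi <- function(a, b, c, d, alpha = 0.05,
                sens_exp = NULL, spec_exp = NULL,
                sens_ctl = sens_exp, spec_ctl = spec_exp,
                invert = FALSE) {
  tab <- if (missing(b)) as_contingency_table(a) else contingency_table(a, b, c, d)
  if (invert) tab <- invert_table(tab)
  chi2 <- chi_squared(tab)
  nu_c <- chisq_critical_value(alpha)
  coeffs <- ellipse_coefficients(tab, alpha)
  sol <- feckup_point(coeffs)
  if (sol$degenerate) {
    intercepts <- list(x_i = 0, y_i = 0)
  } else {
    intercepts <- axis_intercepts(coeffs)
  }
  eps <- tolerance_metrics(tab, intercepts, sol)

  fit <- structure(
    list(table = tab, alpha = alpha, nu_c = nu_c,
         statistic = chi2, significant = chi2 > nu_c,
         inverted = invert,
         coefficients = coeffs, feckup = sol,
         intercepts = intercepts,
         epsilon = eps[setdiff(names(eps), "flags")],
         flags = eps$flags,
         miscoding = NULL, verdict = NULL),
    class = "eoi")

  if (!is.null(sens_exp) || !is.null(spec_exp)) {
    if (is.null(sens_exp) || is.null(spec_exp))
      stop("supply both sens_exp and spec_exp (or neither)", call. = FALSE)
    ctl_known <- !is.null(sens_ctl) && !is.null(spec_ctl) &&
      !is.na(sens_ctl) && !is.na(spec_ctl)
    est <- minimum_miscoding(tab, sens_exp, spec_exp,
                             sens_ctl = if (ctl_known) sens_ctl else sens_exp,
                             spec_ctl = if (ctl_known) spec_ctl else spec_exp,
                             both_arms = ctl_known)
    fit$miscoding <- est
    fit$verdict <- robustness_verdict(coeffs, est)
  }
  fit
}

pct1 <- function(x) sprintf("%.1f%%", 100 * x)

#' @export
print.eoi <- function(x, ...) {
  tab <- x$table
  cat("Ellipse-of-insignificance analysis",
      if (x$inverted) "(inverted: arm-misallocation view)" else "", "\n")
  cat(sprintf("  table (a, b, c, d) = (%d, %d, %d, %d), n = %d\n",
              tab$a, tab$b, tab$c, tab$d, tab$n))
  cat(sprintf("  chi-squared = %.4g, critical value (alpha = %g) = %.4g -> %s\n",
              x$statistic, x$alpha, x$nu_c,
              if (x$significant) "significant" else "not significant"))
  if (x$significant) {
    cat(sprintf("  FECKUP point (x_e, y_e) = (%.1f, %.1f), f_min = %.1f, d_min = %d\n",
                x$feckup$x_e, x$feckup$y_e, x$feckup$f_min, x$feckup$d_min))
    fi <- function(v) if (is.na(v)) "none" else sprintf("%.1f", v)
    cat(sprintf("  single-arm tolerances x_i = %s, y_i = %s subjects\n",
                fi(x$intercepts$x_i), fi(x$intercepts$y_i)))
    cat(sprintf("  tolerance thresholds: eps_E = %s, eps_C = %s, eps_A = %s\n",
                pct1(x$epsilon$epsilon_E), pct1(x$epsilon$epsilon_C),
                pct1(x$epsilon$epsilon_A)))
  } else {
    cat("  no recoding needed; all tolerance thresholds are zero\n")
  }
  if (!is.null(x$verdict))
    cat(sprintf("  test-implied miscoding (x_m, y_m) = (%.1f, %.1f) -> %s\n",
                x$miscoding$x_m, x$miscoding$y_m, toupper(x$verdict)))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' @export
summary.eoi <- function(object, ...) {
  structure(list(fit = object), class = "summary.eoi")
}

#' @export
print.summary.eoi <- function(x, ...) {
  print(x$fit)
  cat("\nConic coefficients:\n")
  print(x$fit$coefficients$coef)
  if (x$fit$significant) {
    cat("\nAll nearest-point candidates (quartic roots):\n")
    print(round(x$fit$feckup$all_roots, 4))
    cat(sprintf("solver residual (relative): %.2e\n", x$fit$feckup$residual))
    cat(sprintf("integer-floored arm tolerances: eps_E = %s, eps_C = %s\n",
                pct1(x$fit$epsilon$epsilon_E_int),
                pct1(x$fit$epsilon$epsilon_C_int)))
  }
  invisible(x)
}

#' @export
coef.eoi <- function(object, ...) object$coefficients$coef

#' One-row data-frame summary of an analysis
#'
#' @param x An `eoi` fit.
#' @param row.names,optional,... Passed through for compatibility.
#' @return A one-row `data.frame` with the inputs, statistic, geometry and
#'   tolerance metrics (percentage scale for the epsilons).
#' @export
as.data.frame.eoi <- function(x, row.names = NULL, optional = FALSE, ...) {
  tab <- x$table
  data.frame(
    a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
    alpha = x$alpha, chi_squared = x$statistic, significant = x$significant,
    x_e = x$feckup$x_e, y_e = x$feckup$y_e,
    f_min = x$feckup$f_min, d_min = x$feckup$d_min,
    x_i = x$intercepts$x_i, y_i = x$intercepts$y_i,
    epsilon_E_pct = 100 * x$epsilon$epsilon_E,
    epsilon_C_pct = 100 * x$epsilon$epsilon_C,
    epsilon_A_pct = 100 * x$epsilon$epsilon_A,
    x_m = if (is.null(x$miscoding)) NA_real_ else x$miscoding$x_m,
    y_m = if (is.null(x$miscoding)) NA_real_ else x$miscoding$y_m,
    verdict = if (is.null(x$verdict)) NA_character_ else x$verdict,
    row.names = row.names, stringsAsFactors = FALSE)
}

#' Plot an ellipse-of-insignificance analysis
#'
#' Base-graphics rendering: the ellipse, the FECKUP vector from the origin,
#' axis intercepts, optionally the enclosing integer polygon and the
#' test-implied miscoding point.
#'
#' @param x An `eoi` fit.
#' @param polygon Draw the outer integer polygon too?
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.eoi <- function(x, polygon = FALSE, ...) {
  if (!x$significant) {
    warning("table not significant: nothing to draw")
    return(invisible(x))
  }
  bd <- ellipse_boundary(x$coefficients, 720L)
  xl <- range(bd[, 1], 0); yl <- range(bd[, 2], 0)
  graphics::plot(bd, type = "l", asp = 1, xlim = xl, ylim = yl,
                 xlab = "x (experimental recodings)",
                 ylab = "y (control recodings)", ...)
  graphics::polygon(bd, col = grDevices::adjustcolor("steelblue", 0.25),
                    border = "steelblue")
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::segments(0, 0, x$feckup$x_e, x$feckup$y_e, col = "red", lwd = 2)
  graphics::points(x$feckup$x_e, x$feckup$y_e, pch = 19, col = "red")
  if (!is.na(x$intercepts$x_i))
    graphics::points(x$intercepts$x_i, 0, pch = 17, col = "darkgreen")
  if (!is.na(x$intercepts$y_i))
    graphics::points(0, x$intercepts$y_i, pch = 17, col = "blue")
  if (polygon) {
    pv <- polygon_of_insignificance(x$table, x$alpha)
    graphics::polygon(pv, border = "grey30", lty = 2)
  }
  if (!is.null(x$miscoding))
    graphics::points(x$miscoding$x_m, x$miscoding$y_m, pch = 4, cex = 1.4,
                     col = "purple", lwd = 2)
  invisible(x)
}
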