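#' Build a 2x2 contingency table
#'
#' Represents a dichotomous-outcome trial: an experimental arm with `a`
#' endpoint-positive and `b` endpoint-negative participants, and a control arm
#' with `c` endpoint-positive and `d` endpoint-negative participants.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a`/`b` are the
#'   endpoint-positive / endpoint-negative counts in the experimental arm,
#'   `c`/`d` the same in the control arm.
#' @return An object of class `"contingency_table"`: a list with elements
#'   `a`, `b`, `c`, `d` and the total `n = a + b + c + d`.
#' @examples
#' contingency_table(164, 530, 36, 183)
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (length(counts) != 4L || anyNA(counts) || !is.numeric(counts))
    stop("counts a, b, c, d must be four non-missing numbers", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be whole numbers", call. = FALSE)
  counts <- round(counts)
  structure(
    list(a = counts[["a"]], b = counts[["b"]], c = counts[["c"]],
         d = counts[["d"]], n = sum(counts)),
    class = "contingency_table"
  )
}

#' Coerce to a contingency table
#'
#' Accepts an existing `contingency_table`, a length-4 vector `(a, b, c, d)`,
#' or a 2x2 matrix laid out with arms as rows (`a b / c d`).
#'
#' @param x Object to coerce.
#' @return A `contingency_table`.
#' @export
as_contingency_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L)))
      stop("only 2x2 tables are supported", call. = FALSE)
    return(contingency_table(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  }
  if (is.numeric(x) && length(x) == 4L)
    return(contingency_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("cannot interpret input as a 2x2 contingency table", call. = FALSE)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("experimental", "control"),
                              c("endpoint+", "endpoint-")))
  cat("2x2 contingency table (n =", x$n, ")\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
         dimnames = list(c("experimental", "control"),
                         c("endpoint+", "endpoint-")))
}

# margins of a table (or recoded real-valued layout given as a named list)
table_margins <- function(tab) {
  c("a+b" = tab$a + tab$b, "c+d" = tab$c + tab$d,
    "a+c" = tab$a + tab$c, "b+d" = tab$b + tab$d)
}

check_margins <- function(tab) {
  m <- table_margins(tab)
  if (any(m <= 0)) {
    bad <- names(m)[m <= 0][1L]
    stop(sprintf("chi-squared statistic undefined: margin (%s) is empty", bad),
         call. = FALSE)
  }
  invisible(m)
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' The uncorrected (no continuity correction) statistic
#' \deqn{\chi^2 = \frac{n (ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}.}
#' Defined only when all four margins are positive. Real-valued (recoded)
#' cells are accepted via a named list with elements `a`, `b`, `c`, `d`.
#'
#' @param table A `contingency_table`, or anything [as_contingency_table()]
#'   accepts, or a list of (possibly real-valued) cells `a`, `b`, `c`, `d`.
#' @return The chi-squared statistic, a non-negative number; zero exactly
#'   when `ad = bc` (no association).
#' @examples
#' chi_squared(contingency_table(50, 50, 10, 90))
#' @export
chi_squared <- function(table) {
  tab <- if (is.list(table) && !inherits(table, "contingency_table") &&
             all(c("a", "b", "c", "d") %in% names(table))) table
         else as_contingency_table(table)
  check_margins(tab)
  n <- tab$a + tab$b + tab$c + tab$d
  n * (tab$a * tab$d - tab$b * tab$c)^2 /
    ((tab$a + tab$b) * (tab$c + tab$d) * (tab$a + tab$c) * (tab$b + tab$d))
}

#' Critical chi-squared value at a significance level
#'
#' Upper-`alpha` quantile of the chi-squared distribution with one degree of
#' freedom: the threshold the statistic of a 2x2 table must exceed for
#' significance at level `alpha`.
#'
#' @param alpha Significance level, strictly between 0 and 1.
#' @return The critical value `nu_c > 0`, strictly decreasing in `alpha`.
#' @examples
#' chisq_critical_value(0.05)  # 3.8415
#' @export
chisq_critical_value <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number strictly between 0 and 1",
         call. = FALSE)
  stats::qchisq(1 - alpha, df = 1)
}

#' Recode a 2x2 table along the fragility displacement directions
#'
#' Moves `x` participants in the experimental arm from endpoint-positive to
#' endpoint-negative and `y` participants in the control arm from
#' endpoint-negative to endpoint-positive, giving cells
#' `(a - x, b + x, c + y, d - y)`. Both displacements are continuous; row
#' margins and the total are unchanged by construction. Callers are
#' responsible for checking feasibility (non-negative cells).
#'
#' @param table A `contingency_table` (or coercible).
#' @param x,y Real-valued displacements.
#' @return A list of real-valued cells `a`, `b`, `c`, `d` (and `n`), suitable
#'   for [chi_squared()].
#' @export
recode_table <- function(table, x, y) {
  tab <- as_contingency_table(table)
  list(a = tab$a - x, b = tab$b + x, c = tab$c + y, d = tab$d - y, n = tab$n)
}

#' Is a 2x2 table significant at level alpha?
#'
#' @param table A `contingency_table` (or coercible).
#' @param alpha Significance level in (0, 1).
#' @return `TRUE` iff the chi-squared statistic strictly exceeds the critical
#'   value at `alpha`.
#' @examples
#' is_significant(contingency_table(50, 50, 10, 90), 0.05)
#' @export
is_significant <- function(table, alpha = 0.05) {
  chi_squared(table) > chisq_critical_value(alpha)
}

#' Invert a table to probe arm (rather than endpoint) miscoding
#'
#' Transposes the 2x2 layout, reassigning the endpoint-positive counts of the
#' two arms as the new experimental arm and the endpoint-negative counts as
#' the new control arm. Analysing the inverted table asks how many
#' participants could have been misallocated between the experimental and
#' control groups — instead of between endpoint states — before significance
#' is lost. The chi-squared statistic itself is unchanged by the inversion.
#'
#' @param table A `contingency_table` (or coercible).
#' @return The transposed `contingency_table` `(a, c, b, d)`.
#' @examples
#' invert_table(contingency_table(164, 530, 36, 183))
#' @export
invert_table <- function(table) {
  tab <- as_contingency_table(table)
  contingency_table(tab$a, tab$c, tab$b, tab$d)
}
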