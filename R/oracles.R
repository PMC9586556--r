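#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution; the two-sided p-value is the sum of the probabilities of
#' all tables (with the same margins) no more probable than the observed
#' one — the usual convention. Terms are accumulated from log-scale
#' hypergeometric masses, so there is no factorial overflow; tables up to
#' `n = 1e5` are accepted.
#'
#' @param table A `contingency_table` (or coercible).
#' @return The two-sided exact p-value.
#' @export
fisher_exact_p <- function(table) {
  tab <- as_contingency_table(table)
  if (tab$n > 1e5)
    stop("exact test guarded at n <= 1e5; use the chi-squared-based analysis for larger tables",
         call. = FALSE)
  m <- tab$a + tab$b          # experimental-arm size
  n2 <- tab$c + tab$d         # control-arm size
  k <- tab$a + tab$c          # endpoint-positive margin
  support <- max(0L, k - n2):min(k, m)
  logp <- stats::dhyper(support, m, n2, k, log = TRUE)
  logp_obs <- stats::dhyper(tab$a, m, n2, k, log = TRUE)
  # include terms within relative tolerance of the observed mass
  sum(exp(logp[logp <= logp_obs + log1p(1e-7)]))
}

#' Classic fragility index via Fisher's exact test
#'
#' The traditional fragility index: starting from a significant table,
#' recode participants one at a time from event to non-event in the arm with
#' the higher event rate (the direction that attenuates the observed
#' effect), recomputing the two-sided Fisher exact p-value, until it reaches
#' or exceeds `alpha`. The number of recodings is the index; a table that is
#' non-significant by Fisher's test without any recoding has index 0.
#'
#' Provided as a diagnostic companion to the geometric analysis: the two can
#' disagree for small counts, where the exact test and the chi-squared
#' statistic themselves disagree.
#'
#' @param table A `contingency_table` (or coercible).
#' @param alpha Significance level in (0, 1).
#' @return Object of class `"classic_fi"`: list with `fi` (integer), `arm`
#'   (`"experimental"` or `"control"`), and `p_trace` (p-value after each
#'   step, starting with the unrecoded table).
#' @examples
#' classic_fragility_index(contingency_table(9, 1, 3, 7))
#' @export
classic_fragility_index <- function(table, alpha = 0.05) {
  tab <- as_contingency_table(table)
  chisq_critical_value(alpha)  # validates alpha
  rate_e <- tab$a / (tab$a + tab$b)
  rate_c <- tab$c / (tab$c + tab$d)
  arm <- if (rate_e >= rate_c) "experimental" else "control"
  cur <- tab
  p <- fisher_exact_p(cur)
  p_trace <- p
  fi <- 0L
  while (p < alpha) {
    if (arm == "experimental") {
      if (cur$a == 0L) break
      cur <- contingency_table(cur$a - 1L, cur$b + 1L, cur$c, cur$d)
    } else {
      if (cur$c == 0L) break
      cur <- contingency_table(cur$a, cur$b, cur$c - 1L, cur$d + 1L)
    }
    fi <- fi + 1L
    p <- fisher_exact_p(cur)
    p_trace <- c(p_trace, p)
  }
  structure(list(fi = fi, arm = arm, p_trace = p_trace), class = "classic_fi")
}

#' @export
print.classic_fi <- function(x, ...) {
  cat(sprintf("classic fragility index: %d (%s arm recoded; final p = %.4g)\n",
              x$fi, x$arm, x$p_trace[length(x$p_trace)]))
  invisible(x)
}

#' Brute-force lattice scan of recoding displacements
#'
#' Exhaustive verification oracle: evaluates the recoded chi-squared
#' statistic at every feasible integer displacement `(x, y)` with
#' `|x|, |y| <= bound` (all recoded cells non-negative, recoded column
#' margins positive), records where significance is lost, checks the
#' conic-sign prediction at every point, and reports the minimal
#' `|x| + |y|` displacement that removes significance.
#'
#' @param table A `contingency_table` (or coercible).
#' @param alpha Significance level in (0, 1).
#' @param bound Positive integer scan radius.
#' @return List with `min_L1` (integer, or `NA` if no witness within the
#'   bound), `witness` (the `(x, y)` achieving it), `n_points` scanned,
#'   `n_disagree` (points where the conic sign contradicts the chi-squared
#'   comparison) and `disagreements` (their coordinates, if any).
#' @export
lattice_scan <- function(table, alpha = 0.05, bound = 50L) {
  tab <- as_contingency_table(table)
  stopifnot(bound >= 1)
  nu_c <- chisq_critical_value(alpha)
  coeffs <- ellipse_coefficients(tab, alpha)
  g <- expand.grid(x = -bound:bound, y = -bound:bound)
  aa <- tab$a - g$x; bb <- tab$b + g$x; cc <- tab$c + g$y; dd <- tab$d - g$y
  feas <- aa >= 0 & bb >= 0 & cc >= 0 & dd >= 0 & (aa + cc) > 0 & (bb + dd) > 0
  g <- g[feas, ]; aa <- aa[feas]; bb <- bb[feas]; cc <- cc[feas]; dd <- dd[feas]
  chi2 <- tab$n * (aa * dd - bb * cc)^2 /
    ((aa + bb) * (cc + dd) * (aa + cc) * (bb + dd))
  insig <- chi2 <= nu_c
  conic_in <- eoi_contains(coeffs, g$x, g$y)
  dis <- which(insig != conic_in)
  L1 <- abs(g$x) + abs(g$y)
  if (any(insig)) {
    i <- which(insig)[which.min(L1[insig])]
    min_L1 <- L1[i]; witness <- c(x = g$x[i], y = g$y[i])
  } else {
    min_L1 <- NA_integer_; witness <- NULL
  }
  list(min_L1 = min_L1, witness = witness, n_points = nrow(g),
       n_disagree = length(dis),
       disagreements = if (length(dis)) cbind(x = g$x[dis], y = g$y[dis])
                       else NULL)
}

#' Generate reproducible fixture tables
#'
#' Seeded random 2x2 tables in a requested significance regime at
#' alpha = 0.05, for property testing. Regimes: `"significant"`
#' (chi-squared above the 0.05 critical value), `"borderline"` (statistic
#' within roughly one unit of it), `"null"` (at or below it), and
#' `"large-n"` (significant tables with about a million participants). Each
#' table carries its chi-squared statistic as attribute `"chi_squared"`.
#' The caller's random-number state is left untouched.
#'
#' @param count Number of tables.
#' @param seed Integer seed; identical seeds give identical lists.
#' @param regime One of `"significant"`, `"borderline"`, `"null"`,
#'   `"large-n"`.
#' @param file Optional path: also write the tables as delimited text with
#'   columns `a,b,c,d,alpha` (comma-separated), the batch-input format.
#' @return List of `contingency_table` objects.
#' @export
generate_fixture_tables <- function(count, seed,
                                    regime = c("significant", "borderline",
                                               "null", "large-n"),
                                    file = NULL) {
  regime <- match.arg(regime)
  stopifnot(count >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  nu_c <- chisq_critical_value(0.05)

  draw <- function() {
    if (regime == "large-n") {
      arm <- round(stats::runif(2, 3e5, 7e5))
      p1 <- stats::runif(1, 0.05, 0.5)
      p2 <- p1 * stats::runif(1, 1.01, 1.3)
      a <- stats::rbinom(1, arm[1], p2); cc <- stats::rbinom(1, arm[2], p1)
      contingency_table(a, arm[1] - a, cc, arm[2] - cc)
    } else {
      arm <- round(stats::runif(2, 20, 200))
      p1 <- stats::runif(1, 0.1, 0.9)
      p2 <- switch(regime,
                   significant = stats::runif(1, 0.1, 0.9),
                   borderline = p1,
                   null = p1)
      a <- stats::rbinom(1, arm[1], p2); cc <- stats::rbinom(1, arm[2], p1)
      contingency_table(a, arm[1] - a, cc, arm[2] - cc)
    }
  }
  ok <- function(tab) {
    m <- table_margins(tab)
    if (any(m <= 0)) return(FALSE)
    chi2 <- chi_squared(tab)
    switch(regime,
           significant = chi2 > nu_c,
           borderline = chi2 > nu_c - 1 && chi2 < nu_c + 1.2,
           null = chi2 <= nu_c,
           `large-n` = chi2 > nu_c)
  }

  out <- vector("list", count)
  for (i in seq_len(count)) {
    tries <- 0L
    repeat {
      tab <- draw()
      tries <- tries + 1L
      if (ok(tab)) break
      if (tries > 20000L)
        stop("fixture generation failed: regime '", regime,
             "' not reachable with current parameters", call. = FALSE)
    }
    attr(tab, "chi_squared") <- chi_squared(tab)
    out[[i]] <- tab
  }
  if (!is.null(file)) {
    df <- do.call(rbind, lapply(out, function(t)
      data.frame(a = t$a, b = t$b, c = t$c, d = t$d, alpha = 0.05)))
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  }
  out
}
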