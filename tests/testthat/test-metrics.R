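test_that("tolerance thresholds reproduce the published-study worked example", {
  fit <- eoi(164, 530, 36, 183, alpha = 0.05)
  expect_lt(abs(100 * fit$epsilon$epsilon_E - 0.99), 0.05)
  expect_lt(abs(100 * fit$epsilon$epsilon_C - 0.89), 0.05)
  expect_lt(abs(100 * fit$epsilon$epsilon_A - 0.22), 0.05)
  # fraction identities against the geometry
  expect_equal(fit$epsilon$epsilon_E, abs(fit$intercepts$x_i) / 694)
  expect_equal(fit$epsilon$epsilon_C, abs(fit$intercepts$y_i) / 219)
  expect_equal(fit$epsilon$epsilon_A, fit$feckup$d_min / 913)
  expect_equal(fit$epsilon$epsilon_A * 913, fit$feckup$d_min)
  # integer-floored variants never exceed the continuous ones
  expect_lte(fit$epsilon$epsilon_E_int, fit$epsilon$epsilon_E)
  expect_lte(fit$epsilon$epsilon_C_int, fit$epsilon$epsilon_C)
})

test_that("tolerances shrink as alpha tightens, matching the two-experiment comparison", {
  alphas <- c(0.05, 0.01, 0.001, 0.0001)
  for (cells in list(c(770, 230, 550, 450), c(144, 856, 20, 980))) {
    eps <- t(sapply(alphas, function(al) {
      f <- eoi(cells[1], cells[2], cells[3], cells[4], alpha = al)
      c(f$epsilon$epsilon_E, f$epsilon$epsilon_C, f$epsilon$epsilon_A)
    }))
    expect_true(all(diff(eps[, 1]) <= 1e-12))
    expect_true(all(diff(eps[, 2]) <= 1e-12))
    expect_true(all(diff(eps[, 3]) <= 1e-12))
  }
})

test_that("a non-significant table reports zero tolerances with a flag", {
  fit <- eoi(10, 10, 10, 10)
  expect_false(fit$significant)
  expect_equal(fit$epsilon$epsilon_E, 0)
  expect_equal(fit$epsilon$epsilon_C, 0)
  expect_equal(fit$epsilon$epsilon_A, 0)
  expect_match(fit$flags, "not significant", all = FALSE)
})

test_that("a missing axis crossing caps the arm tolerance at 100% with a flag", {
  # unreachable from valid tables (both crossings provably exist when all
  # margins are positive), so the defensive path is exercised directly
  tab <- contingency_table(50, 50, 10, 90)
  sol <- feckup_point(ellipse_coefficients(tab, 0.05))
  eps <- eoi:::tolerance_metrics(tab, list(x_i = NA_real_, y_i = 26.27), sol)
  expect_equal(eps$epsilon_E, 1)
  expect_match(eps$flags, "cannot remove significance", all = FALSE)
})

test_that("test-implied miscoding follows the sensitivity/specificity identity", {
  est <- minimum_miscoding(contingency_table(113, 887, 24, 976),
                           sens_exp = 0.75, spec_exp = 0.90, both_arms = FALSE)
  expect_equal(est$x_m, (88.7 - 28.25) / 0.65)  # = 93 exactly
  expect_equal(est$x_m, 93)
  expect_equal(est$y_m, 0)
  # perfect test implies zero guaranteed miscoding
  perfect <- minimum_miscoding(contingency_table(113, 887, 24, 976), 1, 1)
  expect_equal(perfect$x_m, 0)
  expect_equal(perfect$y_m, 0)
  expect_error(minimum_miscoding(contingency_table(5, 5, 5, 5), 0.4, 0.6),
               "[Uu]ninformative")
  expect_error(minimum_miscoding(contingency_table(5, 5, 5, 5), 0.9, 0.9,
                                 sens_ctl = 0.3, spec_ctl = 0.7),
               "control-arm")
  expect_error(minimum_miscoding(contingency_table(5, 5, 5, 5), 1.2, 0.9),
               "probability")
})

test_that("misclassifying known true counts at expectation is recovered exactly", {
  set.seed(53)
  for (i in 1:25) {
    n_e <- sample(50:5000, 1)
    a_o <- sample(0:n_e, 1)
    sn <- runif(1, 0.55, 1)
    sp <- runif(1, 0.55, 1)
    a_obs <- a_o * sn + (n_e - a_o) * (1 - sp)
    est <- minimum_miscoding(list(a = a_obs, b = n_e - a_obs, c = 1, d = 1),
                             sens_exp = sn, spec_exp = sp, both_arms = FALSE)
    expect_equal(est$x_m, a_obs - a_o, tolerance = 1e-12)
  }
})

test_that("the robustness verdict matches re-testing the corrected counts", {
  # screening example: guaranteed miscoding exceeds the single-arm tolerance
  fit <- eoi(113, 887, 24, 976, sens_exp = 0.75, spec_exp = 0.90,
             sens_ctl = NA)
  expect_equal(fit$verdict, "not robust")
  expect_true(eoi_contains(fit$coefficients, 93, 0))
  # perfect tests leave the origin, which is outside the ellipse
  fit_perfect <- eoi(113, 887, 24, 976, sens_exp = 1, spec_exp = 1)
  expect_equal(fit_perfect$verdict, "robust")
  # a boundary point counts as inside
  k <- fit$coefficients
  x_i <- axis_intercepts(k)$x_i
  expect_equal(robustness_verdict(k, list(x_m = x_i, y_m = 0)), "not robust")

  # equivalence with recoding by (x_m, y_m) and re-testing at the same level
  set.seed(59)
  nu_c <- chisq_critical_value(0.05)
  checked <- 0
  for (cells in random_cells(40, seed = 59, lo = 5, hi = 300)) {
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    if (!is_significant(tab, 0.05)) next
    sn <- runif(1, 0.6, 1); sp <- runif(1, 0.6, 1)
    est <- minimum_miscoding(tab, sn, sp)
    rec <- recode_table(tab, est$x_m, est$y_m)
    if (rec$a + rec$c <= 0 || rec$b + rec$d <= 0) next
    verdict <- robustness_verdict(ellipse_coefficients(tab, 0.05), est)
    corrected_chi2 <- chi2_direct(rec$a, rec$b, rec$c, rec$d)
    expect_identical(verdict == "not robust", corrected_chi2 <= nu_c)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("table inversion transposes, involutes and preserves the statistic", {
  tab <- contingency_table(164, 530, 36, 183)
  inv <- invert_table(tab)
  expect_equal(unlist(inv[c("a", "b", "c", "d")]),
               c(a = 164, b = 36, c = 530, d = 183))
  expect_equal(unlist(invert_table(inv)[c("a", "b", "c", "d")]),
               unlist(tab[c("a", "b", "c", "d")]))
  expect_equal(chi_squared(inv), chi_squared(tab))
  # the fitted interface applies it before analysis
  expect_equal(eoi(164, 530, 36, 183, invert = TRUE)$table$b, 36)
})
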