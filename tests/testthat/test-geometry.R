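test_that("conic coefficients describe an ellipse whose origin value flags significance", {
  for (cells in random_cells(40, seed = 31)) {
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    k <- ellipse_coefficients(tab, 0.05)
    cf <- k$coef
    expect_lt(cf[["B"]]^2 - 4 * cf[["A"]] * cf[["C"]], 0)
    expect_equal(conic_value(k, 0, 0), cf[["F"]])
    expect_identical(cf[["F"]] > 0, is_significant(tab, 0.05))
  }
})

test_that("conic sign agrees with the recoded chi-squared comparison", {
  for (cells in random_cells(12, seed = 37)) {
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    k <- ellipse_coefficients(tab, 0.05)
    nu_c <- chisq_critical_value(0.05)
    xs <- sample(seq(-tab$b, tab$a), 15, replace = TRUE)
    ys <- sample(seq(-tab$c, tab$d), 15, replace = TRUE)
    for (x in xs) for (y in ys) {
      rec <- recode_table(tab, x, y)
      if (rec$a + rec$c <= 0 || rec$b + rec$d <= 0) next
      chi2 <- chi2_direct(rec$a, rec$b, rec$c, rec$d)
      expect_identical(eoi_contains(k, x, y), chi2 <= nu_c)
    }
  }
})

test_that("nearest-point solution reproduces the worked minimal-recoding examples", {
  fp <- feckup_point(ellipse_coefficients(contingency_table(50, 50, 10, 90), 0.05))
  expect_equal(fp$x_e, 12.8, tolerance = 0.05 / 12.8)
  expect_equal(fp$y_e, 14.4, tolerance = 0.05 / 14.4)
  expect_equal(fp$f_min, 19.3, tolerance = 0.05 / 19.3)
  expect_equal(fp$d_min, 27L)
  expect_lt(fp$residual, 1e-9)
  expect_equal(sqrt(fp$x_e^2 + fp$y_e^2), fp$f_min)
  expect_true(fp$feasible)

  fp1 <- feckup_point(ellipse_coefficients(contingency_table(164, 530, 36, 183), 0.05))
  expect_equal(fp1$f_min, 1.9, tolerance = 0.05 / 1.9)

  expect_equal(feckup_point(ellipse_coefficients(contingency_table(770, 230, 550, 450), 0.05))$d_min, 178L)
  expect_equal(feckup_point(ellipse_coefficients(contingency_table(144, 856, 20, 980), 0.05))$d_min, 99L)
})

test_that("a non-significant table yields the degenerate zero solution", {
  fp <- feckup_point(ellipse_coefficients(contingency_table(10, 10, 10, 10), 0.05))
  expect_true(fp$degenerate)
  expect_equal(c(fp$x_e, fp$y_e, fp$f_min), c(0, 0, 0))
  expect_equal(d_min(fp), 0L)
})

test_that("the nearest point satisfies both governing equations and beats all boundary points", {
  for (cells in random_cells(8, seed = 41)) {
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    if (!is_significant(tab, 0.05)) next
    k <- ellipse_coefficients(tab, 0.05)
    fp <- feckup_point(k)
    expect_lt(fp$residual, 1e-9)
    # conic residual at the point, relative to term scale
    cf <- k$coef
    scale <- sum(abs(cf) * c(fp$x_e^2, abs(fp$x_e * fp$y_e), fp$y_e^2,
                             abs(fp$x_e), abs(fp$y_e), 1))
    expect_lt(abs(conic_value(k, fp$x_e, fp$y_e)) / scale, 1e-9)
    bd <- ellipse_boundary(k, 2000L)
    expect_gte(min(sqrt(rowSums(bd^2))), fp$f_min - 1e-6 * fp$f_min)
  }
})

test_that("axis intercepts reproduce the worked single-arm tolerances", {
  ic1 <- axis_intercepts(ellipse_coefficients(contingency_table(164, 530, 36, 183), 0.05))
  expect_equal(ic1$x_i, 6.9, tolerance = 0.05 / 6.9)
  expect_equal(ic1$y_i, 1.9, tolerance = 0.05 / 1.9)

  ic2 <- axis_intercepts(ellipse_coefficients(contingency_table(50, 50, 10, 90), 0.05))
  expect_equal(ic2$x_i, 30.1, tolerance = 0.05 / 30.1)
  expect_equal(ic2$y_i, 26.3, tolerance = 0.05 / 26.3)

  ic3 <- axis_intercepts(ellipse_coefficients(contingency_table(113, 887, 24, 976), 0.05))
  expect_equal(ic3$y_i, 62.7, tolerance = 0.05 / 62.7)
  # intercepts are points of the same ellipse, so f_min cannot exceed them
  fp <- feckup_point(ellipse_coefficients(contingency_table(113, 887, 24, 976), 0.05))
  expect_lte(fp$f_min, min(abs(ic3$x_i), abs(ic3$y_i)) + 1e-9)
  # each intercept satisfies the conic to tolerance
  k <- ellipse_coefficients(contingency_table(113, 887, 24, 976), 0.05)
  expect_lt(abs(conic_value(k, ic3$x_i, 0)) / max(abs(k$coef)), 1e-9)
  expect_lt(abs(conic_value(k, 0, ic3$y_i)) / max(abs(k$coef)), 1e-9)
})

test_that("tightening alpha shrinks every fragility measure", {
  tabs <- list(contingency_table(770, 230, 550, 450),
               contingency_table(144, 856, 20, 980),
               contingency_table(50, 50, 10, 90))
  alphas <- c(0.05, 0.01, 0.001, 0.0001)
  for (tab in tabs) {
    fits <- lapply(alphas, function(al) eoi(tab, alpha = al))
    f_min <- sapply(fits, function(f) f$feckup$f_min)
    x_i <- sapply(fits, function(f) abs(f$intercepts$x_i))
    y_i <- sapply(fits, function(f) abs(f$intercepts$y_i))
    dm <- sapply(fits, function(f) f$feckup$d_min)
    expect_true(all(diff(f_min) <= 1e-9))
    expect_true(all(diff(x_i) <= 1e-9))
    expect_true(all(diff(y_i) <= 1e-9))
    expect_true(all(diff(dm) <= 0))
  }
})

test_that("recoding by the solution removes significance; smaller single-arm recodes do not", {
  for (cells in random_cells(10, seed = 47)) {
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    if (!is_significant(tab, 0.05)) next
    fit <- eoi(tab)
    nu_c <- fit$nu_c
    # push slightly beyond the nearest point, along it
    gr <- 1.0001
    rec <- recode_table(tab, gr * fit$feckup$x_e, gr * fit$feckup$y_e)
    if (rec$a + rec$c > 0 && rec$b + rec$d > 0)
      expect_lte(chi2_direct(rec$a, rec$b, rec$c, rec$d), nu_c)
    # single-axis displacement short of the intercept keeps significance
    x_in <- 0.98 * fit$intercepts$x_i
    rec_x <- recode_table(tab, x_in, 0)
    if (rec_x$a + rec_x$c > 0 && rec_x$b + rec_x$d > 0)
      expect_gt(chi2_direct(rec_x$a, rec_x$b, rec_x$c, rec_x$d), nu_c)
    y_in <- 0.98 * fit$intercepts$y_i
    rec_y <- recode_table(tab, 0, y_in)
    if (rec_y$a + rec_y$c > 0 && rec_y$b + rec_y$d > 0)
      expect_gt(chi2_direct(rec_y$a, rec_y$b, rec_y$c, rec_y$d), nu_c)
  }
})

test_that("the outer integer polygon encloses the ellipse; the inner one is inscribed", {
  tab <- contingency_table(50, 50, 10, 90)
  poly <- polygon_of_insignificance(tab, 0.05)
  expect_true(is.integer(poly))
  # counter-clockwise orientation (positive signed area)
  xs <- poly[, 1]; ys <- poly[, 2]
  area2 <- sum(xs * ys[c(2:nrow(poly), 1)] - xs[c(2:nrow(poly), 1)] * ys)
  expect_gt(area2, 0)
  # starts at minimum x (then minimum y)
  expect_equal(unname(poly[1, 1]), min(xs))
  k <- ellipse_coefficients(tab, 0.05)
  bd <- ellipse_boundary(k, 500L)
  expect_true(all(vapply(seq_len(nrow(bd)), function(i)
    pip_raycast(poly, bd[i, 1], bd[i, 2]), logical(1))))
  expect_true(polygon_contains(poly, 13, 15))

  inner <- polygon_of_insignificance(tab, 0.05, type = "inner")
  expect_true(all(eoi_contains(k, inner[, 1], inner[, 2])))

  expect_error(polygon_of_insignificance(contingency_table(10, 10, 10, 10)),
               "not significant")
})
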