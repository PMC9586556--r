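#' Coefficients of the ellipse of insignificance
#'
#' Substituting the recoded cells `(a - x, b + x, c + y, d - y)` into the
#' chi-squared statistic, setting it equal to the critical value `nu_c` and
#' clearing the (positive) denominator gives a conic
#' \deqn{A x^2 + B x y + C y^2 + D x + E y + F = 0,}
#' which for any table with positive margins and `0 < nu_c < n` is an
#' inclined ellipse. Its interior is exactly the set of simultaneous
#' displacements under which the recoded table is no longer significant.
#'
#' The coefficients, with `n = a+b+c+d`:
#' \deqn{A = (c+d)\,[(c+d)n + (a+b)\nu_c]}
#' \deqn{B = 2(a+b)(c+d)(n - \nu_c)}
#' \deqn{C = (a+b)\,[(a+b)n + (c+d)\nu_c]}
#' \deqn{D = (c+d)\,[2(bc-ad)n + (a+b)(b-a+d-c)\nu_c]}
#' \deqn{E = (a+b)\,[2(bc-ad)n + (c+d)(a-b+c-d)\nu_c]}
#' \deqn{F = (bc-ad)^2 n - (a+b)(a+c)(b+d)(c+d)\nu_c}
#'
#' `F` is the conic value at the origin and is positive exactly when the
#' unrecoded table is significant at `alpha`.
#'
#' @param table A `contingency_table` (or coercible).
#' @param alpha Significance level in (0, 1).
#' @return An object of class `"eoi_coefficients"`: list with the named
#'   coefficient vector `coef` (`A`..`F`), `nu_c`, `n`, `alpha` and the
#'   originating `table`.
#' @examples
#' ellipse_coefficients(contingency_table(50, 50, 10, 90), 0.05)
#' @export
ellipse_coefficients <- function(table, alpha = 0.05) {
  tab <- as_contingency_table(table)
  check_margins(tab)
  nu_c <- chisq_critical_value(alpha)
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d; n <- tab$n
  cf <- c(
    A = (c + d) * ((c + d) * n + (a + b) * nu_c),
    B = 2 * (a + b) * (c + d) * (n - nu_c),
    C = (a + b) * ((a + b) * n + (c + d) * nu_c),
    D = (c + d) * (2 * (b * c - a * d) * n + (a + b) * (b - a + d - c) * nu_c),
    E = (a + b) * (2 * (b * c - a * d) * n + (c + d) * (a - b + c - d) * nu_c),
    F = (b * c - a * d)^2 * n - (a + b) * (a + c) * (b + d) * (c + d) * nu_c
  )
  structure(list(coef = cf, nu_c = nu_c, n = n, alpha = alpha, table = tab),
            class = "eoi_coefficients")
}

#' @export
print.eoi_coefficients <- function(x, ...) {
  cat("Ellipse-of-insignificance conic (alpha =", x$alpha,
      ", nu_c =", format(x$nu_c, digits = 6), ")\n")
  print(x$coef)
  invisible(x)
}

coef_vector <- function(coeffs) {
  if (inherits(coeffs, "eoi_coefficients")) coeffs$coef
  else if (is.numeric(coeffs) && length(coeffs) == 6L)
    stats::setNames(coeffs, c("A", "B", "C", "D", "E", "F"))
  else stop("expected an 'eoi_coefficients' object", call. = FALSE)
}

#' Evaluate the insignificance conic
#'
#' Returns `A x^2 + B x y + C y^2 + D x + E y + F`, vectorised over `x`, `y`.
#' Negative strictly inside the ellipse of insignificance, positive outside,
#' zero (to tolerance) on its boundary.
#'
#' @param coeffs An [ellipse_coefficients()] object.
#' @param x,y Displacement coordinates (recycled together).
#' @return Numeric vector of conic values.
#' @export
conic_value <- function(coeffs, x, y) {
  k <- coef_vector(coeffs)
  k[["A"]] * x^2 + k[["B"]] * x * y + k[["C"]] * y^2 +
    k[["D"]] * x + k[["E"]] * y + k[["F"]]
}

#' Does a displacement fall within the ellipse of insignificance?
#'
#' Boundary points count as inside: any displacement on or within the
#' ellipse leaves the recoded table below the significance threshold.
#'
#' @inheritParams conic_value
#' @return Logical vector: `TRUE` where `conic_value(coeffs, x, y) <= 0`.
#' @export
eoi_contains <- function(coeffs, x, y) {
  conic_value(coeffs, x, y) <= 0
}

# Principal-axis frame of the ellipse: center, rotation matrix (columns are
# the axis directions), semi-axis lengths. Coefficients are normalised by
# their largest magnitude first, purely for conditioning; the curve is
# unchanged. Errors if the conic is not a real ellipse.
ellipse_frame <- function(coeffs) {
  k <- coef_vector(coeffs)
  k <- k / max(abs(k))
  A <- k[["A"]]; B <- k[["B"]]; C <- k[["C"]]
  D <- k[["D"]]; E <- k[["E"]]; F <- k[["F"]]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0)
    stop("conic is not an ellipse (discriminant >= 0)", call. = FALSE)
  center <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  f0 <- F + (D * center[1] + E * center[2]) / 2  # conic value at center
  if (f0 >= 0)
    stop("degenerate ellipse: no real boundary (table not significant at this level?)",
         call. = FALSE)
  eg <- eigen(matrix(c(A, B / 2, B / 2, C), 2, 2), symmetric = TRUE)
  # eigen() sorts decreasing; keep that order, axes follow the eigenvectors
  semi <- sqrt(-f0 / eg$values)
  list(center = center, rotation = eg$vectors, semi = semi, f_center = f0)
}

#' Sample points on the ellipse boundary
#'
#' Parametric boundary samples, mainly for plotting, geometry export and
#' verification; every returned point satisfies the conic equation to
#' numerical tolerance.
#'
#' @param coeffs An [ellipse_coefficients()] object.
#' @param n_points Number of samples (default 360).
#' @return A two-column matrix with columns `x`, `y`.
#' @export
ellipse_boundary <- function(coeffs, n_points = 360L) {
  fr <- ellipse_frame(coeffs)
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  pts <- fr$rotation %*% rbind(fr$semi[1] * cos(th), fr$semi[2] * sin(th)) +
    fr$center
  out <- t(pts)
  colnames(out) <- c("x", "y")
  out
}

# All real candidate nearest/farthest points of the ellipse from the origin,
# via the Lagrange quartic for an axis-aligned ellipse u^2/p^2 + v^2/q^2 = 1
# and query point (u0, v0):  (p u0)^2 (t+q^2)^2 + (q v0)^2 (t+p^2)^2
#                            = (t+p^2)^2 (t+q^2)^2.
# Returns a matrix of candidate points in the original (x, y) frame.
critical_points_origin <- function(frame) {
  p <- frame$semi[1]; q <- frame$semi[2]
  w <- drop(t(frame$rotation) %*% (-frame$center))  # origin in ellipse frame
  u0 <- w[1]; v0 <- w[2]
  p2 <- p^2; q2 <- q^2
  scale_uv <- max(abs(u0), abs(v0), p, q)
  tiny <- 1e-12 * scale_uv
  cand <- NULL
  if (abs(u0) <= tiny || abs(v0) <= tiny) {
    # origin on a principal axis: quartic degenerates; enumerate directly
    if (abs(u0) <= tiny && abs(v0) <= tiny) {
      cand <- rbind(c(p, 0), c(-p, 0), c(0, q), c(0, -q))
    } else if (abs(v0) <= tiny) {
      cand <- rbind(c(p, 0), c(-p, 0))
      # off-axis critical points exist when |u0| < p (1 - q^2/p^2)
      u <- p2 * u0 / (p2 - q2)
      if (is.finite(u) && abs(u) < p) {
        v <- q * sqrt(max(0, 1 - u^2 / p2))
        cand <- rbind(cand, c(u, v), c(u, -v))
      }
    } else {
      cand <- rbind(c(0, q), c(0, -q))
      v <- q2 * v0 / (q2 - p2)
      if (is.finite(v) && abs(v) < q) {
        u <- p * sqrt(max(0, 1 - v^2 / q2))
        cand <- rbind(cand, c(u, v), c(-u, v))
      }
    }
  } else {
    conv <- function(x, y) {
      r <- numeric(length(x) + length(y) - 1L)
      for (i in seq_along(x)) r[i:(i + length(y) - 1L)] <-
          r[i:(i + length(y) - 1L)] + x[i] * y
      r
    }
    sq <- function(s) c(s^2, 2 * s, 1)  # (t + s)^2, ascending powers
    poly <- (p * u0)^2 * c(sq(q2), 0, 0) +
            (q * v0)^2 * c(sq(p2), 0, 0) -
            conv(sq(p2), sq(q2))
    poly <- poly / max(abs(poly))
    rt <- polyroot(poly)  # ascending coefficient order
    keep <- abs(Im(rt)) <= 1e-8 * (Mod(rt) + 1)
    tt <- Re(rt[keep])
    cand <- cbind(p2 * u0 / (tt + p2), q2 * v0 / (tt + q2))
  }
  pts <- t(frame$rotation %*% t(cand) + frame$center)
  colnames(pts) <- c("x", "y")
  pts
}

# Newton polish of a candidate (x, y) on the simultaneous system
#   g1 = (2Ax + By + D) y - x (Bx + 2Cy + E) = 0   (stationarity)
#   g2 = Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0       (on the ellipse)
# using normalised coefficients. Returns the polished point and the relative
# residuals of both equations.
polish_newton <- function(k, x, y, steps = 3L) {
  A <- k[["A"]]; B <- k[["B"]]; C <- k[["C"]]
  D <- k[["D"]]; E <- k[["E"]]; F <- k[["F"]]
  for (i in seq_len(steps)) {
    g1 <- 2 * A * x * y + B * y^2 + D * y - B * x^2 - 2 * C * x * y - E * x
    g2 <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
    J <- matrix(c(2 * A * y - 2 * B * x - 2 * C * y - E,
                  2 * A * x + 2 * B * y + D - 2 * C * x,
                  2 * A * x + B * y + D,
                  B * x + 2 * C * y + E), 2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, c(g1, g2)), error = function(e) c(0, 0))
    if (!all(is.finite(step))) break
    x <- x - step[1]; y <- y - step[2]
  }
  s1 <- abs(2 * A * x * y) + abs(B * y^2) + abs(D * y) + abs(B * x^2) +
    abs(2 * C * x * y) + abs(E * x)
  s2 <- abs(A * x^2) + abs(B * x * y) + abs(C * y^2) + abs(D * x) +
    abs(E * y) + abs(F)
  g1 <- 2 * A * x * y + B * y^2 + D * y - B * x^2 - 2 * C * x * y - E * x
  g2 <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
  list(x = x, y = y,
       residual = max(abs(g1) / max(s1, .Machine$double.xmin),
                      abs(g2) / max(s2, .Machine$double.xmin)))
}

#' Nearest point of the ellipse of insignificance to the origin
#'
#' The point `(x_e, y_e)` on the ellipse boundary closest (Euclidean) to the
#' origin is the smallest simultaneous recoding of the two arms that removes
#' significance: `x_e` participants in the experimental arm and `y_e` in the
#' control arm. Its length is `f_min` and the integer bound on combined
#' miscoding is `d_min = floor(|x_e| + |y_e|)`.
#'
#' Stationary points of the squared distance on the conic satisfy a pair of
#' simultaneous equations whose elimination yields a quartic with (up to)
#' four real solutions; all candidates are computed, polished with a few
#' Newton steps on the original system, and the one nearest the origin is
#' selected. If the table is not significant at the configured level the
#' origin itself is already inside the region of insignificance and the
#' degenerate solution `(0, 0)` is returned, flagged accordingly.
#'
#' @param coeffs An [ellipse_coefficients()] object.
#' @return An object of class `"feckup"`: list with `x_e`, `y_e`, `f_min`,
#'   `d_min`, the candidate matrix `all_roots`, the maximum relative
#'   `residual` of the two governing equations at the solution, a `feasible`
#'   flag (`FALSE` when the implied recoded table would need a negative
#'   cell), and `degenerate` (`TRUE` for an already-insignificant table).
#' @examples
#' feckup_point(ellipse_coefficients(contingency_table(50, 50, 10, 90), 0.05))
#' @export
feckup_point <- function(coeffs) {
  if (!inherits(coeffs, "eoi_coefficients"))
    stop("expected an 'eoi_coefficients' object", call. = FALSE)
  tab <- coeffs$table
  if (coeffs$coef[["F"]] <= 0) {
    return(structure(list(x_e = 0, y_e = 0, f_min = 0, d_min = 0L,
                          all_roots = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL, c("x", "y"))),
                          residual = 0, feasible = TRUE, degenerate = TRUE),
                     class = "feckup"))
  }
  fr <- ellipse_frame(coeffs)
  cand <- critical_points_origin(fr)
  if (nrow(cand) == 0L)
    stop("no real solution found for the nearest-point system; conic may be degenerate",
         call. = FALSE)
  knorm <- coeffs$coef / max(abs(coeffs$coef))
  polished <- lapply(seq_len(nrow(cand)), function(i)
    polish_newton(knorm, cand[i, 1], cand[i, 2]))
  pts <- do.call(rbind, lapply(polished, function(p) c(p$x, p$y)))
  colnames(pts) <- c("x", "y")
  dist <- sqrt(rowSums(pts^2))
  best <- which.min(dist)
  x_e <- unname(pts[best, 1]); y_e <- unname(pts[best, 2])
  feasible <- (tab$a - x_e >= 0) && (tab$b + x_e >= 0) &&
    (tab$c + y_e >= 0) && (tab$d - y_e >= 0)
  structure(list(x_e = x_e, y_e = y_e,
                 f_min = dist[best],
                 d_min = as.integer(floor(abs(x_e) + abs(y_e))),
                 all_roots = pts,
                 residual = polished[[best]]$residual,
                 feasible = feasible,
                 degenerate = FALSE),
            class = "feckup")
}

#' @export
print.feckup <- function(x, ...) {
  if (x$degenerate) {
    cat("FECKUP point: table already insignificant; (0, 0)\n")
  } else {
    cat(sprintf("FECKUP point (x_e, y_e) = (%.4g, %.4g); f_min = %.4g; d_min = %d\n",
                x$x_e, x$y_e, x$f_min, x$d_min))
    if (!x$feasible)
      cat("note: displacement exceeds available counts (infeasible as literal recoding)\n")
  }
  invisible(x)
}

#' Integer bound on combined miscoding
#'
#' `d_min = floor(|x_e| + |y_e|)`: since participants come in whole numbers,
#' this is the largest whole number of combined (both-arm) miscodings that is
#' still guaranteed insufficient to remove significance.
#'
#' @param solution A [feckup_point()] result.
#' @return Integer `d_min`.
#' @export
d_min <- function(solution) {
  stopifnot(inherits(solution, "feckup"))
  solution$d_min
}

# stable quadratic roots of  alpha t^2 + beta t + gamma = 0 (alpha != 0);
# returns NULL when complex
quad_roots <- function(alpha, beta, gamma) {
  disc <- beta^2 - 4 * alpha * gamma
  if (!is.finite(disc) || disc < 0) return(NULL)
  if (beta == 0) {
    r <- sqrt(disc) / (2 * alpha)
    return(c(-r, r))
  }
  qq <- -(beta + sign(beta) * sqrt(disc)) / 2
  c(qq / alpha, gamma / qq)
}

#' Axis intercepts of the ellipse of insignificance
#'
#' Single-arm tolerances: setting `y = 0` in the conic leaves the quadratic
#' `A x^2 + D x + F = 0`, whose root of smallest magnitude, `x_i`, is the
#' nearest point at which experimental-arm recoding alone removes
#' significance; likewise `C y^2 + E y + F = 0` gives `y_i` for the control
#' arm. When the ellipse does not cross an axis (negative discriminant) no
#' amount of single-arm recoding can remove significance and the intercept is
#' `NA`. Ties between roots of equal magnitude are broken toward the positive
#' (effect-attenuating) direction.
#'
#' @param coeffs An [ellipse_coefficients()] object.
#' @return List with elements `x_i` and `y_i` (each a number or `NA`).
#' @examples
#' axis_intercepts(ellipse_coefficients(contingency_table(164, 530, 36, 183)))
#' @export
axis_intercepts <- function(coeffs) {
  k <- coef_vector(coeffs) / max(abs(coef_vector(coeffs)))
  pick <- function(r) {
    if (is.null(r)) return(NA_real_)
    i <- order(abs(r), -r)[1L]  # smallest magnitude, positive wins ties
    r[i]
  }
  list(x_i = pick(quad_roots(k[["A"]], k[["D"]], k[["F"]])),
       y_i = pick(quad_roots(k[["C"]], k[["E"]], k[["F"]])))
}

#' Integer polygon enclosing (or inscribed in) the ellipse
#'
#' Because participants come in whole numbers, the continuous ellipse is
#' usefully replaced by an integer-valued polygon. The default `"outer"`
#' dialect is the smallest convex lattice polygon found by taking, for each
#' integer abscissa the ellipse spans, the floor/ceiling of the conic's
#' y-interval endpoints (plus the lattice cells around densely sampled
#' boundary points, so the whole ellipse is provably enclosed) and forming
#' the convex hull. The `"inner"` dialect is the convex hull of the lattice
#' points actually inside the ellipse (conic value <= 0), useful as a
#' membership oracle.
#'
#' @param table A `contingency_table` (or coercible).
#' @param alpha Significance level in (0, 1).
#' @param type `"outer"` (enclosing, default) or `"inner"` (inscribed).
#' @return A two-column integer matrix of vertices in counter-clockwise
#'   order, starting from the vertex with minimum x (then minimum y).
#' @export
polygon_of_insignificance <- function(table, alpha = 0.05,
                                      type = c("outer", "inner")) {
  type <- match.arg(type)
  tab <- as_contingency_table(table)
  if (!is_significant(tab, alpha))
    stop("table is not significant at this level: the region of insignificance contains the origin and no bounding polygon is reported",
         call. = FALSE)
  coeffs <- ellipse_coefficients(tab, alpha)
  k <- coeffs$coef / max(abs(coeffs$coef))
  fr <- ellipse_frame(coeffs)
  ext <- abs(fr$rotation) %*% fr$semi  # half-widths along x and y
  x_lo <- fr$center[1] - ext[1]; x_hi <- fr$center[1] + ext[1]

  y_interval <- function(x) {
    r <- quad_roots(k[["C"]], k[["B"]] * x + k[["E"]],
                    k[["A"]] * x^2 + k[["D"]] * x + k[["F"]])
    if (is.null(r)) NULL else sort(r)
  }

  pts <- matrix(numeric(0), 0, 2)
  xs <- seq(ceiling(x_lo), floor(x_hi))
  if (type == "inner") {
    for (x in xs) {
      iv <- y_interval(x)
      if (is.null(iv)) next
      ys <- seq(ceiling(iv[1] - 1e-9), floor(iv[2] + 1e-9))
      ys <- ys[conic_value(coeffs, rep(x, length(ys)), ys) <= 0]
      if (length(ys))
        pts <- rbind(pts, cbind(x, range(ys)[1]), cbind(x, range(ys)[2]))
    }
    if (nrow(pts) == 0L)
      stop("no lattice point lies inside the ellipse", call. = FALSE)
  } else {
    for (x in xs) {
      iv <- y_interval(x)
      if (is.null(iv)) next
      pts <- rbind(pts, cbind(x, floor(iv[1])), cbind(x, ceiling(iv[2])))
    }
    # lattice cells around dense boundary samples guarantee enclosure,
    # including the slivers beyond the first/last integer abscissa
    nb <- max(720L, 8L * ceiling(sum(fr$semi)))
    bd <- ellipse_boundary(coeffs, nb)
    pts <- rbind(pts,
                 cbind(floor(bd[, 1]), floor(bd[, 2])),
                 cbind(floor(bd[, 1]), ceiling(bd[, 2])),
                 cbind(ceiling(bd[, 1]), floor(bd[, 2])),
                 cbind(ceiling(bd[, 1]), ceiling(bd[, 2])))
  }
  pts <- unique(round(pts))
  hull <- grDevices::chull(pts)         # clockwise order
  verts <- pts[rev(hull), , drop = FALSE]  # counter-clockwise
  start <- order(verts[, 1], verts[, 2])[1L]
  verts <- verts[c(start:nrow(verts), seq_len(start - 1L)), , drop = FALSE]
  storage.mode(verts) <- "integer"
  colnames(verts) <- c("x", "y")
  verts
}

#' Point-in-convex-polygon test
#'
#' Membership check for polygons produced by [polygon_of_insignificance()]
#' (vertices in counter-clockwise order); boundary points count as inside.
#'
#' @param vertices Two-column matrix of polygon vertices, counter-clockwise.
#' @param x,y Query coordinates (recycled together).
#' @return Logical vector.
#' @export
polygon_contains <- function(vertices, x, y) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  n <- nrow(vertices)
  pts <- cbind(x, y)
  inside <- rep(TRUE, nrow(pts))
  tol <- 1e-9 * max(abs(vertices), 1)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- vertices[j, 1] - vertices[i, 1]
    ey <- vertices[j, 2] - vertices[i, 2]
    cross <- ex * (pts[, 2] - vertices[i, 2]) - ey * (pts[, 1] - vertices[i, 1])
    inside <- inside & (cross >= -tol)
  }
  inside
}
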