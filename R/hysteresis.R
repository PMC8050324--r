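## Anchored quadratic branch fits, hysteresis statistics, and
## Boltzmann-Arrhenius apparent activation energies.

#' Polynomial least squares through fixed points
#'
#' Fits the degree-\code{degree} polynomial minimizing
#' \eqn{\sum_i (y_i - p(x_i))^2} subject to \eqn{p(x_0) = y_0} for every
#' fixed point. Two algebraically equivalent routes are implemented:
#' \describe{
#'   \item{\code{"elimination"}}{writes \eqn{p = q + r\,s} where \eqn{q}
#'     interpolates the fixed points, \eqn{r(x) = \prod_j (x - x_{0j})}
#'     vanishes at them, and the free polynomial \eqn{s} is fit by ordinary
#'     least squares (the default);}
#'   \item{\code{"lagrange"}}{solves the Lagrange-multiplier (KKT) normal
#'     equations directly.}
#' }
#' The two must agree to machine tolerance; the second serves as an internal
#' cross-check of the first.
#'
#' @param x,y Data points (equal length, \code{length(x) >= 1}).
#' @param degree Polynomial degree, \code{degree >= length(xfix) - 1}.
#' @param xfix,yfix Coordinates of the fixed (anchor) points; \code{xfix}
#'   must be distinct.
#' @param method \code{"elimination"} or \code{"lagrange"}.
#' @return Numeric coefficients of length \code{degree + 1}, ascending
#'   powers.
#' @export
constrained_polyfit <- function(x, y, degree, xfix = numeric(0),
                                yfix = numeric(0),
                                method = c("elimination", "lagrange")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  m <- length(xfix)
  if (length(yfix) != m) {
    abort("`xfix` and `yfix` must have equal length.",
          class = "ch4hyst_constraint_error")
  }
  if (m > 1 && any(duplicated(xfix))) {
    dup <- xfix[duplicated(xfix)][1]
    ys <- unique(yfix[xfix == dup])
    if (length(ys) > 1) {
      abort("Inconsistent constraints: duplicate x with different y.",
            class = "ch4hyst_constraint_error")
    }
    keepc <- !duplicated(xfix)
    xfix <- xfix[keepc]; yfix <- yfix[keepc]; m <- length(xfix)
  }
  if (degree < m - 1) {
    abort("`degree` must be >= number of constraints - 1.",
          class = "ch4hyst_constraint_error")
  }
  if (length(x) < 1 && degree > m - 1) {
    abort("Need at least one data point.", class = "ch4hyst_degenerate_fit")
  }
  ## map the abscissa onto [-1, 1] for Vandermonde conditioning
  xs <- c(x, xfix)
  ctr <- (max(xs) + min(xs)) / 2
  hw <- max((max(xs) - min(xs)) / 2, 1e-12)
  coefs <- if (method == "elimination") {
    polyfit_eliminate((x - ctr) / hw, y, degree, (xfix - ctr) / hw, yfix)
  } else {
    polyfit_kkt((x - ctr) / hw, y, degree, (xfix - ctr) / hw, yfix)
  }
  ## compose back through u = (x - ctr)/hw (Horner in coefficient space)
  lin <- c(-ctr / hw, 1 / hw)
  out <- coefs[length(coefs)]
  for (k in rev(seq_len(length(coefs) - 1L))) {
    out <- poly_add(poly_mult(out, lin), coefs[k])
  }
  c(out, rep(0, degree + 1L - length(out)))
}

## Interpolating polynomial through the fixed points (Lagrange form),
## returned as ascending coefficients of length m (or c(0) when m = 0).
lagrange_interp_coefs <- function(xfix, yfix) {
  m <- length(xfix)
  if (m == 0) return(0)
  out <- rep(0, m)
  for (j in seq_len(m)) {
    term <- yfix[j]
    for (k in seq_len(m)[-j]) {
      term <- poly_mult(term, c(-xfix[k], 1) / (xfix[j] - xfix[k]))
    }
    out <- poly_add(out, term)
  }
  out
}

polyfit_eliminate <- function(x, y, degree, xfix, yfix) {
  m <- length(xfix)
  if (m == 0) {
    X <- outer(x, 0:degree, `^`)
    cf <- unname(qr.coef(qr(X), y))
    cf[is.na(cf)] <- 0  # rank deficiency: drop unidentifiable directions
    return(cf)
  }
  q <- lagrange_interp_coefs(xfix, yfix)
  r <- 1
  for (xf in xfix) r <- poly_mult(r, c(-xf, 1))
  nfree <- degree - m + 1L
  p <- q
  if (nfree > 0) {
    resid <- y - eval_poly(q, x)
    rx <- eval_poly(r, x)
    B <- outer(x, seq_len(nfree) - 1L, `^`) * rx
    s <- qr.coef(qr(B), resid)
    s[is.na(s)] <- 0  # rank deficiency: drop unidentifiable directions
    p <- poly_add(q, poly_mult(r, s))
  }
  out <- rep(0, degree + 1L)
  out[seq_along(p)] <- p
  unname(out)
}

polyfit_kkt <- function(x, y, degree, xfix, yfix) {
  d1 <- degree + 1L
  X <- outer(x, 0:degree, `^`)
  A <- outer(xfix, 0:degree, `^`)
  m <- length(xfix)
  K <- rbind(cbind(2 * crossprod(X), t(A)),
             cbind(A, matrix(0, m, m)))
  rhs <- c(2 * crossprod(X, y), yfix)
  solve_k <- function(b) {
    tryCatch(solve(K, b), error = function(e) {
      cf <- qr.coef(qr(K), b)
      cf[is.na(cf)] <- 0
      cf
    })
  }
  sol <- solve_k(rhs)
  ## iterative refinement sharpens the ill-conditioned solve
  for (it in 1:3) sol <- sol + solve_k(rhs - K %*% sol)
  unname(sol[seq_len(d1)])
}

#' Fit the anchored quadratic temperature response for one branch
#'
#' Fits the one-parameter emergent flux-temperature model
#' \deqn{F(T) = a_{hys} T^2 + (F_{Tmax}/T_{max} - a_{hys} T_{max})\, T,}
#' which is the quadratic through the origin (or a prescribed intercept) and
#' the anchor \eqn{(T_{max}, F_{Tmax})}. The single free curvature
#' \eqn{a_{hys}} (mg C m^-2 d^-1 degC^-2) is the hysteresis parameter; it has
#' the closed-form least-squares solution
#' \eqn{a = \sum x' y' / \sum x'^2} with \eqn{x' = T^2 - T_{max} T} and
#' \eqn{y'} the flux after removing the anchored linear part.
#'
#' @param t Branch temperatures, degC.
#' @param f Branch CH4 fluxes, mg C m^-2 d^-1 (negative values retained).
#' @param t_max Seasonal maximum temperature (> 0), degC.
#' @param f_at_tmax Flux measured at \code{t_max}.
#' @param branch \code{"earlier"}, \code{"later"}, or \code{"full"}.
#' @param intercept Flux imposed at 0 degC (default 0; see
#'   [near_zero_flux()] for the alternative anchoring).
#' @return A list of class \code{branch_fit}: \code{a_hys}, \code{t_max},
#'   \code{f_at_tmax}, \code{intercept}, \code{branch}, \code{n_points},
#'   \code{rmse}.
#' @export
fit_branch <- function(t, f, t_max, f_at_tmax,
                       branch = c("full", "earlier", "later"),
                       intercept = 0) {
  branch <- match.arg(branch)
  stopifnot_scalar_number(t_max, "t_max")
  stopifnot_scalar_number(f_at_tmax, "f_at_tmax")
  if (t_max <= 0) {
    abort("`t_max` must be positive (the anchors would coincide).",
          class = "ch4hyst_domain_error")
  }
  keep <- !is.na(t) & !is.na(f)
  t <- t[keep]; f <- f[keep]
  if (length(t) == 0) {
    abort("Empty branch.", class = "ch4hyst_degenerate_fit")
  }
  xp <- t^2 - t_max * t
  yp <- f - intercept - ((f_at_tmax - intercept) / t_max) * t
  sxx <- sum(xp^2)
  if (sxx == 0) {
    abort("All branch temperatures sit on the anchors; curvature unidentified.",
          class = "ch4hyst_degenerate_fit")
  }
  a <- sum(xp * yp) / sxx
  fit <- structure(list(a_hys = a, t_max = t_max, f_at_tmax = f_at_tmax,
                        intercept = intercept, branch = branch,
                        n_points = length(t), rmse = NA_real_),
                   class = "branch_fit")
  fit$rmse <- sqrt(mean((f - eval_curve(fit, t))^2))
  fit
}

#' Evaluate an anchored quadratic branch curve
#'
#' Exact polynomial evaluation; by construction \code{F(0) = intercept} and
#' \code{F(t_max) = f_at_tmax} for any \code{a_hys}.
#'
#' @param fit A \code{branch_fit}.
#' @param t Temperatures, degC.
#' @return Flux values, mg C m^-2 d^-1.
#' @export
eval_curve <- function(fit, t) {
  c0 <- fit$intercept
  fit$a_hys * (t^2 - fit$t_max * t) +
    ((fit$f_at_tmax - c0) / fit$t_max) * t + c0
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf(
    "<branch_fit %s> a_hys = %.4g mg C m-2 d-1 degC-2 (Tmax %.1f, F@Tmax %.3g, n = %d, rmse %.3g)\n",
    x$branch, x$a_hys, x$t_max, x$f_at_tmax, x$n_points, x$rmse))
  invisible(x)
}

## Max |F| over [0, t_max] for one anchored quadratic: candidates are the
## interval endpoints and the parabola vertex when it lies inside.
curve_max_abs <- function(fit) {
  a <- fit$a_hys
  b <- (fit$f_at_tmax - fit$intercept) / fit$t_max - a * fit$t_max
  cand <- c(0, fit$t_max)
  if (a != 0) {
    v <- -b / (2 * a)
    if (v > 0 && v < fit$t_max) cand <- c(cand, v)
  }
  max(abs(eval_curve(fit, cand)))
}

#' Normalized hysteresis loop area H_A
#'
#' The area enclosed by the later- and earlier-branch fitted curves,
#' \deqn{H_A = \frac{\int_0^{T_{max}} (F_{later}(T) - F_{earlier}(T))\,dT}
#'   {\max |F| \cdot T_{max}},}
#' computed in closed form: the numerator is
#' \eqn{(a_{earlier} - a_{later}) T_{max}^3 / 6} and the default denominator
#' is the analytic maximum of \eqn{|F|} over both fitted curves on
#' \eqn{[0, T_{max}]} (candidate points: the endpoints and each parabola's
#' vertex). \eqn{H_A > 0} means the later curve lies above the earlier one
#' (a counterclockwise loop: more flux at the same temperature later in the
#' season).
#'
#' @param fit_earlier,fit_later \code{branch_fit}s sharing the same anchors.
#' @param denominator \code{"fitted_curves"} (the formula's max over fitted
#'   curves, default) or \code{"measured_max"} (max |flux| over measured
#'   season days, supplied via \code{f_obs}).
#' @param f_obs Measured season fluxes, only used for
#'   \code{denominator = "measured_max"}.
#' @return Dimensionless \code{h_area}.
#' @export
hysteresis_area <- function(fit_earlier, fit_later,
                            denominator = c("fitted_curves", "measured_max"),
                            f_obs = NULL) {
  denominator <- match.arg(denominator)
  tol <- 1e-8 * max(1, abs(fit_earlier$t_max), abs(fit_earlier$f_at_tmax))
  if (abs(fit_earlier$t_max - fit_later$t_max) > tol ||
      abs(fit_earlier$f_at_tmax - fit_later$f_at_tmax) > tol ||
      abs(fit_earlier$intercept - fit_later$intercept) > tol) {
    abort("Branch fits must share the same anchors to enclose a loop.",
          class = "ch4hyst_domain_error")
  }
  t_max <- fit_earlier$t_max
  num <- (fit_earlier$a_hys - fit_later$a_hys) * t_max^3 / 6
  fmax <- if (denominator == "fitted_curves") {
    max(curve_max_abs(fit_earlier), curve_max_abs(fit_later))
  } else {
    if (is.null(f_obs) || all(is.na(f_obs))) {
      abort("`f_obs` needed for the measured-max denominator.",
            class = "ch4hyst_domain_error")
    }
    max(abs(f_obs), na.rm = TRUE)
  }
  if (fmax == 0) {
    abort("Both curves are identically zero; H_A undefined.",
          class = "ch4hyst_undefined_area")
  }
  num / (fmax * t_max)
}

#' Mean seasonal hysteresis H_mu
#'
#' Difference of mean measured daily flux, later branch minus earlier branch
#' (measured values, not fitted curves).
#'
#' @param f_earlier,f_later Measured daily fluxes per branch.
#' @return \code{h_mu} in mg C m^-2 d^-1.
#' @export
hysteresis_mean <- function(f_earlier, f_later) {
  f_earlier <- f_earlier[!is.na(f_earlier)]
  f_later <- f_later[!is.na(f_later)]
  if (length(f_earlier) == 0 || length(f_later) == 0) {
    abort("Both branches need measured flux days.",
          class = "ch4hyst_degenerate_fit")
  }
  mean(f_later) - mean(f_earlier)
}

#' Mean flux measured near 0 degC
#'
#' The alternative intercept anchor: mean CH4 flux on days whose driver
#' temperature lies in \[-0.5, 0.5\] degC. Returns 0 (with a note) when no
#' such day exists, falling back to the zero-intercept assumption.
#'
#' @param series A \code{daily_series}.
#' @param driver Driver temperature column.
#' @param window Half-width of the near-zero window, degC (default 0.5).
#' @return Scalar intercept with attribute \code{n} (days used).
#' @export
near_zero_flux <- function(series, driver = "t_air", window = 0.5) {
  d <- series[[driver]]
  sel <- !is.na(d) & abs(d) <= window & !is.na(series$f_ch4)
  if (!any(sel)) {
    inform("No flux measured within the near-zero window; using 0 intercept.")
    return(structure(0, n = 0L, fallback = TRUE))
  }
  structure(mean(series$f_ch4[sel]), n = sum(sel), fallback = FALSE)
}

#' Boltzmann-Arrhenius fit of the apparent activation energy
#'
#' Ordinary least squares of \eqn{\ln F} on \eqn{-1/(kT)},
#' \deqn{\ln F(T) = \bar{E_a} \cdot \frac{-1}{kT} + \varepsilon,}
#' with \eqn{k = 8.62 \times 10^{-5}} eV K^-1 fixed. Days with
#' \eqn{F \le 0} cannot enter the log and are excluded (and counted).
#'
#' @param t_kelvin Absolute temperatures, K.
#' @param f CH4 fluxes, mg C m^-2 d^-1.
#' @return A list of class \code{arrhenius_fit}: \code{e_a} (eV),
#'   \code{epsilon}, \code{k}, \code{n_points}, \code{n_excluded},
#'   \code{r_squared}.
#' @export
fit_arrhenius <- function(t_kelvin, f) {
  keep <- !is.na(t_kelvin) & !is.na(f) & t_kelvin > 0
  n_excluded <- sum(keep & f <= 0)
  use <- keep & f > 0
  if (sum(use) < 3) {
    abort("Need >= 3 days with positive flux for an Arrhenius fit.",
          class = "ch4hyst_insufficient_data")
  }
  x <- -1 / (BOLTZMANN_EV * t_kelvin[use])
  if (sd(x) == 0) {
    abort("No temperature variation; activation energy unidentified.",
          class = "ch4hyst_degenerate_fit")
  }
  yl <- log(f[use])
  fit <- lm.fit(cbind(1, x), yl)
  e_a <- unname(fit$coefficients[2])
  eps <- unname(fit$coefficients[1])
  r2 <- if (sd(yl) == 0) 1 else 1 - sum(fit$residuals^2) /
    sum((yl - mean(yl))^2)
  structure(list(e_a = e_a, epsilon = eps, k = BOLTZMANN_EV,
                 n_points = sum(use), n_excluded = n_excluded,
                 r_squared = r2),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> Ea = %.3f eV, eps = %.3f (n = %d, %d non-positive excluded, R2 = %.3f)\n",
    x$e_a, x$epsilon, x$n_points, x$n_excluded, x$r_squared))
  invisible(x)
}

#' Compare candidate temperature-response functional forms
#'
#' Fits anchored polynomials of orders 1, 2, 3 and 5 (each forced through
#' both loop anchors) and an unconstrained Boltzmann-Arrhenius curve to the
#' same branch days, and reports each form's RMSE on those days. Per-form
#' failures are recorded in the table, not raised.
#'
#' @param t Temperatures, degC.
#' @param f Fluxes, mg C m^-2 d^-1.
#' @param t_max,f_at_tmax Loop anchors.
#' @param degrees Polynomial orders to try (default \code{c(1, 2, 3, 5)}).
#' @param intercept Flux imposed at 0 degC (default 0).
#' @return A tibble with columns \code{form}, \code{rmse}, \code{n_fit},
#'   \code{note}.
#' @export
compare_functional_forms <- function(t, f, t_max, f_at_tmax,
                                     degrees = c(1, 2, 3, 5), intercept = 0) {
  keep <- !is.na(t) & !is.na(f)
  t <- t[keep]; f <- f[keep]
  rows <- list()
  for (d in degrees) {
    res <- tryCatch({
      cf <- constrained_polyfit(t, f, d, xfix = c(0, t_max),
                                yfix = c(intercept, f_at_tmax))
      list(rmse = sqrt(mean((f - eval_poly(cf, t))^2)), n = length(t),
           note = NA_character_)
    }, error = function(e) list(rmse = NA_real_, n = 0L,
                                note = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      form = sprintf("poly%d", d), rmse = res$rmse, n_fit = res$n,
      note = res$note)
  }
  arr <- tryCatch({
    af <- fit_arrhenius(t + 273.15, f)
    pred <- exp(af$epsilon + af$e_a * (-1 / (af$k * (t + 273.15))))
    list(rmse = sqrt(mean((f - pred)^2)), n = af$n_points,
         note = NA_character_)
  }, error = function(e) list(rmse = NA_real_, n = 0L,
                              note = conditionMessage(e)))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    form = "arrhenius", rmse = arr$rmse, n_fit = arr$n, note = arr$note)
  dplyr::bind_rows(rows)
}
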