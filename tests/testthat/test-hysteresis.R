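test_that("constrained polynomial fits satisfy worked closed forms", {
  # data already on the constrained line
  cf <- constrained_polyfit(c(1, 2, 3), c(2, 4, 6), 1, xfix = 0, yfix = 0)
  expect_equal(cf, c(0, 2), tolerance = 1e-12)

  # single free quadratic coefficient, closed form a = sum(x'y')/sum(x'^2)
  cf2 <- constrained_polyfit(5, 30, 2, xfix = c(0, 10), yfix = c(0, 20))
  expect_equal(cf2[3], -0.8, tolerance = 1e-10)
  expect_equal(eval_poly(cf2, c(0, 5, 10)), c(0, 30, 20), tolerance = 1e-9)
})

test_that("both constrained-fit routes agree and satisfy the constraints", {
  withr::with_seed(11, {
    for (i in 1:50) {
      degree <- sample(1:5, 1)
      n <- sample((2 * (degree + 1)):30, 1)  # well-posed free design
      m <- sample(0:min(2, degree + 1), 1)
      x <- runif(n, -1, 3)
      y <- rnorm(n, 0, 5)
      xfix <- switch(m + 1L, numeric(0), -0.5, c(-0.5, 3.5))
      yfix <- if (m == 0) numeric(0) else rnorm(m, 0, 5)
      a <- constrained_polyfit(x, y, degree, xfix, yfix, "elimination")
      b <- constrained_polyfit(x, y, degree, xfix, yfix, "lagrange")
      scale <- max(abs(a), 1)
      expect_lt(max(abs(a - b)) / scale, 1e-9)
      if (m > 0) {
        expect_lt(max(abs(eval_poly(a, xfix) - yfix)) /
                    max(abs(yfix), 1), 1e-9)
      }
    }
  })
  expect_error(
    constrained_polyfit(1:3, 1:3, 2, xfix = c(1, 1), yfix = c(0, 2)),
    class = "ch4hyst_constraint_error")
  expect_error(
    constrained_polyfit(1:3, 1:3, 0, xfix = c(0, 1), yfix = c(0, 2)),
    class = "ch4hyst_constraint_error")
})

test_that("branch fits recover the generating curvature", {
  t <- seq(2, 18, by = 2)
  a_true <- 0.5; t_max <- 20; f_max <- 100
  f <- a_true * t^2 + (f_max / t_max - a_true * t_max) * t
  fit <- fit_branch(t, f, t_max, f_max)
  expect_equal(fit$a_hys, a_true, tolerance = 1e-10)
  expect_lt(fit$rmse, 1e-9)

  # purely linear data has no curvature
  lin <- fit_branch(t, 5 * t, 12, 60)
  expect_equal(lin$a_hys, 0, tolerance = 1e-12)

  expect_error(fit_branch(t, f, -1, 10), class = "ch4hyst_domain_error")
  expect_error(fit_branch(numeric(0), numeric(0), 20, 100),
               class = "ch4hyst_degenerate_fit")
})

test_that("noisy branch fit matches a brute-force SSE grid search", {
  withr::with_seed(21, {
    t_max <- 20; f_max <- 100; a_true <- -0.3
    t <- runif(80, 1, t_max)
    f <- a_true * t^2 + (f_max / t_max - a_true * t_max) * t + rnorm(80, 0, 5)
    fit <- fit_branch(t, f, t_max, f_max)
    grid <- seq(-2, 2, length.out = 4001)
    sse <- vapply(grid, function(a) {
      sum((f - (a * t^2 + (f_max / t_max - a * t_max) * t))^2)
    }, numeric(1))
    a_grid <- grid[which.min(sse)]
    expect_lt(abs(fit$a_hys - a_grid), diff(grid[1:2]))
  })
})

test_that("anchored curves pass through both anchors exactly", {
  withr::with_seed(31, {
    for (i in 1:25) {
      fit <- fit_branch(runif(15, 0.5, 24), rnorm(15, 40, 30),
                        t_max = runif(1, 5, 30),
                        f_at_tmax = runif(1, -50, 300))
      expect_lt(abs(eval_curve(fit, 0)),
                1e-9 * max(1, abs(fit$f_at_tmax)))
      expect_lt(abs(eval_curve(fit, fit$t_max) - fit$f_at_tmax),
                1e-9 * max(1, abs(fit$f_at_tmax)))
    }
  })
  # hand-evaluated interior point
  fit <- structure(list(a_hys = 1, t_max = 10, f_at_tmax = 100,
                        intercept = 0), class = "branch_fit")
  expect_equal(eval_curve(fit, 5), 25)
})

test_that("loop area matches numeric integration and is antisymmetric", {
  mk <- function(a, br) {
    t <- seq(1, 9.5, by = 0.5)
    f <- a * t^2 + (100 / 10 - a * 10) * t
    fit_branch(t, f, 10, 100, branch = br)
  }
  fe <- mk(1, "earlier"); fl <- mk(-1, "later")
  h <- hysteresis_area(fe, fl)
  expect_equal(h, 1 / 3, tolerance = 1e-10)

  # independent 1e5-point trapezoidal check of the full ratio
  tt <- seq(0, 10, length.out = 1e5)
  dif <- eval_curve(fl, tt) - eval_curve(fe, tt)
  num <- sum((dif[-1] + dif[-length(dif)]) / 2 * diff(tt))
  den <- max(abs(c(eval_curve(fe, tt), eval_curve(fl, tt)))) * 10
  expect_equal(h, num / den, tolerance = 1e-6)

  expect_equal(hysteresis_area(fl, fe), -h, tolerance = 1e-12)
  expect_equal(hysteresis_area(fe, fe), 0)
  expect_error(hysteresis_area(fe, mk(1, "later")), NA)
  zero_e <- fit_branch(c(2, 5), c(0, 0), 10, 0, branch = "earlier")
  zero_l <- fit_branch(c(2, 5), c(0, 0), 10, 0, branch = "later")
  expect_error(hysteresis_area(zero_e, zero_l),
               class = "ch4hyst_undefined_area")
})

test_that("closed-form loop area equals trapezoidal integration on random fits", {
  withr::with_seed(41, {
    for (i in 1:20) {
      t_max <- runif(1, 5, 30); f_max <- runif(1, 10, 300)
      t <- runif(25, 0.5, t_max)
      fe <- fit_branch(t, rnorm(25, 50, 40), t_max, f_max, "earlier")
      fl <- fit_branch(t, rnorm(25, 80, 40), t_max, f_max, "later")
      tt <- seq(0, t_max, length.out = 1e5)
      dif <- eval_curve(fl, tt) - eval_curve(fe, tt)
      num_trapz <- sum((dif[-1] + dif[-length(dif)]) / 2 * diff(tt))
      num_closed <- (fe$a_hys - fl$a_hys) * t_max^3 / 6
      expect_equal(num_closed, num_trapz,
                   tolerance = 1e-6 * max(1, abs(num_closed)))
    }
  })
})

test_that("H_mu is the later-minus-earlier mean of measured values", {
  expect_equal(hysteresis_mean(c(20, 40), c(45, 55)), 20)
  expect_equal(hysteresis_mean(c(3, 4), c(3, 4)), 0)
  expect_equal(hysteresis_mean(c(45, 55), c(20, 40)), -20)
  expect_error(hysteresis_mean(numeric(0), 1),
               class = "ch4hyst_degenerate_fit")
})

test_that("hysteresis statistics scale correctly and shift is not invariant", {
  sr <- make_sine_year(a_early = 0.4, a_late = -0.2)
  meta <- site_meta("TEST-SIN", "fen", 55)
  res <- analyze_site_year(sr, meta, 2015)
  sr2 <- sr
  sr2$f_ch4 <- 3 * sr2$f_ch4
  res2 <- analyze_site_year(sr2, meta, 2015)
  expect_equal(res2$h_area, res$h_area, tolerance = 1e-10)
  expect_equal(res2$h_mu, 3 * res$h_mu, tolerance = 1e-10)

  # shifting the driver is NOT an invariance: the 0 degC anchor is physical
  sr3 <- sr
  sr3$t_air <- sr3$t_air + 5
  res3 <- analyze_site_year(sr3, meta, 2015)
  expect_gt(abs(res3$h_area - res$h_area), 1e-3)
})

test_that("a later branch generated above the earlier one gives positive H", {
  sr <- make_sine_year(a_early = 0.6, a_late = -0.6)
  res <- analyze_site_year(sr, site_meta("TEST-SIN", "marsh", 50), 2015)
  expect_gt(res$h_area, 0)
  expect_gt(res$h_mu, 0)
  expect_equal(res$sign, "positive")
})

test_that("the near-zero intercept replaces the origin constraint", {
  expect_equal(as.numeric(near_zero_flux(
    daily_series("Z", as.Date("2015-01-01") + 0:1, t_air = c(-0.4, 0.3),
                 f_ch4 = c(4, 6)))), 5)
  msgless <- daily_series("Z", as.Date("2015-01-01"), t_air = 10, f_ch4 = 9)
  expect_message(nz <- near_zero_flux(msgless))
  expect_equal(as.numeric(nz), 0)

  # exact recovery under the shifted generating model
  c0 <- 5; a_true <- 0.25; t_max <- 20; f_max <- 80
  t <- seq(1, 19, by = 1)
  f <- c0 + a_true * (t^2 - t_max * t) + ((f_max - c0) / t_max) * t
  fit <- fit_branch(t, f, t_max, f_max, intercept = c0)
  expect_equal(fit$a_hys, a_true, tolerance = 1e-10)
  expect_equal(eval_curve(fit, 0), c0, tolerance = 1e-10)
})

test_that("Arrhenius fits recover exact generative parameters", {
  k <- 8.62e-5
  tk <- seq(278, 300, by = 1)
  f <- exp(30 - 1.0 / (k * tk))
  fit <- fit_arrhenius(tk, f)
  expect_equal(fit$e_a, 1.0, tolerance = 1e-8)
  expect_equal(fit$epsilon, 30, tolerance = 1e-8)
  expect_equal(fit$k, k)

  flat <- fit_arrhenius(tk, rep(12, length(tk)))
  expect_equal(flat$e_a, 0, tolerance = 1e-10)

  expect_error(fit_arrhenius(c(280, 285, 290), c(-1, -2, 0)),
               class = "ch4hyst_insufficient_data")
  expect_error(fit_arrhenius(rep(285, 5), rep(2, 5)),
               class = "ch4hyst_degenerate_fit")
})

test_that("noisy Arrhenius fit matches an independent normal-equations solve", {
  withr::with_seed(51, {
    k <- 8.62e-5
    tk <- runif(100, 275, 303)
    f <- exp(28 - 0.8 / (k * tk)) * exp(rnorm(100, 0, 0.3))
    fit <- fit_arrhenius(tk, f)
    X <- cbind(1, -1 / (k * tk))
    beta <- solve(t(X) %*% X, t(X) %*% log(f))
    expect_equal(fit$epsilon, beta[1], tolerance = 1e-9)
    expect_equal(fit$e_a, beta[2], tolerance = 1e-9)
    expect_equal(fit$n_excluded, 0)
  })
})

test_that("functional-form comparison respects model nesting", {
  withr::with_seed(61, {
    t_max <- 22; f_max <- 120
    t <- runif(50, 1, t_max)
    f_true <- 0.3 * t^2 + (f_max / t_max - 0.3 * t_max) * t
    f <- f_true + rnorm(50, 0, 8)
    tab <- compare_functional_forms(t, f, t_max, f_max)
    rmse <- setNames(tab$rmse, tab$form)
    expect_lte(rmse[["poly5"]], rmse[["poly3"]] + 1e-9)
    expect_lte(rmse[["poly3"]], rmse[["poly2"]] + 1e-9)
    expect_lte(rmse[["poly2"]], rmse[["poly1"]] + 1e-9)

    # on data generated from the anchored quadratic, no polynomial beats it
    tab0 <- compare_functional_forms(t, f_true, t_max, f_max)
    rmse0 <- setNames(tab0$rmse, tab0$form)
    expect_lt(rmse0[["poly2"]], 1e-9)

    # the table matches a brute-force refit of each polynomial
    for (d in c(1, 2, 3, 5)) {
      cf <- constrained_polyfit(t, f, d, c(0, t_max), c(0, f_max))
      expect_equal(rmse[[sprintf("poly%d", d)]],
                   sqrt(mean((f - eval_poly(cf, t))^2)), tolerance = 1e-12)
    }
  })
})
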