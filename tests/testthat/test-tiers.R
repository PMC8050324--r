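make_day_table <- function(n_sites = 3, n_types = 2, n_years = 2,
                           days_per_branch = 20, curve = NULL, seed = 71) {
  withr::with_seed(seed, {
    rows <- list()
    types <- ecosystem_types()[seq_len(n_types)]
    for (i in seq_len(n_sites)) {
      sid <- sprintf("S%02d", i)
      type <- types[(i - 1) %% n_types + 1]
      for (yr in 2015 + seq_len(n_years) - 1) {
        for (br in c("earlier", "later")) {
          t <- runif(days_per_branch, 1, 25)
          f <- if (is.null(curve)) runif(days_per_branch, 10, 100) else
            curve(t, sid, yr, br)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            site_id = sid, ecosystem_type = type, season_year = yr,
            site_year = paste(sid, yr, sep = "_"), branch = br,
            date = as.Date(sprintf("%d-06-01", yr)), t = t, f_ch4 = f,
            t_max = 25, f_at_tmax = 100)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

test_that("tier specs form a closed, validated set", {
  expect_equal(length(tier_labels()), 7)
  expect_equal(tier_spec("T")$factors, character(0))
  expect_setequal(tier_spec("T+site+IAV+ISV")$factors,
                  c("site", "IAV", "ISV"))
  expect_error(tier_spec("T+pH"), class = "ch4hyst_spec_error")
  expect_error(tier_spec("site"), class = "ch4hyst_spec_error")
  expect_error(tier_spec("T+IAV"), class = "ch4hyst_spec_error")
})

test_that("partitioning yields the factor cross-product and conserves days", {
  days <- make_day_table(n_sites = 3, n_types = 2, n_years = 2)
  expect_equal(length(unique(partition_data(days, "T")$.group)), 1)
  expect_equal(length(unique(partition_data(days, "T+type")$.group)), 2)
  expect_equal(length(unique(partition_data(days, "T+site")$.group)), 3)
  expect_equal(
    length(unique(partition_data(days, "T+site+IAV+ISV")$.group)), 12)
  for (lab in setdiff(tier_labels(), "hybrid")) {
    p <- partition_data(days, lab)
    expect_equal(sum(table(p$.group)), nrow(days))
  }
})

test_that("group fits recover exact curves and predict through the origin", {
  days <- make_day_table(curve = function(t, ...) 2 * t + 0.1 * t^2)
  model <- fit_tier(days, "T")
  g <- model$levels[[1]]$fits[["(all)"]]
  expect_equal(g$b1, 2, tolerance = 1e-10)
  expect_equal(g$b2, 0.1, tolerance = 1e-10)
  newdays <- days[1:3, ]
  newdays$t <- c(7, 0, 10)
  expect_equal(predict_tier(model, newdays),
               c(2 * 7 + 0.1 * 49, 0, 2 * 10 + 0.1 * 100),
               tolerance = 1e-10)
})

test_that("branch-resolved tiers reproduce per-branch generating curves", {
  curve <- function(t, sid, yr, br) {
    a <- if (br == "earlier") 0.4 else -0.4
    a * (t^2 - 25 * t) + 4 * t
  }
  days <- make_day_table(curve = curve)
  model <- fit_tier(days, "T+site+IAV+ISV")
  pred <- predict_tier(model, days)
  expect_lt(sqrt(mean((pred - days$f_ch4)^2)), 1e-9)
})

test_that("unseen groups fall back to the parent fit with a warning", {
  days <- make_day_table(curve = function(t, ...) 2 * t)
  model <- fit_tier(days, "T+site")
  new <- days[1, ]
  new$site_id <- "UNSEEN"
  new$t <- 7
  expect_warning(p <- predict_tier(model, new), "fallback")
  expect_equal(p, 14, tolerance = 1e-9)
})

test_that("arrhenius-form tiers recover the generating activation energy", {
  k <- 8.62e-5
  days <- make_day_table(curve = function(t, ...)
    exp(25 - 0.7 / (k * (t + 273.15))))
  model <- fit_tier(days, "T", form = "arrhenius")
  g <- model$levels[[1]]$fits[["(all)"]]
  expect_equal(g$e_a, 0.7, tolerance = 1e-8)
  pred <- predict_tier(model, days)
  expect_equal(pred, days$f_ch4, tolerance = 1e-6)
})

test_that("absolute bias follows its defining ratio", {
  obs <- c(10, 30)
  expect_equal(absolute_bias(obs, obs), 0)
  expect_equal(absolute_bias(1.5 * obs, obs), 50)
  expect_equal(absolute_bias(c(14, 24), obs), 25)
  expect_error(absolute_bias(c(1, 1), c(-2, 1)),
               class = "ch4hyst_undefined_bias")
})

test_that("branch bias aggregates signed site-year biases", {
  # two site-years with +10% and +30% bias in one branch
  pred <- c(11, 11, 13, 13)
  obs <- c(10, 10, 10, 10)
  sy <- c("a", "a", "b", "b")
  br <- rep("earlier", 4)
  bb <- branch_bias(pred, obs, sy, br)
  expect_equal(bb$summary$mean_pct, 20)
  expect_equal(bb$summary$sd_pct, sqrt((10 - 20)^2 + (30 - 20)^2),
               tolerance = 1e-12)

  perfect <- branch_bias(obs, obs, sy, c("earlier", "earlier", "later",
                                         "later"))
  expect_equal(perfect$summary$mean_pct, c(0, 0))
  expect_true(all(perfect$summary$sd_pct == 0 |
                    is.na(perfect$summary$sd_pct)))

  # overprediction is positive by convention
  over <- branch_bias(c(12, 12), c(10, 10), c("a", "a"), c("later", "later"))
  expect_gt(over$summary$mean_pct, 0)
})

test_that("finer tiers cannot do worse than the universal tier in-sample", {
  net <- gen_network(n_sites = 8, seed = 301, years_range = c(2, 2))
  an <- analyze_network(net$data, net$meta)
  days <- build_day_table(an)
  ev <- evaluate_tiers(days)
  bias <- setNames(ev$bias_overall$absolute_bias_pct, ev$bias_overall$tier)
  expect_lte(bias[["T+site+IAV+ISV"]], bias[["T"]])
  expect_lte(bias[["T+site"]], bias[["T"]] + 1e-9)
  # every tier scores exactly the same days
  expect_equal(unique(ev$bias_overall$n_days), nrow(days))
})

test_that("the hybrid tier pins predictions to the site-year anchors", {
  net <- gen_network(n_sites = 8, seed = 311, years_range = c(2, 3))
  an <- analyze_network(net$data, net$meta)
  days <- build_day_table(an)
  training <- build_training_table(an)
  reg <- fit_ahys_regressor(training, n_trees = 100, seed = 1)
  pred <- hybrid_predict_days(reg, days, training)
  expect_equal(length(pred), nrow(days))
  at_tmax <- abs(days$t - days$t_max) < 1e-12
  expect_equal(pred[at_tmax], days$f_at_tmax[at_tmax], tolerance = 1e-9)
  ev <- evaluate_tiers(days, hybrid = reg, training = training)
  expect_true("hybrid" %in% ev$bias_overall$tier)
})
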