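test_that("temperature generator is an exact seeded sinusoid plus AR(1)", {
  cfg <- synth_site_config(seed = 500, years = 1, t_noise_sd = 0,
                           t_mean = 5, t_amplitude = 12)
  tt <- gen_temperature(cfg)
  doy <- as.integer(format(tt$date, "%j"))
  expect_equal(tt$t_air, 5 + 12 * sin(2 * pi * (doy - 91) / 365.25),
               tolerance = 1e-12)
  expect_equal(which.max(tt$t_air), 182, tolerance = 1)

  expect_identical(gen_temperature(cfg), gen_temperature(cfg))

  # stationary AR(1) SD: sd / sqrt(1 - phi^2)
  cfg2 <- synth_site_config(seed = 501, years = 28, t_noise_sd = 2,
                            t_ar1 = 0.6)
  t2 <- gen_temperature(cfg2)
  doy2 <- as.integer(format(t2$date, "%j"))
  noise <- t2$t_air - (cfg2$t_mean +
                         cfg2$t_amplitude * sin(2 * pi * (doy2 - 91) / 365.25))
  expect_equal(sd(noise), 2 / sqrt(1 - 0.6^2), tolerance = 0.05)
})

test_that("southern sites flip the seasonal phase", {
  cfg <- synth_site_config(seed = 502, years = 1, t_noise_sd = 0,
                           latitude = -40)
  tt <- gen_temperature(cfg)
  midwinter <- tt$t_air[tt$date == as.Date("2015-07-10")]
  expect_lt(midwinter, tt$t_air[1])  # mid-year colder than January
})

test_that("parametric flux inverts to the injected parameters", {
  cfg <- synth_site_config(seed = 510, years = 2, flux_noise_cv = 0,
                           a_early = 0.42, a_late = -0.17)
  sr <- gen_site(cfg)
  truth <- attr(sr, "truth")
  expect_equal(nrow(truth), 2)
  res <- analyze_site_year(sr, site_meta("SY-001", "fen", 55), 2015)
  expect_lt(abs(res$fit_earlier$a_hys - 0.42), 1e-9)
  expect_lt(abs(res$fit_later$a_hys + 0.17), 1e-9)
  expect_gt(res$h_area, 0)

  # a closed loop with equal branch parameters has no area
  cfg0 <- synth_site_config(seed = 511, years = 1, flux_noise_cv = 0,
                            a_early = 0.2, a_late = 0.2)
  res0 <- analyze_site_year(gen_site(cfg0), site_meta("SY-001", "fen", 55),
                            2015)
  expect_lt(abs(res0$h_area), 1e-9)
})

test_that("covariates obey their generating rules", {
  cfg <- synth_site_config(seed = 520, years = 28)
  tt <- gen_temperature(cfg)
  cv <- gen_covariates(cfg, tt$t_air)
  expect_true(all(cv$gpp[tt$t_air <= 0] == 0))
  expect_equal(mean(cv$precip),
               cfg$precip_p * cfg$precip_shape * cfg$precip_scale,
               tolerance = 0.05)

  dry_cfg <- synth_site_config(seed = 521, years = 2, precip_p = 0)
  tt2 <- gen_temperature(dry_cfg)
  cv2 <- gen_covariates(dry_cfg, tt2$t_air)
  expect_true(all(cv2$precip == 0))
  expect_true(all(diff(cv2$wtd) <= 0))       # monotone drawdown
  expect_gte(min(cv2$wtd), -60)              # bounded at the floor
})

test_that("the mechanistic generator conserves mass and needs substrate", {
  p <- mechanistic_params()
  f0 <- gen_flux_mechanistic(rep(15, 200), rep(0, 200), p, s0 = 0)
  expect_true(all(f0 == 0))

  withr::with_seed(530, {
    t_air <- 10 + 8 * sin(2 * pi * (1:730) / 365)
    gpp <- pmax(0, 5 * sin(2 * pi * (1:730) / 365))
    f <- gen_flux_mechanistic(t_air, gpp, p, s0 = 1)
    expect_true(all(f >= 0))
    expect_lte(sum(f) / p$unit_scale,
               p$gpp_to_substrate * sum(gpp) + 1 + 1e-9)
  })
})

test_that("substrate lag past the temperature peak yields positive H_A", {
  cfg <- synth_site_config(seed = 540, years = 2, generator = "mechanistic",
                           flux_noise_cv = 0,
                           mechanistic = mechanistic_params(
                             substrate_lag = 20, q10 = 2.5))
  sr <- gen_site(cfg)
  res <- analyze_site_year(sr, site_meta("SY-001", "fen", 55), 2016,
                           qc = qc_policy(min_days_per_branch = 5))
  expect_gt(res$h_area, 0)
})

test_that("mechanistic hysteresis is predominantly positive across plausible parameters", {
  # Latin-hypercube over (lag, q10, decay, gpp_to_substrate)
  grid <- withr::with_seed(550, lhs::randomLHS(50, 4))
  signs <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- synth_site_config(
      seed = 550 + i, years = 2, generator = "mechanistic",
      flux_noise_cv = 0,
      mechanistic = mechanistic_params(
        substrate_lag = round(5 + 30 * g[1]), q10 = 1.5 + 2 * g[2],
        decay_rate = 0.005 + 0.045 * g[3],
        gpp_to_substrate = 0.005 + 0.045 * g[4]))
    res <- tryCatch(
      analyze_site_year(gen_site(cfg), site_meta("SY-001", "fen", 55), 2016,
                        qc = qc_policy(min_days_per_branch = 5)),
      error = function(e) NULL)
    if (is.null(res)) NA else res$h_area > 0
  }, logical(1))
  expect_gt(mean(signs, na.rm = TRUE), 0.5)
})

test_that("network generation is reproducible down to the written bytes", {
  net1 <- gen_network(n_sites = 4, seed = 560, years_range = c(2, 3))
  net2 <- gen_network(n_sites = 4, seed = 560, years_range = c(2, 3))
  expect_equal(nrow(net1$truth),
               sum(vapply(net1$data, function(s)
                 length(unique(format(s$date, "%Y"))), numeric(1))))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_network(net1, d1)
  write_network(net2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the injected hysteresis sign controls the detected sign", {
  net <- gen_network(n_sites = 10, seed = 570, years_range = c(2, 2),
                     flux_noise_cv = 0)
  an <- analyze_network(net$data, net$meta)
  merged <- dplyr::inner_join(an$summary, net$truth,
                              by = c("site_id", "season_year"))
  expect_gt(nrow(merged), 15)
  expect_true(all((merged$h_area > 0) == merged$positive))
  # noise-free recovery of the injected branch parameters
  expect_lt(max(abs(merged$a_earlier - merged$a_early)), 1e-9)
  expect_lt(max(abs(merged$a_later - merged$a_late)), 1e-9)
})
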