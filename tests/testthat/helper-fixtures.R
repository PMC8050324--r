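# Fixtures are built in code at test time; no data files.

# One synthetic-but-hand-made series: a clean sinusoidal year with flux
# following the anchored quadratic exactly (branch-specific curvature).
make_sine_year <- function(amp = 10, f_peak = 100, a_early = 0.5,
                           a_late = -0.5, year = 2015) {
  t_day <- seq_len(365)
  t_air <- amp * sin(2 * pi * t_day / 365)
  dates <- as.Date(sprintf("%d-01-01", year)) + t_day - 1
  above <- which(t_air > 0)
  t_max <- max(t_air[above])
  i_max <- above[which.max(t_air[above])]
  f <- rep(0, 365)
  curve <- function(a, t) a * (t^2 - t_max * t) + (f_peak / t_max) * t
  earlier <- above[above <= i_max]
  later <- above[above > i_max]
  f[earlier] <- curve(a_early, t_air[earlier])
  f[later] <- curve(a_late, t_air[later])
  daily_series("TEST-SIN", dates, t_air = t_air, f_ch4 = f)
}

# Write a small FLUXNET-dialect CSV from a text literal.
write_csv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A training table with the ten predictor columns; a_hys given by `fun`
# applied row-wise, plus optional noise.
make_ahys_table <- function(n_sites = 40, rows_per_site = 5, seed = 1,
                            fun = function(df) 2 * df$t_max,
                            noise_sd = 0) {
  withr::with_seed(seed, {
    n <- n_sites * rows_per_site
    df <- tibble::tibble(
      site_id = rep(sprintf("S%02d", seq_len(n_sites)),
                    each = rows_per_site),
      site_year = paste0(site_id, "_", rep(seq_len(rows_per_site),
                                           n_sites)),
      seasonal_branch = rep(c("earlier", "later"), length.out = n),
      gpp_cum_branch = runif(n, 50, 500),
      precip_cum_branch = runif(n, 50, 400),
      t_max = runif(n, 10, 30),
      t_mean_branch = runif(n, 5, 20),
      ecosystem_type = sample(ecosystem_types(), n, replace = TRUE),
      latitude = runif(n, 35, 68),
      f_at_tmax = runif(n, 20, 300))
    df$a_hys <- fun(df) + rnorm(n, 0, noise_sd)
    df
  })
}
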