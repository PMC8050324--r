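## Per-site-year analysis and network-level orchestration.

#' Analyze one site-year: season, branch fits, hysteresis statistics
#'
#' Runs the full single-site-year pipeline: quality control, season
#' extraction, the earlier/later branch split at the seasonal temperature
#' maximum, anchored quadratic fits per branch and for the full season, the
#' hysteresis statistics \eqn{H_A} and \eqn{H_\mu}, a Boltzmann-Arrhenius
#' fit over the season, and per-branch covariate summaries (cumulative GPP
#' and precipitation, mean driver temperature) used downstream by the
#' hysteresis-parameter regressor.
#'
#' @param series A \code{daily_series}.
#' @param meta Optional [site_meta()] row (supplies ecosystem type and
#'   latitude; latitude drives hemisphere wrapping).
#' @param year Season-year label (integer).
#' @param season A [season_policy()].
#' @param qc A [qc_policy()].
#' @param intercept_mode \code{"zero"} (flux forced to 0 at 0 degC, default)
#'   or \code{"near_zero_mean"} (anchored at the mean flux measured within
#'   +/- 0.5 degC, falling back to 0 when no such day exists).
#' @param h_area_denominator Passed to [hysteresis_area()].
#' @return A list of class \code{hysteresis_result}.
#' @export
analyze_site_year <- function(series, meta = NULL, year,
                              season = season_policy(),
                              qc = qc_policy(),
                              intercept_mode = c("zero", "near_zero_mean"),
                              h_area_denominator = c("fitted_curves",
                                                     "measured_max")) {
  intercept_mode <- match.arg(intercept_mode)
  h_area_denominator <- match.arg(h_area_denominator)
  latitude <- if (!is.null(meta)) meta$latitude[1] else NULL
  qcd <- apply_qc(series, qc)
  if (season$resolution == "monthly") {
    qcd <- aggregate_monthly(qcd)
    ## ~30.44 days per month; floors keep short monthly seasons fittable
    season$min_season_days <- max(3L, as.integer(ceiling(
      season$min_season_days / 30.44)))
    qc$min_days_per_branch <- 3L
    season$max_gap_days <- 0L
  }
  ffs <- extract_season(qcd, season, year, latitude = latitude)
  drv <- qcd[[season$driver]]
  usable <- function(idx) idx[!is.na(drv[idx]) & !is.na(qcd$f_ch4[idx])]
  e_idx <- usable(ffs$earlier_idx)
  l_idx <- usable(ffs$later_idx)
  if (length(e_idx) < qc$min_days_per_branch ||
      length(l_idx) < qc$min_days_per_branch) {
    abort(sprintf(
      "Branch too short after QC (%d earlier / %d later; need %d each).",
      length(e_idx), length(l_idx), qc$min_days_per_branch),
      class = "ch4hyst_insufficient_branch")
  }
  c0 <- 0
  intercept_n <- NA_integer_
  if (intercept_mode == "near_zero_mean") {
    nz <- near_zero_flux(qcd, season$driver)
    c0 <- as.numeric(nz)
    intercept_n <- attr(nz, "n")
  }
  fit_e <- fit_branch(drv[e_idx], qcd$f_ch4[e_idx], ffs$t_max, ffs$f_at_tmax,
                      branch = "earlier", intercept = c0)
  fit_l <- fit_branch(drv[l_idx], qcd$f_ch4[l_idx], ffs$t_max, ffs$f_at_tmax,
                      branch = "later", intercept = c0)
  s_idx <- c(e_idx, l_idx)
  fit_f <- fit_branch(drv[s_idx], qcd$f_ch4[s_idx], ffs$t_max, ffs$f_at_tmax,
                      branch = "full", intercept = c0)
  h_area <- hysteresis_area(fit_e, fit_l, denominator = h_area_denominator,
                            f_obs = qcd$f_ch4[s_idx])
  h_mu <- hysteresis_mean(qcd$f_ch4[e_idx], qcd$f_ch4[l_idx])
  arr <- tryCatch(fit_arrhenius(drv[s_idx] + 273.15, qcd$f_ch4[s_idx]),
                  error = function(e) NULL)
  branch_summary <- function(idx, fit) {
    all_idx <- if (fit$branch == "earlier") ffs$earlier_idx else ffs$later_idx
    cum <- function(v) sum(v[all_idx], na.rm = TRUE)
    cov <- function(v) mean(!is.na(v[all_idx]))
    tibble::tibble(
      branch = fit$branch, a_hys = fit$a_hys, n_days = length(idx),
      rmse = fit$rmse,
      gpp_cum = cum(qcd$gpp), gpp_coverage = cov(qcd$gpp),
      precip_cum = cum(qcd$precip), precip_coverage = cov(qcd$precip),
      t_mean = mean(drv[all_idx], na.rm = TRUE),
      wtd_mean = mean(qcd$wtd[all_idx], na.rm = TRUE),
      wind_mean = mean(qcd$wind_speed[all_idx], na.rm = TRUE),
      pressure_mean = mean(qcd$pressure[all_idx], na.rm = TRUE))
  }
  sid <- attr(series, "site_id")
  day_rows <- function(idx, br) tibble::tibble(
    site_id = sid, season_year = year,
    site_year = paste(sid, year, sep = "_"), branch = br,
    date = qcd$date[idx], t = drv[idx], f_ch4 = qcd$f_ch4[idx],
    t_max = ffs$t_max, f_at_tmax = ffs$f_at_tmax)
  structure(list(
    site_id = sid, season_year = year,
    driver = season$driver,
    ecosystem_type = if (!is.null(meta)) meta$ecosystem_type[1] else
      NA_character_,
    latitude = if (!is.null(meta)) meta$latitude[1] else NA_real_,
    season = ffs, fit_earlier = fit_e, fit_later = fit_l, fit_full = fit_f,
    h_area = h_area, h_mu = h_mu,
    day_table = dplyr::bind_rows(day_rows(e_idx, "earlier"),
                                 day_rows(l_idx, "later")),
    sign = if (h_area > 0) "positive" else if (h_area < 0) "negative" else
      "zero",
    arrhenius = arr, intercept = c0, intercept_n = intercept_n,
    branch_table = dplyr::bind_rows(branch_summary(e_idx, fit_e),
                                    branch_summary(l_idx, fit_l)),
    earlier_fit_idx = e_idx, later_fit_idx = l_idx,
    resolution = season$resolution),
    class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf("<hysteresis_result> %s %s (%s)\n", x$site_id, x$season_year,
              x$driver))
  cat(sprintf("  H_A = %+.4f (%s), H_mu = %+.3g mg C m-2 d-1\n",
              x$h_area, x$sign, x$h_mu))
  cat(sprintf("  a_earlier = %+.4g, a_later = %+.4g, Tmax = %.1f degC, F@Tmax = %.3g\n",
              x$fit_earlier$a_hys, x$fit_later$a_hys, x$season$t_max,
              x$season$f_at_tmax))
  invisible(x)
}

result_list <- function(results) {
  if (inherits(results, "network_analysis")) results$results else
    if (inherits(results, "hysteresis_result")) list(results) else results
}

#' Summarise hysteresis results, one row per site-year
#'
#' @param results A list of \code{hysteresis_result}s or a
#'   \code{network_analysis}.
#' @return A tibble with the hysteresis statistics, branch parameters,
#'   anchors, season window, and branch day counts.
#' @export
siteyear_summary <- function(results) {
  results <- result_list(results)
  if (length(results) == 0) {
    return(tibble::tibble(
      site_id = character(0), season_year = integer(0), driver = character(0),
      h_area = numeric(0), h_mu = numeric(0), a_earlier = numeric(0),
      a_later = numeric(0), a_full = numeric(0), t_max = numeric(0),
      f_at_tmax = numeric(0), start_date = as.Date(character(0)),
      end_date = as.Date(character(0)), n_earlier = integer(0),
      n_later = integer(0), sign = character(0)))
  }
  purrr::map_dfr(results, function(r) tibble::tibble(
    site_id = r$site_id, season_year = r$season_year, driver = r$driver,
    h_area = r$h_area, h_mu = r$h_mu,
    a_earlier = r$fit_earlier$a_hys, a_later = r$fit_later$a_hys,
    a_full = r$fit_full$a_hys, t_max = r$season$t_max,
    f_at_tmax = r$season$f_at_tmax,
    start_date = r$season$start_date, end_date = r$season$end_date,
    n_earlier = length(r$earlier_fit_idx), n_later = length(r$later_fit_idx),
    sign = r$sign))
}

#' Analyze a multi-site network of daily series
#'
#' Runs [analyze_site_year()] over every site and every calendar season-year
#' its series covers. Site-years that fail (no season, short branches,
#' missing anchor) are skipped with their reason recorded.
#'
#' @param data Named list of \code{daily_series} (names = site codes).
#' @param meta Tibble of site metadata (one [site_meta()] row per site).
#' @param ... Passed to [analyze_site_year()].
#' @return A list of class \code{network_analysis}: \code{results} (list of
#'   \code{hysteresis_result}), \code{summary} (tibble), \code{skipped}
#'   (tibble of site, year, reason).
#' @export
analyze_network <- function(data, meta, ...) {
  results <- list()
  skipped <- list()
  for (sid in names(data)) {
    series <- data[[sid]]
    m <- meta[meta$site_id == sid, , drop = FALSE]
    if (nrow(m) == 0) m <- NULL
    years <- sort(unique(as.integer(format(series$date, "%Y"))))
    if (!is.null(m) && isTRUE(m$latitude[1] < 0)) years <- head(years, -1)
    for (yr in years) {
      res <- tryCatch(
        analyze_site_year(series, meta = m, year = yr, ...),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          site_id = sid, season_year = yr,
          reason = conditionMessage(res))
      } else {
        results[[length(results) + 1L]] <- res
      }
    }
  }
  structure(list(results = results, summary = siteyear_summary(results),
                 skipped = dplyr::bind_rows(skipped)),
            class = "network_analysis")
}

#' @export
print.network_analysis <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("<network_analysis> %d site-years analyzed, %d skipped\n",
              n, nrow(x$skipped)))
  if (n > 0) {
    cat(sprintf("  positive H_A: %.1f%% | positive H_mu: %.1f%%\n",
                100 * mean(x$summary$h_area > 0),
                100 * mean(x$summary$h_mu > 0)))
  }
  invisible(x)
}

#' Fraction of site-years with positive hysteresis
#'
#' @param results A \code{network_analysis} or list of results.
#' @param metric \code{"h_area"} or \code{"h_mu"}.
#' @return Fraction in \[0, 1\].
#' @export
positive_fraction <- function(results, metric = c("h_area", "h_mu")) {
  metric <- match.arg(metric)
  tab <- siteyear_summary(results)
  mean(tab[[metric]] > 0)
}

#' Build the day-level table for the pooled model comparison
#'
#' One row per analyzable season day across all analyzed site-years, carrying
#' the labels every pooled tier can group on (ecosystem type, site, season
#' year, branch) plus the anchors of its site-year.
#'
#' @param results A \code{network_analysis} or list of results.
#' @return A tibble with columns \code{site_id, ecosystem_type, season_year,
#'   site_year, branch, date, t, f_ch4, t_max, f_at_tmax}.
#' @export
build_day_table <- function(results) {
  results <- result_list(results)
  purrr::map_dfr(results, function(r) {
    dplyr::mutate(r$day_table, ecosystem_type = r$ecosystem_type,
                  .after = "site_id")
  })
}
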