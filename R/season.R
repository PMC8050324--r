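## Frost-free season detection and earlier/later branch split.

#' Season-detection policy
#'
#' @param threshold_mode How the biologically active season is thresholded:
#'   \code{"temp_above_zero"} (driver temperature > 0 degC, the frost-free
#'   season), \code{"gpp_above_zero"}, or \code{"gpp_above_5pct_max"}
#'   (GPP above 5\% of its annual maximum).
#' @param driver Which temperature drives the response: \code{"t_air"},
#'   \code{"t_soil_shallow"}, or \code{"t_soil_deep"}.
#' @param hemisphere_wrap Use a 1 July - 30 June season-year window for
#'   southern-hemisphere sites so one austral season stays contiguous.
#' @param min_season_days Shortest acceptable season (default 30 days).
#' @param max_gap_days Interior below-threshold gaps up to this long do not
#'   break the season run (default 3; set 0 for strict contiguity). Gap days
#'   are excluded from fitting.
#' @param resolution \code{"daily"} or \code{"monthly"} analysis resolution.
#' @return A list of class \code{season_policy}.
#' @export
season_policy <- function(threshold_mode = c("temp_above_zero",
                                             "gpp_above_zero",
                                             "gpp_above_5pct_max"),
                          driver = c("t_air", "t_soil_shallow", "t_soil_deep"),
                          hemisphere_wrap = TRUE,
                          min_season_days = 30,
                          max_gap_days = 3,
                          resolution = c("daily", "monthly")) {
  structure(list(threshold_mode = match.arg(threshold_mode),
                 driver = match.arg(driver),
                 hemisphere_wrap = isTRUE(hemisphere_wrap),
                 min_season_days = as.integer(min_season_days),
                 max_gap_days = as.integer(max_gap_days),
                 resolution = match.arg(resolution)),
            class = "season_policy")
}

## Longest run of TRUE positions tolerating interior gaps of <= max_gap.
## Returns indices (into `above`) of the TRUE members of the winning run.
longest_tolerant_run <- function(above, max_gap) {
  idx <- which(above)
  if (length(idx) == 0) return(integer(0))
  breaks <- which(diff(idx) > max_gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  sizes <- ends - starts + 1L
  w <- which.max(sizes)  # ties -> first (earliest) run
  idx[starts[w]:ends[w]]
}

#' Extract the frost-free (or GPP-thresholded) season for one site-year
#'
#' Finds the longest run of above-threshold days inside the site-year window
#' (calendar year, or 1 July - 30 June starting in \code{year} for southern
#' sites when \code{hemisphere_wrap} is on), locates the seasonal driver
#' maximum \eqn{T_{max}} (earliest day on ties), records the CH4 flux
#' measured that day (\eqn{F_{CH4,Tmax}}, the loop anchor), and splits the
#' season into earlier/later branches at that day.
#'
#' If the flux is missing on the \eqn{T_{max}} day, the anchor falls back to
#' the mean flux over the nearest (up to 2 per side) season days whose driver
#' is within 1 degC of \eqn{T_{max}}; if none exist the site-year errors out.
#'
#' @param series A (QC-filtered) \code{daily_series}.
#' @param policy A [season_policy()].
#' @param year Season-year label (integer calendar year; for wrapped southern
#'   sites, the year the window starts in).
#' @param latitude Site latitude, needed for hemisphere wrapping (default
#'   \code{NULL} treats the site as northern).
#' @return A list of class \code{frost_free_season} with elements
#'   \code{idx} (row indices of season days), \code{start_date},
#'   \code{end_date}, \code{t_max}, \code{t_max_day}, \code{f_at_tmax},
#'   \code{earlier_idx}, \code{later_idx}, \code{degenerate}.
#' @export
extract_season <- function(series, policy = season_policy(), year,
                           latitude = NULL) {
  southern <- policy$hemisphere_wrap && !is.null(latitude) &&
    is.finite(latitude) && latitude < 0
  if (southern) {
    win <- c(as.Date(sprintf("%d-07-01", year)),
             as.Date(sprintf("%d-06-30", year + 1L)))
  } else {
    win <- c(as.Date(sprintf("%d-01-01", year)),
             as.Date(sprintf("%d-12-31", year)))
  }
  rows <- which(series$date >= win[1] & series$date <= win[2])
  drv <- series[[policy$driver]][rows]
  above <- switch(policy$threshold_mode,
    temp_above_zero = !is.na(drv) & drv > 0,
    gpp_above_zero = !is.na(series$gpp[rows]) & series$gpp[rows] > 0,
    gpp_above_5pct_max = {
      g <- series$gpp[rows]
      gmax <- suppressWarnings(max(g, na.rm = TRUE))
      !is.na(g) & is.finite(gmax) & g > 0.05 * gmax
    })
  ## season days must also have the driver observed (fits need it)
  above <- above & !is.na(drv)
  run <- longest_tolerant_run(above, policy$max_gap_days)
  if (length(run) < policy$min_season_days) {
    abort(sprintf("No season of >= %d above-threshold days in %s %d.",
                  policy$min_season_days, attr(series, "site_id") %||% "?",
                  year),
          class = "ch4hyst_no_season")
  }
  idx <- rows[run]
  dvals <- series[[policy$driver]][idx]
  t_max <- max(dvals)
  t_max_pos <- which(dvals == t_max)[1]  # earliest occurrence on ties
  t_max_i <- idx[t_max_pos]
  t_max_day <- series$date[t_max_i]
  f_at_tmax <- series$f_ch4[t_max_i]
  fallback <- FALSE
  if (is.na(f_at_tmax)) {
    near <- which(abs(dvals - t_max) <= 1 & !is.na(series$f_ch4[idx]))
    before <- rev(near[near < t_max_pos])
    after <- near[near > t_max_pos]
    cand <- idx[c(head(before, 2), head(after, 2))]
    if (length(cand) == 0) {
      abort(sprintf(
        "CH4 flux missing on the Tmax day (%s) with no near-Tmax fallback.",
        t_max_day), class = "ch4hyst_anchor_error")
    }
    f_at_tmax <- mean(series$f_ch4[cand])
    fallback <- TRUE
  }
  earlier <- idx[idx <= t_max_i]  # Tmax day belongs to the earlier branch
  later <- idx[idx > t_max_i]
  structure(list(
    site_id = attr(series, "site_id"), season_year = year,
    driver = policy$driver, idx = idx,
    start_date = series$date[idx[1]], end_date = series$date[idx[length(idx)]],
    t_max = t_max, t_max_day = t_max_day, f_at_tmax = f_at_tmax,
    f_at_tmax_fallback = fallback,
    earlier_idx = earlier, later_idx = later,
    degenerate = length(earlier) == 0 || length(later) == 0),
    class = "frost_free_season")
}

#' @export
print.frost_free_season <- function(x, ...) {
  cat(sprintf(
    "<frost_free_season> %s %s: %s to %s (%d days), Tmax %.1f on %s, F@Tmax %.2f\n",
    x$site_id %||% "?", x$season_year, x$start_date, x$end_date,
    length(x$idx), x$t_max, x$t_max_day, x$f_at_tmax))
  cat(sprintf("  earlier %d days | later %d days%s\n",
              length(x$earlier_idx), length(x$later_idx),
              if (x$degenerate) " [degenerate branch]" else ""))
  invisible(x)
}

#' Split a season into earlier and later branches
#'
#' Earlier = season days up to and including the seasonal-maximum day; later
#' = days after it. Both branches sharing the \eqn{(T_{max}, F_{CH4,Tmax})}
#' anchor is what closes the hysteresis loop.
#'
#' @param season A \code{frost_free_season}.
#' @return List with \code{earlier}, \code{later} (row indices) and
#'   \code{degenerate} flag.
#' @export
split_branches <- function(season) {
  list(earlier = season$earlier_idx, later = season$later_idx,
       degenerate = season$degenerate)
}

#' Aggregate a daily series to calendar-month means
#'
#' Per month and field, the mean over non-missing days; months with fewer
#' than \code{min_days} valid days for a field become missing for it. Used
#' for the monthly-resolution robustness check of the hysteresis statistics.
#'
#' @param series A \code{daily_series}.
#' @param min_days Minimum valid days per month (default 15).
#' @return A \code{daily_series}-like tibble with one row per month (dated at
#'   the month's 15th).
#' @export
aggregate_monthly <- function(series, min_days = 15) {
  if (nrow(series) == 0) return(new_daily_series(series[0, ],
                                                 attr(series, "site_id")))
  key <- format(series$date, "%Y-%m")
  months <- sort(unique(key))
  out <- tibble::tibble(date = as.Date(paste0(months, "-15")))
  for (f in numeric_fields()) {
    v <- vapply(months, function(m) {
      x <- series[[f]][key == m]
      x <- x[!is.na(x)]
      if (length(x) < min_days) NA_real_ else mean(x)
    }, numeric(1))
    out[[f]] <- unname(v)
  }
  out$f_ch4_gapfilled <- rep(FALSE, nrow(out))
  new_daily_series(out, attr(series, "site_id"))
}
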