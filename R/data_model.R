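## Core records and FLUXNET-CH4-style daily CSV I/O with quality control.

#' Site metadata record
#'
#' @param site_id Short site code, e.g. \code{"JP-BBY"}.
#' @param ecosystem_type One of [ecosystem_types()].
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east, in \[-180, 180\].
#' @return A one-row tibble of class \code{site_meta}.
#' @export
site_meta <- function(site_id, ecosystem_type, latitude, longitude = 0) {
  if (!ecosystem_type %in% ecosystem_types()) {
    abort(sprintf("Unknown ecosystem type '%s'.", ecosystem_type),
          class = "ch4hyst_domain_error")
  }
  stopifnot_scalar_number(latitude, "latitude")
  stopifnot_scalar_number(longitude, "longitude")
  if (abs(latitude) > 90 || abs(longitude) > 180) {
    abort("Coordinates out of range.", class = "ch4hyst_domain_error")
  }
  out <- tibble::tibble(site_id = as.character(site_id),
                        ecosystem_type = ecosystem_type,
                        latitude = latitude, longitude = longitude)
  class(out) <- c("site_meta", class(out))
  out
}

#' Quality-control policy
#'
#' Controls whether gap-filled flux days are usable, the minimum number of
#' analyzable days a seasonal branch must retain, and which driver fields a
#' day must report to count as analyzable.
#'
#' @param use_gapfilled Keep days whose CH4 flux was gap-filled? Default
#'   \code{FALSE}: gap-filled fluxes are examined but excluded from analysis.
#' @param min_days_per_branch Minimum analyzable days per seasonal branch
#'   (default 10, must be >= 3: a one-parameter anchored fit needs at least
#'   one interior point).
#' @param required_fields Fields a day must have non-missing.
#' @return A list of class \code{qc_policy}.
#' @export
qc_policy <- function(use_gapfilled = FALSE, min_days_per_branch = 10,
                      required_fields = c("t_air", "f_ch4")) {
  if (min_days_per_branch < 3) {
    abort("`min_days_per_branch` must be >= 3.", class = "ch4hyst_domain_error")
  }
  structure(list(use_gapfilled = isTRUE(use_gapfilled),
                 min_days_per_branch = as.integer(min_days_per_branch),
                 required_fields = as.character(required_fields)),
            class = "qc_policy")
}

## Canonical internal column names and their FLUXNET-dialect CSV headers.
default_col_map <- function() {
  c(date = "TIMESTAMP", t_air = "TA", t_soil_shallow = "TS_1",
    t_soil_deep = "TS_2", f_ch4 = "FCH4", f_ch4_fill = "FCH4_F",
    f_ch4_fill_flag = "FCH4_F_FLAG", gpp = "GPP", wtd = "WTD",
    precip = "P", wind_speed = "WS", pressure = "PA")
}

numeric_fields <- function() {
  c("t_air", "t_soil_shallow", "t_soil_deep", "f_ch4", "gpp", "wtd",
    "precip", "wind_speed", "pressure")
}

new_daily_series <- function(df, site_id) {
  stopifnot(is.data.frame(df))
  df <- tibble::as_tibble(df)
  if (nrow(df) > 0) {
    if (anyDuplicated(df$date)) {
      abort("Duplicate dates in daily series.", class = "ch4hyst_integrity_error")
    }
    if (is.unsorted(df$date, strictly = TRUE)) {
      abort("Dates must be strictly increasing.",
            class = "ch4hyst_integrity_error")
    }
  }
  for (f in setdiff(c(numeric_fields(), "f_ch4_gapfilled"), names(df))) {
    df[[f]] <- if (f == "f_ch4_gapfilled") rep(FALSE, nrow(df)) else
      rep(NA_real_, nrow(df))
  }
  attr(df, "site_id") <- as.character(site_id)
  class(df) <- unique(c("daily_series", class(df)))
  df
}

#' Assemble a daily series from vectors
#'
#' Builds the universal per-site input record: one row per day with drivers
#' (air/soil temperature, GPP, water-table depth, precipitation, wind,
#' pressure), the CH4 flux (mg C m^-2 d^-1; negative values mean uptake),
#' and a per-day gap-fill flag.
#'
#' @param site_id Site code.
#' @param date Vector of \code{Date}s, strictly increasing.
#' @param t_air Daily mean air temperature, degrees C.
#' @param f_ch4 Daily CH4 flux, mg C m^-2 d^-1.
#' @param ... Further per-day fields among \code{t_soil_shallow, t_soil_deep,
#'   gpp, wtd, precip, wind_speed, pressure, f_ch4_gapfilled}.
#' @return A tibble of class \code{daily_series}.
#' @export
daily_series <- function(site_id, date, t_air = NULL, f_ch4 = NULL, ...) {
  extra <- list(...)
  df <- tibble::tibble(date = as.Date(date))
  if (!is.null(t_air)) df$t_air <- as.numeric(t_air)
  if (!is.null(f_ch4)) df$f_ch4 <- as.numeric(f_ch4)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  new_daily_series(df, site_id)
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> site %s: %d days", attr(x, "site_id"), nrow(x)))
  if (nrow(x) > 0) cat(sprintf(" (%s to %s)", min(x$date), max(x$date)))
  cat(sprintf(", %d measured CH4 flux days\n",
              sum(!is.na(x$f_ch4) & !x$f_ch4_gapfilled)))
  NextMethod()
}

parse_fluxnet_dates <- function(x) {
  x <- as.character(x)
  if (all(grepl("^[0-9]{8}$", x[!is.na(x)]))) {
    as.Date(x, format = "%Y%m%d")
  } else {
    as.Date(x)
  }
}

#' Read a FLUXNET-CH4-style daily CSV table
#'
#' Expects a header row; the timestamp column holds ISO dates or YYYYMMDD
#' integers; missing values are encoded as -9999 or empty cells and are
#' mapped to \code{NA}. If a gap-filled flux column (\code{FCH4_F}) is
#' present, days whose measured flux is missing but whose gap-filled flux is
#' not are flagged gap-filled and take the gap-filled value (a 0/1
#' \code{FCH4_F_FLAG} column, if present, takes precedence as the flag).
#' Unknown columns are preserved unchanged.
#'
#' @param path CSV file path.
#' @param site_id Site code attached to the series (default: file stem).
#' @param col_map Named character vector remapping canonical fields to CSV
#'   headers; see \code{ch4hyst:::default_col_map()} for the default dialect.
#' @return A \code{daily_series}.
#' @export
read_daily_table <- function(path, site_id = NULL, col_map = NULL) {
  map <- default_col_map()
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "-9999", "-9999.0"))
  if (!map[["date"]] %in% names(raw)) {
    abort(sprintf("Timestamp column '%s' not found.", map[["date"]]),
          class = "ch4hyst_format_error")
  }
  if (is.null(site_id)) site_id <- sub("\\.[^.]*$", "", basename(path))
  df <- tibble::tibble(date = parse_fluxnet_dates(raw[[map[["date"]]]]))
  if (anyNA(df$date)) {
    abort("Unparseable timestamps.", class = "ch4hyst_format_error")
  }
  for (f in numeric_fields()) {
    col <- map[[f]]
    if (!is.na(col) && col %in% names(raw)) {
      v <- as.numeric(raw[[col]])
      v[!is.na(v) & v == -9999] <- NA_real_
      df[[f]] <- v
    }
  }
  fill_col <- map[["f_ch4_fill"]]
  flag_col <- map[["f_ch4_fill_flag"]]
  if (!is.na(flag_col) && flag_col %in% names(raw)) {
    df$f_ch4_gapfilled <- !is.na(raw[[flag_col]]) & raw[[flag_col]] > 0
  } else if (!is.na(fill_col) && fill_col %in% names(raw)) {
    fill <- as.numeric(raw[[fill_col]])
    fill[!is.na(fill) & fill == -9999] <- NA_real_
    filled <- is.na(df$f_ch4) & !is.na(fill)
    df$f_ch4[filled] <- fill[filled]
    df$f_ch4_gapfilled <- filled
  } else {
    df$f_ch4_gapfilled <- rep(FALSE, nrow(df))
  }
  known <- unname(map)
  for (col in setdiff(names(raw), known)) df[[col]] <- raw[[col]]
  new_daily_series(df, site_id)
}

#' Write a daily series in the FLUXNET-CH4 CSV dialect
#'
#' Missing values become empty cells; gap-filled flux days are written to the
#' \code{FCH4_F} column and measured days to \code{FCH4}, so a round trip
#' through [read_daily_table()] reproduces the series.
#'
#' @param series A \code{daily_series}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_daily_table <- function(series, path) {
  out <- tibble::tibble(TIMESTAMP = format(series$date, "%Y%m%d"))
  map <- default_col_map()
  measured <- ifelse(series$f_ch4_gapfilled, NA_real_, series$f_ch4)
  filled <- ifelse(series$f_ch4_gapfilled, series$f_ch4, NA_real_)
  for (f in numeric_fields()) {
    v <- if (f == "f_ch4") measured else series[[f]]
    if (any(!is.na(v))) out[[map[[f]]]] <- v
  }
  if (any(series$f_ch4_gapfilled)) out[["FCH4_F"]] <- filled
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply quality control to a daily series
#'
#' Masks (sets to missing) the CH4 flux on days excluded by the policy:
#' gap-filled days when \code{use_gapfilled} is \code{FALSE}, and days
#' lacking any required field. Filtering only; idempotent; the input is not
#' modified.
#'
#' @param series A \code{daily_series}.
#' @param policy A [qc_policy()].
#' @return A new \code{daily_series} with non-analyzable days masked.
#' @export
apply_qc <- function(series, policy = qc_policy()) {
  out <- series
  if (!policy$use_gapfilled) {
    out$f_ch4[out$f_ch4_gapfilled] <- NA_real_
  }
  bad <- rep(FALSE, nrow(out))
  for (f in policy$required_fields) {
    if (!f %in% names(out)) {
      abort(sprintf("Required field '%s' absent from series.", f),
            class = "ch4hyst_domain_error")
    }
    bad <- bad | is.na(out[[f]])
  }
  out$f_ch4[bad] <- NA_real_
  out
}

#' Count analyzable days under a QC policy
#'
#' @param series A \code{daily_series}.
#' @param policy A [qc_policy()].
#' @return Integer count of days usable for fitting.
#' @export
n_analyzable <- function(series, policy = qc_policy()) {
  sum(!is.na(apply_qc(series, policy)$f_ch4))
}

#' Write the per-site-year hysteresis summary CSV
#'
#' One row per (site, season-year, driver) with the hysteresis statistics,
#' branch parameters, anchors, season window, and branch day counts. Values
#' are written at full double precision so a read-back reproduces them.
#'
#' @param results A list of \code{hysteresis_result} objects, or a
#'   \code{network_analysis}.
#' @param path Output CSV path.
#' @return The summary tibble, invisibly.
#' @export
write_siteyear_summary <- function(results, path) {
  tab <- siteyear_summary(results)
  readr::write_csv(tab, path, na = "", progress = FALSE)
  invisible(tab)
}

#' Read back a site-year summary CSV
#'
#' @param path CSV path written by [write_siteyear_summary()].
#' @return A tibble.
#' @export
read_siteyear_summary <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
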