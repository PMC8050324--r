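## Pooled temperature-dependence model groups and bias scoring.
##
## Six regression tiers pool the day-level data at different resolutions
## (global, ecosystem type, site, site-year, optionally split by seasonal
## branch) and fit a quadratic-through-the-origin (or Boltzmann-Arrhenius)
## flux-temperature curve per group; a seventh "hybrid" tier plugs a
## tree-ensemble prediction of the hysteresis parameter into the anchored
## quadratic.

#' The seven temperature-dependence model labels
#'
#' @return Character vector: \code{"T"}, \code{"T+type"}, \code{"T+type+ISV"},
#'   \code{"T+site"}, \code{"T+site+IAV"}, \code{"T+site+IAV+ISV"},
#'   \code{"hybrid"}.
#' @export
tier_labels <- function() {
  c("T", "T+type", "T+type+ISV", "T+site", "T+site+IAV", "T+site+IAV+ISV",
    "hybrid")
}

#' Define a pooled-model tier
#'
#' A tier is named by the variability factors it resolves: \code{type}
#' (ecosystem-type variability), \code{site} (inter-site), \code{IAV}
#' (inter-annual; requires \code{site}), and \code{ISV} (intra-seasonal,
#' i.e. separate earlier/later branch curves). \code{T} (the temperature
#' response itself) is always present.
#'
#' @param label One of [tier_labels()] except \code{"hybrid"}, or any
#'   \code{"+"}-joined combination of valid factors.
#' @return A list of class \code{tier_spec} with \code{label} and
#'   \code{factors}.
#' @export
tier_spec <- function(label) {
  toks <- strsplit(label, "+", fixed = TRUE)[[1]]
  valid <- c("T", "type", "ISV", "site", "IAV")
  if (!all(toks %in% valid)) {
    abort(sprintf("Unknown factor(s): %s.",
                  paste(setdiff(toks, valid), collapse = ", ")),
          class = "ch4hyst_spec_error")
  }
  if (!"T" %in% toks) {
    abort("Every tier resolves T.", class = "ch4hyst_spec_error")
  }
  if ("IAV" %in% toks && !"site" %in% toks) {
    abort("IAV requires site.", class = "ch4hyst_spec_error")
  }
  structure(list(label = label, factors = setdiff(toks, "T")),
            class = "tier_spec")
}

## Grouping columns of the day table for a factor set, coarse -> fine.
factor_columns <- function(factors) {
  cols <- character(0)
  if ("type" %in% factors) cols <- c(cols, "ecosystem_type")
  if ("site" %in% factors) cols <- c(cols, "site_id")
  if ("IAV" %in% factors) cols <- c(cols, "season_year")
  if ("ISV" %in% factors) cols <- c(cols, "branch")
  cols
}

group_key <- function(days, cols) {
  if (length(cols) == 0) rep("(all)", nrow(days)) else
    do.call(paste, c(unname(as.list(days[cols])), sep = "|"))
}

#' Partition day-level data into a tier's fitting groups
#'
#' Groups are the cross-product of the tier's active factors; every
#' analyzable day falls in exactly one group.
#'
#' @param days Day table from [build_day_table()].
#' @param spec A [tier_spec()] (or its label).
#' @return \code{days} with a \code{.group} column added.
#' @export
partition_data <- function(days, spec) {
  if (is.character(spec)) spec <- tier_spec(spec)
  days$.group <- group_key(days, factor_columns(spec$factors))
  days
}

## Fallback order: drop the finest factor first when a group is too small
## or unseen at prediction time.
fallback_chain <- function(factors) {
  chain <- list(factors)
  cur <- factors
  for (drop in c("ISV", "IAV", "site", "type")) {
    if (drop %in% cur) {
      cur <- setdiff(cur, drop)
      chain[[length(chain) + 1L]] <- cur
    }
  }
  chain
}

fit_one_group <- function(t, f, form) {
  if (form == "quadratic_origin") {
    X <- cbind(t, t^2)
    cf <- tryCatch(unname(qr.coef(qr(X), f)),
                   error = function(e) c(NA_real_, NA_real_))
    cf[is.na(cf)] <- 0
    list(b1 = cf[1], b2 = cf[2])
  } else {
    af <- tryCatch(fit_arrhenius(t + 273.15, f), error = function(e) NULL)
    if (is.null(af)) NULL else list(e_a = af$e_a, epsilon = af$epsilon)
  }
}

#' Fit a pooled tier model
#'
#' Per group, either a quadratic through the origin with free linear and
#' quadratic coefficients (\eqn{F = b_1 T + b_2 T^2}, default) or a
#' Boltzmann-Arrhenius curve, by least squares. Groups with fewer than
#' \code{min_group_n} days inherit the fit of their parent group (factors
#' dropped finest-first: ISV, IAV, site, type), as do unseen groups at
#' prediction time.
#'
#' @param days Day table from [build_day_table()].
#' @param spec A [tier_spec()] or its label.
#' @param form \code{"quadratic_origin"} or \code{"arrhenius"}.
#' @param min_group_n Minimum days for a group to get its own fit.
#' @return A list of class \code{tier_model}.
#' @export
fit_tier <- function(days, spec, form = c("quadratic_origin", "arrhenius"),
                     min_group_n = 3) {
  if (is.character(spec)) spec <- tier_spec(spec)
  form <- match.arg(form)
  days <- days[!is.na(days$t) & !is.na(days$f_ch4), , drop = FALSE]
  chain <- fallback_chain(spec$factors)
  levels <- lapply(chain, function(factors) {
    cols <- factor_columns(factors)
    key <- group_key(days, cols)
    fits <- list()
    for (k in unique(key)) {
      sel <- key == k
      if (sum(sel) < min_group_n) next
      g <- fit_one_group(days$t[sel], days$f_ch4[sel], form)
      if (!is.null(g)) fits[[k]] <- c(g, n = sum(sel))
    }
    list(cols = cols, fits = fits)
  })
  if (all(vapply(levels, function(l) length(l$fits) == 0, logical(1)))) {
    abort("No group could be fit at any fallback level.",
          class = "ch4hyst_tier_error")
  }
  structure(list(spec = spec, form = form, levels = levels,
                 min_group_n = min_group_n),
            class = "tier_model")
}

#' @export
print.tier_model <- function(x, ...) {
  cat(sprintf("<tier_model %s, %s> %d group(s) at finest level\n",
              x$spec$label, x$form, length(x$levels[[1]]$fits)))
  invisible(x)
}

eval_group <- function(g, t, form) {
  if (form == "quadratic_origin") g$b1 * t + g$b2 * t^2 else
    exp(g$epsilon + g$e_a * (-1 / (BOLTZMANN_EV * (t + 273.15))))
}

#' Predict daily flux from a pooled tier model
#'
#' Each day is scored by its group's curve; days whose group was unseen or
#' too small fall back to the parent group's curve (with one warning).
#'
#' @param model A \code{tier_model}.
#' @param days Day table rows to predict.
#' @return Numeric vector of predicted fluxes, mg C m^-2 d^-1.
#' @export
predict_tier <- function(model, days) {
  pred <- rep(NA_real_, nrow(days))
  unresolved <- 0L
  for (lev in seq_along(model$levels)) {
    level <- model$levels[[lev]]
    todo <- which(is.na(pred))
    if (length(todo) == 0) break
    key <- group_key(days[todo, , drop = FALSE], level$cols)
    for (k in unique(key)) {
      g <- level$fits[[k]]
      if (is.null(g)) next
      sel <- todo[key == k]
      pred[sel] <- eval_group(g, days$t[sel], model$form)
      if (lev > 1) unresolved <- unresolved + length(sel)
    }
  }
  if (unresolved > 0) {
    warn(sprintf("%d day(s) scored by a coarser fallback group.",
                 unresolved))
  }
  pred
}

#' Absolute bias of predictions relative to observations
#'
#' \eqn{100 \sum_i |pred_i - obs_i| / \sum_i obs_i}, in percent.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return Percentage (>= 0).
#' @export
absolute_bias <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  keep <- !is.na(pred) & !is.na(obs)
  denom <- sum(obs[keep])
  if (denom <= 0) {
    abort("Sum of observations must be positive for the bias ratio.",
          class = "ch4hyst_undefined_bias")
  }
  100 * sum(abs(pred[keep] - obs[keep])) / denom
}

#' Signed branch-wise prediction bias across site-years
#'
#' Per site-year and branch, the signed relative bias
#' \eqn{100 (\sum pred - \sum obs)/\sum obs} (overprediction positive);
#' reported as mean and sample SD across site-years per branch. Site-years
#' with non-positive observed totals are excluded and counted.
#'
#' @param pred,obs Day-level predictions and observations.
#' @param site_year Site-year label per day.
#' @param branch Branch label per day (\code{"earlier"}/\code{"later"}).
#' @return A list with \code{per_siteyear} (tibble), \code{summary} (tibble
#'   of branch, mean, sd, n), and \code{n_excluded}.
#' @export
branch_bias <- function(pred, obs, site_year, branch) {
  tab <- tibble::tibble(pred = pred, obs = obs, site_year = site_year,
                        branch = branch)
  tab <- tab[!is.na(tab$pred) & !is.na(tab$obs), , drop = FALSE]
  per <- tab |>
    dplyr::group_by(.data$site_year, .data$branch) |>
    dplyr::summarise(sum_pred = sum(.data$pred), sum_obs = sum(.data$obs),
                     .groups = "drop")
  bad <- per$sum_obs <= 0
  n_excluded <- sum(bad)
  per <- per[!bad, , drop = FALSE]
  per$bias_pct <- 100 * (per$sum_pred - per$sum_obs) / per$sum_obs
  summary <- per |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(mean_pct = mean(.data$bias_pct),
                     sd_pct = sd(.data$bias_pct),
                     n = dplyr::n(), .groups = "drop")
  list(per_siteyear = per, summary = summary, n_excluded = n_excluded)
}

#' Evaluate the tier hierarchy on a day table
#'
#' Fits and scores every requested regression tier (and optionally the
#' hybrid model) on the same prediction days, reporting absolute bias per
#' ecosystem type and overall, branch-wise signed biases, and the per-day
#' predictions (for error-vs-magnitude scatter summaries).
#'
#' @param days Day table from [build_day_table()].
#' @param specs Tier labels to fit (default: the six regression tiers).
#' @param form Group functional form, as in [fit_tier()].
#' @param hybrid Optional \code{ahys_regressor} (adds the \code{"hybrid"}
#'   tier); requires \code{training} rows covering the day table's
#'   site-year/branches.
#' @param training Training table from [build_training_table()], needed for
#'   the hybrid tier.
#' @return A list of class \code{tier_evaluation}: \code{bias_overall},
#'   \code{bias_by_type}, \code{branch_bias}, \code{predictions}.
#' @export
evaluate_tiers <- function(days, specs = setdiff(tier_labels(), "hybrid"),
                           form = "quadratic_origin", hybrid = NULL,
                           training = NULL) {
  days <- days[!is.na(days$t) & !is.na(days$f_ch4), , drop = FALSE]
  preds <- list()
  for (lab in specs) {
    model <- fit_tier(days, lab, form = form)
    preds[[lab]] <- suppressWarnings(predict_tier(model, days))
  }
  if (!is.null(hybrid)) {
    if (is.null(training)) {
      abort("`training` table required for the hybrid tier.",
            class = "ch4hyst_spec_error")
    }
    preds[["hybrid"]] <- hybrid_predict_days(hybrid, days, training)
  }
  bias_overall <- purrr::imap_dfr(preds, function(p, lab) tibble::tibble(
    tier = lab, absolute_bias_pct = absolute_bias(p, days$f_ch4),
    n_days = sum(!is.na(p))))
  bias_by_type <- purrr::imap_dfr(preds, function(p, lab) {
    days |>
      dplyr::mutate(pred = p) |>
      dplyr::group_by(.data$ecosystem_type) |>
      dplyr::summarise(
        tier = lab,
        absolute_bias_pct = absolute_bias(.data$pred, .data$f_ch4),
        n_sites = dplyr::n_distinct(.data$site_id),
        n_days = dplyr::n(), .groups = "drop")
  })
  branch <- purrr::imap_dfr(preds, function(p, lab) {
    bb <- branch_bias(p, days$f_ch4, days$site_year, days$branch)
    dplyr::mutate(bb$summary, tier = lab, .before = 1)
  })
  long <- purrr::imap_dfr(preds, function(p, lab) tibble::tibble(
    tier = lab, site_year = days$site_year, branch = days$branch,
    t = days$t, obs = days$f_ch4, pred = p))
  structure(list(bias_overall = bias_overall, bias_by_type = bias_by_type,
                 branch_bias = branch, predictions = long),
            class = "tier_evaluation")
}

#' @export
print.tier_evaluation <- function(x, ...) {
  cat("<tier_evaluation>\n")
  ord <- order(x$bias_overall$absolute_bias_pct, decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-16s %6.1f%% absolute bias (%d days)\n",
                x$bias_overall$tier[i], x$bias_overall$absolute_bias_pct[i],
                x$bias_overall$n_days[i]))
  }
  invisible(x)
}
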