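## Tree-ensemble regression of the hysteresis parameter and the hybrid
## flux model that plugs its prediction into the anchored quadratic.

#' The ten default hysteresis-parameter predictors
#'
#' Four categorical (seasonal branch, ecosystem type, site, site-year) and
#' six numeric (branch-cumulative GPP and precipitation, seasonal maximum
#' temperature, branch mean temperature, latitude, flux at the seasonal
#' temperature maximum).
#'
#' @return Character vector of length 10.
#' @export
ahys_predictors <- function() {
  c("seasonal_branch", "gpp_cum_branch", "precip_cum_branch", "t_max",
    "t_mean_branch", "ecosystem_type", "latitude", "site_id", "site_year",
    "f_at_tmax")
}

ahys_categoricals <- function() {
  c("seasonal_branch", "ecosystem_type", "site_id", "site_year")
}

## Extra predictors computed and stored but excluded by default (limited
## predictive power on a_hys).
ahys_extra_predictors <- function() {
  c("year", "wtd_mean_branch", "wind_mean_branch", "pressure_mean_branch")
}

#' Build the hysteresis-parameter training table
#'
#' One row per (site-year, branch) with a valid branch fit: the response
#' \code{a_hys} plus the ten default predictors and the stored extras.
#' Branch-cumulative GPP/precipitation sums skip missing days; their
#' coverage fractions are recorded. Rows with missing latitude are dropped
#' and counted in the \code{n_dropped} attribute.
#'
#' @param results A \code{network_analysis} or list of
#'   \code{hysteresis_result}s.
#' @return A tibble, one row per branch fit.
#' @export
build_training_table <- function(results) {
  results <- result_list(results)
  tab <- purrr::map_dfr(results, function(r) {
    bt <- r$branch_table
    tibble::tibble(
      site_id = r$site_id, season_year = r$season_year,
      site_year = paste(r$site_id, r$season_year, sep = "_"),
      seasonal_branch = bt$branch, a_hys = bt$a_hys,
      gpp_cum_branch = bt$gpp_cum, gpp_coverage = bt$gpp_coverage,
      precip_cum_branch = bt$precip_cum,
      precip_coverage = bt$precip_coverage,
      t_max = r$season$t_max, t_mean_branch = bt$t_mean,
      ecosystem_type = r$ecosystem_type, latitude = r$latitude,
      f_at_tmax = r$season$f_at_tmax,
      year = r$season_year, wtd_mean_branch = bt$wtd_mean,
      wind_mean_branch = bt$wind_mean,
      pressure_mean_branch = bt$pressure_mean,
      n_days_branch = bt$n_days)
  })
  drop <- is.na(tab$latitude)
  out <- tab[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}

## Deterministic ordinal label-coding of categorical predictors: integer
## codes fixed by first appearance in the training table; unseen levels at
## prediction time get code 0 (below every training code).
encode_table <- function(table, predictors, levels = NULL) {
  out <- table[intersect(predictors, names(table))]
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing predictor column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "ch4hyst_spec_error")
  }
  learned <- is.null(levels)
  if (learned) levels <- list()
  for (col in intersect(ahys_categoricals(), predictors)) {
    v <- as.character(out[[col]])
    if (learned) levels[[col]] <- unique(v)
    code <- match(v, levels[[col]])
    code[is.na(code)] <- 0L
    out[[col]] <- code
  }
  list(x = as.data.frame(out), levels = levels)
}

#' Fit the seeded tree-ensemble regressor for a_hys
#'
#' A random-forest regression of the hysteresis parameter on the ten default
#' predictors (or a supplied subset/superset). Categorical predictors are
#' label-coded deterministically by first appearance. Identical seed and
#' data give identical predictions.
#'
#' @param table Training table from [build_training_table()] (>= 30 rows).
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed (default 20210415).
#' @param predictors Predictor columns (default [ahys_predictors()]).
#' @param include_extras Also use the stored low-power extras
#'   ([ahys_extra_predictors()])? Default \code{FALSE}.
#' @param mtry Candidate predictors per split; default half the predictor
#'   count (regression with few strong predictors needs a larger draw than
#'   the square-root convention).
#' @param min_node_size Minimum node size (default 3, the usual regression
#'   setting).
#' @return A list of class \code{ahys_regressor}: the fitted forest,
#'   encoding levels, out-of-bag MSE and R-squared, and the configuration.
#' @export
fit_ahys_regressor <- function(table, n_trees = 500, seed = 20210415,
                               predictors = ahys_predictors(),
                               include_extras = FALSE,
                               mtry = NULL, min_node_size = 3) {
  if (include_extras) {
    predictors <- union(predictors, ahys_extra_predictors())
  }
  table <- table[!is.na(table$a_hys), , drop = FALSE]
  if (nrow(table) < 30) {
    abort("Need >= 30 training rows for the a_hys regressor.",
          class = "ch4hyst_insufficient_data")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(length(predictors) / 2))
  enc <- encode_table(table, predictors)
  rf <- ranger::ranger(
    x = enc$x, y = table$a_hys, num.trees = n_trees, seed = seed,
    num.threads = 1, oob.error = TRUE, mtry = mtry,
    min.node.size = min_node_size,
    respect.unordered.factors = "ignore")
  oob_mse <- rf$prediction.error
  structure(list(model = rf, predictors = predictors, levels = enc$levels,
                 n_trees = n_trees, seed = seed, mtry = mtry,
                 min_node_size = min_node_size,
                 oob_mse = oob_mse, oob_r_squared = rf$r.squared,
                 n_rows = nrow(table)),
            class = "ahys_regressor")
}

#' @export
print.ahys_regressor <- function(x, ...) {
  cat(sprintf(
    "<ahys_regressor> %d trees, seed %d, %d rows, OOB R2 = %.3f\n",
    x$n_trees, x$seed, x$n_rows, x$oob_r_squared))
  invisible(x)
}

#' Predict the hysteresis parameter for new branch rows
#'
#' @param regressor An \code{ahys_regressor}.
#' @param table Rows with the predictor columns (unseen categorical levels
#'   are coded below every training level).
#' @return Numeric vector of predicted \code{a_hys}.
#' @export
predict_ahys <- function(regressor, table) {
  enc <- encode_table(table, regressor$predictors, regressor$levels)
  as.numeric(predict(regressor$model, data = enc$x,
                     num.threads = 1)$predictions)
}

#' Permutation importance of the a_hys predictors
#'
#' Per predictor, the mean increase in in-sample mean squared prediction
#' error over \code{n_repeats} seeded permutations of that column, ranked
#' descending. A predictor the response does not depend on scores near 0.
#'
#' @param regressor An \code{ahys_regressor}.
#' @param table The table to score on (typically the training table).
#' @param n_repeats Permutations per predictor (default 10).
#' @param seed RNG seed for the permutations.
#' @return A tibble of class \code{importance_report}: \code{predictor},
#'   \code{importance} (MSE increase), \code{rank}.
#' @export
permutation_importance <- function(regressor, table, n_repeats = 10,
                                   seed = 20210415) {
  table <- table[!is.na(table$a_hys), , drop = FALSE]
  base_mse <- mean((predict_ahys(regressor, table) - table$a_hys)^2)
  imp <- with_seed(seed, {
    vapply(regressor$predictors, function(p) {
      mses <- vapply(seq_len(n_repeats), function(r) {
        perm <- table
        perm[[p]] <- perm[[p]][sample.int(nrow(perm))]
        mean((predict_ahys(regressor, perm) - perm$a_hys)^2)
      }, numeric(1))
      mean(mses) - base_mse
    }, numeric(1))
  })
  out <- tibble::tibble(predictor = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("importance_report", class(out))
  out
}

#' Grouped-holdout error of the a_hys regressor
#'
#' Leave-one-group-out cross-validation (default: leave-site-out). Because
#' site and site-year identifiers are themselves predictors, the in-sample
#' fit is near-perfect by construction; this grouped holdout is the honest
#' error and should always be reported alongside it.
#'
#' @param table Training table.
#' @param group Grouping column (default \code{"site_id"}).
#' @param ... Passed to [fit_ahys_regressor()] (e.g. \code{n_trees},
#'   \code{seed}).
#' @return A list: \code{mse}, \code{r_squared}, \code{in_sample_mse},
#'   \code{predictions} (tibble).
#' @export
grouped_holdout_error <- function(table, group = "site_id", ...) {
  table <- table[!is.na(table$a_hys), , drop = FALSE]
  groups <- unique(table[[group]])
  preds <- rep(NA_real_, nrow(table))
  for (g in groups) {
    hold <- table[[group]] == g
    reg <- fit_ahys_regressor(table[!hold, , drop = FALSE], ...)
    preds[hold] <- predict_ahys(reg, table[hold, , drop = FALSE])
  }
  full <- fit_ahys_regressor(table, ...)
  in_mse <- mean((predict_ahys(full, table) - table$a_hys)^2)
  mse <- mean((preds - table$a_hys)^2)
  list(mse = mse,
       r_squared = 1 - mse / mean((table$a_hys - mean(table$a_hys))^2),
       in_sample_mse = in_mse,
       predictions = tibble::tibble(group = table[[group]],
                                    a_hys = table$a_hys, pred = preds))
}

#' Hybrid daily flux prediction
#'
#' Predicts each branch's hysteresis parameter with the tree ensemble and
#' evaluates the anchored quadratic with the site-year's own
#' \eqn{(T_{max}, F_{Tmax})} anchors: at \eqn{T = T_{max}} the prediction
#' equals the measured anchor flux regardless of the predicted parameter.
#'
#' @param regressor An \code{ahys_regressor}.
#' @param days Day table rows (need \code{site_year}, \code{branch},
#'   \code{t}, \code{t_max}, \code{f_at_tmax}).
#' @param training Branch rows from [build_training_table()] supplying the
#'   predictor values per (site-year, branch).
#' @return Numeric vector of daily flux predictions.
#' @export
hybrid_predict_days <- function(regressor, days, training) {
  key_t <- paste(training$site_year, training$seasonal_branch, sep = "#")
  a_hat <- predict_ahys(regressor, training)
  idx <- match(paste(days$site_year, days$branch, sep = "#"), key_t)
  if (anyNA(idx)) {
    abort("Day rows without a matching (site-year, branch) training row.",
          class = "ch4hyst_anchor_error")
  }
  a <- a_hat[idx]
  a * (days$t^2 - days$t_max * days$t) +
    (days$f_at_tmax / days$t_max) * days$t
}
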