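#' @title Random-forest variable importance with permutation significance
#' @description Regression random forests ranking the 13 standard plant /
#'   soil-abiotic / soil-biotic covariates as predictors of the microbial-
#'   and plant-derived carbon pools, with a response-permutation null for
#'   per-predictor significance and grouped variance shares.
#' @name variable_importance
NULL

#' Default predictor set and grouping
#'
#' The 13 covariates used to explain the derived carbon pools, grouped as
#' plant biomass, soil abiotic and soil biotic factors. The membership is
#' configuration, not a law: pass your own list to regroup.
#'
#' @return Named list mapping group name to predictor columns.
#' @export
default_predictor_groups <- function() {
  list(
    plant_biomass = "plant_biomass",
    soil_abiotic = c("ph", "tp", "tn", "doc", "cec", "clay", "water_content",
                     "fe_al_o", "fe_al_d", "fe_al_p"),
    soil_biotic = c("plfa_fungal", "plfa_bacterial",
                    "ligninase_cellulase_ratio")
  )
}

groups_to_map <- function(groups) {
  stats::setNames(rep(names(groups), lengths(groups)), unlist(groups))
}

#' Random-forest importance of predictors for one response
#'
#' Fits a regression random forest and reports, per predictor, the
#' out-of-bag permutation importance expressed as percent increase in OOB
#' mean squared error (100 x mean MSE increase under within-predictor
#' permutation / OOB MSE). Significance is assessed against a null built by
#' refitting the forest `n_perm` times with the response permuted:
#' p = (1 + #\{null importance >= observed\}) / (n_perm + 1). The whole
#' procedure is deterministic for a fixed seed.
#'
#' @param data Data frame containing the response and predictors.
#' @param response Response column name; must be non-constant.
#' @param predictors Character vector of predictor columns (default: the 13
#'   standard covariates from [default_predictor_groups()]).
#' @param groups Named list mapping group -> predictors for the grouped
#'   shares; predictors outside any group are labelled `"ungrouped"`.
#' @param n_trees Trees per forest (default 1000).
#' @param n_perm Response permutations for the null (default 199; below 99
#'   a warning is emitted because the p-values become unstable).
#' @param mtry Predictors sampled per split; default `ceiling(p/3)`.
#' @param seed Integer seed (mandatory for reports).
#' @return Object of class `soc_importance`: `response`, `table` (predictor,
#'   group, importance, p, stars), `explained_variance` (% of response
#'   variance explained out-of-bag), `group_shares`, `n`, `seed` and the
#'   forest settings.
#' @export
rf_importance <- function(data, response,
                          predictors = unlist(default_predictor_groups(),
                                              use.names = FALSE),
                          groups = default_predictor_groups(),
                          n_trees = 1000, n_perm = 199, mtry = NULL,
                          seed = 42) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(c(response, predictors), names(data))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < 8) stop("need at least 8 rows", call. = FALSE)
  y <- data[[response]]
  x <- data[, predictors, drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1))) || !is.numeric(y)) {
    stop("response and predictors must be numeric", call. = FALSE)
  }
  if (stats::var(y) == 0) stop("response is constant", call. = FALSE)
  if (n_perm < 99) {
    warning("n_perm < 99 gives unstable permutation p-values", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- ceiling(length(predictors) / 3)

  set.seed(as.integer(seed))
  pct_inc_mse <- function(yy) {
    rf <- randomForest::randomForest(x, yy, ntree = n_trees, mtry = mtry,
                                     importance = TRUE)
    raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    oob_mse <- rf$mse[n_trees]
    list(imp = 100 * raw / oob_mse, mse = oob_mse)
  }
  obs <- pct_inc_mse(y)
  null_ge <- rep(0L, length(predictors))
  for (b in seq_len(n_perm)) {
    null_imp <- pct_inc_mse(sample(y))$imp
    null_ge <- null_ge + as.integer(null_imp >= obs$imp)
  }
  p <- (1 + null_ge) / (n_perm + 1)

  map <- groups_to_map(groups)
  group <- unname(ifelse(predictors %in% names(map), map[predictors],
                         "ungrouped"))
  tab <- data.frame(predictor = predictors, group = group,
                    importance = unname(obs$imp), p = p,
                    stars = p_stars(p), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance), ]
  rownames(tab) <- NULL
  res <- structure(list(
    response = response, table = tab,
    explained_variance = 100 * (1 - obs$mse / (stats::var(y) * (length(y) - 1) / length(y))),
    n = nrow(data), n_trees = n_trees, n_perm = n_perm, mtry = mtry,
    seed = seed
  ), class = "soc_importance")
  res$group_shares <- grouped_contribution(res)
  res
}

#' Grouped share of total importance
#'
#' Aggregates per-predictor importances into per-group percentages of the
#' total. Negative permutation importances (common for pure-noise
#' predictors) are floored at zero for the share computation only; the raw
#' values stay in the importance table.
#'
#' @param result A `soc_importance` object, or a data frame with
#'   `importance` and `group` columns.
#' @return Named numeric vector of group shares summing to 100.
#' @export
grouped_contribution <- function(result) {
  tab <- if (inherits(result, "soc_importance")) result$table else result
  stopifnot(is.data.frame(tab), all(c("importance", "group") %in% names(tab)))
  imp <- pmax(tab$importance, 0)
  total <- sum(imp)
  if (total <= 0) {
    stop("total (floored) importance is not positive; shares undefined",
         call. = FALSE)
  }
  shares <- tapply(imp, tab$group, sum) / total * 100
  out <- as.numeric(shares)
  names(out) <- names(shares)
  out
}

#' @export
print.soc_importance <- function(x, ...) {
  cat(sprintf("Random-forest importance for '%s' (n = %d, %d trees, %d permutations, seed %s)\n",
              x$response, x$n, x$n_trees, x$n_perm, format(x$seed)))
  cat(sprintf("OOB explained variance: %.1f%%\n", x$explained_variance))
  print(transform(x$table, importance = round(importance, 2),
                  p = signif(p, 3)), row.names = FALSE)
  cat("Group shares (% of total importance):\n")
  print(round(x$group_shares, 1))
  invisible(x)
}
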