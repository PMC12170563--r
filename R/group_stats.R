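#' @title Two-group contrasts and degradation-index regressions
#' @name group_stats
NULL

p_stars <- function(p) {
  ifelse(is.na(p), "ns", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Independent two-sample comparison of one variable
#'
#' Classic independent-sample t test (pooled-variance Student by default,
#' Welch by flag) with group summaries and the percent difference of group b
#' relative to group a. Degenerate zero-variance input is resolved without
#' an exception: equal constant groups give t = 0, p = 1; unequal constant
#' groups give infinite t and p = 0.
#'
#' @param values_a,values_b Numeric vectors (>= 2 finite values each);
#'   conventionally a = broadleaf (reference), b = moso bamboo.
#' @param method `"student"` (pooled variance) or `"welch"`.
#' @param variable Optional variable name carried into the result.
#' @return A list of class `soc_group_comparison`: `variable`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p`, `pct_diff`
#'   (100 * (mean_b - mean_a) / mean_a), `stars` (`**` p < 0.01, `*`
#'   p < 0.05, `ns` otherwise) and `method`.
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("student", "welch"),
                           variable = NA_character_) {
  method <- match.arg(method)
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop("groups must contain only finite values", call. = FALSE)
  }
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  m_a <- mean(values_a); m_b <- mean(values_b)
  s_a <- stats::sd(values_a); s_b <- stats::sd(values_b)

  if (s_a == 0 && s_b == 0) {
    if (m_a == m_b) {
      t_stat <- 0; df <- length(values_a) + length(values_b) - 2; p <- 1
    } else {
      t_stat <- sign(m_b - m_a) * Inf
      df <- length(values_a) + length(values_b) - 2; p <- 0
    }
  } else {
    tt <- stats::t.test(values_b, values_a, var.equal = (method == "student"))
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(
    variable = variable, mean_a = m_a, sd_a = s_a, mean_b = m_b, sd_b = s_b,
    t = t_stat, df = df, p = p,
    pct_diff = 100 * (m_b - m_a) / m_a,
    stars = p_stars(p), method = method
  ), class = "soc_group_comparison")
}

#' @export
print.soc_group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.3f vs %.3f (%+.2f%%), t = %.3f, df = %.1f, p = %.4g %s\n",
              ifelse(is.na(x$variable), "comparison", x$variable),
              x$mean_a, x$mean_b, x$pct_diff, x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Ordinary least-squares regression with slope test
#'
#' Simple linear regression y ~ x, used for the lignin degradation-index
#' relations (total lignin against the acid-to-aldehyde ratios).
#'
#' @param x,y Numeric vectors, n >= 3, finite; x must vary.
#' @return A list of class `soc_regression`: `slope`, `intercept`,
#'   `r_squared`, `p` (two-sided slope test), `slope_ci` (95% interval),
#'   `n`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit)["x", ]
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p = if (nrow(sm$coefficients) > 1) sm$coefficients["x", 4] else NA_real_,
    slope_ci = unname(ci),
    n = length(x)
  ), class = "soc_regression")
}

#' @export
print.soc_regression <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x; R^2 = %.3f, p = %.4g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p, x$n))
  invisible(x)
}

# Variables contrasted by default, in reporting order
default_contrast_variables <- function() {
  c("soc",
    "v_total", "s_total", "c_total", "lignin_total",
    "glcn", "galn", "murn",
    "ac_al_v", "ac_al_s",
    "plant_c", "fungal_c", "bacterial_c", "microbial_c",
    "plant_fraction", "fungal_fraction", "bacterial_fraction",
    "microbial_fraction")
}

#' Forest-type contrast table
#'
#' Runs [compare_groups()] for every requested variable of an attributed
#' plot table (broadleaf as reference group a, Moso bamboo as group b) and
#' assembles one report row per variable. Variables absent from the table
#' are skipped with a warning. The `ratio_m_over_b` column reports the
#' moso/broadleaf ratio of group means, the convention used for the pool
#' comparisons (e.g. microbial-derived C "0.75 times").
#'
#' @param attributed Data frame from [attribute_table()] (must contain
#'   `forest_type`).
#' @param variables Character vector of columns to contrast; defaults to
#'   the standard reporting set (SOC, lignin classes, amino sugars, Ac/Al
#'   indices, derived pools and fractions).
#' @inheritParams compare_groups
#' @return Data frame with one row per variable: group means/SDs, t, df, p,
#'   `pct_diff`, `ratio_m_over_b`, `stars`.
#' @export
summarize_forest_contrast <- function(attributed,
                                      variables = default_contrast_variables(),
                                      method = c("student", "welch")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(attributed), "forest_type" %in% names(attributed))
  if (!all(attributed$forest_type %in% .forest_levels)) {
    stop("forest_type must be one of: ", paste(.forest_levels, collapse = ", "),
         call. = FALSE)
  }
  a <- attributed[attributed$forest_type == "broadleaf", , drop = FALSE]
  b <- attributed[attributed$forest_type == "moso_bamboo", , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("need at least 2 plots per forest type", call. = FALSE)
  }
  present <- variables[variables %in% names(attributed)]
  absent <- setdiff(variables, present)
  if (length(absent) > 0) {
    warning("skipping missing variable(s): ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  rows <- lapply(present, function(v) {
    cmp <- compare_groups(a[[v]], b[[v]], method = method, variable = v)
    data.frame(variable = v,
               mean_broadleaf = cmp$mean_a, sd_broadleaf = cmp$sd_a,
               mean_moso = cmp$mean_b, sd_moso = cmp$sd_b,
               t = cmp$t, df = cmp$df, p = cmp$p,
               pct_diff = cmp$pct_diff,
               ratio_m_over_b = cmp$mean_b / cmp$mean_a,
               stars = cmp$stars,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
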