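#' @title Recursive path model with standardized coefficients and fit indices
#' @description Maximum-likelihood path analysis for recursive (acyclic)
#'   systems of observed variables. All variables are z-scored before
#'   estimation, so path coefficients are standardized by construction. For
#'   a recursive system with uncorrelated disturbances and a saturated
#'   exogenous block, the ML solution coincides with equation-wise ordinary
#'   least squares; the discrepancy function F_ML between the sample and
#'   model-implied covariance then yields the chi-square, RMSEA and CFI fit
#'   indices.
#' @name path_model
NULL

#' Define a recursive path model
#'
#' @param edges Character vector of `"source -> target"` strings, or a data
#'   frame with `source` and `target` columns. The graph must be acyclic.
#' @param composites Optional named list of composite definitions; each
#'   element is `list(indicators = c(...), orientation = "var")` and defines
#'   a node computed by [build_composite()] before fitting.
#' @param extra_variables Observed variables to include in the model without
#'   any directed path (they join the saturated exogenous block, so their
#'   covariances with modelled variables contribute to the fit test).
#' @return Object of class `soc_path_spec` with `edges`, `composites` and
#'   the derived `variables`, `endogenous` and `exogenous` sets.
#' @export
path_model_spec <- function(edges, composites = list(),
                            extra_variables = character(0)) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) {
      stop("malformed edge(s): ", paste(edges[bad], collapse = ", "),
           call. = FALSE)
    }
    edges <- data.frame(source = trimws(vapply(parts, `[`, "", 1)),
                        target = trimws(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  if (nrow(edges) == 0) stop("model needs at least one edge", call. = FALSE)
  topological_order(edges$source, edges$target) # errors on cycles
  for (nm in names(composites)) {
    comp <- composites[[nm]]
    if (is.null(comp$indicators) || length(comp$indicators) < 2) {
      stop("composite '", nm, "' needs at least 2 indicators", call. = FALSE)
    }
    if (is.null(comp$orientation)) {
      stop("composite '", nm, "' needs an orientation variable", call. = FALSE)
    }
  }
  variables <- unique(c(edges$source, edges$target, extra_variables))
  endogenous <- unique(edges$target)
  structure(list(edges = edges, composites = composites,
                 variables = variables, endogenous = endogenous,
                 exogenous = setdiff(variables, endogenous)),
            class = "soc_path_spec")
}

#' Standard mineral-protection path model
#'
#' The default hypothesis graph for the forest-conversion analysis: soil pH,
#' the ligninase/cellulase ratio and a mineral-properties composite act on
#' microbial-derived C; the mineral composite also acts on plant-derived C;
#' both pools feed SOC. The mineral composite is the first principal
#' component of the poorly crystalline and free Fe+Al oxide pools and CEC
#' (`fe_al_o`, `fe_al_d`, `cec`), oriented to track `fe_al_o`; add
#' `fe_al_p` via the `include_fe_al_p` switch.
#'
#' @param include_fe_al_p Also include the organically complexed oxide pool
#'   among the composite indicators.
#' @return A `soc_path_spec` with 6 edges.
#' @export
default_study_spec <- function(include_fe_al_p = FALSE) {
  indicators <- c("fe_al_o", "fe_al_d", "cec")
  if (include_fe_al_p) indicators <- c(indicators, "fe_al_p")
  path_model_spec(
    edges = c(
      "ph -> microbial_c",
      "ligninase_cellulase_ratio -> microbial_c",
      "mineral_composite -> microbial_c",
      "mineral_composite -> plant_c",
      "microbial_c -> soc",
      "plant_c -> soc"
    ),
    composites = list(
      mineral_composite = list(indicators = indicators,
                               orientation = "fe_al_o")
    )
  )
}

#' First-principal-component composite score
#'
#' Builds a single composite variable from several indicators: indicators
#' are z-scored, their first principal component extracted, the component
#' sign-oriented to correlate non-negatively with the orientation variable,
#' and the scores z-scored again. Zero-variance indicators are dropped with
#' a warning.
#'
#' @param table Data frame with the indicator and orientation columns.
#' @param indicators Character vector (>= 2) of indicator columns.
#' @param orientation_var Column whose positive direction fixes the sign of
#'   the composite.
#' @return Numeric vector of z-scored composite scores (one per row).
#' @export
build_composite <- function(table, indicators, orientation_var) {
  stopifnot(is.data.frame(table), length(indicators) >= 2,
            orientation_var %in% names(table))
  missing <- setdiff(indicators, names(table))
  if (length(missing) > 0) {
    stop("missing indicator(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[, indicators, drop = FALSE])
  if (any(!is.finite(x))) stop("indicators must be complete and finite",
                               call. = FALSE)
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) {
    warning("dropping zero-variance indicator(s): ",
            paste(indicators[vars == 0], collapse = ", "), call. = FALSE)
    x <- x[, vars > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 usable indicators", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  orient <- table[[orientation_var]]
  r <- suppressWarnings(stats::cor(scores, orient))
  if (is.finite(r) && r < 0) scores <- -scores
  as.numeric(scale(scores))
}

# F_ML discrepancy between sample covariance S and implied sigma
f_ml <- function(S, sigma) {
  p <- nrow(S)
  as.numeric(log(det(sigma)) + sum(diag(S %*% solve(sigma))) - log(det(S)) - p)
}

# Implied covariance of a recursive system: sigma = (I-B)^-1 Psi (I-B)^-T
implied_cov <- function(vars, edges, B_coef, psi_exo, psi_endo) {
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_len(nrow(edges))) {
    B[edges$target[i], edges$source[i]] <- B_coef[i]
  }
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  exo <- rownames(psi_exo)
  Psi[exo, exo] <- psi_exo
  for (v in names(psi_endo)) Psi[v, v] <- psi_endo[[v]]
  inv <- solve(diag(p) - B)
  inv %*% Psi %*% t(inv)
}

#' Fit a recursive path model
#'
#' Estimates the standardized coefficients of an acyclic path model by
#' maximum likelihood on z-scored data (equation-wise OLS, which is the ML
#' solution for recursive systems with uncorrelated disturbances and a
#' saturated exogenous block), then evaluates global fit from the ML
#' discrepancy between the sample correlation matrix and the model-implied
#' covariance: chi-square = (n - 1) F_ML with df = p(p+1)/2 minus free
#' parameters (exogenous covariances, paths, disturbance variances);
#' RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1))); CFI relative to the
#' zero-covariance baseline. A model with every edge present is saturated
#' (df = 0) and fits perfectly by construction. Per-edge standard errors and
#' p-values come from the corresponding OLS equations.
#'
#' @param table Data frame of observed variables (composites declared in
#'   the spec are built first).
#' @param spec A [path_model_spec()].
#' @return Object of class `soc_path_fit`: `edges` (with `coefficient`,
#'   `se`, `p`, `stars`), `chi_square`, `df`, `chi_square_over_df`,
#'   `p_value`, `rmsea`, `cfi`, `n`, `r_squared` (per endogenous variable),
#'   `saturated`, `free_parameters`.
#' @export
fit_path_model <- function(table, spec) {
  stopifnot(is.data.frame(table), inherits(spec, "soc_path_spec"))
  dat <- table
  for (nm in names(spec$composites)) {
    comp <- spec$composites[[nm]]
    dat[[nm]] <- build_composite(dat, comp$indicators, comp$orientation)
  }
  vars <- spec$variables
  missing <- setdiff(vars, names(dat))
  if (length(missing) > 0) {
    stop("missing model variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Z <- as.matrix(dat[, vars, drop = FALSE])
  if (any(!is.finite(Z))) stop("model variables must be complete and finite",
                               call. = FALSE)
  if (any(apply(Z, 2, stats::var) == 0)) {
    stop("model variables must not be constant", call. = FALSE)
  }
  Z <- scale(Z)
  n <- nrow(Z)
  p <- length(vars)
  S <- stats::cov(Z) # correlation matrix of the observed variables

  edges <- spec$edges
  n_edges <- nrow(edges)
  exo <- spec$exogenous
  endo <- spec$endogenous
  free <- length(exo) * (length(exo) + 1) / 2 + n_edges + length(endo)
  if (n <= free) {
    stop("n (", n, ") must exceed the number of free parameters (", free, ")",
         call. = FALSE)
  }
  if (n < 5 * free) {
    warning("small sample: n = ", n, " < 5 x ", free, " free parameters; ",
            "interpret fit indices cautiously", call. = FALSE)
  }

  # Equation-wise OLS (= ML for a recursive system) on the z-scored data
  coef <- se <- pval <- numeric(n_edges)
  psi_endo <- stats::setNames(numeric(length(endo)), endo)
  r_squared <- stats::setNames(numeric(length(endo)), endo)
  for (yv in endo) {
    parents <- edges$source[edges$target == yv]
    Sxx <- S[parents, parents, drop = FALSE]
    Sxy <- S[parents, yv, drop = FALSE]
    b <- tryCatch(solve(Sxx, Sxy),
                  error = function(e) stop("estimation failed for '", yv,
                                           "': collinear parents", call. = FALSE))
    rv <- as.numeric(S[yv, yv] - crossprod(b, Sxy))
    psi_endo[yv] <- rv
    r_squared[yv] <- 1 - rv
    k <- length(parents)
    sigma2 <- rv * (n - 1) / (n - 1 - k) # unbiased residual variance
    covb <- sigma2 * solve(Sxx) / (n - 1)
    idx <- which(edges$target == yv)
    coef[idx] <- as.numeric(b)
    se[idx] <- sqrt(diag(covb))
    pval[idx] <- 2 * stats::pt(abs(coef[idx] / se[idx]), df = n - 1 - k,
                               lower.tail = FALSE)
  }

  sigma <- implied_cov(vars, edges, coef, S[exo, exo, drop = FALSE], psi_endo)
  chi2 <- max((n - 1) * f_ml(S, sigma), 0)
  df <- p * (p + 1) / 2 - free
  saturated <- df <= 0
  if (saturated && abs(chi2) < 1e-8) chi2 <- 0

  # Baseline (independence) model: implied covariance = identity
  chi2_base <- max(-(n - 1) * as.numeric(determinant(S)$modulus), 0)
  df_base <- p * (p - 1) / 2

  excess <- max(chi2 - df, 0)
  rmsea <- if (df > 0) sqrt(excess / (df * (n - 1))) else 0
  denom <- max(chi2_base - df_base, chi2 - df, 0)
  cfi <- if (denom > 0) 1 - excess / denom else 1

  edges_out <- data.frame(edges, coefficient = coef, se = se, p = pval,
                          stars = p_stars(pval), stringsAsFactors = FALSE)
  structure(list(
    edges = edges_out,
    chi_square = chi2, df = df,
    chi_square_over_df = if (df > 0) chi2 / df else NA_real_,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
              else NA_real_,
    rmsea = rmsea, cfi = cfi,
    n = n, r_squared = as.list(r_squared),
    saturated = saturated, free_parameters = free,
    variables = vars
  ), class = "soc_path_fit")
}

#' @export
print.soc_path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model (n = %d, %d variables, %d free parameters)\n",
              x$n, length(x$variables), x$free_parameters))
  print(transform(x$edges, coefficient = round(coefficient, 3),
                  se = round(se, 3), p = signif(p, 3)), row.names = FALSE)
  if (x$saturated) {
    cat("Saturated model: chi-square = 0 by construction\n")
  } else {
    cat(sprintf("chi2 = %.3f, df = %d, chi2/df = %.3f, p = %.3f, RMSEA = %.3f, CFI = %.3f\n",
                x$chi_square, x$df, x$chi_square_over_df, x$p_value,
                x$rmsea, x$cfi))
  }
  rsq <- unlist(x$r_squared)
  cat("R-squared:", paste(sprintf("%s = %.3f", names(rsq), rsq),
                          collapse = ", "), "\n")
  invisible(x)
}
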