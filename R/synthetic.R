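#' @title Synthetic paired-plot generator
#' @description Simulates the paired-plot field design the analysis chain
#'   assumes: adjacent broadleaf / Moso-bamboo plots sharing a pair-level
#'   random effect, with per-variable forest means, between-pair variation
#'   and within-plot residual noise. The default configuration is calibrated
#'   so its expected values reproduce the directions and magnitudes reported
#'   for the two forest types (SOC, amino sugars, lignin classes, Ac/Al
#'   indices, covariates).
#' @name synthetic
NULL

.forest_levels <- c("broadleaf", "moso_bamboo")
.dists <- c("lognormal", "normal", "truncated-normal")

#' Build a synthetic paired-plot configuration
#'
#' @param variables Data frame with one row per variable and columns
#'   `name`, `mean_broadleaf`, `mean_moso`, `pair_cv` (between-pair
#'   coefficient of variation), `resid_cv` (within-plot residual CV) and
#'   `dist` (one of `"lognormal"`, `"normal"`, `"truncated-normal"`).
#' @param n_pairs Number of plot pairs (>= 2); the classic design uses 11.
#' @param path_structure Optional data frame with columns `source`,
#'   `target`, `beta` defining an acyclic set of standardized linear paths;
#'   listed targets are generated from their sources instead of from their
#'   forest means (see [generate_paired_dataset()]).
#' @return An object of class `soc_synth_config`.
#' @seealso [default_config()] for the calibrated study design.
#' @export
synthetic_config <- function(variables, n_pairs = 11, path_structure = NULL) {
  stopifnot(is.data.frame(variables))
  needed <- c("name", "mean_broadleaf", "mean_moso", "pair_cv", "resid_cv", "dist")
  missing <- setdiff(needed, names(variables))
  if (length(missing) > 0) {
    stop("variables is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(variables$name)) stop("duplicate variable names", call. = FALSE)
  if (!all(variables$dist %in% .dists)) {
    stop("dist must be one of: ", paste(.dists, collapse = ", "), call. = FALSE)
  }
  if (n_pairs < 2) stop("n_pairs must be >= 2", call. = FALSE)
  if (any(variables$pair_cv < 0) || any(variables$resid_cv < 0)) {
    stop("pair_cv and resid_cv must be non-negative", call. = FALSE)
  }
  ln <- variables$dist == "lognormal"
  if (any(variables$mean_broadleaf[ln] <= 0) || any(variables$mean_moso[ln] <= 0)) {
    stop("lognormal variables require positive means", call. = FALSE)
  }
  if (!is.null(path_structure)) {
    stopifnot(is.data.frame(path_structure),
              all(c("source", "target", "beta") %in% names(path_structure)))
    vars <- variables$name
    unknown <- setdiff(c(path_structure$source, path_structure$target), vars)
    if (length(unknown) > 0) {
      stop("path_structure refers to unknown variable(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    topological_order(path_structure$source, path_structure$target) # cycle check
  }
  structure(list(n_pairs = as.integer(n_pairs), variables = variables,
                 path_structure = path_structure),
            class = "soc_synth_config")
}

# Kahn topological sort over edge lists; errors on cycles.
topological_order <- function(source, target) {
  nodes <- unique(c(source, target))
  edges <- data.frame(source = source, target = target,
                      stringsAsFactors = FALSE)
  order <- character(0)
  while (length(nodes) > 0) {
    indeg <- vapply(nodes, function(v) sum(edges$target == v), integer(1))
    free <- nodes[indeg == 0]
    if (length(free) == 0) {
      stop("path structure contains a cycle", call. = FALSE)
    }
    order <- c(order, free)
    nodes <- setdiff(nodes, free)
    edges <- edges[!(edges$source %in% free), , drop = FALSE]
  }
  order
}

#' Calibrated default study configuration
#'
#' Returns the generator configuration whose expected values encode the
#' reported contrasts between adjacent broadleaf and Moso-bamboo forest
#' soils:
#'
#' * SOC means 17.99 (broadleaf) vs 15.72 (moso) g/kg, back-calculated from
#'   the reported microbial pools (9.18 + 1.21 and 6.85 + 0.93 g/kg) and
#'   microbial fractions of SOC (57.75% and 49.49%); the implied SOC
#'   contrast is a 12.6% reduction under Moso bamboo.
#' * Muramic acid and glucosamine means obtained by exact algebraic
#'   inversion of the necromass conversion formulas at those pool values;
#'   the galactosamine means are set so the expected broadleaf/moso total
#'   amino-sugar ratio is exactly 1.2843 (a 28.43% excess).
#' * Total lignin phenols derived from the plant-derived C fractions (8.38%
#'   of SOC in broadleaf, 21.31% in moso, a 2.22x pool ratio), split into
#'   V/S/C classes at 56.30/15.09/28.61% (broadleaf) and 54.46/14.72/30.82%
#'   (moso) of the total; the implied moso/broadleaf lignin ratio is about
#'   2.1 ("more than twice").
#' * Acid-to-aldehyde indices higher in broadleaf ((Ac/Al)v 0.65 vs 0.45,
#'   (Ac/Al)s 0.55 vs 0.40), encoding stronger lignin oxidation there and a
#'   negative lignin-vs-Ac/Al association across the pooled plots.
#' * Covariates with the reported directions: higher pH under Moso bamboo;
#'   higher plant biomass, PLFA, CEC and Fe/Al oxide pools and a lower
#'   ligninase/cellulase ratio in broadleaf; higher TP under the
#'   (historically fertilised) bamboo stands.
#'
#' Within-group spreads are not reported, so the defaults use a residual CV
#' of 15% and a between-pair CV of 10% — assumptions, not observed values.
#'
#' @param n_pairs Number of plot pairs (default 11, the study design).
#' @return A `soc_synth_config`.
#' @export
default_config <- function(n_pairs = 11) {
  coeffs <- attribution_coefficients()

  # SOC back-calculated from microbial pools and fractions of SOC
  fungal <- c(broadleaf = 9.18, moso = 6.85)
  bacterial <- c(broadleaf = 1.21, moso = 0.93)
  micro_frac <- c(broadleaf = 0.5775, moso = 0.4949)
  soc <- (fungal + bacterial) / micro_frac

  # Amino sugars by inversion of the necromass formulas (mg/kg)
  murn <- bacterial * 1000 / coeffs$bacterial_factor
  glcn <- (fungal * 1000 / (coeffs$mw_glcn * coeffs$fungal_factor) +
             2 * murn / coeffs$mw_murn) * coeffs$mw_glcn
  # GalN: moso mean assumed; broadleaf solved so expected total ratio = 1.2843
  galn_m <- 400
  galn_b <- 1.2843 * (glcn[["moso"]] + galn_m + murn[["moso"]]) -
    (glcn[["broadleaf"]] + murn[["broadleaf"]])
  galn <- c(broadleaf = galn_b, moso = galn_m)

  # Lignin totals from plant-derived C fractions and class proportions
  plant_frac <- c(broadleaf = 0.0838, moso = 0.2131)
  props <- rbind(broadleaf = c(v = 0.5630, s = 0.1509, c = 0.2861),
                 moso = c(v = 0.5446, s = 0.1472, c = 0.3082))
  plant_c <- plant_frac * soc # g/kg
  per_mg <- props[, "v"] / coeffs$lignin_coeff_v +
    props[, "s"] / coeffs$lignin_coeff_s +
    props[, "c"] / coeffs$lignin_coeff_c
  lignin_total <- plant_c * 1000 / per_mg # mg/kg

  # Monomer means within classes: fixed ketone share, acid/aldehyde from
  # the configured Ac/Al targets
  ac_al_v <- c(broadleaf = 0.65, moso = 0.45)
  ac_al_s <- c(broadleaf = 0.55, moso = 0.40)
  v_tot <- lignin_total * props[, "v"]
  s_tot <- lignin_total * props[, "s"]
  c_tot <- lignin_total * props[, "c"]
  vanillin <- 0.75 * v_tot / (1 + ac_al_v)
  vanillic <- ac_al_v * vanillin
  acetovan <- v_tot - vanillin - vanillic
  syringald <- 0.75 * s_tot / (1 + ac_al_s)
  syringic <- ac_al_s * syringald
  acetosyr <- s_tot - syringald - syringic

  row <- function(name, b, m, dist = "lognormal", pair_cv = 0.10,
                  resid_cv = 0.15) {
    data.frame(name = name, mean_broadleaf = b, mean_moso = m,
               pair_cv = pair_cv, resid_cv = resid_cv, dist = dist,
               stringsAsFactors = FALSE)
  }
  variables <- rbind(
    row("soc", soc[["broadleaf"]], soc[["moso"]]),
    row("vanillin", vanillin[["broadleaf"]], vanillin[["moso"]]),
    row("acetovanillone", acetovan[["broadleaf"]], acetovan[["moso"]]),
    row("vanillic_acid", vanillic[["broadleaf"]], vanillic[["moso"]]),
    row("syringaldehyde", syringald[["broadleaf"]], syringald[["moso"]]),
    row("acetosyringone", acetosyr[["broadleaf"]], acetosyr[["moso"]]),
    row("syringic_acid", syringic[["broadleaf"]], syringic[["moso"]]),
    row("p_coumaric_acid", 0.6 * c_tot[["broadleaf"]], 0.6 * c_tot[["moso"]]),
    row("ferulic_acid", 0.4 * c_tot[["broadleaf"]], 0.4 * c_tot[["moso"]]),
    row("glcn", glcn[["broadleaf"]], glcn[["moso"]]),
    row("galn", galn[["broadleaf"]], galn[["moso"]]),
    row("murn", murn[["broadleaf"]], murn[["moso"]]),
    row("ph", 4.8, 5.4, dist = "normal", pair_cv = 0.03, resid_cv = 0.04),
    row("tp", 0.42, 0.55),
    row("tn", 1.85, 1.55),
    row("doc", 260, 205),
    row("cec", 12.5, 10.2),
    row("clay", 26, 22, dist = "truncated-normal"),
    row("water_content", 28, 25, dist = "truncated-normal"),
    row("fe_al_o", 4.6, 3.7),
    row("fe_al_d", 18.5, 15.0),
    row("fe_al_p", 2.6, 2.0),
    row("plfa_fungal", 21, 14),
    row("plfa_bacterial", 46, 38),
    row("ligninase", 24, 36),
    row("cellulase", 52, 44),
    row("plant_biomass", 180, 95)
  )
  synthetic_config(variables, n_pairs = n_pairs)
}

draw_variable <- function(spec, pair_idx, forest) {
  m_f <- ifelse(forest == "broadleaf", spec$mean_broadleaf, spec$mean_moso)
  n_pairs <- max(pair_idx)
  n <- length(pair_idx)
  if (spec$dist == "lognormal") {
    s_p <- sqrt(log(1 + spec$pair_cv^2))
    s_r <- sqrt(log(1 + spec$resid_cv^2))
    z_p <- stats::rnorm(n_pairs, 0, s_p)[pair_idx]
    z_r <- stats::rnorm(n, 0, s_r)
    # moment-matched: E[value] = configured mean for each forest
    exp(log(m_f) - (s_p^2 + s_r^2) / 2 + z_p + z_r)
  } else {
    m_grand <- (spec$mean_broadleaf + spec$mean_moso) / 2
    u_p <- stats::rnorm(n_pairs, 0, spec$pair_cv * m_grand)[pair_idx]
    u_r <- stats::rnorm(n, 0, spec$resid_cv * abs(m_f))
    val <- m_f + u_p + u_r
    if (spec$dist == "truncated-normal") {
      for (k in 1:100) {
        bad <- val < 0
        if (!any(bad)) break
        val[bad] <- m_f[bad] + u_p[bad] +
          stats::rnorm(sum(bad), 0, spec$resid_cv * abs(m_f[bad]))
      }
      val <- pmax(val, 0)
    }
    val
  }
}

#' Generate a paired-plot dataset
#'
#' Draws `2 * n_pairs` plots (one broadleaf, one Moso bamboo per pair). Each
#' variable is drawn as forest mean + shared pair effect + residual, on the
#' log scale for lognormal variables (moment-matched so the expectation
#' equals the configured mean) and on the natural scale for (truncated)
#' normal ones. Variables listed as targets in `path_structure` are instead
#' generated as standardized linear combinations of their (already
#' generated) sources plus Gaussian noise sized so the population
#' standardized coefficients equal the configured `beta` (assuming
#' independent sources), then mapped to the variable's grand mean and
#' residual-CV scale; forest and pair effects do not apply to path targets.
#'
#' @param config A [synthetic_config()] / [default_config()] object.
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @return A data frame with `plot_id`, `pair_id`, `forest_type` and one
#'   column per configured variable.
#' @export
generate_paired_dataset <- function(config, seed = 42) {
  stopifnot(inherits(config, "soc_synth_config"))
  set.seed(as.integer(seed))
  n_pairs <- config$n_pairs
  pair_idx <- rep(seq_len(n_pairs), each = 2)
  forest <- rep(.forest_levels, times = n_pairs)
  out <- data.frame(
    plot_id = sprintf("P%03d_%s", pair_idx,
                      ifelse(forest == "broadleaf", "BL", "MB")),
    pair_id = sprintf("pair%03d", pair_idx),
    forest_type = forest,
    stringsAsFactors = FALSE
  )

  ps <- config$path_structure
  targets <- if (is.null(ps)) character(0) else unique(ps$target)
  for (i in seq_len(nrow(config$variables))) {
    spec <- config$variables[i, ]
    if (spec$name %in% targets) next
    out[[spec$name]] <- draw_variable(spec, pair_idx, forest)
  }
  if (length(targets) > 0) {
    ord <- topological_order(ps$source, ps$target)
    for (tg in intersect(ord, targets)) {
      edges <- ps[ps$target == tg, , drop = FALSE]
      betas <- edges$beta
      resid_var <- 1 - sum(betas^2)
      if (resid_var < 0) {
        stop("path coefficients into '", tg,
             "' imply negative residual variance", call. = FALSE)
      }
      z <- rep(0, nrow(out))
      for (j in seq_len(nrow(edges))) {
        src <- out[[edges$source[j]]]
        z <- z + betas[j] * as.numeric(scale(src))
      }
      z <- z + stats::rnorm(nrow(out), 0, sqrt(resid_var))
      spec <- config$variables[config$variables$name == tg, ]
      m_grand <- (spec$mean_broadleaf + spec$mean_moso) / 2
      out[[tg]] <- m_grand + spec$resid_cv * m_grand * z
    }
  }
  out
}

#' Expected study dataset (noise-free)
#'
#' Convenience wrapper returning a deterministic paired table with every
#' variable constant at its configured forest mean — the generator run with
#' all variation switched off. Useful as a fixture for arithmetic checks on
#' the attribution and contrast stages.
#'
#' @inheritParams default_config
#' @return A data frame of `2 * n_pairs` constant rows.
#' @export
expected_means_dataset <- function(n_pairs = 11) {
  cfg <- default_config(n_pairs)
  cfg$variables$pair_cv <- 0
  cfg$variables$resid_cv <- 0
  generate_paired_dataset(cfg, seed = 1)
}
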