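#' @title Pipeline orchestration and plot-table I/O
#' @name pipeline
NULL

required_plot_columns <- function() {
  c("plot_id", "pair_id", "forest_type", "soc",
    lignin_monomers(), amino_sugar_names())
}

covariate_columns <- function() {
  c("ph", "tp", "tn", "doc", "cec", "clay", "water_content",
    "fe_al_o", "fe_al_d", "fe_al_p", "plfa_fungal", "plfa_bacterial",
    "ligninase", "cellulase", "plant_biomass")
}

#' Read and validate a plot table
#'
#' Reads the per-plot CSV consumed by the pipeline (one row per plot:
#' identifiers, forest type, SOC, the eight lignin monomers, three amino
#' sugars, and covariates). Validation errors name the offending column or
#' plot. SOC outside the plausible 1-200 g/kg band triggers a unit-sanity
#' warning, as does broken pairing (each `pair_id` should occur exactly
#' twice, once per forest type).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame of plot records.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plot_table(df)
}

#' Validate an in-memory plot table
#'
#' @param df Data frame with the plot-table schema.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_plot_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(required_plot_columns(), names(df))
  if (length(missing) > 0) {
    stop("plot table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$forest_type %in% .forest_levels)) {
    stop("forest_type must be one of: ", paste(.forest_levels, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(required_plot_columns(),
                      c("plot_id", "pair_id", "forest_type"))
  num_cols <- c(num_cols, intersect(covariate_columns(), names(df)))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric '", col, "' for plot(s): ",
           paste(df$plot_id[utils::head(bad, 5)], collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))
      stop("non-finite '", col, "' for plot(s): ",
           paste(df$plot_id[utils::head(bad, 5)], collapse = ", "),
           call. = FALSE)
    }
  }
  if (anyDuplicated(df$plot_id)) stop("duplicate plot_id values", call. = FALSE)
  if (any(df$soc <= 0)) {
    stop("soc must be positive for plot(s): ",
         paste(df$plot_id[df$soc <= 0], collapse = ", "), call. = FALSE)
  }
  if (any(df$soc < 1 | df$soc > 200)) {
    warning("soc outside the plausible 1-200 g/kg band for some plots; ",
            "check units", call. = FALSE)
  }
  tab <- table(df$pair_id, df$forest_type)
  if (!all(dim(tab) == c(nrow(df) / 2, 2)) || !all(tab == 1)) {
    warning("pairing is not one broadleaf + one moso_bamboo plot per pair_id",
            call. = FALSE)
  }
  invisible(df)
}

#' Write a plot table
#'
#' @param df Plot table data frame.
#' @param path Output CSV path.
#' @export
write_plot_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full source-partitioning pipeline
#'
#' Orchestrates the analysis end to end: read (or generate) the plot table,
#' attribute carbon pools, contrast the forest types, run the degradation-
#' index regressions, rank predictors of the microbial- and plant-derived
#' pools by random-forest importance, and fit the recursive path model.
#' Every artifact is written to `output_dir` and the resolved settings plus
#' seed go into `manifest.json`, so a rerun with the same inputs and seed
#' reproduces every numeric output.
#'
#' @param input Path to a plot-table CSV, or `NULL` to generate a synthetic
#'   dataset from `config`.
#' @param output_dir Directory for the report bundle (created if absent).
#' @param seed Integer seed controlling generation and the random forests.
#' @param config Synthetic configuration used when `input` is `NULL`.
#' @param coeffs Attribution coefficients.
#' @param method Two-group test flavour, `"student"` or `"welch"`.
#' @param rf_responses Responses ranked by the random-forest stage.
#' @param n_trees,n_perm Random-forest settings (see [rf_importance()]).
#' @param path_spec Path-model specification.
#' @return Invisibly, a list with the attributed table and all stage
#'   results.
#' @export
run_pipeline <- function(input = NULL,
                         output_dir,
                         seed = 42,
                         config = default_config(),
                         coeffs = attribution_coefficients(),
                         method = c("student", "welch"),
                         rf_responses = c("microbial_c", "plant_c"),
                         n_trees = 1000, n_perm = 199,
                         path_spec = default_study_spec()) {
  method <- match.arg(method)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(output_dir, f)

  stage <- "input"
  result <- tryCatch({
    plots <- if (is.null(input)) {
      generate_paired_dataset(config, seed = seed)
    } else {
      read_plot_table(input)
    }
    write_plot_table(plots, out("plots.csv"))

    stage <- "attribution"
    attributed <- attribute_table(plots, coeffs)
    utils::write.csv(attributed, out("attribution.csv"), row.names = FALSE)

    stage <- "group_contrast"
    contrast <- summarize_forest_contrast(attributed, method = method)
    utils::write.csv(contrast, out("group_comparisons.csv"), row.names = FALSE)

    stage <- "regressions"
    reg_pairs <- list(c("ac_al_v", "ac_al_s"),
                      c("lignin_total", "ac_al_v"),
                      c("lignin_total", "ac_al_s"))
    regressions <- do.call(rbind, lapply(reg_pairs, function(pr) {
      fit <- fit_linear(attributed[[pr[1]]], attributed[[pr[2]]])
      data.frame(x = pr[1], y = pr[2], slope = fit$slope,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 p = fit$p, n = fit$n, stringsAsFactors = FALSE)
    }))
    utils::write.csv(regressions, out("regressions.csv"), row.names = FALSE)

    stage <- "importance"
    importance <- list()
    shares <- list()
    for (i in seq_along(rf_responses)) {
      resp <- rf_responses[i]
      imp <- rf_importance(attributed, resp, n_trees = n_trees,
                           n_perm = n_perm, seed = seed + i)
      importance[[resp]] <- imp
      utils::write.csv(imp$table, out(paste0("importance_", resp, ".csv")),
                       row.names = FALSE)
      shares[[resp]] <- data.frame(response = resp,
                                   group = names(imp$group_shares),
                                   share = as.numeric(imp$group_shares),
                                   stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, shares), out("group_shares.csv"),
                     row.names = FALSE)

    stage <- "path_model"
    fit <- fit_path_model(attributed, path_spec)
    jsonlite::write_json(
      list(edges = fit$edges, chi_square = fit$chi_square, df = fit$df,
           chi_square_over_df = fit$chi_square_over_df,
           p_value = fit$p_value, rmsea = fit$rmsea, cfi = fit$cfi,
           n = fit$n, r_squared = fit$r_squared, saturated = fit$saturated),
      out("path_model.json"), auto_unbox = TRUE, digits = NA, na = "null")

    stage <- "manifest"
    qc <- attributed$qc_flags[nzchar(attributed$qc_flags)]
    manifest <- list(
      package = "socsource",
      version = as.character(utils::packageVersion("socsource")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = seed,
      input = if (is.null(input)) "synthetic" else input,
      method = method,
      n_trees = n_trees, n_perm = n_perm,
      n_plots = nrow(plots),
      coefficients = unclass(coeffs),
      qc_flag_summary = as.list(table(unlist(strsplit(qc, ";"))))
    )
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)

    list(plots = plots, attributed = attributed, contrast = contrast,
         regressions = regressions, importance = importance,
         path_fit = fit, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
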