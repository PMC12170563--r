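#' @title Biomarker-based carbon source attribution
#' @description Core operations turning lignin-phenol and amino-sugar
#'   concentrations (mg per kg dry soil) into plant-, fungal-, bacterial- and
#'   microbial-derived carbon pools (g per kg) and their shares of soil
#'   organic carbon.
#' @name attribution
NULL

# Monomer membership of the three structural phenol classes.
.v_monomers <- c("vanillin", "acetovanillone", "vanillic_acid")
.s_monomers <- c("syringaldehyde", "acetosyringone", "syringic_acid")
.c_monomers <- c("p_coumaric_acid", "ferulic_acid")

lignin_monomers <- function() c(.v_monomers, .s_monomers, .c_monomers)
amino_sugar_names <- function() c("glcn", "galn", "murn")

# Validate a set of named non-negative finite concentration vectors,
# naming the offending field in the error.
check_concentrations <- function(values, what) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.numeric(v)) {
      stop(what, " field '", nm, "' must be numeric", call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop(what, " field '", nm, "' contains non-finite values", call. = FALSE)
    }
    if (any(v < 0)) {
      stop(what, " field '", nm, "' contains negative concentrations",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

as_profile <- function(x, fields, what) {
  x <- as.list(x)
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0) {
    stop(what, " is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[fields]
  check_concentrations(x, what)
  lens <- vapply(x, length, integer(1))
  n <- max(lens)
  if (!all(lens %in% c(1L, n))) {
    stop(what, " fields have unequal lengths", call. = FALSE)
  }
  if (n > 1L) x[lens == 1L] <- lapply(x[lens == 1L], rep, n)
  x
}

#' Sum lignin monomers into vanillyl, syringyl and cinnamyl class totals
#'
#' The eight CuO-oxidation phenol monomers are grouped into three structural
#' classes: vanillyl (vanillin, acetovanillone, vanillic acid), syringyl
#' (syringaldehyde, acetosyringone, syringic acid) and cinnamyl (p-coumaric
#' acid, ferulic acid).
#'
#' @param profile Named list (or one-row data frame) with the eight monomer
#'   concentrations in mg per kg dry soil; fields may be vectors of equal
#'   length for batch use.
#' @return A list with components `v_total`, `s_total`, `c_total` (mg/kg).
#' @examples
#' classify_phenols(list(vanillin = 1, acetovanillone = 2, vanillic_acid = 3,
#'   syringaldehyde = 0, acetosyringone = 0, syringic_acid = 0,
#'   p_coumaric_acid = 0, ferulic_acid = 0))
#' @export
classify_phenols <- function(profile) {
  p <- as_profile(profile, lignin_monomers(), "lignin profile")
  list(
    v_total = p$vanillin + p$acetovanillone + p$vanillic_acid,
    s_total = p$syringaldehyde + p$acetosyringone + p$syringic_acid,
    c_total = p$p_coumaric_acid + p$ferulic_acid
  )
}

#' Lignin composition summary and degradation indices
#'
#' Computes the total lignin phenol content, the percentage contribution of
#' each structural class, and the acid-to-aldehyde degradation indices
#' (Ac/Al)v = vanillic acid / vanillin and (Ac/Al)s = syringic acid /
#' syringaldehyde. Higher Ac/Al values indicate more oxidised, degraded
#' lignin. Degenerate inputs (zero aldehyde, zero total lignin) yield `NA`
#' for the affected quantity plus a QC flag rather than an error, so batch
#' runs survive degenerate records.
#'
#' @inheritParams classify_phenols
#' @return A list with `lignin_total`, `prop_v`, `prop_s`, `prop_c` (% of
#'   total), `ac_al_v`, `ac_al_s`, and `qc_flags` (character vector of flags
#'   per record: `"zero_lignin"`, `"undefined_ac_al_v"`,
#'   `"undefined_ac_al_s"`, empty string if clean; flags are
#'   semicolon-joined when several apply).
#' @export
lignin_summary <- function(profile) {
  p <- as_profile(profile, lignin_monomers(), "lignin profile")
  cls <- classify_phenols(p)
  total <- cls$v_total + cls$s_total + cls$c_total
  n <- length(total)
  flags <- vector("list", n)

  prop_v <- prop_s <- prop_c <- rep(NA_real_, n)
  ok <- total > 0
  prop_v[ok] <- 100 * cls$v_total[ok] / total[ok]
  prop_s[ok] <- 100 * cls$s_total[ok] / total[ok]
  prop_c[ok] <- 100 * cls$c_total[ok] / total[ok]

  ac_al_v <- ifelse(p$vanillin > 0, p$vanillic_acid / p$vanillin, NA_real_)
  ac_al_s <- ifelse(p$syringaldehyde > 0,
                    p$syringic_acid / p$syringaldehyde, NA_real_)

  for (i in seq_len(n)) {
    f <- character(0)
    if (!ok[i]) f <- c(f, "zero_lignin")
    if (p$vanillin[i] <= 0) f <- c(f, "undefined_ac_al_v")
    if (p$syringaldehyde[i] <= 0) f <- c(f, "undefined_ac_al_s")
    flags[[i]] <- f
  }

  list(lignin_total = total,
       prop_v = prop_v, prop_s = prop_s, prop_c = prop_c,
       ac_al_v = ac_al_v, ac_al_s = ac_al_s,
       qc_flags = vapply(flags, paste, character(1), collapse = ";"))
}

#' Plant-derived carbon from lignin phenol class totals
#'
#' Plant-derived C (g/kg) is a coefficient-weighted sum of the three phenol
#' class totals: `(V/cV + S/cS + C/cC) / 1000`, with default class
#' coefficients 0.33, 0.9 and 0.03 (the cinnamyl coefficient encodes the
#' 3% minimal lignin content of the principal plant residues). The division
#' by 1000 converts mg/kg inputs to a g/kg pool.
#'
#' @param v_total,s_total,c_total Class totals in mg per kg dry soil.
#' @param coeffs An [attribution_coefficients()] object.
#' @return Plant-derived C in g per kg dry soil.
#' @examples
#' plant_derived_c(330, 900, 30) # 3 g/kg
#' @export
plant_derived_c <- function(v_total, s_total, c_total,
                            coeffs = attribution_coefficients()) {
  stopifnot(inherits(coeffs, "soc_coefficients"))
  check_concentrations(list(v_total = v_total, s_total = s_total,
                            c_total = c_total), "phenol class total")
  (v_total / coeffs$lignin_coeff_v +
     s_total / coeffs$lignin_coeff_s +
     c_total / coeffs$lignin_coeff_c) / 1000
}

#' Carbon pool as a percentage of soil organic carbon
#'
#' @param pool_c Carbon pool in g per kg (plant-, fungal-, bacterial- or
#'   microbial-derived C). Negative values (flagged fungal estimates) are
#'   clipped to zero before division; use the QC flags to trace clips.
#' @param soc Soil organic carbon in g per kg; must be positive.
#' @return Percentage of SOC.
#' @export
plant_fraction <- function(pool_c, soc) {
  if (any(!is.finite(soc)) || any(soc <= 0)) {
    stop("soc must be positive and finite", call. = FALSE)
  }
  100 * pmax(pool_c, 0) / soc
}

#' Fungal-derived carbon from amino sugars
#'
#' Fungal necromass C (g/kg) from glucosamine after subtracting the
#' bacterial glucosamine contribution (assumed 2 mol GlcN per mol muramic
#' acid): `(GlcN/179.17 - 2 * MurN/253.23) * 179.17 * 9 / 1000`. When soils
#' are bacterially dominated the parenthesis can go negative; the raw
#' (negative) value is returned together with the QC flag
#' `"negative_fungal_c"` rather than silently truncated, because truncation
#' would bias group means.
#'
#' @param asp Named list (or one-row data frame) with `glcn`, `galn`, `murn`
#'   in mg per kg dry soil; fields may be equal-length vectors.
#' @inheritParams plant_derived_c
#' @return A list with `fungal_c` (g/kg, possibly negative) and `qc_flags`.
#' @export
fungal_derived_c <- function(asp, coeffs = attribution_coefficients()) {
  stopifnot(inherits(coeffs, "soc_coefficients"))
  a <- as_profile(asp, amino_sugar_names(), "amino sugar profile")
  moles <- a$glcn / coeffs$mw_glcn - 2 * a$murn / coeffs$mw_murn
  val <- moles * coeffs$mw_glcn * coeffs$fungal_factor / 1000
  list(fungal_c = val,
       qc_flags = ifelse(moles < 0, "negative_fungal_c", ""))
}

#' Bacterial-derived carbon from muramic acid
#'
#' Bacterial necromass C (g/kg) = `MurN * 45 / 1000` with MurN in mg/kg.
#'
#' @inheritParams fungal_derived_c
#' @return Bacterial-derived C in g per kg dry soil.
#' @export
bacterial_derived_c <- function(asp, coeffs = attribution_coefficients()) {
  stopifnot(inherits(coeffs, "soc_coefficients"))
  a <- as_profile(asp, amino_sugar_names(), "amino sugar profile")
  a$murn * coeffs$bacterial_factor / 1000
}

join_flags <- function(...) {
  parts <- list(...)
  out <- do.call(mapply, c(list(FUN = function(...) {
    f <- c(...)
    paste(f[nzchar(f)], collapse = ";")
  }, SIMPLIFY = TRUE), parts))
  as.character(out)
}

#' Full carbon-source attribution of one plot sample
#'
#' Composes the class sums, lignin summary, plant/fungal/bacterial pool
#' operations and fraction-of-SOC computations for a single plot record.
#' Microbial-derived C is the exact sum of the fungal and bacterial pools.
#' Fractions use pools clipped at zero (clips are visible through the
#' `negative_fungal_c` flag); if plant plus microbial fractions exceed 100%
#' the flag `fractions_exceed_soc` is added.
#'
#' @param sample Named list or one-row data frame with `soc` (g/kg), the
#'   eight lignin monomers and three amino sugars (mg/kg).
#' @inheritParams plant_derived_c
#' @return A named list with every attribution field: class totals,
#'   proportions, Ac/Al ratios, the four carbon pools, their SOC fractions
#'   and `qc_flags`.
#' @export
attribute_sample <- function(sample, coeffs = attribution_coefficients()) {
  s <- as.list(sample)
  if (is.null(s$soc)) stop("sample is missing 'soc'", call. = FALSE)
  if (!is.numeric(s$soc) || any(!is.finite(s$soc)) || any(s$soc <= 0)) {
    stop("soc must be positive and finite", call. = FALSE)
  }
  lig <- lignin_summary(s)
  cls <- classify_phenols(s)
  fun <- fungal_derived_c(s, coeffs)
  bact <- bacterial_derived_c(s, coeffs)
  plant <- plant_derived_c(cls$v_total, cls$s_total, cls$c_total, coeffs)
  microbial <- fun$fungal_c + bact

  out <- list(
    v_total = cls$v_total, s_total = cls$s_total, c_total = cls$c_total,
    lignin_total = lig$lignin_total,
    prop_v = lig$prop_v, prop_s = lig$prop_s, prop_c = lig$prop_c,
    ac_al_v = lig$ac_al_v, ac_al_s = lig$ac_al_s,
    plant_c = plant,
    fungal_c = fun$fungal_c,
    bacterial_c = bact,
    microbial_c = microbial,
    plant_fraction = plant_fraction(plant, s$soc),
    fungal_fraction = plant_fraction(fun$fungal_c, s$soc),
    bacterial_fraction = plant_fraction(bact, s$soc),
    microbial_fraction = plant_fraction(microbial, s$soc)
  )
  over <- ifelse(out$plant_fraction + out$microbial_fraction > 100,
                 "fractions_exceed_soc", "")
  out$qc_flags <- join_flags(lig$qc_flags, fun$qc_flags, over)
  out
}

#' Attribute every plot in a table
#'
#' Vectorised [attribute_sample()] over a plot table: appends all
#' attribution columns to the input data frame, plus the derived
#' `ligninase_cellulase_ratio` covariate when `ligninase` and `cellulase`
#' columns are present. This is the analysis table that the group
#' contrasts, variable-importance and path-model stages consume.
#'
#' @param plots Data frame with one row per plot; must contain `soc`, the
#'   eight lignin monomer columns and `glcn`, `galn`, `murn`.
#' @inheritParams plant_derived_c
#' @return The input data frame with attribution columns appended.
#' @export
attribute_table <- function(plots, coeffs = attribution_coefficients()) {
  stopifnot(is.data.frame(plots))
  att <- attribute_sample(plots, coeffs)
  out <- cbind(plots, as.data.frame(att, stringsAsFactors = FALSE))
  if (all(c("ligninase", "cellulase") %in% names(out)) &&
      !"ligninase_cellulase_ratio" %in% names(out)) {
    out$ligninase_cellulase_ratio <- out$ligninase / out$cellulase
  }
  out
}
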