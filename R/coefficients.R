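#' Conversion constants for biomarker-to-carbon attribution
#'
#' Bundles every constant used to convert biomarker concentrations into
#' carbon pools: the relative molecular weights of glucosamine and muramic
#' acid, the fungal and bacterial necromass conversion factors, and the
#' class coefficients of the lignin-based plant-carbon estimate. All values
#' are the conventional ones from the amino-sugar and CuO-oxidation
#' literature; each can be overridden, e.g. to explore alternative readings
#' of the plant-carbon formula.
#'
#' @param mw_glcn Relative molecular weight of glucosamine.
#' @param mw_murn Relative molecular weight of muramic acid.
#' @param fungal_factor Conversion factor from fungal glucosamine (as GlcN
#'   carbon equivalents) to fungal-derived C.
#' @param bacterial_factor Conversion factor from muramic acid to
#'   bacterial-derived C.
#' @param lignin_coeff_v,lignin_coeff_s,lignin_coeff_c Class coefficients
#'   dividing the vanillyl, syringyl and cinnamyl phenol pools in the
#'   plant-derived C estimate; 0.03 encodes the minimal (3%) lignin content
#'   of the principal plant residues.
#'
#' @return A named list of class `soc_coefficients`.
#' @examples
#' attribution_coefficients()
#' attribution_coefficients(fungal_factor = 12)
#' @export
attribution_coefficients <- function(mw_glcn = 179.17,
                                     mw_murn = 253.23,
                                     fungal_factor = 9,
                                     bacterial_factor = 45,
                                     lignin_coeff_v = 0.33,
                                     lignin_coeff_s = 0.9,
                                     lignin_coeff_c = 0.03) {
  coeffs <- list(
    mw_glcn = mw_glcn, mw_murn = mw_murn,
    fungal_factor = fungal_factor, bacterial_factor = bacterial_factor,
    lignin_coeff_v = lignin_coeff_v, lignin_coeff_s = lignin_coeff_s,
    lignin_coeff_c = lignin_coeff_c
  )
  bad <- vapply(coeffs, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("attribution coefficients must be single positive finite numbers; ",
         "invalid: ", paste(names(coeffs)[bad], collapse = ", "),
         call. = FALSE)
  }
  structure(coeffs, class = "soc_coefficients")
}

#' @export
print.soc_coefficients <- function(x, ...) {
  cat("Biomarker-to-carbon attribution coefficients\n")
  cat(sprintf("  GlcN MW %.2f, MurN MW %.2f; fungal factor %g, bacterial factor %g\n",
              x$mw_glcn, x$mw_murn, x$fungal_factor, x$bacterial_factor))
  cat(sprintf("  lignin class coefficients: V %g, S %g, C %g\n",
              x$lignin_coeff_v, x$lignin_coeff_s, x$lignin_coeff_c))
  invisible(x)
}
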