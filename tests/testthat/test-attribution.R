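zero_profile <- function(...) {
  p <- as.list(setNames(rep(0, 8), c("vanillin", "acetovanillone",
                                     "vanillic_acid", "syringaldehyde",
                                     "acetosyringone", "syringic_acid",
                                     "p_coumaric_acid", "ferulic_acid")))
  utils::modifyList(p, list(...))
}

test_that("phenol classification sums monomers into the three classes", {
  expect_equal(unname(unlist(classify_phenols(zero_profile()))), c(0, 0, 0))
  cls <- classify_phenols(zero_profile(vanillin = 1, acetovanillone = 2,
                                       vanillic_acid = 3))
  expect_equal(cls, list(v_total = 6, s_total = 0, c_total = 0))
  ones <- as.list(setNames(rep(1, 8), names(zero_profile())))
  expect_equal(classify_phenols(ones),
               list(v_total = 3, s_total = 3, c_total = 2))
})

test_that("invalid monomers are rejected with the field named", {
  expect_error(classify_phenols(zero_profile(vanillin = -1)), "vanillin")
  expect_error(classify_phenols(zero_profile(ferulic_acid = NaN)),
               "ferulic_acid")
  expect_error(classify_phenols(zero_profile()[-1]), "vanillin")
})

test_that("lignin summary computes proportions and Ac/Al ratios", {
  p <- zero_profile(vanillin = 0.5, vanillic_acid = 0.5, syringaldehyde = 1,
                    syringic_acid = 0.25)
  ls <- lignin_summary(p)
  expect_equal(ls$ac_al_v, 1.0)
  expect_equal(ls$ac_al_s, 0.25)

  # class totals 5.5 / 1.5 / 3.0 -> 55 / 15 / 30 percent
  p2 <- zero_profile(vanillin = 5.5, syringaldehyde = 1.5,
                     p_coumaric_acid = 3.0)
  ls2 <- lignin_summary(p2)
  expect_equal(ls2$lignin_total, 10)
  expect_equal(c(ls2$prop_v, ls2$prop_s, ls2$prop_c), c(55, 15, 30))
  expect_equal(ls2$prop_v + ls2$prop_s + ls2$prop_c, 100)
})

test_that("degenerate lignin inputs are flagged, not fatal", {
  ls <- lignin_summary(zero_profile())
  expect_equal(ls$lignin_total, 0)
  expect_true(is.na(ls$prop_v) && is.na(ls$ac_al_v) && is.na(ls$ac_al_s))
  flags <- strsplit(ls$qc_flags, ";")[[1]]
  expect_setequal(flags, c("zero_lignin", "undefined_ac_al_v",
                           "undefined_ac_al_s"))
  # only the syringyl ratio is undefined here
  ls2 <- lignin_summary(zero_profile(vanillin = 1, p_coumaric_acid = 1))
  expect_equal(ls2$qc_flags, "undefined_ac_al_s")
  expect_equal(ls2$ac_al_v, 0)
})

test_that("plant-derived C is the coefficient-weighted class sum in g/kg", {
  expect_equal(plant_derived_c(0, 0, 0), 0)
  expect_equal(plant_derived_c(0.33, 0.9, 0.03), 0.003)
  expect_equal(plant_derived_c(330, 900, 30), 3)
  # coefficients are overridable configuration
  alt <- attribution_coefficients(lignin_coeff_v = 1, lignin_coeff_s = 1,
                                  lignin_coeff_c = 1)
  expect_equal(plant_derived_c(1, 2, 3, alt), 0.006)
  expect_error(attribution_coefficients(lignin_coeff_c = 0), "lignin_coeff_c")
})

test_that("pool fractions of SOC behave as percentages", {
  expect_equal(plant_fraction(0, 10), 0)
  expect_equal(plant_fraction(17.99, 17.99), 100)
  expect_equal(plant_fraction(1.508, 17.99), 8.38, tolerance = 1e-3)
  expect_error(plant_fraction(1, 0), "positive")
  expect_error(plant_fraction(1, -5), "positive")
})

test_that("fungal and bacterial pools invert to the reported group values", {
  expect_equal(fungal_derived_c(list(glcn = 0, galn = 0, murn = 0))$fungal_c, 0)
  expect_equal(fungal_derived_c(list(glcn = 179.17, galn = 0,
                                     murn = 0))$fungal_c,
               179.17 * 9 / 1000)
  expect_equal(bacterial_derived_c(list(glcn = 0, galn = 0, murn = 0)), 0)
  expect_equal(bacterial_derived_c(list(glcn = 0, galn = 0, murn = 1)), 0.045)

  # oracle: solve the conversion formulas for the biomarker concentrations
  # that give the reported broadleaf pools, then run them forward
  murn_b <- reported$bacterial_c[1] * 1000 / 45
  glcn_b <- (reported$fungal_c[1] * 1000 / (179.17 * 9) +
               2 * murn_b / 253.23) * 179.17
  expect_equal(murn_b, 26.889, tolerance = 1e-4)
  expect_equal(glcn_b, 1058.05, tolerance = 1e-4)
  asp <- list(glcn = glcn_b, galn = 0, murn = murn_b)
  expect_equal(fungal_derived_c(asp)$fungal_c, 9.18, tolerance = 1e-10)
  expect_equal(bacterial_derived_c(asp), 1.21, tolerance = 1e-12)
})

test_that("bacterially dominated profiles flag negative fungal C", {
  asp <- list(glcn = 10, galn = 0, murn = 50)
  fc <- fungal_derived_c(asp)
  expect_lt(fc$fungal_c, 0)
  expect_equal(fc$qc_flags, "negative_fungal_c")
  # the raw value is reported, fractions clip at zero
  s <- c(list(soc = 10), zero_profile(vanillin = 1), asp)
  att <- attribute_sample(s)
  expect_lt(att$fungal_c, 0)
  expect_equal(att$fungal_fraction, 0)
  expect_match(att$qc_flags, "negative_fungal_c")
})

test_that("attribute_sample composes pools, fractions and flags", {
  murn_b <- reported$bacterial_c[1] * 1000 / 45
  glcn_b <- (reported$fungal_c[1] * 1000 / (179.17 * 9) +
               2 * murn_b / 253.23) * 179.17
  soc_b <- sum(reported$fungal_c[1], reported$bacterial_c[1]) /
    (reported$microbial_fraction[1] / 100)
  s <- c(list(soc = soc_b), zero_profile(vanillin = 10),
         list(glcn = glcn_b, galn = 100, murn = murn_b))
  att <- attribute_sample(s)
  expect_equal(att$microbial_c, att$fungal_c + att$bacterial_c)
  expect_equal(att$microbial_c, 9.18 + 1.21, tolerance = 1e-10)
  expect_equal(att$microbial_fraction, 57.75, tolerance = 1e-3)

  # all-zero biomarkers: every pool and fraction zero, lignin flags only
  z <- c(list(soc = 10), zero_profile(), list(glcn = 0, galn = 0, murn = 0))
  attz <- attribute_sample(z)
  expect_equal(attz$plant_c, 0)
  expect_equal(attz$microbial_c, 0)
  expect_equal(attz$plant_fraction + attz$microbial_fraction, 0)
  expect_false(grepl("negative_fungal_c|fractions_exceed_soc", attz$qc_flags))

  # tiny SOC forces the over-100% closure flag
  s$soc <- 5
  expect_match(attribute_sample(s)$qc_flags, "fractions_exceed_soc")
})

test_that("attribution matches brute-force recomputation on random profiles", {
  rows <- random_biomarker_rows(500, seed = 101)
  att <- attribute_table(rows)
  for (i in c(1, 57, 250, 500)) {
    oracle <- brute_force_attribution(rows[i, ])
    for (f in names(oracle)) {
      expect_equal(att[[f]][i], oracle[[f]], tolerance = 1e-12, label = f)
    }
  }
  # vectorised equality for the key pools over all rows
  oracle_all <- lapply(seq_len(nrow(rows)), function(i)
    brute_force_attribution(rows[i, ]))
  expect_equal(att$microbial_c,
               vapply(oracle_all, `[[`, numeric(1), "microbial_c"),
               tolerance = 1e-12)
  expect_equal(att$plant_c, vapply(oracle_all, `[[`, numeric(1), "plant_c"),
               tolerance = 1e-12)
})

test_that("pools are additive, degree-1 homogeneous, and scale invariant", {
  rows <- random_biomarker_rows(50, seed = 7)
  att <- attribute_table(rows)
  expect_equal(att$microbial_c, att$fungal_c + att$bacterial_c)
  expect_equal(att$lignin_total, att$v_total + att$s_total + att$c_total)

  for (k in c(0.25, 3, 17)) {
    scaled <- rows
    biom <- setdiff(names(rows), character(0))
    scaled[biom] <- rows[biom] * k
    att_k <- attribute_table(scaled)
    # pools scale linearly with concentrations
    expect_equal(att_k$plant_c, k * att$plant_c, tolerance = 1e-12)
    expect_equal(att_k$microbial_c, k * att$microbial_c, tolerance = 1e-12)
    # fractions and ratios are invariant when SOC scales too
    expect_equal(att_k$plant_fraction, att$plant_fraction, tolerance = 1e-12)
    expect_equal(att_k$microbial_fraction, att$microbial_fraction,
                 tolerance = 1e-12)
    expect_equal(att_k$ac_al_v, att$ac_al_v, tolerance = 1e-12)
    expect_equal(att_k$prop_v, att$prop_v, tolerance = 1e-12)
  }
})

test_that("fungal C crosses zero exactly at the stoichiometric boundary", {
  # glcn/179.17 == 2 * murn/253.23
  murn <- c(1, 10, 33.7)
  glcn <- 2 * murn / 253.23 * 179.17
  fc <- fungal_derived_c(list(glcn = glcn, galn = 0, murn = murn))
  expect_identical(fc$fungal_c, rep(0, 3))
  eps <- 1e-9
  expect_gt(fungal_derived_c(list(glcn = glcn[1] + eps, galn = 0,
                                  murn = murn[1]))$fungal_c, 0)
  expect_lt(fungal_derived_c(list(glcn = glcn[1] - eps, galn = 0,
                                  murn = murn[1]))$fungal_c, 0)
})
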