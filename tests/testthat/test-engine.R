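test_that("the hub map and its inverse reproduce the fixture arithmetic", {
  expect_equal(to_ome(f1, "morphine", "oral", 60), 60)
  expect_equal(to_ome(f1, "oxycodone", "oral", 30), 60)
  expect_equal(to_ome(f1, "codeine", "oral", 100), 10)
  expect_null(to_ome(f1, "buprenorphine", "oral", 10))
  expect_error(to_ome(f1, "morphine", "oral", -1), "positive")

  expect_equal(from_ome(f1, "oxycodone", "oral", 60), 30)
  expect_equal(from_ome(f1, "morphine", "subcutaneous", 60), 30)
  expect_null(from_ome(f1, "buprenorphine", "oral", 60))
  expect_error(from_ome(f1, "fentanyl", "transdermal", 60), "select_patch")
})

test_that("from_ome inverts to_ome for every supported continuous pair", {
  for (i in seq_len(nrow(f1_continuous))) {
    d <- f1_continuous$drug[i]
    r <- f1_continuous$route[i]
    for (dose in c(0.3, 1, 7.5, 60, 123.4)) {
      expect_equal(from_ome(f1, d, r, to_ome(f1, d, r, dose)), dose,
                   tolerance = 1e-12, label = paste(d, r, dose))
    }
  }
})

test_that("patch selection: interior, border-down, below, above, gaps", {
  tab <- f1$patch_tables$fentanyl
  expect_equal(select_patch(tab, 70)$band$strength, 25)
  expect_equal(select_patch(tab, 45)$band$strength, 12)
  expect_equal(select_patch(tab, 265)$band$strength, 100)

  # every shared border resolves to the lower-strength patch
  lower <- c(12, 25, 50, 75)
  upper <- c(25, 50, 75, 100)
  borders <- c(60, 90, 150, 210)
  for (i in seq_along(borders)) {
    expect_equal(select_patch(tab, borders[i])$band$strength, lower[i],
                 label = paste("border", borders[i]))
    expect_equal(select_patch(tab, borders[i] - 1e-6)$band$strength, lower[i])
    expect_equal(select_patch(tab, borders[i] + 1e-6)$band$strength, upper[i])
    # the historical defect flag flips exactly the border case
    expect_equal(select_patch(tab, borders[i], tie = "up")$band$strength,
                 upper[i])
    expect_equal(select_patch(tab, borders[i] - 1e-6, tie = "up")$band$strength,
                 lower[i])
  }

  # a border OME computed through decimal factors still hits the border
  expect_equal(select_patch(tab, to_ome(f1, "codeine", "oral", 600))$band$strength,
               12)

  below <- select_patch(tab, 10)
  expect_null(below$band)
  expect_identical(below$warning$code, "below_smallest_patch")

  above <- select_patch(tab, 400)
  expect_equal(above$band$strength, 100)
  expect_identical(above$warning$code, "above_largest_patch")

  # gap between bands rounds down to the band below
  gappy <- data.frame(strength = c(12, 25), ome_low = c(30, 70),
                      ome_high = c(60, 90))
  expect_equal(select_patch(gappy, 65)$band$strength, 12)

  expect_error(select_patch(tab[0, ], 60), "empty")
})

test_that("patch strength is a non-decreasing step function of OME", {
  tab <- f1$patch_tables$fentanyl
  omes <- seq(30, 270, by = 0.5)
  strengths <- vapply(omes, function(o) select_patch(tab, o)$band$strength,
                      numeric(1))
  expect_true(all(diff(strengths) >= 0))
})

test_that("practical rounding floors to the increment and never returns zero", {
  expect_equal(round_practical(31.2, 2.5), list(dose = 30, inflated = FALSE))
  expect_equal(round_practical(30, 2.5), list(dose = 30, inflated = FALSE))
  expect_equal(round_practical(1.1, 2.5), list(dose = 2.5, inflated = TRUE))
  expect_equal(round_practical(2.5, 2.5), list(dose = 2.5, inflated = FALSE))
  # decimal representation, not binary float, decides exact multiples
  expect_equal(round_practical(0.3, 0.1)$dose, 0.3)
  expect_error(round_practical(10, 0), "positive")
})

test_that("breakthrough dose is the daily dose over the divisor", {
  expect_equal(breakthrough_dose(f1, "morphine", "oral", 60), 10)
  expect_equal(breakthrough_dose(f1, "oxycodone", "oral", 30), 5)
  expect_error(breakthrough_dose(f1, "fentanyl", "transdermal", 60),
               "convert the patch to OME first")
  expect_error(breakthrough_dose(f1, "morphine", "oral", 0), "positive")

  # divisor is formulary data, not a constant
  f10 <- f1
  f10$breakthrough_divisor <- 10
  expect_equal(breakthrough_dose(f10, "morphine", "oral", 60), 6)

  # opt-in practical rounding floors to the increment
  expect_equal(as.numeric(breakthrough_dose(f1, "morphine", "oral", 62,
                                            rounding = "practical")), 10)
})

test_that("renal caution fires only on flagged drugs below the threshold", {
  expect_identical(renal_warning(f1, "morphine", egfr = 20)$code, "renal_caution")
  expect_null(renal_warning(f1, "morphine", egfr = 80))
  expect_null(renal_warning(f1, "morphine", egfr = 30))  # threshold exclusive
  expect_null(renal_warning(f1, "alfentanil", egfr = 20))
  expect_null(renal_warning(f1, "morphine"))  # absent eGFR: no assumption
  expect_error(renal_warning(f1, "morphine", egfr = -1), "non-negative")
})

test_that("convert runs the full pipeline with explicit statuses", {
  ok <- convert(f1, conversion_request("morphine", "oral", 60,
                                       "oxycodone", "oral"))
  expect_identical(ok$status, "ok")
  expect_equal(ok$ome, 60)
  expect_equal(ok$exact_target_dose, 30)
  expect_equal(ok$practical_target_dose, 30)
  expect_identical(ok$target_unit, "mg/24h")
  expect_identical(ok$formulary_version, "F1")

  meth <- convert(f1, conversion_request("morphine", "oral", 60,
                                         "methadone", "oral"))
  expect_identical(meth$status, "unsupported_drug")
  expect_null(meth$ome)
  expect_null(meth$practical_target_dose)

  gap <- convert(f1, conversion_request("morphine", "oral", 60,
                                        "buprenorphine", "oral"))
  expect_identical(gap$status, "no_guideline_equivalence")
  expect_null(gap$exact_target_dose)

  # a patch index has no conversion factor: refusal, not a fabricated dose
  patch_idx <- convert(f1, conversion_request("fentanyl", "transdermal", 25,
                                              "morphine", "oral"))
  expect_identical(patch_idx$status, "no_guideline_equivalence")

  expect_error(conversion_request("morphine", "oral", -5, "oxycodone", "oral"),
               "positive")
  expect_error(convert(f1, list(index_drug = "morphine")),
               "conversion_request")
})

test_that("convert attaches warnings without suppressing doses", {
  renal <- convert(f1, conversion_request("oxycodone", "oral", 30,
                                          "morphine", "oral", egfr = 15))
  expect_identical(vapply(renal$warnings, `[[`, "", "code"), "renal_caution")
  expect_equal(renal$practical_target_dose, 60)

  low <- convert(f1, conversion_request("morphine", "oral", 10,
                                        "fentanyl", "transdermal"))
  expect_identical(low$status, "ok")
  expect_null(low$practical_target_dose)
  expect_identical(vapply(low$warnings, `[[`, "", "code"),
                   "below_smallest_patch")

  high <- convert(f1, conversion_request("morphine", "oral", 400,
                                         "fentanyl", "transdermal"))
  expect_equal(high$practical_target_dose, 100)
  expect_identical(vapply(high$warnings, `[[`, "", "code"),
                   "above_largest_patch")

  inflated <- convert(f1, conversion_request("codeine", "oral", 30,
                                             "oxycodone", "oral",
                                             rounding = "practical"))
  expect_equal(inflated$exact_target_dose, 1.5)
  expect_equal(inflated$practical_target_dose, 2.5)
  expect_identical(vapply(inflated$warnings, `[[`, "", "code"), "large_dose")
})

test_that("patch targets report the discrete strength as the practical dose", {
  res <- convert(f1, conversion_request("oxycodone", "oral", 35,
                                        "fentanyl", "transdermal"))
  expect_identical(res$status, "ok")
  expect_equal(res$ome, 70)
  expect_null(res$exact_target_dose)
  expect_equal(res$practical_target_dose, 25)
  expect_true(res$practical_target_dose %in% f1$patch_tables$fentanyl$strength)
  expect_identical(res$target_unit, "microgram/h")
})
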