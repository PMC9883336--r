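test_that("formula parsing, formatting and Hill-order round trips", {
  expect_equal(formula_parse("C22H38O3"), c(C = 22L, H = 38L, O = 3L))
  expect_equal(formula_parse("O"), c(O = 1L))
  expect_equal(formula_parse("CH4"), c(C = 1L, H = 4L))
  # round trip over every formula style in the reference tables
  printed <- c("C22H38O3", "C23H42O2", "C60H99O9", "C61H103O8", "C59H105O7",
               "C61H97O6", "C38H67O5", "C39H71O4", "C41H71O5", "C43H63O4",
               "C57H98O6", "C18H35O", "C16H31O", "C58H99O7", "C57H96O7",
               "C61H102O8", "C56H100O7")
  for (f in printed) expect_identical(formula_format(formula_parse(f)), f)
  # Hill order is canonical regardless of input order
  expect_identical(formula_format(c(O = 3, H = 38, C = 22)), "C22H38O3")
  expect_error(formula_parse("C22Xx3"), "unknown element")
  expect_error(formula_parse("H-3"), "malformed")
})

test_that("formula arithmetic is element-wise and guards against negatives", {
  expect_equal(formula_add("C18H32O2", "C3H8O3"), formula_parse("C21H40O5"))
  expect_equal(formula_subtract("C19H32O3", "HO"), formula_parse("C19H31O2"))
  expect_error(formula_subtract("CH4", "O"), "below zero")
  # zero-count entries equal absence
  expect_equal(formula_subtract("C2H4", "C2"), c(H = 4L))
})

test_that("monoisotopic masses reproduce the printed exact masses", {
  r4 <- function(x) round_half_up(x, 4)
  expect_equal(r4(monoisotopic_mass("CH4")), 16.0313)
  expect_equal(r4(monoisotopic_mass("O")), 15.9949)
  expect_equal(r4(monoisotopic_mass("C22H38O3")), 350.2821)
  expect_equal(r4(monoisotopic_mass("C23H42O2")), 350.3185)
  expect_equal(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass(c(Zz = 2)), "unknown element")
})

test_that("mass additivity holds to 1e-9 Da for random formulas", {
  set.seed(42)
  for (k in 1:50) {
    a <- random_formula(); b <- random_formula()
    expect_equal(monoisotopic_mass(formula_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("ion m/z handles proton, ammonium and fragment-cation conventions", {
  r4 <- function(x) round_half_up(x, 4)
  expect_equal(r4(ion_mz("C57H98O6")), 879.7442)             # trilinolein +H
  expect_equal(r4(ion_mz("C60H98O9")), 963.7289)             # tri-FuFA TAG +H
  # ammonium adduct is NH3 heavier than the proton adduct
  expect_equal(ion_mz("C57H98O6", "NH4") - ion_mz("C57H98O6", "H"),
               monoisotopic_mass("NH3"), tolerance = 1e-12)
  # fragment cations return the atom-inventory mass; the electron correction
  # subtracts exactly one electron mass per charge
  off <- ion_mz("C11H17O", adduct = "none")
  on <- ion_mz("C11H17O", adduct = "none", electron_correction = TRUE)
  expect_equal(off - on, 0.00054857990924, tolerance = 1e-9)
  expect_equal(r4(off), 165.1279)
  expect_lt(abs(ppm_error(165.1280, off)), 1)   # both printed variants are
  expect_lt(abs(ppm_error(165.1275, on)), 1)    # within 1 ppm of the sums
  expect_error(ion_mz("C11H17O", adduct = "none", charge = 0), "charge")
})

test_that("ppm error matches the printed deviation and its conventions", {
  # printed measured/calculated pair of trilinolein
  expect_equal(round_half_up(ppm_error(879.7458, 879.7442), 3), 1.819)
  expect_equal(ppm_error(305.2481, 305.2481), 0)
  # antisymmetry up to the change of reference
  expect_equal(ppm_error(911.7690, 911.7704),
               -ppm_error(911.7718, 911.7704), tolerance = 1e-6)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("required resolution reproduces the precursor isobar case", {
  expect_equal(round(required_resolution(925.7285, 0.0575) / 100) * 100, 16100)
  expect_equal(round(required_resolution(963.7289, 0.0364) / 100) * 100, 26500)
  expect_equal(required_resolution(100, 1), 100)
  expect_error(required_resolution(100, 0), "positive")
})

test_that("isobar deltas recover the two interference classes with sign", {
  d1 <- isobar_delta("C22H38O3", "C23H42O2")
  expect_equal(d1$class, "O vs CH4")
  expect_equal(round_half_up(d1$delta_m, 4), -0.0364)
  expect_identical(formula_format(d1$surplus1), "O")
  expect_identical(formula_format(d1$surplus2), "CH4")

  d2 <- isobar_delta("C59H105O7", "C61H97O6")   # protonated OO-FuFA vs OEpEp
  expect_equal(d2$class, "C2 vs H8O")
  expect_equal(round_half_up(d2$delta_m, 4), 0.0575)

  d3 <- isobar_delta("C57H98O6", "C57H98O6")
  expect_equal(d3$class, "identical")
  expect_equal(d3$delta_m, 0)
})
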