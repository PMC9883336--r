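test_that("TAG assembly derives formula, name and carbon number", {
  tag <- build_tag("L", "L", "9M5")
  expect_identical(tag$name, "LL9M5")
  expect_identical(formula_format(tag$formula), "C58H98O7")
  # the printed TAG formulas are the protonated ions
  expect_identical(formula_format(formula_add(tag$formula, c(H = 1L))),
                   "C58H99O7")
  expect_equal(tag$carbon_number, 55)
  expect_equal(tag$n_fufa, 1)
  # multiset semantics: argument order is irrelevant
  tag2 <- build_tag("9M5", "L", "L")
  expect_identical(tag2$name, tag$name)
  expect_identical(tag2$formula, tag$formula)
  expect_equal(build_tag("L", "L", "9D5")$carbon_number, 56)
})

test_that("canonical names order conventional FAs by ascending mass", {
  expect_identical(build_tag("O", "L", "9D5")$name, "LO9D5")
  expect_identical(build_tag("S", "O", "9D5")$name, "OS9D5")
  expect_identical(build_tag("Ln", "15:0", "9D5")$name, "15:0-Ln9D5")
  expect_identical(build_tag("9D5", "L", "9D5")$name, "L9D59D5")
})

test_that("TAG names parse back to their compositions", {
  for (nm in c("LL9M5", "PnL9D5", "15:0-Ln9D5", "17:0-L9D5", "L9D59D5",
               "OS9D5", "LLL"))
    expect_identical(parse_tag_name(nm)$name, nm)
  expect_error(parse_tag_name("LL"), "three fatty-acid")
  expect_error(parse_tag_name("QQ9M5"), "tokenize")
})

test_that("precursor m/z values reproduce the printed calculated masses", {
  r4 <- function(x) round_half_up(x, 4)
  expect_equal(r4(tag_precursor_mz(build_tag("L", "L", "9M5"))), 907.7391)
  expect_equal(r4(tag_precursor_mz(build_tag("O", "O", "9M5"))), 911.7704)
  expect_equal(r4(tag_precursor_mz(build_tag("O", "O", "9D5"))), 925.7860)
  expect_equal(r4(tag_precursor_mz(build_tag("L", "9M5", "9M5"))), 935.7340)
  expect_equal(r4(tag_precursor_mz(build_tag("9M5", "9M5", "9M5"))), 963.7289)
  expect_equal(r4(tag_precursor_mz(build_tag("Ep", "Dh", "11D5"))), 1019.7704)
})

test_that("atom conservation holds for random compositions", {
  set.seed(7)
  for (k in 1:30) {
    tag <- random_tag()
    lhs <- tag$formula
    rhs <- formula_subtract(
      Reduce(formula_add, lapply(tag$fas, fa_neutral_formula),
             c(C = 3L, H = 8L, O = 3L)),
      c(H = 6L, O = 3L))
    expect_identical(lhs, rhs)
  }
})

test_that("candidate enumeration matches the multiset closed form", {
  blocks <- default_building_blocks()
  # the screening configuration: 6 FuFAs x 7 conventional FAs, one FuFA each
  db <- enumerate_candidates(blocks, 1,
                             conv = c("P", "O", "L", "Ln", "Ep", "Dp", "Dh"),
                             fufas = c("9M5", "11M3", "9D5", "11D3", "11D5", "13D3"))
  expect_equal(nrow(db), 6 * 7 * 8 / 2)   # f * k(k+1)/2 = 168
  # oracle: exhaustive generation of distinct names
  oracle <- character(0)
  for (f in c("9M5", "11M3", "9D5", "11D3", "11D5", "13D3"))
    for (a in c("P", "O", "L", "Ln", "Ep", "Dp", "Dh"))
      for (b in c("P", "O", "L", "Ln", "Ep", "Dp", "Dh"))
        oracle <- c(oracle, build_tag(a, b, f)$name)
  expect_setequal(db$name, unique(oracle))
  expect_equal(nrow(enumerate_candidates(blocks, 1, conv = "L", fufas = "9M5")), 1)
  # sorted for binary-search style matching, no duplicates
  expect_false(is.unsorted(db$mz_h))
  expect_false(anyDuplicated(db$name) > 0)
})

test_that("two-FuFA enumeration covers the printed double-FuFA TAGs", {
  db <- enumerate_candidates(default_building_blocks(), 2,
                             conv = "L", fufas = c("9M5", "9D5"))
  expect_setequal(db$name, c("L9M59M5", "L9M59D5", "L9D59D5"))
  i <- match("L9M59M5", db$name)
  expect_equal(round_half_up(db$mz_h[i], 4), 935.7340)
})

test_that("true isomers share a precursor but stay separate candidates", {
  db <- enumerate_candidates(default_building_blocks(), 1,
                             conv = c("P", "O", "L", "Ln"),
                             fufas = c("9D5", "11D5"))
  i <- match("LO9D5", db$name); j <- match("PLn11D5", db$name)
  expect_false(is.na(i) || is.na(j))
  expect_identical(db$formula[i], db$formula[j])
  expect_equal(db$mz_h[i], db$mz_h[j])
})

test_that("isobaric conflicts are detected below the resolution limit", {
  blocks <- default_building_blocks()
  fdb <- enumerate_candidates(blocks, 1, conv = "O", fufas = "9D5")
  cdb <- enumerate_candidates(blocks, 0, conv = c("O", "Ep"))
  # delta 0.0575 Da resolved at R = 70,000 (FWHM ~ 0.013 Da)
  expect_equal(nrow(find_isobaric_conflicts(fdb, cdb, 70000)), 0)
  # but not at R = 10,000 (FWHM ~ 0.093 Da)
  confl <- find_isobaric_conflicts(fdb, cdb, 10000)
  hit <- confl[confl$name1 == "OO9D5" & confl$name2 == "OEpEp", ]
  expect_equal(nrow(hit), 1)
  expect_identical(hit$class, "C2 vs H8O")
  expect_equal(round_half_up(hit$delta_m, 4), 0.0575)
  # tri-FuFA vs mixed two-FuFA: the O-vs-CH4 class
  f3 <- enumerate_candidates(blocks, 3, fufas = "9M5")
  f2 <- enumerate_candidates(blocks, 2, conv = "L", fufas = "9D5")
  confl2 <- find_isobaric_conflicts(f3, f2, 10000)
  expect_identical(confl2$class, "O vs CH4")
  expect_equal(round_half_up(confl2$delta_m, 4), -0.0364)
  # a database conflicts with itself only across distinct compositions
  expect_equal(nrow(find_isobaric_conflicts(fdb, fdb, 1e6)), 0)
})

test_that("candidate export writes the documented columns", {
  db <- small_db()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(db, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(db))
  expect_true(all(c("name", "formula", "mz_h", "mz_nh4", "fufa_tokens",
                    "conv_tokens", "carbon_number") %in% names(back)))
})
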