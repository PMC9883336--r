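test_that("the filter identifies a clean FuFA-TAG spectrum as FULL", {
  db <- small_db()
  # the six diagnostic peaks of an LL-9M5 spectrum
  s <- ms2_spectrum(c(907.7391, 627.4989, 599.5039, 291.2324, 165.1280, 109.0653),
                    c(80, 400, 420, 1000, 100, 150), precursor_mz = 907.7391)
  ann <- screen_spectrum(s, db)
  expect_equal(nrow(ann), 1)
  expect_identical(ann$name, "LL9M5")
  expect_identical(ann$tier, "FULL")
  expect_equal(ann$intensity, 1000)          # the [FCO]+ peak intensity
  expect_equal(ann$carbon_number, 55)
  expect_identical(ann$positional_isomers, "unresolved")
  ions <- ann$ions[[1]]
  expect_true(all(c("fco", "furan_core", "mclafferty", "diacyl")
                  %in% ions$ion_type))
})

test_that("removing the diacyl ions demotes the call to FUFA_ONLY", {
  db <- small_db()
  s <- ms2_spectrum(c(907.7391, 291.2324, 165.1280, 109.0653),
                    c(80, 1000, 100, 150), precursor_mz = 907.7391)
  ann <- screen_spectrum(s, db)
  expect_equal(nrow(ann), 1)
  expect_identical(ann$tier, "FUFA_ONLY")
  expect_identical(ann$name, "XY9M5")
  expect_equal(ann$n_diacyl_matched, 0)
  expect_equal(ann$carbon_number, 55)   # from the precursor formula
})

test_that("FuFA-free spectra and missing trio ions yield no annotation", {
  db <- small_db()
  # trilinolein: precursor + single diacyl ion, no furan chemistry
  lll <- fragment_set(build_tag("L", "L", "L"))
  s <- ms2_spectrum(c(lll$precursor_h, lll$diacyl$mz), c(100, 900),
                    precursor_mz = lll$precursor_h)
  expect_equal(nrow(screen_spectrum(s, db)), 0)
  # [FCO]+ present but furan core missing: rejected at the core step
  s2 <- ms2_spectrum(c(907.7391, 291.2324, 109.0653), c(80, 1000, 150),
                     precursor_mz = 907.7391)
  ann2 <- screen_spectrum(s2, db)
  expect_equal(nrow(ann2), 0)
  rej <- attr(ann2, "rejections")
  expect_true("furan_core" %in% rej$failed_step)
})

test_that("the furan core ion arbitrates acylium-degenerate FuFA pairs", {
  db <- small_db()
  # an LL-11M3 spectrum: same [FCO]+ and McLafferty as LL-9M5 but the
  # 11M3 core at m/z ~137.097 instead of ~165.128
  fs <- fragment_set(build_tag("L", "L", "11M3"))
  s <- ms2_spectrum(c(fs$precursor_h, fs$diacyl$mz, 291.2324,
                      fs$core$mz, 109.0653),
                    c(80, 400, 420, 1000, 100, 150),
                    precursor_mz = fs$precursor_h)
  ann <- screen_spectrum(s, db)
  expect_identical(ann$name, "LL11M3")
  # pathological spectrum carrying both cores: both emitted, flagged
  s2 <- ms2_spectrum(c(fs$precursor_h, fs$diacyl$mz, 291.2324,
                       fs$core$mz, 165.1279, 109.0653),
                     c(80, 400, 420, 1000, 100, 90, 150),
                     precursor_mz = fs$precursor_h)
  ann2 <- screen_spectrum(s2, db)
  expect_setequal(ann2$name, c("LL11M3", "LL9M5"))
  expect_true(all(ann2$ambiguous))
})

test_that("base-peak strict mode requires [FCO]+ to top the spectrum", {
  db <- small_db()
  peaks_mz <- c(907.7391, 627.4989, 599.5039, 291.2324, 165.1280, 109.0653)
  s_ok <- ms2_spectrum(peaks_mz, c(80, 400, 420, 1000, 100, 150),
                       precursor_mz = 907.7391)
  s_weak <- ms2_spectrum(peaks_mz, c(80, 2000, 420, 1000, 100, 150),
                         precursor_mz = 907.7391)
  expect_equal(nrow(screen_spectrum(s_ok, db, require_base_peak = TRUE)), 1)
  expect_equal(nrow(screen_spectrum(s_weak, db, require_base_peak = TRUE)), 0)
  expect_equal(nrow(screen_spectrum(s_weak, db)), 1)   # default: permissive
})

test_that("annotations shrink monotonically as the tolerance tightens", {
  db <- shared_db()
  fx <- table6_fixture()
  tols <- c(8, 4, 2, 1, 0.5, 0.1)
  counts <- vapply(tols, function(tol)
    nrow(annotate_run(fx, db, tol_ppm = tol)), 0L)
  expect_false(is.unsorted(rev(counts)))
  # the printed observed masses deviate from theory by ~1-3 ppm, so an
  # over-tight window must lose identifications
  expect_lt(counts[length(tols)], counts[2])
})

test_that("runs deduplicate by TAG keeping the strongest [FCO]+ signal", {
  db <- shared_db()
  fx <- table6_fixture()
  ann <- annotate_run(fx, db)
  dup <- annotate_run(c(fx, fx), db)
  expect_equal(nrow(dup), nrow(ann))
  expect_setequal(dup$name, ann$name)
  # empty run
  empty <- annotate_run(list(), db)
  expect_equal(nrow(empty), 0)
})

test_that("every FULL annotation is self-consistent with its named TAG", {
  db <- shared_db()
  ann <- annotate_run(table6_fixture(), db)
  full <- ann[ann$tier == "FULL", ]
  for (r in seq_len(nrow(full))) {
    fs <- fragment_set(parse_tag_name(full$name[r]))
    ions <- full$ions[[r]]
    dia <- ions[ions$ion_type == "diacyl", ]
    for (k in seq_len(nrow(dia)))
      expect_true(any(abs(ppm_error(dia$mz_obs[k], fs$diacyl$mz)) <= 4))
    fco <- ions[ions$ion_type == "fco", ]
    expect_true(all(abs(ppm_error(
      fco$mz_obs, fs$acylium$mz[fs$acylium$is_fufa])) <= 4))
  }
})

test_that("annotation reports and evidence files are written", {
  db <- shared_db()
  ann <- annotate_run(table6_fixture(), db)
  dir <- withr::local_tempdir()
  report <- file.path(dir, "report.tsv")
  evid <- file.path(dir, "evidence.json")
  write_annotations(ann, report, evidence_path = evid)
  back <- read.delim(report)
  expect_equal(nrow(back), nrow(ann))
  ev <- jsonlite::read_json(evid)
  expect_length(ev, nrow(ann))
  expect_identical(ev[[1]]$name, ann$name[1])
})

test_that("relative abundances normalize to the first run's top TAG", {
  t1 <- data.frame(name = c("A", "B"), intensity = c(1000, 500))
  t2 <- t1; t3 <- t1
  ra <- relative_abundances(list(t1, t2, t3))
  expect_equal(ra$percent_run1[ra$name == "A"], 100)
  expect_equal(ra$percent_run1[ra$name == "B"], 50)
  expect_equal(ra$rsd_percent, c(0, 0))
  # a run lacking the reference is flagged, not dropped
  t4 <- data.frame(name = "B", intensity = 480)
  ra2 <- relative_abundances(list(t1, t4))
  expect_match(attr(ra2, "flagged_runs"), "run 2")
})

test_that("replicate noise at CV 0.2 yields double-digit relative spreads", {
  set.seed(99)
  base <- data.frame(name = paste0("tag", 1:8),
                     intensity = c(66800, 29100, 10100, 9980, 3770,
                                   1280, 570, 121) * 1000)
  rsds <- replicate(40, {
    runs <- lapply(1:3, function(i) {
      tab <- base
      tab$intensity <- tab$intensity * exp(stats::rnorm(nrow(tab), 0, 0.2))
      tab
    })
    mean(relative_abundances(runs)$rsd_percent, na.rm = TRUE)
  })
  # multiplicative noise with sigma 0.2 gives spreads of order 10-40%
  expect_gt(mean(rsds), 5)
  expect_lt(mean(rsds), 60)
})

test_that("content estimation allocates proportionally and conserves totals", {
  tab <- data.frame(name = c("A", "B"), intensity = c(3, 1))
  est <- estimate_contents(tab, total_fufa_content = 4)
  expect_equal(est$content, c(3, 1))
  expect_equal(sum(est$content), 4, tolerance = 1e-12)
  # 0.1 mg/100 g dry weight at 5% lipid -> 2 mg/100 g lipids
  tab2 <- data.frame(name = c("A", "B"), intensity = c(39, 1))
  est2 <- estimate_contents(tab2, total_fufa_content = 4, basis = "lipid",
                            lipid_fraction = 0.05)
  expect_equal(attr(est2, "minimum"), (4 * 1 / 40) / 0.05)
  expect_equal(attr(est2, "minimum"), 2)
  single <- estimate_contents(data.frame(name = "A", intensity = 7), 4)
  expect_equal(single$content, 4)
  expect_error(estimate_contents(data.frame(name = "A", intensity = 0), 4),
               "zero")
  # conservation for random intensity vectors
  set.seed(5)
  for (k in 1:10) {
    n <- sample(2:10, 1)
    tabk <- data.frame(name = paste0("t", 1:n),
                       intensity = stats::runif(n, 1, 1000))
    expect_equal(sum(estimate_contents(tabk, 123.4)$content), 123.4,
                 tolerance = 1e-9)
  }
})
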