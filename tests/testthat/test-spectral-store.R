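test_that("metadata validation follows the technique's group table", {
  meta_lc <- list(sample = list(label = "x"),
                  liquid_chromatography = list(column_name = "C18", flow_rate = "0.3"),
                  ionization_method = list(ionization = "ESI", polarity = "+"),
                  ion_analyzer = list(instrument = "QTOF"))
  expect_identical(nrow(validate_metadata("LC-MS", meta_lc)), 0L)

  # GC-MS with an LC group instead of a GC group: both a missing-group and
  # an inapplicable-group issue
  meta_gc_wrong <- meta_lc
  issues <- validate_metadata("GC-MS", meta_gc_wrong)
  expect_gte(nrow(issues), 2)
  expect_true(any(issues$group == "gas_chromatography"))
  expect_true(any(issues$group == "liquid_chromatography"))

  # missing mandatory field inside a present group
  meta_nofield <- meta_lc
  meta_nofield$ionization_method$polarity <- NULL
  issues <- validate_metadata("LC-MS", meta_nofield)
  expect_identical(issues$field, "polarity")

  expect_error(validate_metadata("XRF", meta_lc), "unknown technique")
})

test_that("register_spectrum normalizes peaks, computes SPLASH and links compounds", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "L-tryptophan",
    inchi = "InChI=1S/C11H12N2O2/synthetic-fixture",
    inchikey = "TRYPTOPHANESYN-SYNTHKEYSA-N",
    formula = "C11H12N2O2"))
  peaks <- data.frame(mz = c(227.079097, 205.097155, 187.086590),
                      intensity = c(120, 999, 80),
                      annotation = c("[M+Na]+", "[M+H]+", "[M+H-H2O]+"))
  card <- register_spectrum(store, valid_lcms_draft(store, comp$pf_id, peaks))

  expect_identical(card$pf_id, "PFs000001")
  expect_true(startsWith(card$splash, "splash10-"))
  expect_identical(card$splash, compute_splash(card$peaks))
  # sorted by m/z; relative intensities 0..999 with base peak 999
  expect_identical(card$peaks$mz, sort(peaks$mz))
  expect_identical(max(card$peaks$relative_intensity), 999L)
  # single linked compound: theoretical m/z and ppm auto-filled
  i <- which(card$peaks$annotation == "[M+H]+")
  expect_equal(card$peaks$theoretical_mz[i],
               theoretical_mz("C11H12N2O2", "[M+H]+"), tolerance = 1e-10)
  expect_lt(abs(card$peaks$ppm[i]), 0.01)
  # re-read card recomputes to the same SPLASH
  expect_identical(compute_splash(get_spectrum(store, card$pf_id)$peaks),
                   card$splash)
})

test_that("register_spectrum rejects invalid drafts with precise reasons", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "x", inchi = "InChI=1S/C6H12O6/synthetic-fixture",
    inchikey = "AAAAAAAAAAAAAA-SYNTHKEYSA-N"))

  d <- valid_lcms_draft(store, comp$pf_id)
  d$technique <- "NMR-1D-1H" # LC metadata on an NMR technique
  err <- tryCatch(register_spectrum(store, d), error = function(e) conditionMessage(e))
  expect_match(err, "nmr_instrument")

  d <- valid_lcms_draft(store, comp$pf_id)
  d$compound_links <- list()
  expect_error(register_spectrum(store, d), "at least one compound")

  d <- valid_lcms_draft(store, comp$pf_id)
  d$compound_links <- list(list(compound = "PFc999999"))
  expect_error(register_spectrum(store, d), "dangling")

  d <- valid_lcms_draft(store, comp$pf_id)
  d$sample_type <- "mystery"
  expect_error(register_spectrum(store, d), "sample_type")

  d <- valid_lcms_draft(store, comp$pf_id)
  d$peaks <- NULL
  expect_error(register_spectrum(store, d), "at least one peak")
})

test_that("relative intensities are scale-invariant", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "x", inchi = "InChI=1S/C6H12O6/synthetic-fixture",
    inchikey = "AAAAAAAAAAAAAA-SYNTHKEYSA-N"))
  set.seed(77)
  base <- data.frame(mz = sort(runif(8, 100, 900)), intensity = rlnorm(8, 6, 1))
  ref <- register_spectrum(store, valid_lcms_draft(store, comp$pf_id, base))
  for (k in c(0.001, 3, 1e5)) {
    scaled <- base
    scaled$intensity <- scaled$intensity * k
    card <- register_spectrum(store, valid_lcms_draft(store, comp$pf_id, scaled))
    expect_identical(card$peaks$relative_intensity, ref$peaks$relative_intensity)
  }
})

test_that("1D NMR drafts validate shifts and multiplicities", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "x", inchi = "InChI=1S/C6H12O6/synthetic-fixture",
    inchikey = "AAAAAAAAAAAAAA-SYNTHKEYSA-N"))
  draft <- list(
    technique = "NMR-1D-1H", sample_type = "chemical_standard",
    compound_links = list(list(compound = comp$pf_id)),
    metadata = list(sample = list(label = "s"),
                    nmr_instrument = list(field_mhz = 600, pulse_sequence = "zg30")),
    peaks = data.frame(shift_ppm = c(7.2, 3.1, 1.4),
                       intensity = c(10, 30, 22),
                       multiplicity = c("d", "m", "t")))
  card <- register_spectrum(store, draft)
  expect_identical(card$peaks$shift_ppm, sort(draft$peaks$shift_ppm))
  expect_null(card$splash) # no SPLASH for NMR

  draft$peaks$multiplicity <- c("d", "zz", "t")
  expect_error(register_spectrum(store, draft), "multiplicity")
})

test_that("peak annotation auto-fills only for unambiguous compound links", {
  store <- new_store()
  a <- register_compound(store, list(
    common_name = "hypaphorine", inchi = "InChI=1S/C14H18N2O2/synthetic-fixture",
    inchikey = "HYPAPHORINESYN-SYNTHKEYSA-N", formula = "C14H18N2O2"))
  b <- register_compound(store, list(
    common_name = "other", inchi = "InChI=1S/C6H12O6/synthetic-fixture",
    inchikey = "AAAAAAAAAAAAAA-SYNTHKEYSA-N"))

  peaks <- data.frame(mz = c(247.1453, 188.070), intensity = c(999, 50))
  card <- register_spectrum(store, valid_lcms_draft(store, a$pf_id, peaks))
  card <- annotate_peak(store, card$pf_id, 2, "[M+H]+", actor = "user")
  expect_equal(card$peaks$theoretical_mz[2], 247.14410, tolerance = 1e-5)
  expect_equal(card$peaks$ppm[2],
               ppm_error(card$peaks$mz[2], card$peaks$theoretical_mz[2]),
               tolerance = 1e-9)

  # two linked compounds: annotation stored verbatim, no auto-fill
  d <- valid_lcms_draft(store, a$pf_id, peaks)
  d$sample_type <- "standard_mix"
  d$compound_links <- list(list(compound = a$pf_id), list(compound = b$pf_id))
  mix <- register_spectrum(store, d)
  mix <- annotate_peak(store, mix$pf_id, 2, "[M+H]+", actor = "user")
  expect_identical(mix$peaks$annotation[2], "[M+H]+")
  expect_true(is.na(mix$peaks$theoretical_mz[2]))

  expect_error(annotate_peak(store, card$pf_id, 99, "[M+H]+", "user"),
               "out of range")
  expect_error(annotate_peak(store, card$pf_id, 1, "junk", "user"), "cannot parse")
  expect_error(annotate_peak(store, card$pf_id, 1, "[M+H]+", "stranger"),
               class = "pb_permission_error")
})

test_that("MSI levels are recorded per compound link with audit", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "hypaphorine", inchi = "InChI=1S/C14H18N2O2/synthetic-fixture",
    inchikey = "HYPAPHORINESYN-SYNTHKEYSA-N", formula = "C14H18N2O2"))
  d <- valid_lcms_draft(store, comp$pf_id)
  d$sample_type <- "biological_matrix"
  card <- register_spectrum(store, d)

  # putative annotation by spectral match, later confirmed with a standard
  card <- set_msi_level(store, card$pf_id, comp$pf_id, 2, actor = "curator")
  expect_identical(card$compound_links[[1]]$msi_level, 2L)
  card <- set_msi_level(store, card$pf_id, comp$pf_id, 1, actor = "curator")
  expect_identical(card$compound_links[[1]]$msi_level, 1L)

  expect_error(set_msi_level(store, card$pf_id, comp$pf_id, 7, "curator"), "1..4")
  expect_error(set_msi_level(store, card$pf_id, comp$pf_id, 2, "user"),
               class = "pb_permission_error")
  log <- audit_log(store)
  expect_identical(sum(log$action == "set_msi_level"), 2L)
})
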