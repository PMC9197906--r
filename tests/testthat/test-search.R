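test_that("quick search ranks id > key > primary name > synonym > mass", {
  store <- make_fixture_store(10, 8, seed = 15)
  comp <- store$compounds[["PFc000002"]] # fixed L-tryptophan anchor row

  hits <- quick_search(store, comp$pf_id)
  expect_identical(hits$pf_id[1], comp$pf_id)
  expect_identical(hits$match[1], "exact_id")

  hits <- quick_search(store, comp$inchikey)
  expect_identical(hits$match[1], "exact_inchikey")

  hits <- quick_search(store, "tryptoph")
  expect_true(comp$pf_id %in% hits$pf_id)
  expect_identical(hits$match[hits$pf_id == comp$pf_id], "primary_name")

  hits <- quick_search(store, "Trp") # synonym only
  expect_identical(hits$match[hits$pf_id == comp$pf_id], "synonym")

  hits <- quick_search(store, "204.0899")
  expect_true(comp$pf_id %in% hits$pf_id)
  expect_true(all(abs(vapply(hits$pf_id, function(id) {
    store$compounds[[id]]$monoisotopic_mass
  }, numeric(1)) - 204.0899) <= 0.01))

  expect_identical(nrow(quick_search(store, "zzz-no-such-thing")), 0L)
  expect_error(quick_search(store, ""), "non-empty")
})

test_that("quick search result set equals the brute-force scan", {
  store <- make_fixture_store(15, 12, seed = 21)
  queries <- c("PFc000003", "PFs000005", "fixturine", "syn-00", "lenticin",
               store$compounds[["PFc000004"]]$inchikey,
               as.character(round(store$compounds[["PFc000005"]]$monoisotopic_mass, 4)),
               "204.0899", "nonexistent-xyz")
  for (q in queries) {
    got <- quick_search(store, q)
    expect_identical(sort(unique(got$pf_id)), oracle_quick(store, q), label = q)
  }
})

test_that("advanced search equals predicate-logic brute force on random trees", {
  store <- make_fixture_store(15, 20, seed = 33)
  random_expr <- function(depth = 2) {
    if (depth == 0 || runif(1) < 0.4) {
      k <- sample(7, 1)
      return(switch(k,
        flt_name_contains(sample(c("fixturine", "syn", "tryp", "zz"), 1)),
        flt_mass_between(runif(1, 50, 300), runif(1, 300, 700)),
        flt_technique_is(sample(techniques(), 1)),
        flt_polarity_is(sample(c("+", "-"), 1)),
        flt_column_name_contains(sample(c("c18", "hilic", "db-5"), 1)),
        flt_formula_is(store$compounds[[sample(length(store$compounds), 1)]]$formula),
        flt_pf_id_is(sample(c(names(store$compounds), names(store$spectra)), 1))))
    }
    op <- if (runif(1) < 0.5) flt_and else flt_or
    do.call(op, lapply(seq_len(sample(2:3, 1)), function(i) random_expr(depth - 1)))
  }
  set.seed(44)
  for (i in 1:40) {
    expr <- random_expr()
    expect_identical(advanced_search(store, expr), oracle_advanced(store, expr))
  }
  # identity of conjunction: empty AND matches every card
  expect_identical(advanced_search(store, flt_and()),
                   sort(c(names(store$compounds), names(store$spectra))))
  # disjoint OR is the union
  u <- advanced_search(store, flt_or(flt_name_contains("tryptophan"),
                                     flt_name_contains("hypaphorine")))
  expect_identical(u, sort(union(
    advanced_search(store, flt_name_contains("tryptophan")),
    advanced_search(store, flt_name_contains("hypaphorine")))))
})

test_that("filter expressions round-trip through JSON", {
  expr <- flt_and(flt_technique_is("LC-MS"),
                  flt_or(flt_name_contains("tryp"), flt_mass_between(100, 300)))
  back <- filter_from_json(filter_to_json(expr))
  store <- make_fixture_store(8, 10, seed = 5)
  expect_identical(advanced_search(store, back), advanced_search(store, expr))
  expect_error(filter_from_json('{"foo": 1}'), "malformed")
})

test_that("m/z search honours unit, boundary inclusion and ordering", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "hypaphorine", inchi = "InChI=1S/C14H18N2O2/synthetic-fixture",
    inchikey = "HYPAPHORINESYN-SYNTHKEYSA-N", formula = "C14H18N2O2"))
  peaks <- data.frame(mz = c(247.1453, 247.1441, 250.0000),
                      intensity = c(10, 999, 5))
  register_spectrum(store, valid_lcms_draft(store, comp$pf_id, peaks))

  # 247.1453 sits 4.855 ppm from the 247.1441 target
  res5 <- search_peaks_mz(store, 247.1441, mass_tolerance(5, "ppm"))
  expect_identical(nrow(res5), 2L)
  expect_identical(res5$mz[1], 247.1441) # sorted by |delta|
  res3 <- search_peaks_mz(store, 247.1441, mass_tolerance(3, "ppm"))
  expect_identical(res3$mz, 247.1441)

  # boundary inclusive in Da: peak exactly at target + tol is returned
  res_da <- search_peaks_mz(store, 247.1441, mass_tolerance(0.0012, "Da"))
  expect_true(247.1453 %in% res_da$mz)

  expect_error(search_peaks_mz(store, -5, mass_tolerance(5, "ppm")), "positive")
})

test_that("shift search windows 1D and 2D peaks with dimension control", {
  store <- new_store()
  comp <- register_compound(store, list(
    common_name = "x", inchi = "InChI=1S/C6H12O6/synthetic-fixture",
    inchikey = "AAAAAAAAAAAAAA-SYNTHKEYSA-N"))
  nmr_meta <- list(sample = list(label = "s"),
                   nmr_instrument = list(field_mhz = 600, pulse_sequence = "zg30"))
  register_spectrum(store, list(
    technique = "NMR-1D-1H", sample_type = "chemical_standard",
    compound_links = list(list(compound = comp$pf_id)), metadata = nmr_meta,
    peaks = data.frame(shift_ppm = c(3.100, 3.130, 7.000))))
  register_spectrum(store, list(
    technique = "NMR-2D-HSQC", sample_type = "chemical_standard",
    compound_links = list(list(compound = comp$pf_id)), metadata = nmr_meta,
    peaks = data.frame(shift_f1_ppm = c(35.0, 120.0), shift_f2_ppm = c(3.1, 7.2))))

  res <- search_peaks_shift(store, 3.1, 0.02)
  expect_identical(res$delta[1], 0) # exact hit first
  expect_true(all(abs(res$delta) <= 0.02))
  expect_false(any(res$shift == 3.130)) # 0.03 away -> excluded
  expect_true("f2" %in% res$dimension)  # 2D matched on F2

  # pinning the dimension to F1 removes the F2-only hit
  res_f1 <- search_peaks_shift(store, 3.1, 0.02, dimension = "f1")
  expect_identical(nrow(res_f1), 0L)
  res_f1b <- search_peaks_shift(store, 35.0, 0.02, dimension = "f1")
  expect_identical(res_f1b$dimension, "f1")

  expect_error(search_peaks_shift(store, 3.1, 0), "positive")
})

test_that("peak searches are monotone in tolerance", {
  store <- make_fixture_store(10, 25, seed = 61, noise_ppm = 2)
  set.seed(62)
  for (i in 1:10) {
    target <- runif(1, 100, 600)
    t1 <- runif(1, 1, 20); t2 <- t1 + runif(1, 0, 30)
    r1 <- search_peaks_mz(store, target, mass_tolerance(t1, "ppm"))
    r2 <- search_peaks_mz(store, target, mass_tolerance(t2, "ppm"))
    expect_true(all(paste(r1$pf_id, r1$peak) %in% paste(r2$pf_id, r2$peak)))

    s <- runif(1, 0, 10)
    w1 <- runif(1, 0.005, 0.05); w2 <- w1 + runif(1, 0, 0.2)
    q1 <- search_peaks_shift(store, s, w1)
    q2 <- search_peaks_shift(store, s, w2)
    expect_true(all(paste(q1$pf_id, q1$peak, q1$dimension) %in%
                      paste(q2$pf_id, q2$peak, q2$dimension)))
  }
})
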