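trp_draft <- function(...) {
  utils::modifyList(list(
    common_name = "L-tryptophan",
    inchi = "InChI=1S/C11H12N2O2/synthetic-fixture",
    inchikey = "TRYPTOPHANESYN-SYNTHKEYSA-N",
    synonyms = c("tryptophan", "Trp"),
    formula = "C11H12N2O2",
    cross_refs = c(chebi = "CHEBI:16828")
  ), list(...))
}

test_that("registering a new compound builds a complete card", {
  store <- new_store()
  card <- register_compound(store, trp_draft())
  expect_identical(card$pf_id, "PFc000001")
  expect_identical(card$stars, 1L)
  expect_identical(card$formula, "C11H12N2O2")
  expect_equal(card$monoisotopic_mass, 204.0899, tolerance = 1e-6)
  expect_equal(card$average_mass, 204.23, tolerance = 1e-4)
  expect_identical(compound_primary_name(card), "L-tryptophan")
  expect_setequal(compound_names(card)$text, c("L-tryptophan", "tryptophan", "Trp"))
  # provider stub fills unknowns offline
  expect_identical(card$endogenous_flag, "unknown")
  expect_true(is.na(card$logp))
})

test_that("mandatory trio and key validity are enforced", {
  store <- new_store()
  expect_error(register_compound(store, trp_draft(inchi = NULL)), "inchi")
  expect_error(register_compound(store, trp_draft(common_name = NULL)), "common_name")
  expect_error(register_compound(store, trp_draft(inchikey = NULL)), "inchikey")
  expect_error(register_compound(store, trp_draft(inchikey = "not-a-key")),
               class = "pb_inchikey_error")
  expect_length(store$compounds, 0)
})

test_that("formula falls back to the InChI formula layer", {
  store <- new_store()
  card <- register_compound(store, trp_draft(formula = NULL))
  expect_identical(card$formula, "C11H12N2O2")
  expect_equal(card$monoisotopic_mass, monoisotopic_mass("C11H12N2O2"))
})

test_that("re-registering an InChIKey merges instead of duplicating", {
  store <- new_store()
  first <- register_compound(store, trp_draft())
  again <- register_compound(store, trp_draft(common_name = "tryptophane",
                                              synonyms = "W"))
  expect_identical(again$pf_id, first$pf_id)
  expect_length(store$compounds, 1)
  nm <- compound_names(again)
  # new names arrive as score-0 synonyms; primary unchanged
  expect_identical(compound_primary_name(again), "L-tryptophan")
  expect_true(all(c("tryptophane", "W") %in% nm$text))
  expect_true(all(nm$score[nm$text %in% c("tryptophane", "W")] == 0L))
})

test_that("merge never touches stored masses, structure or id, and flags id conflicts", {
  store <- new_store()
  card <- register_compound(store, trp_draft())
  res <- merge_compound(store, card$pf_id, list(
    common_name = "conflicting import",
    cross_refs = c(chebi = "CHEBI:99999", kegg = "C00078")
  ))
  merged <- res$card
  expect_identical(merged$pf_id, card$pf_id)
  expect_identical(merged$inchi, card$inchi)
  expect_identical(merged$formula, card$formula)
  expect_identical(merged$monoisotopic_mass, card$monoisotopic_mass)
  # stored chebi untouched, one conflict message; absent kegg adopted silently
  expect_identical(unname(merged$cross_refs["chebi"]), "CHEBI:16828")
  expect_identical(unname(merged$cross_refs["kegg"]), "C00078")
  expect_length(res$messages, 1)
  expect_identical(res$messages[[1]]$kind, "EXTERNAL_ID_CONFLICT")
  expect_match(res$messages[[1]]$text, "CHEBI:99999")
  expect_match(res$messages[[1]]$text, "CHEBI:16828")

  # identical re-import: no change, no messages
  res2 <- merge_compound(store, card$pf_id, trp_draft())
  expect_length(res2$messages, 0)
  expect_identical(compound_names(res2$card), compound_names(merged))
})

test_that("batch import reports created/merged/rejected per independent row", {
  store <- new_store()
  batch <- generate_compounds(5, seed = 3)
  batch <- rbind(batch, batch[3, ]) # duplicate inchikey -> merged
  batch$inchikey[2] <- ""           # missing mandatory -> rejected
  report <- batch_import_compounds(store, batch)
  expect_identical(unname(report$counts), c(4L, 1L, 1L))
  expect_identical(report$rows$outcome,
                   c("created", "rejected", "created", "created", "created", "merged"))
  expect_match(report$rows$reason[2], "inchikey")
  expect_length(store$compounds, 4)
})

test_that("import order never changes the deduplicated card set", {
  batch <- generate_compounds(6, seed = 8, with_duplicates = 3)
  reference <- NULL
  for (rep in 1:25) {
    store <- new_store()
    perm <- batch[sample(nrow(batch)), , drop = FALSE]
    batch_import_compounds(store, perm)
    keys <- vapply(store$compounds, `[[`, character(1), "inchikey")
    expect_identical(anyDuplicated(keys), 0L)
    name_sets <- lapply(store$compounds, function(c1) sort(compound_names(c1)$text))
    names(name_sets) <- keys
    name_sets <- name_sets[order(names(name_sets))]
    if (is.null(reference)) reference <- name_sets
    expect_identical(name_sets, reference)
  }
})

test_that("name scoring and promotion keep the primary at maximal score", {
  store <- new_store()
  card <- register_compound(store, trp_draft())
  card <- set_name_score(store, card$pf_id, "tryptophan", 9, actor = "curator")
  expect_identical(compound_primary_name(card), "tryptophan")
  nm <- compound_names(card)
  expect_identical(nm$score[nm$is_primary], 9L)

  expect_error(set_name_score(store, card$pf_id, "tryptophan", 11, "curator"),
               "0..10")
  expect_error(set_name_score(store, card$pf_id, "nope", 5, "curator"), "not on card")
  expect_error(set_name_score(store, card$pf_id, "Trp", 5, "user"),
               class = "pb_permission_error")

  card <- promote_primary(store, card$pf_id, "Trp", actor = "curator")
  expect_identical(compound_primary_name(card), "Trp")
  nm <- compound_names(card)
  expect_gte(nm$score[nm$text == "Trp"], max(nm$score))
})

test_that("star grading is range- and role-checked and audited", {
  store <- new_store()
  card <- register_compound(store, trp_draft())
  card <- set_stars(store, card$pf_id, 5, actor = "curator")
  expect_identical(card$stars, 5L)
  expect_error(set_stars(store, card$pf_id, 0, "curator"), "1..5")
  expect_error(set_stars(store, card$pf_id, 3, "user"),
               class = "pb_permission_error")
  set_stars(store, card$pf_id, 2, actor = "admin")
  log <- audit_log(store)
  star_rows <- log[log$action == "set_stars", ]
  expect_identical(nrow(star_rows), 2L) # only successful transitions audited
  expect_identical(star_rows$to, c("5", "2"))
})

test_that("publications attach idempotently with shape validation", {
  store <- new_store()
  card <- register_compound(store, trp_draft())
  card <- attach_publication(store, card$pf_id, "DOI", "10.1000/xyz")
  card <- attach_publication(store, card$pf_id, "DOI", "10.1000/xyz")
  card <- attach_publication(store, card$pf_id, "PMID", "123456")
  expect_length(card$publications, 2)
  expect_error(attach_publication(store, card$pf_id, "PMID", "abc"), "malformed")
  expect_error(attach_publication(store, card$pf_id, "DOI", "doi:10/xyz"), "malformed")
})
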