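# Independent brute-force oracles for the search engine. Deliberately naive
# (per-card loops over public accessors) and kept separate from the engine
# implementations they check.

oracle_search_mz <- function(store, target, tol_value, tol_unit) {
  hits <- list()
  for (id in names(store$spectra)) {
    card <- get_spectrum(store, id)
    if (!card$technique %in% c("LC-MS", "LC-MSMS", "FIA-MS", "FIA-MSMS",
                               "GC-MS", "IC-MS")) next
    for (i in seq_len(nrow(card$peaks))) {
      mz <- card$peaks$mz[i]
      inside <- if (tol_unit == "Da") {
        abs(mz - target) <= tol_value
      } else {
        abs((mz - target) / target * 1e6) <= tol_value
      }
      if (inside) hits[[length(hits) + 1L]] <- c(id, i)
    }
  }
  hits
}

oracle_search_shift <- function(store, target, window, dimension = "any") {
  hits <- list()
  for (id in names(store$spectra)) {
    card <- get_spectrum(store, id)
    if (card$technique %in% c("NMR-1D-1H", "NMR-1D-13C")) {
      if (dimension != "any") next
      for (i in seq_len(nrow(card$peaks))) {
        if (abs(card$peaks$shift_ppm[i] - target) <= window) {
          hits[[length(hits) + 1L]] <- c(id, i, "1d")
        }
      }
    } else if (startsWith(card$technique, "NMR-2D-")) {
      for (i in seq_len(nrow(card$peaks))) {
        if (dimension %in% c("any", "f1") &&
            abs(card$peaks$shift_f1_ppm[i] - target) <= window) {
          hits[[length(hits) + 1L]] <- c(id, i, "f1")
        }
        if (dimension %in% c("any", "f2") &&
            abs(card$peaks$shift_f2_ppm[i] - target) <= window) {
          hits[[length(hits) + 1L]] <- c(id, i, "f2")
        }
      }
    }
  }
  hits
}

# recursive predicate evaluation, written independently of the engine
oracle_filter <- function(store, expr, id) {
  comp <- store$compounds[[id]]
  spec <- store$spectra[[id]]
  if (expr$node == "and") {
    return(all(vapply(expr$children, function(ch) oracle_filter(store, ch, id),
                      logical(1))))
  }
  if (expr$node == "or") {
    return(any(vapply(expr$children, function(ch) oracle_filter(store, ch, id),
                      logical(1))))
  }
  a <- expr$args
  if (expr$pred == "pf_id_is") return(id == a$value)
  if (expr$pred == "name_contains") {
    if (is.null(comp)) return(FALSE)
    texts <- tolower(compound_names(comp)$text)
    return(any(grepl(tolower(a$value), texts, fixed = TRUE)))
  }
  if (expr$pred == "inchikey_is") return(!is.null(comp) && comp$inchikey == a$value)
  if (expr$pred == "formula_is") return(!is.null(comp) && comp$formula == a$value)
  if (expr$pred == "mass_between") {
    return(!is.null(comp) && comp$monoisotopic_mass >= a$lo &&
             comp$monoisotopic_mass <= a$hi)
  }
  if (expr$pred == "technique_is") return(!is.null(spec) && spec$technique == a$value)
  if (expr$pred == "polarity_is") {
    if (is.null(spec)) return(FALSE)
    pol <- spec$metadata$ionization_method$polarity
    return(!is.null(pol) && as.character(pol) == a$value)
  }
  if (expr$pred == "column_name_contains") {
    if (is.null(spec)) return(FALSE)
    for (g in c("liquid_chromatography", "gas_chromatography", "ion_chromatography")) {
      cn <- spec$metadata[[g]]$column_name
      if (!is.null(cn) && grepl(tolower(a$value), tolower(cn), fixed = TRUE)) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  if (expr$pred == "retention_time_between") {
    if (is.null(spec)) return(FALSE)
    for (g in c("liquid_chromatography", "gas_chromatography", "ion_chromatography")) {
      rt <- spec$metadata[[g]]$retention_time_min
      if (!is.null(rt) && as.numeric(rt) >= a$lo && as.numeric(rt) <= a$hi) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  stop("oracle: unknown predicate ", expr$pred)
}

oracle_advanced <- function(store, expr) {
  ids <- c(names(store$compounds), names(store$spectra))
  sort(ids[vapply(ids, function(id) oracle_filter(store, expr, id), logical(1))])
}

oracle_quick <- function(store, query, mass_window = 0.01) {
  found <- character(0)
  for (id in c(names(store$compounds), names(store$spectra))) {
    if (id == query) found <- c(found, id)
  }
  for (id in names(store$compounds)) {
    comp <- store$compounds[[id]]
    if (comp$inchikey == query) found <- c(found, id)
    texts <- tolower(compound_names(comp)$text)
    if (any(grepl(tolower(query), texts, fixed = TRUE))) found <- c(found, id)
  }
  qn <- suppressWarnings(as.numeric(query))
  if (!is.na(qn)) {
    for (id in names(store$compounds)) {
      if (abs(store$compounds[[id]]$monoisotopic_mass - qn) <= mass_window) {
        found <- c(found, id)
      }
    }
  }
  sort(unique(found))
}

# small populated store used across suites
make_fixture_store <- function(n_compounds = 12, n_spectra = 15, seed = 99,
                               noise_ppm = 0) {
  store <- new_store()
  comp <- generate_compounds(n_compounds, seed = seed)
  batch_import_compounds(store, comp)
  drafts <- generate_spectra(comp, m = n_spectra, seed = seed + 1,
                             noise_ppm = noise_ppm)
  for (d in drafts) register_spectrum(store, d)
  store
}

valid_lcms_draft <- function(store, compound_id, peaks = NULL) {
  if (is.null(peaks)) {
    peaks <- data.frame(mz = c(205.097155, 227.079097, 187.086590),
                        intensity = c(999, 120, 80),
                        annotation = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+"))
  }
  list(
    technique = "LC-MS",
    sample_type = "chemical_standard",
    compound_links = list(list(compound = compound_id)),
    metadata = list(
      sample = list(label = "test standard"),
      liquid_chromatography = list(column_name = "C18 100x2.1",
                                   flow_rate = "0.3 mL/min"),
      ionization_method = list(ionization = "ESI", polarity = "+"),
      ion_analyzer = list(instrument = "QTOF-sim")
    ),
    peaks = peaks
  )
}
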