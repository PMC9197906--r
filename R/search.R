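#' Quick search over compounds and spectra
#'
#' Single-box search in the style of a database landing page. The query is
#' matched, in decreasing rank, as: exact internal pf_id; exact InChIKey;
#' case-insensitive substring of a primary compound name; substring of a
#' synonym; and, when the query parses as a number, monoisotopic mass
#' within a +/- `mass_window` Da window.
#'
#' @param store A `pb_store`.
#' @param query Non-empty query string.
#' @param mass_window Half-width in Da of the numeric-query mass window.
#' @return Data frame of hits with `kind` ("compound"/"spectrum"), `pf_id`,
#'   `label`, `match` (match type) and `rank`, ordered by rank; zero rows
#'   when nothing matches.
#' @export
quick_search <- function(store, query, mass_window = 0.01) {
  .pb_check_store(store)
  if (!is.character(query) || length(query) != 1 || is.na(query) || !nzchar(query)) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  hits <- list()
  add <- function(kind, pf_id, label, match, rank) {
    hits[[length(hits) + 1L]] <<- data.frame(
      kind = kind, pf_id = pf_id, label = label, match = match, rank = rank,
      stringsAsFactors = FALSE)
  }

  if (query %in% names(store$compounds)) {
    add("compound", query, compound_primary_name(store$compounds[[query]]),
        "exact_id", 1L)
  }
  if (query %in% names(store$spectra)) {
    add("spectrum", query, store$spectra[[query]]$technique, "exact_id", 1L)
  }
  if (query %in% names(store$inchikey_index)) {
    pf <- store$inchikey_index[[query]]
    add("compound", pf, compound_primary_name(store$compounds[[pf]]),
        "exact_inchikey", 2L)
  }

  q_lower <- tolower(query)
  for (card in store$compounds) {
    nm <- compound_names(card)
    primary_hit <- any(nm$is_primary & grepl(q_lower, tolower(nm$text), fixed = TRUE))
    synonym_hit <- any(!nm$is_primary & grepl(q_lower, tolower(nm$text), fixed = TRUE))
    if (primary_hit) {
      add("compound", card$pf_id, compound_primary_name(card), "primary_name", 3L)
    } else if (synonym_hit) {
      add("compound", card$pf_id, compound_primary_name(card), "synonym", 4L)
    }
  }

  q_num <- suppressWarnings(as.numeric(query))
  if (!is.na(q_num)) {
    for (card in store$compounds) {
      if (abs(card$monoisotopic_mass - q_num) <= mass_window) {
        add("compound", card$pf_id, compound_primary_name(card), "mass_window", 5L)
      }
    }
  }

  if (length(hits) == 0) {
    return(data.frame(kind = character(0), pf_id = character(0),
                      label = character(0), match = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # one row per card at its best rank
  out <- out[order(out$rank, out$pf_id), , drop = FALSE]
  out <- out[!duplicated(paste(out$kind, out$pf_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter-expression constructors
#'
#' Build AND/OR filter trees for [advanced_search()]. Atomic predicates:
#' `name_contains`, `inchikey_is`, `formula_is`, `mass_between`,
#' `pf_id_is` (compound attributes; compound cards only),
#' `technique_is`, `polarity_is`, `column_name_contains`,
#' `retention_time_between` (spectrum attributes; spectrum cards only,
#' except `pf_id_is` which matches both kinds). A predicate evaluated on a
#' card that lacks the attribute is false for that card; `flt_and()` with
#' no arguments matches every card.
#'
#' @param ... Child expressions (for `flt_and`/`flt_or`) .
#' @param value,lo,hi Predicate arguments.
#' @return A filter expression (nested list, JSON-serializable).
#' @name filter-expressions
NULL

#' @rdname filter-expressions
#' @export
flt_and <- function(...) structure(list(node = "and", children = list(...)),
                                   class = "pb_filter")

#' @rdname filter-expressions
#' @export
flt_or <- function(...) structure(list(node = "or", children = list(...)),
                                  class = "pb_filter")

.pb_pred <- function(pred, ...) {
  structure(list(node = "pred", pred = pred, args = list(...)),
            class = "pb_filter")
}

#' @rdname filter-expressions
#' @export
flt_name_contains <- function(value) .pb_pred("name_contains", value = value)

#' @rdname filter-expressions
#' @export
flt_inchikey_is <- function(value) .pb_pred("inchikey_is", value = value)

#' @rdname filter-expressions
#' @export
flt_formula_is <- function(value) .pb_pred("formula_is", value = value)

#' @rdname filter-expressions
#' @export
flt_mass_between <- function(lo, hi) .pb_pred("mass_between", lo = lo, hi = hi)

#' @rdname filter-expressions
#' @export
flt_technique_is <- function(value) .pb_pred("technique_is", value = value)

#' @rdname filter-expressions
#' @export
flt_polarity_is <- function(value) .pb_pred("polarity_is", value = value)

#' @rdname filter-expressions
#' @export
flt_column_name_contains <- function(value) .pb_pred("column_name_contains", value = value)

#' @rdname filter-expressions
#' @export
flt_retention_time_between <- function(lo, hi) .pb_pred("retention_time_between", lo = lo, hi = hi)

#' @rdname filter-expressions
#' @export
flt_pf_id_is <- function(value) .pb_pred("pf_id_is", value = value)

#' Serialize / deserialize a filter expression to JSON
#'
#' @param expr A filter expression.
#' @return `filter_to_json`: a JSON string; `filter_from_json`: the
#'   expression.
#' @export
filter_to_json <- function(expr) {
  stopifnot(inherits(expr, "pb_filter"))
  jsonlite::toJSON(unclass(.pb_filter_plain(expr)), auto_unbox = TRUE, digits = NA)
}

.pb_filter_plain <- function(expr) {
  if (expr$node == "pred") {
    list(node = "pred", pred = expr$pred, args = expr$args)
  } else {
    list(node = expr$node, children = lapply(expr$children, .pb_filter_plain))
  }
}

#' @rdname filter_to_json
#' @param json JSON produced by `filter_to_json`.
#' @export
filter_from_json <- function(json) {
  .pb_filter_from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

.pb_filter_from_list <- function(x) {
  if (is.null(x$node)) stop("malformed filter JSON", call. = FALSE)
  if (x$node == "pred") {
    structure(list(node = "pred", pred = x$pred, args = x$args),
              class = "pb_filter")
  } else if (x$node %in% c("and", "or")) {
    structure(list(node = x$node,
                   children = lapply(x$children, .pb_filter_from_list)),
              class = "pb_filter")
  } else {
    stop("malformed filter JSON: unknown node ", x$node, call. = FALSE)
  }
}

#' Advanced search with AND/OR filters
#'
#' Evaluates a filter tree over every card (compounds and spectra) in the
#' store. The contract is plain predicate logic: the result set is exactly
#' the set of cards on which the expression evaluates true.
#'
#' @param store A `pb_store`.
#' @param expr Filter expression from the `flt_*` constructors or
#'   [filter_from_json()].
#' @return Sorted character vector of matching pf_ids.
#' @export
advanced_search <- function(store, expr) {
  .pb_check_store(store)
  if (!inherits(expr, "pb_filter")) stop("not a filter expression", call. = FALSE)
  ids <- c(names(store$compounds), names(store$spectra))
  keep <- vapply(ids, function(id) .pb_eval_filter(store, expr, id), logical(1))
  sort(ids[keep])
}

.pb_eval_filter <- function(store, expr, pf_id) {
  if (expr$node == "and") {
    for (child in expr$children) {
      if (!.pb_eval_filter(store, child, pf_id)) return(FALSE)
    }
    return(TRUE)
  }
  if (expr$node == "or") {
    for (child in expr$children) {
      if (.pb_eval_filter(store, child, pf_id)) return(TRUE)
    }
    return(FALSE)
  }
  .pb_eval_pred(store, expr$pred, expr$args, pf_id)
}

.pb_eval_pred <- function(store, pred, args, pf_id) {
  compound <- store$compounds[[pf_id]]
  spectrum <- store$spectra[[pf_id]]
  switch(pred,
    pf_id_is = identical(pf_id, args$value),
    name_contains = {
      if (is.null(compound)) return(FALSE)
      any(grepl(tolower(args$value),
                tolower(vapply(compound$names, `[[`, character(1), "text")),
                fixed = TRUE))
    },
    inchikey_is = !is.null(compound) && identical(compound$inchikey, args$value),
    formula_is = !is.null(compound) &&
      identical(compound$formula, format_formula(args$value)),
    mass_between = !is.null(compound) &&
      compound$monoisotopic_mass >= args$lo &&
      compound$monoisotopic_mass <= args$hi,
    technique_is = !is.null(spectrum) && identical(spectrum$technique, args$value),
    polarity_is = {
      if (is.null(spectrum)) return(FALSE)
      pol <- spectrum$metadata$ionization_method$polarity
      !is.null(pol) && identical(as.character(pol), args$value)
    },
    column_name_contains = {
      if (is.null(spectrum)) return(FALSE)
      cols <- unlist(lapply(c("liquid_chromatography", "gas_chromatography",
                              "ion_chromatography"), function(g) {
        spectrum$metadata[[g]]$column_name
      }))
      length(cols) > 0 &&
        any(grepl(tolower(args$value), tolower(cols), fixed = TRUE))
    },
    retention_time_between = {
      if (is.null(spectrum)) return(FALSE)
      rt <- unlist(lapply(c("liquid_chromatography", "gas_chromatography",
                            "ion_chromatography"), function(g) {
        spectrum$metadata[[g]]$retention_time_min
      }))
      length(rt) > 0 && any(as.numeric(rt) >= args$lo & as.numeric(rt) <= args$hi)
    },
    stop(sprintf("unknown predicate '%s'", pred), call. = FALSE)
  )
}

#' Search MS peaks by m/z with tolerance
#'
#' Finds every peak of every mass spectrum within a tolerance of a target
#' m/z. The boundary is inclusive: a peak exactly at the tolerance limit is
#' returned.
#'
#' @param store A `pb_store`.
#' @param target Target m/z (> 0).
#' @param tolerance A [mass_tolerance()] (ppm or Da).
#' @param techniques_scope Optional character vector restricting the MS
#'   techniques searched.
#' @param polarity Optional `"+"`/`"-"` filter on the ionization polarity
#'   metadata.
#' @return Data frame with `pf_id`, `peak` (row index in the card's peak
#'   table), `mz`, `intensity`, `delta` (observed - target, Da) and `ppm`,
#'   sorted by `abs(delta)`.
#' @export
search_peaks_mz <- function(store, target, tolerance, techniques_scope = NULL,
                            polarity = NULL) {
  .pb_check_store(store)
  if (!is.numeric(target) || length(target) != 1 || is.na(target) || target <= 0) {
    stop("target m/z must be a positive number", call. = FALSE)
  }
  if (!inherits(tolerance, "mass_tolerance")) {
    stop("tolerance must be a mass_tolerance object", call. = FALSE)
  }
  rows <- list()
  for (card in store$spectra) {
    if (!is_ms_technique(card$technique)) next
    if (!is.null(techniques_scope) && !card$technique %in% techniques_scope) next
    if (!is.null(polarity)) {
      pol <- card$metadata$ionization_method$polarity
      if (is.null(pol) || !identical(as.character(pol), polarity)) next
    }
    mz <- card$peaks$mz
    if (length(mz) == 0) next
    delta <- mz - target
    hit <- if (tolerance$unit == "Da") {
      abs(delta) <= tolerance$value
    } else {
      abs(ppm_error(mz, target)) <= tolerance$value
    }
    if (any(hit)) {
      idx <- which(hit)
      rows[[length(rows) + 1L]] <- data.frame(
        pf_id = card$pf_id, peak = idx, mz = mz[idx],
        intensity = card$peaks$intensity[idx],
        delta = delta[idx], ppm = ppm_error(mz[idx], target),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pf_id = character(0), peak = integer(0), mz = numeric(0),
               intensity = numeric(0), delta = numeric(0), ppm = numeric(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(abs(out$delta), out$pf_id, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search NMR peaks by chemical shift
#'
#' Finds 1D peaks (and 2D cross-peak axes) within a shift window of a
#' target chemical shift. For 2D spectra the target is matched on either
#' axis unless `dimension` pins it to F1 or F2. Boundary inclusive.
#'
#' @param store A `pb_store`.
#' @param target Target chemical shift (ppm).
#' @param window Half-width of the search window, in ppm of chemical shift
#'   (> 0).
#' @param techniques_scope Optional character vector restricting the NMR
#'   techniques searched.
#' @param dimension `"any"` (default), `"f1"` or `"f2"`; only meaningful
#'   for 2D experiments.
#' @return Data frame with `pf_id`, `peak`, `shift`, `dimension`
#'   (`"1d"`, `"f1"` or `"f2"`) and `delta`, sorted by `abs(delta)`.
#' @export
search_peaks_shift <- function(store, target, window, techniques_scope = NULL,
                               dimension = c("any", "f1", "f2")) {
  .pb_check_store(store)
  dimension <- match.arg(dimension)
  if (!is.numeric(window) || length(window) != 1 || is.na(window) || window <= 0) {
    stop("shift window must be a positive number of ppm", call. = FALSE)
  }
  rows <- list()
  emit <- function(card, idx, shift, dim) {
    if (length(idx) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      pf_id = card$pf_id, peak = idx, shift = shift[idx], dimension = dim,
      delta = shift[idx] - target, stringsAsFactors = FALSE)
  }
  for (card in store$spectra) {
    if (is_ms_technique(card$technique)) next
    if (!is.null(techniques_scope) && !card$technique %in% techniques_scope) next
    if (is_nmr1d_technique(card$technique)) {
      if (dimension != "any") next # a 1D spectrum has no F1/F2 axes
      shift <- card$peaks$shift_ppm
      emit(card, which(abs(shift - target) <= window), shift, "1d")
    } else {
      if (dimension %in% c("any", "f1")) {
        f1 <- card$peaks$shift_f1_ppm
        emit(card, which(abs(f1 - target) <= window), f1, "f1")
      }
      if (dimension %in% c("any", "f2")) {
        f2 <- card$peaks$shift_f2_ppm
        emit(card, which(abs(f2 - target) <= window), f2, "f2")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pf_id = character(0), peak = integer(0), shift = numeric(0),
               dimension = character(0), delta = numeric(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(abs(out$delta), out$pf_id, out$peak, out$dimension), , drop = FALSE]
  rownames(out) <- NULL
  out
}
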