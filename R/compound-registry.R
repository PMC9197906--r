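#' Register (or merge) a compound
#'
#' Creates a compound card from a draft. The InChIKey is the uniqueness key
#' of the registry: a draft whose InChIKey is already present is not
#' duplicated but merged into the existing card (see [merge_compound()]),
#' mirroring the curation rule that re-imported compounds contribute
#' synonyms but never overwrite stored properties.
#'
#' The mandatory draft fields are `common_name`, `inchi` and `inchikey`
#' (the batch-import trio). Optional fields: `synonyms` (character vector),
#' `formula` (string; derived from the InChI formula layer when absent),
#' `smiles`, `molfile`, `cross_refs` (named character vector with names
#' among `chebi`, `pubchem`, `kegg`, `hmdb`, or arbitrary bank names for
#' modular web links), `publications`, `elucidation`.
#'
#' @param store A `pb_store`.
#' @param draft Named list of compound fields.
#' @param provider Enrichment provider, see [offline_provider()].
#' @return The (new or merged) compound card. Merge-generated curation
#'   messages are posted to the store's message centre.
#' @examples
#' store <- new_store()
#' card <- register_compound(store, list(
#'   common_name = "L-tryptophan",
#'   inchi = "InChI=1S/C11H12N2O2/c12-9(11(14)15)5-7-6-13-10-4-2-1-3-8(7)10/h1-4,6,9,13H,5,12H2,(H,14,15)",
#'   inchikey = "QIVBCDIJIAJPQS-VIFPVBQESA-N"
#' ))
#' card$monoisotopic_mass
#' @export
register_compound <- function(store, draft, provider = offline_provider()) {
  .pb_check_store(store)
  for (f in c("common_name", "inchi", "inchikey")) {
    v <- draft[[f]]
    if (is.null(v) || !is.character(v) || length(v) != 1 || is.na(v) || !nzchar(v)) {
      stop(sprintf("compound draft is missing mandatory field '%s' (common name, InChI and InChIKey are required)", f),
           call. = FALSE)
    }
  }
  key <- validate_inchikey(draft$inchikey)

  if (key %in% names(store$inchikey_index)) {
    existing <- store$compounds[[store$inchikey_index[[key]]]]
    return(merge_compound(store, existing$pf_id, draft)$card)
  }

  comp <- if (!is.null(draft$formula)) {
    as_formula(draft$formula)
  } else {
    .pb_formula_from_inchi(draft$inchi)
  }

  enrich <- provider(draft)
  names_list <- .pb_new_name_list(draft$common_name,
                                  unique(c(draft$synonyms, enrich$synonyms)))

  cross_refs <- .pb_as_cross_refs(draft$cross_refs)
  pubs <- .pb_as_publications(draft$publications)

  card <- structure(list(
    pf_id = .pb_next_id(store, "compound"),
    inchikey = key,
    inchi = draft$inchi,
    names = names_list,
    formula = format_formula(comp),
    monoisotopic_mass = monoisotopic_mass(comp),
    average_mass = average_mass(comp),
    canonical_smiles = draft$smiles,
    molfile = draft$molfile,
    cross_refs = cross_refs,
    publications = pubs,
    stars = 1L,
    elucidation = if (!is.null(draft$elucidation)) {
      match.arg(draft$elucidation, c("fully_identified", "not_fully_elucidated"))
    } else "fully_identified",
    logp = enrich$logp,
    endogenous_flag = enrich$endogenous
  ), class = "compound_card")

  store$compounds[[card$pf_id]] <- card
  store$inchikey_index[[key]] <- card$pf_id
  card
}

.pb_new_name_list <- function(common_name, synonyms) {
  syns <- setdiff(unique(synonyms[!is.na(synonyms) & nzchar(synonyms)]), common_name)
  c(
    list(list(text = common_name, score = 1L, is_primary = TRUE)),
    lapply(syns, function(s) list(text = s, score = 0L, is_primary = FALSE))
  )
}

.pb_as_cross_refs <- function(x) {
  if (is.null(x) || length(x) == 0) return(character(0))
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("cross_refs must be a named vector (bank = identifier)", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("at most one identifier per bank", call. = FALSE)
  }
  stats::setNames(as.character(x), names(x))
}

.pb_as_publications <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(p) {
    stopifnot(is.list(p), !is.null(p$type), !is.null(p$value))
    list(type = p$type, value = as.character(p$value))
  })
}

#' @export
print.compound_card <- function(x, ...) {
  cat("<compound card> ", x$pf_id, "  ", compound_primary_name(x), "\n",
      "  formula ", x$formula,
      "  monoisotopic ", sprintf("%.4f", x$monoisotopic_mass),
      "  average ", sprintf("%.2f", x$average_mass), "\n",
      "  InChIKey ", x$inchikey, "  stars ", x$stars, "\n", sep = "")
  invisible(x)
}

#' Primary (display) name of a compound card
#'
#' @param card A compound card.
#' @return The name flagged primary.
#' @export
compound_primary_name <- function(card) {
  for (n in card$names) if (isTRUE(n$is_primary)) return(n$text)
  card$names[[1]]$text
}

#' All names of a compound card
#'
#' @param card A compound card.
#' @return Data frame with `text`, `score`, `is_primary`.
#' @export
compound_names <- function(card) {
  data.frame(
    text = vapply(card$names, `[[`, character(1), "text"),
    score = vapply(card$names, function(n) as.integer(n$score), integer(1)),
    is_primary = vapply(card$names, function(n) isTRUE(n$is_primary), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Merge an incoming compound draft into an existing card
#'
#' Implements the non-destructive deduplication rule of the registry: new
#' common names are appended as synonyms (score 0); stored masses, formula,
#' InChI and structure fields are never recomputed or overwritten; an
#' incoming external identifier for a bank that already holds a *different*
#' identifier leaves the stored value intact and posts one
#' `EXTERNAL_ID_CONFLICT` curation message per conflicting bank (an
#' identifier for a bank with none stored is simply adopted).
#'
#' @param store A `pb_store`.
#' @param pf_id Existing compound pf_id (or InChIKey).
#' @param incoming Draft fields (same shape as [register_compound()]).
#' @return List with `card` (the updated card) and `messages` (curation
#'   messages generated by this merge, possibly empty).
#' @export
merge_compound <- function(store, pf_id, incoming) {
  .pb_check_store(store)
  card <- get_compound(store, pf_id)
  if (!is.null(incoming$inchikey) && incoming$inchikey != card$inchikey) {
    stop("merge requires identical InChIKeys", call. = FALSE)
  }

  have <- vapply(card$names, `[[`, character(1), "text")
  incoming_names <- unique(c(incoming$common_name, incoming$synonyms))
  incoming_names <- incoming_names[!is.na(incoming_names) & nzchar(incoming_names)]
  for (nm in setdiff(incoming_names, have)) {
    card$names[[length(card$names) + 1L]] <-
      list(text = nm, score = 0L, is_primary = FALSE)
  }

  msgs <- list()
  inc_refs <- .pb_as_cross_refs(incoming$cross_refs)
  for (bank in names(inc_refs)) {
    stored <- card$cross_refs[bank]
    if (is.na(stored)) {
      card$cross_refs[[bank]] <- inc_refs[[bank]]
    } else if (!identical(unname(stored), unname(inc_refs[[bank]]))) {
      msgs[[length(msgs) + 1L]] <- post_message(
        store,
        target = card$pf_id,
        kind = "EXTERNAL_ID_CONFLICT",
        text = sprintf(
          "conflicting %s identifier for %s: stored '%s', import provided '%s'",
          bank, card$pf_id, unname(stored), unname(inc_refs[[bank]])),
        author = "system"
      )
    }
  }

  for (p in .pb_as_publications(incoming$publications)) {
    dup <- any(vapply(card$publications, function(q) {
      identical(q$type, p$type) && identical(q$value, p$value)
    }, logical(1)))
    if (!dup) card$publications[[length(card$publications) + 1L]] <- p
  }

  store$compounds[[card$pf_id]] <- card
  list(card = card, messages = msgs)
}

#' Batch-import compounds from a table
#'
#' Imports a compound batch table row by row. Rows are independent: a
#' rejected row (missing mandatory trio, malformed InChIKey or formula)
#' never blocks the others.
#'
#' @param store A `pb_store`.
#' @param table A data frame in the compound-batch dialect (see
#'   [read_compound_batch()]) or a path to such a file.
#' @param provider Enrichment provider.
#' @return An `import_report`: list with `counts` (created/merged/rejected)
#'   and `rows` (per-row outcome data frame).
#' @export
batch_import_compounds <- function(store, table, provider = offline_provider()) {
  .pb_check_store(store)
  if (is.character(table)) table <- read_compound_batch(table)$rows
  outcomes <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    row <- table[i, , drop = FALSE]
    draft <- .pb_row_to_draft(row)
    outcomes[[i]] <- tryCatch({
      known <- !is.null(draft$inchikey) && !is.na(draft$inchikey) &&
        draft$inchikey %in% names(store$inchikey_index)
      card <- register_compound(store, draft, provider = provider)
      data.frame(row = i, outcome = if (known) "merged" else "created",
                 pf_id = card$pf_id, reason = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(row = i, outcome = "rejected", pf_id = NA_character_,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  rows <- do.call(rbind, outcomes)
  report <- list(
    counts = c(created = sum(rows$outcome == "created"),
               merged = sum(rows$outcome == "merged"),
               rejected = sum(rows$outcome == "rejected")),
    rows = rows
  )
  class(report) <- "import_report"
  report
}

.pb_row_to_draft <- function(row) {
  val <- function(col) {
    if (!col %in% names(row)) return(NULL)
    v <- row[[col]]
    if (is.na(v) || !nzchar(v)) NULL else as.character(v)
  }
  refs <- c(chebi = val("chebi"), pubchem = val("pubchem"),
            kegg = val("kegg"), hmdb = val("hmdb"))
  list(
    common_name = val("common_name"),
    inchi = val("inchi"),
    inchikey = val("inchikey"),
    synonyms = if (!is.null(val("synonyms"))) {
      trimws(strsplit(val("synonyms"), ";", fixed = TRUE)[[1]])
    },
    formula = val("formula"),
    smiles = val("smiles"),
    cross_refs = refs[!vapply(refs, is.null, logical(1))]
  )
}

#' @export
print.import_report <- function(x, ...) {
  cat("<import report> created ", x$counts[["created"]],
      ", merged ", x$counts[["merged"]],
      ", rejected ", x$counts[["rejected"]], "\n", sep = "")
  rej <- x$rows[x$rows$outcome == "rejected", ]
  if (nrow(rej)) {
    for (i in seq_len(nrow(rej))) {
      cat("  row ", rej$row[i], ": ", rej$reason[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Score a compound name
#'
#' Compound names carry a manual curation score (0..10). The primary
#' (display) name is always a name of maximal score, ties broken by
#' insertion order; re-scoring restores that invariant.
#'
#' @param store A `pb_store`.
#' @param pf_id Compound id.
#' @param name Existing name text on the card.
#' @param score Integer 0..10.
#' @param actor Acting user; must hold the curator (or admin) role.
#' @return The updated compound card.
#' @export
set_name_score <- function(store, pf_id, name, score, actor) {
  .pb_check_store(store)
  .pb_require_role(store, actor, c("curator", "admin"), "score names")
  if (!is.numeric(score) || length(score) != 1 || is.na(score) ||
      score != as.integer(score) || score < 0 || score > 10) {
    stop("name score must be an integer in 0..10", call. = FALSE)
  }
  card <- get_compound(store, pf_id)
  idx <- match(name, vapply(card$names, `[[`, character(1), "text"))
  if (is.na(idx)) stop(sprintf("name '%s' not on card %s", name, card$pf_id), call. = FALSE)
  card$names[[idx]]$score <- as.integer(score)
  card <- .pb_rerank_names(card)
  store$compounds[[card$pf_id]] <- card
  card
}

#' Promote a name to primary
#'
#' Marks `name` as the primary display name. Its score is raised to the
#' current maximum so the primary-has-maximal-score invariant holds.
#'
#' @inheritParams set_name_score
#' @return The updated compound card.
#' @export
promote_primary <- function(store, pf_id, name, actor) {
  .pb_check_store(store)
  .pb_require_role(store, actor, c("curator", "admin"), "promote names")
  card <- get_compound(store, pf_id)
  texts <- vapply(card$names, `[[`, character(1), "text")
  idx <- match(name, texts)
  if (is.na(idx)) stop(sprintf("name '%s' not on card %s", name, card$pf_id), call. = FALSE)
  top <- max(vapply(card$names, function(n) as.integer(n$score), integer(1)))
  card$names[[idx]]$score <- top
  for (k in seq_along(card$names)) card$names[[k]]$is_primary <- FALSE
  card$names[[idx]]$is_primary <- TRUE
  store$compounds[[card$pf_id]] <- card
  card
}

# primary = first name holding the maximal score (insertion order breaks ties)
.pb_rerank_names <- function(card) {
  scores <- vapply(card$names, function(n) as.integer(n$score), integer(1))
  primary <- which.max(scores)
  for (k in seq_along(card$names)) card$names[[k]]$is_primary <- (k == primary)
  card
}

#' Grade the curation status of a compound
#'
#' Stars run from 1 (freshly imported, unreviewed) to 5 (fully validated by
#' a curator). Every transition is recorded in the audit trail.
#'
#' @param store A `pb_store`.
#' @param pf_id Compound id.
#' @param stars Integer 1..5.
#' @param actor Acting user; curator or admin.
#' @return The updated compound card.
#' @export
set_stars <- function(store, pf_id, stars, actor) {
  .pb_check_store(store)
  .pb_require_role(store, actor, c("curator", "admin"), "grade compounds")
  if (!is.numeric(stars) || length(stars) != 1 || is.na(stars) ||
      stars != as.integer(stars) || stars < 1 || stars > 5) {
    stop("stars must be an integer in 1..5", call. = FALSE)
  }
  card <- get_compound(store, pf_id)
  old <- card$stars
  card$stars <- as.integer(stars)
  store$compounds[[card$pf_id]] <- card
  .pb_audit(store, actor, "set_stars", card$pf_id, from = old, to = card$stars)
  card
}

#' Attach a publication to a compound card
#'
#' @param store A `pb_store`.
#' @param pf_id Compound id.
#' @param ref_type `"DOI"` or `"PMID"`.
#' @param value DOI of shape `10.<registrant>/<suffix>` or a positive
#'   integer PMID.
#' @return The updated card; attaching the same reference twice is a no-op.
#' @export
attach_publication <- function(store, pf_id, ref_type = c("DOI", "PMID"), value) {
  .pb_check_store(store)
  ref_type <- match.arg(ref_type)
  value <- as.character(value)
  ok <- switch(ref_type,
    DOI = grepl("^10\\.[^/[:space:]]+/.+$", value),
    PMID = grepl("^[0-9]+$", value) && as.numeric(value) > 0
  )
  if (!ok) stop(sprintf("malformed %s reference: '%s'", ref_type, value), call. = FALSE)
  card <- get_compound(store, pf_id)
  dup <- any(vapply(card$publications, function(p) {
    identical(p$type, ref_type) && identical(p$value, value)
  }, logical(1)))
  if (!dup) {
    card$publications[[length(card$publications) + 1L]] <-
      list(type = ref_type, value = value)
    store$compounds[[card$pf_id]] <- card
  }
  card
}

#' Offline enrichment provider
#'
#' Compound enrichment (extra synonyms, octanol/water logP, endogenous
#' mammalian status) is pluggable: a provider is a function taking the draft
#' and returning `list(synonyms, logp, endogenous)`. The default provider
#' works fully offline and returns "unknown" for everything, so the engine
#' never requires network access.
#'
#' @return A provider function.
#' @export
offline_provider <- function() {
  function(draft) {
    list(synonyms = character(0), logp = NA_real_, endogenous = "unknown")
  }
}
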