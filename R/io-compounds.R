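# Compound batch dialect: CSV, UTF-8, fixed header. Mandatory trio per row:
# common_name, inchi, inchikey. synonyms are ';'-separated.
.pb_batch_columns <- c("common_name", "inchi", "inchikey", "synonyms",
                       "formula", "smiles", "chebi", "pubchem", "kegg", "hmdb")

.pb_read_csv <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
  } else {
    utils::read.csv(text = paste(x, collapse = "\n"), stringsAsFactors = FALSE,
                    colClasses = "character")
  }
}

#' Read a compound batch file
#'
#' Parses the compound batch dialect: a UTF-8 CSV with the fixed header
#' `common_name, inchi, inchikey, synonyms, formula, smiles, chebi,
#' pubchem, kegg, hmdb`. Rows violating the mandatory trio (common name,
#' InChI, InChIKey) or carrying a malformed InChIKey are reported as
#' row-level diagnostics, not file-level failures.
#'
#' @param x Path to a CSV file, or the CSV text itself.
#' @return List with `rows` (data frame of all parsed rows) and
#'   `diagnostics` (data frame `row`, `reason`; zero rows when clean).
#' @export
read_compound_batch <- function(x) {
  rows <- .pb_read_csv(x)
  missing_cols <- setdiff(.pb_batch_columns, names(rows))
  if (length(missing_cols)) {
    stop("compound batch header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- rows[, .pb_batch_columns, drop = FALSE]
  diags <- list()
  for (i in seq_len(nrow(rows))) {
    for (f in c("common_name", "inchi", "inchikey")) {
      v <- rows[[f]][i]
      if (is.na(v) || !nzchar(v)) {
        diags[[length(diags) + 1L]] <- data.frame(
          row = i, reason = sprintf("missing mandatory field '%s'", f),
          stringsAsFactors = FALSE)
      }
    }
    key <- rows$inchikey[i]
    if (!is.na(key) && nzchar(key)) {
      issue <- inchikey_issue(key)
      if (!is.na(issue)) {
        diags[[length(diags) + 1L]] <- data.frame(
          row = i, reason = sprintf("invalid InChIKey (%s)", issue),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    rows = rows,
    diagnostics = if (length(diags)) do.call(rbind, diags) else {
      data.frame(row = integer(0), reason = character(0), stringsAsFactors = FALSE)
    }
  )
}

#' Write a compound batch file
#'
#' Inverse of [read_compound_batch()]; used by the fixture generator.
#'
#' @param rows Data frame in the batch dialect.
#' @param path Output path; when `NULL` the CSV text is returned.
#' @return `path` invisibly, or the CSV text when `path` is `NULL`.
#' @export
write_compound_batch <- function(rows, path = NULL) {
  for (col in setdiff(.pb_batch_columns, names(rows))) rows[[col]] <- ""
  rows <- rows[, .pb_batch_columns, drop = FALSE]
  txt <- .pb_csv_text(rows)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.pb_csv_text <- function(df) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  close(con)
  paste(out, collapse = "\n")
}

#' Export compound cards as CSV
#'
#' One row per compound with the documented stable column set: `pf_id`,
#' `common_name`, `synonyms` (";"-separated), `inchikey`, `inchi`,
#' `formula`, `monoisotopic_mass`, `average_mass`, `smiles`, the four bank
#' cross-references and `stars`. RFC-4180 quoting via the base CSV writer.
#'
#' @param cards List of compound cards (or a `pb_store`, meaning all of
#'   them).
#' @return CSV text (header only for zero cards).
#' @export
export_compounds_csv <- function(cards) {
  if (inherits(cards, "pb_store")) cards <- unname(cards$compounds)
  if (inherits(cards, "compound_card")) cards <- list(cards)
  rows <- lapply(cards, function(card) {
    nm <- compound_names(card)
    data.frame(
      pf_id = card$pf_id,
      common_name = compound_primary_name(card),
      synonyms = paste(nm$text[!nm$is_primary], collapse = ";"),
      inchikey = card$inchikey,
      inchi = card$inchi,
      formula = card$formula,
      monoisotopic_mass = format(card$monoisotopic_mass, digits = 15),
      average_mass = format(card$average_mass, digits = 15),
      smiles = if (is.null(card$canonical_smiles)) "" else card$canonical_smiles,
      chebi = .pb_ref_or_empty(card, "chebi"),
      pubchem = .pb_ref_or_empty(card, "pubchem"),
      kegg = .pb_ref_or_empty(card, "kegg"),
      hmdb = .pb_ref_or_empty(card, "hmdb"),
      stars = card$stars,
      stringsAsFactors = FALSE)
  })
  empty <- data.frame(pf_id = character(0), common_name = character(0),
                      synonyms = character(0), inchikey = character(0),
                      inchi = character(0), formula = character(0),
                      monoisotopic_mass = character(0), average_mass = character(0),
                      smiles = character(0), chebi = character(0),
                      pubchem = character(0), kegg = character(0),
                      hmdb = character(0), stars = integer(0),
                      stringsAsFactors = FALSE)
  .pb_csv_text(if (length(rows)) do.call(rbind, rows) else empty)
}

.pb_ref_or_empty <- function(card, bank) {
  v <- card$cross_refs[bank]
  if (is.na(v)) "" else unname(v)
}

#' Read back a compound CSV export
#'
#' @param x CSV text or path produced by [export_compounds_csv()].
#' @return Data frame with the exported columns; masses as numerics.
#' @export
read_compounds_csv <- function(x) {
  d <- .pb_read_csv(x)
  d$monoisotopic_mass <- as.numeric(d$monoisotopic_mass)
  d$average_mass <- as.numeric(d$average_mass)
  d$stars <- as.integer(d$stars)
  d
}

# Zero-atom V2000 stub used when a card has no molfile; flagged in the
# comment line so exports are never mistaken for real structures.
.pb_stub_molfile <- function(card) {
  paste(
    compound_primary_name(card),
    "  peakbase",
    "no structure block stored; stub record",
    "  0  0  0  0  0  0  0  0  0  0999 V2000",
    "M  END",
    sep = "\n")
}

#' Export a compound card as an SDF record
#'
#' Emits the card's MDL molfile (or a zero-atom V2000 stub when none is
#' stored) followed by `> <tag>` data items carrying the registry fields
#' and the `$$$$` record terminator. Multiple records concatenate into a
#' multi-record SDF.
#'
#' @param card A compound card, or a list of them.
#' @return SDF text.
#' @export
export_compound_sdf <- function(card) {
  if (inherits(card, "compound_card")) card <- list(card)
  recs <- vapply(card, function(c1) {
    mol <- if (is.null(c1$molfile)) .pb_stub_molfile(c1) else c1$molfile
    tags <- c(
      PF_ID = c1$pf_id,
      NAME = compound_primary_name(c1),
      INCHI = c1$inchi,
      INCHIKEY = c1$inchikey,
      FORMULA = c1$formula,
      MONOISOTOPIC_MASS = format(c1$monoisotopic_mass, digits = 15),
      AVERAGE_MASS = format(c1$average_mass, digits = 15)
    )
    items <- paste(vapply(names(tags), function(t) {
      sprintf("> <%s>\n%s\n", t, tags[[t]])
    }, character(1)), collapse = "\n")
    paste0(mol, "\n\n", items, "\n$$$$")
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

#' Read records from an SDF export
#'
#' Minimal SDF reader for round-tripping [export_compound_sdf()] output:
#' splits on `$$$$`, returns the molfile block and the `> <tag>` items of
#' each record.
#'
#' @param x SDF text or path.
#' @return List of records, each `list(molfile, tags)` with `tags` a named
#'   character vector.
#' @export
read_sdf <- function(x) {
  txt <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  chunks <- strsplit(txt, "\\$\\$\\$\\$")[[1]]
  chunks <- chunks[vapply(chunks, function(c1) nzchar(trimws(c1)), logical(1))]
  lapply(chunks, function(chunk) {
    lines <- strsplit(sub("^\n+", "", chunk), "\n", fixed = TRUE)[[1]]
    first_tag <- grep("^> <", lines)[1]
    if (is.na(first_tag)) {
      return(list(molfile = paste(lines, collapse = "\n"),
                  tags = character(0)))
    }
    mol <- paste(lines[seq_len(first_tag - 1)], collapse = "\n")
    mol <- sub("\n+$", "", mol)
    tags <- character(0)
    i <- first_tag
    while (i <= length(lines)) {
      m <- regmatches(lines[i], regexec("^> <([^>]+)>$", lines[i]))[[1]]
      if (length(m)) {
        vals <- character(0)
        j <- i + 1
        while (j <= length(lines) && nzchar(lines[j]) && !grepl("^> <", lines[j])) {
          vals <- c(vals, lines[j])
          j <- j + 1
        }
        tags[m[2]] <- paste(vals, collapse = "\n")
        i <- j
      } else {
        i <- i + 1
      }
    }
    list(molfile = mol, tags = tags)
  })
}
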