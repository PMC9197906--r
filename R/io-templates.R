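# Spectrum template bundles: a directory of UTF-8 CSV files named after the
# import sheets. Metadata sheets have columns group,key,value; peaks.csv is
# tabular; compounds.csv lists linked compounds (InChIKey or PFc id) with an
# optional MSI level. The sheet set must match the technique:
#   LC-MS / LC-MSMS : sample, chromatography, MS_analyzer
#   FIA-MS/FIA-MSMS : sample, MS_analyzer
#   GC-MS           : sample, chromatography, GCMS_analyzer
#   IC-MS           : sample, chromatography, MS_analyzer
#   NMR-*           : sample, NMR_analyzer
# plus optional Other.csv, peaks.csv, compounds.csv everywhere.

.pb_template_sheets <- function(technique) {
  if (technique %in% c("LC-MS", "LC-MSMS", "IC-MS")) {
    c("sample", "chromatography", "MS_analyzer")
  } else if (technique %in% c("FIA-MS", "FIA-MSMS")) {
    c("sample", "MS_analyzer")
  } else if (technique == "GC-MS") {
    c("sample", "chromatography", "GCMS_analyzer")
  } else if (technique %in% techniques()) {
    c("sample", "NMR_analyzer")
  } else {
    stop(sprintf("unknown technique '%s'", technique), call. = FALSE)
  }
}

# chromatography sheet hosts the group matching the technique family
.pb_chromatography_group <- function(technique) {
  switch(substr(technique, 1, 2),
         "LC" = "liquid_chromatography",
         "GC" = "gas_chromatography",
         "IC" = "ion_chromatography",
         stop("no chromatography group for ", technique, call. = FALSE))
}

.pb_numeric_fields <- c("field_mhz", "temperature_k", "ph", "precursor_mz",
                        "collision_energy", "retention_time_min")

.pb_peak_columns <- function(technique) {
  if (is_ms_technique(technique)) {
    c("mz", "intensity", "annotation")
  } else if (is_nmr1d_technique(technique)) {
    c("shift_ppm", "intensity", "multiplicity", "atom_assignment")
  } else {
    c("shift_f1_ppm", "shift_f2_ppm", "assignment")
  }
}

#' Write a spectrum template bundle
#'
#' Generates a template bundle for a technique, optionally prefilled with
#' the user's analytical-method defaults, so routine imports only need the
#' peak list and sample identity filled in. The produced bundle re-reads
#' (see [read_spectrum_template()]) into an empty-peaks draft of the same
#' technique.
#'
#' @param technique One of [techniques()].
#' @param dir Output directory (created if needed).
#' @param defaults Named list of metadata groups with prefilled fields,
#'   e.g. `list(liquid_chromatography = list(column_name = "C18 150mm"))`.
#' @param sample_type Prefilled sample type.
#' @return `dir`, invisibly.
#' @export
write_template <- function(technique, dir, defaults = list(),
                           sample_type = "chemical_standard") {
  sheets <- .pb_template_sheets(technique) # validates technique
  draft <- list(
    technique = technique,
    sample_type = sample_type,
    compound_links = list(),
    metadata = defaults,
    peaks = NULL
  )
  # guarantee the mandatory groups exist (possibly with empty fields)
  req <- metadata_requirements()[[technique]]
  for (g in names(req$mandatory)) {
    if (is.null(draft$metadata[[g]])) draft$metadata[[g]] <- list()
    for (f in req$mandatory[[g]]) {
      if (is.null(draft$metadata[[g]][[f]])) draft$metadata[[g]][[f]] <- ""
    }
  }
  write_spectrum_bundle(draft, dir)
}

#' Write a spectrum draft as a template bundle
#'
#' Serializes a full spectrum draft (the shape [register_spectrum()]
#' accepts, with compound links by InChIKey or pf_id) into the
#' directory-of-CSV template dialect. Inverse of
#' [read_spectrum_template()].
#'
#' @param draft Spectrum draft.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_spectrum_bundle <- function(draft, dir) {
  technique <- draft$technique
  sheets <- .pb_template_sheets(technique)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  kv <- function(group, fields) {
    if (is.null(fields) || length(fields) == 0) {
      return(data.frame(group = character(0), key = character(0),
                        value = character(0), stringsAsFactors = FALSE))
    }
    data.frame(group = group, key = names(fields),
               value = vapply(fields, function(v) {
                 if (is.numeric(v)) .pb_num(v) else as.character(v)
               }, character(1)),
               stringsAsFactors = FALSE)
  }
  write_sheet <- function(name, df) {
    writeLines(.pb_csv_text(df), file.path(dir, paste0(name, ".csv")),
               useBytes = TRUE)
  }

  meta <- draft$metadata
  write_sheet("sample", rbind(
    kv("card", list(spectrum_type = technique,
                    sample_type = draft$sample_type)),
    kv("sample", meta$sample)))

  if ("chromatography" %in% sheets) {
    g <- .pb_chromatography_group(technique)
    write_sheet("chromatography", kv(g, meta[[g]]))
  }
  if ("MS_analyzer" %in% sheets || "GCMS_analyzer" %in% sheets) {
    sheet <- if ("GCMS_analyzer" %in% sheets) "GCMS_analyzer" else "MS_analyzer"
    write_sheet(sheet, rbind(kv("ionization_method", meta$ionization_method),
                             kv("ion_analyzer", meta$ion_analyzer)))
  }
  if ("NMR_analyzer" %in% sheets) {
    write_sheet("NMR_analyzer", rbind(kv("nmr_instrument", meta$nmr_instrument),
                                      kv("nmr_software", meta$nmr_software)))
  }
  if (!is.null(meta$other)) {
    write_sheet("Other", kv("other", meta$other))
  }

  peaks <- draft$peaks
  cols <- .pb_peak_columns(technique)
  if (is.null(peaks)) {
    peaks <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                           stringsAsFactors = FALSE)
  } else {
    peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
    for (col in setdiff(cols, names(peaks))) peaks[[col]] <- ""
    peaks <- peaks[, cols, drop = FALSE]
    for (col in cols) {
      if (is.numeric(peaks[[col]])) {
        v <- peaks[[col]]
        peaks[[col]] <- ifelse(is.na(v), "", .pb_num(v))
      }
    }
  }
  write_sheet("peaks", peaks)

  links <- draft$compound_links
  link_df <- if (length(links)) {
    do.call(rbind, lapply(links, function(l) {
      if (is.character(l)) l <- list(compound = l)
      data.frame(compound = l$compound,
                 msi_level = if (is.null(l$msi_level)) "" else as.character(l$msi_level),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(compound = character(0), msi_level = character(0),
               stringsAsFactors = FALSE)
  }
  write_sheet("compounds", link_df)
  invisible(dir)
}

#' Read a spectrum template bundle
#'
#' Parses a template bundle directory into a spectrum draft ready for
#' [register_spectrum()]. The technique declared in the sample sheet must
#' be consistent with the sheet set present (a bundle carrying both an MS
#' and an NMR analyzer sheet, or the wrong chromatography family, is
#' rejected).
#'
#' @param dir Bundle directory.
#' @return Spectrum draft list (`technique`, `sample_type`,
#'   `compound_links`, `metadata`, `peaks`).
#' @export
read_spectrum_template <- function(dir) {
  if (!dir.exists(dir)) stop("no such template bundle: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.csv$")
  present <- sub("\\.csv$", "", files)

  analyzer_sheets <- intersect(present, c("MS_analyzer", "GCMS_analyzer", "NMR_analyzer"))
  if (length(analyzer_sheets) > 1) {
    stop("ambiguous template bundle: sheets ",
         paste(analyzer_sheets, collapse = " + "), " cannot coexist",
         call. = FALSE)
  }
  if (!"sample" %in% present) {
    stop("template bundle lacks the mandatory sample sheet", call. = FALSE)
  }

  read_sheet <- function(name) .pb_read_csv(file.path(dir, paste0(name, ".csv")))

  sample_sheet <- read_sheet("sample")
  if (!all(c("group", "key", "value") %in% names(sample_sheet))) {
    stop("sample sheet must have group,key,value columns", call. = FALSE)
  }
  card_rows <- sample_sheet[sample_sheet$group == "card", , drop = FALSE]
  technique <- card_rows$value[card_rows$key == "spectrum_type"]
  if (length(technique) != 1 || !technique %in% techniques()) {
    stop("sample sheet must declare a known spectrum_type", call. = FALSE)
  }
  expected <- .pb_template_sheets(technique)
  missing_sheets <- setdiff(expected, present)
  if (length(missing_sheets)) {
    stop(sprintf("bundle does not match technique %s: missing sheet(s) %s",
                 technique, paste(missing_sheets, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(present, c(expected, "Other", "peaks", "compounds"))
  if (length(extra)) {
    stop(sprintf("bundle does not match technique %s: unexpected sheet(s) %s",
                 technique, paste(extra, collapse = ", ")), call. = FALSE)
  }

  sample_type <- card_rows$value[card_rows$key == "sample_type"]
  if (length(sample_type) != 1) {
    stop("sample sheet must declare sample_type", call. = FALSE)
  }

  metadata <- list()
  absorb <- function(df) {
    for (i in seq_len(nrow(df))) {
      g <- df$group[i]
      if (g == "card") next
      v <- df$value[i]
      if (df$key[i] %in% .pb_numeric_fields && nzchar(v)) v <- as.numeric(v)
      metadata[[g]][[df$key[i]]] <<- v
    }
  }
  absorb(sample_sheet)
  for (sheet in intersect(present, c("chromatography", "MS_analyzer",
                                     "GCMS_analyzer", "NMR_analyzer", "Other"))) {
    absorb(read_sheet(sheet))
  }

  peaks <- NULL
  if ("peaks" %in% present) {
    p <- read_sheet("peaks")
    if (nrow(p) > 0) {
      for (col in intersect(c("mz", "intensity", "shift_ppm",
                              "shift_f1_ppm", "shift_f2_ppm"), names(p))) {
        v <- p[[col]]
        v[is.na(v) | !nzchar(v)] <- NA_character_
        p[[col]] <- as.numeric(v)
      }
      for (col in names(p)) {
        if (is.character(p[[col]])) p[[col]][!nzchar(p[[col]])] <- NA_character_
      }
      peaks <- p
    }
  }

  links <- list()
  if ("compounds" %in% present) {
    l <- read_sheet("compounds")
    links <- lapply(seq_len(nrow(l)), function(i) {
      list(compound = l$compound[i],
           msi_level = if (nzchar(l$msi_level[i])) as.integer(l$msi_level[i]) else NULL)
    })
  }

  list(
    technique = technique,
    sample_type = sample_type,
    compound_links = links,
    metadata = metadata,
    peaks = peaks
  )
}
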