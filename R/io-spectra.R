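# Numbers in text exports are printed with format(digits = 15), which
# round-trips every value the generators or templates produce (and any
# double to ~1e-15 relative).
.pb_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

.pb_first_compound <- function(store, card) {
  if (length(card$compound_links) == 0) return(NULL)
  get_compound(store, card$compound_links[[1]]$compound)
}

#' Export a mass spectrum as a MassBank record
#'
#' Writes the line-oriented MassBank record format (2.x field names):
#' `ACCESSION`, `RECORD_TITLE`, the `CH$` compound block (names, formula,
#' exact mass, InChI, links incl. InChIKey), the `AC$` acquisition block
#' (instrument, MS_TYPE, ION_MODE), `PK$SPLASH`, `PK$NUM_PEAK` and the
#' `PK$PEAK` table (`m/z int. rel.int.`, ascending m/z), terminated by
#' `//`. Optional fields without a stored value are omitted rather than
#' emitted empty.
#'
#' @param store A `pb_store` (the compound block is taken from the card's
#'   first linked compound).
#' @param pf_id Spectrum id (or a spectrum card).
#' @return MassBank record text.
#' @export
export_spectrum_massbank <- function(store, pf_id) {
  card <- if (inherits(pf_id, "spectrum_card")) pf_id else get_spectrum(store, pf_id)
  if (!is_ms_technique(card$technique)) {
    stop("MassBank export applies to MS spectra, not ", card$technique,
         call. = FALSE)
  }
  comp <- .pb_first_compound(store, card)
  instrument <- card$metadata$ion_analyzer$instrument
  polarity <- card$metadata$ionization_method$polarity

  lines <- c(
    paste0("ACCESSION: ", card$pf_id),
    paste0("RECORD_TITLE: ",
           paste(c(if (!is.null(comp)) compound_primary_name(comp),
                   card$technique, instrument), collapse = "; "))
  )
  if (!is.null(comp)) {
    nm <- compound_names(comp)
    lines <- c(lines,
      paste0("CH$NAME: ", nm$text),
      paste0("CH$FORMULA: ", comp$formula),
      paste0("CH$EXACT_MASS: ", .pb_num(comp$monoisotopic_mass)),
      paste0("CH$IUPAC: ", comp$inchi),
      paste0("CH$LINK: INCHIKEY ", comp$inchikey))
    for (bank in names(comp$cross_refs)) {
      lines <- c(lines, paste0("CH$LINK: ", toupper(bank), " ",
                               comp$cross_refs[[bank]]))
    }
  }
  if (!is.null(instrument)) {
    lines <- c(lines, paste0("AC$INSTRUMENT: ", instrument))
  }
  lines <- c(lines,
    paste0("AC$MASS_SPECTROMETRY: MS_TYPE ",
           if (is_msms_technique(card$technique)) "MS2" else "MS"),
    paste0("AC$MASS_SPECTROMETRY: ION_MODE ",
           if (identical(as.character(polarity), "-")) "NEGATIVE" else "POSITIVE"),
    paste0("PK$SPLASH: ", card$splash),
    paste0("PK$NUM_PEAK: ", nrow(card$peaks)),
    "PK$PEAK: m/z int. rel.int.",
    sprintf("  %s %s %d", .pb_num(card$peaks$mz), .pb_num(card$peaks$intensity),
            card$peaks$relative_intensity),
    "//")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a MassBank record
#'
#' Companion reader for [export_spectrum_massbank()]; parses one record.
#'
#' @param x Record text or path.
#' @return List with `accession`, `record_title`, `names`, `formula`,
#'   `exact_mass`, `inchi`, `links` (named character vector, InChIKey under
#'   `INCHIKEY`), `instrument`, `ms_type`, `ion_mode`, `splash`,
#'   `num_peak` and `peaks` (data frame `mz`, `intensity`,
#'   `relative_intensity`).
#' @export
read_massbank <- function(x) {
  lines <- .pb_text_lines(x)
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", key, ": "), "", hit)
  }
  links <- field("CH\\$LINK")
  link_map <- character(0)
  for (l in links) {
    parts <- strsplit(l, " ", fixed = TRUE)[[1]]
    link_map[parts[1]] <- paste(parts[-1], collapse = " ")
  }
  acms <- field("AC\\$MASS_SPECTROMETRY")
  ac_get <- function(key) {
    hit <- grep(paste0("^", key, " "), acms, value = TRUE)
    if (length(hit) == 0) NULL else sub(paste0("^", key, " "), "", hit[1])
  }
  peak_header <- grep("^PK\\$PEAK:", lines)
  peaks <- data.frame(mz = numeric(0), intensity = numeric(0),
                      relative_intensity = integer(0), stringsAsFactors = FALSE)
  if (length(peak_header)) {
    i <- peak_header[1] + 1L
    rows <- list()
    while (i <= length(lines) && grepl("^  ", lines[i])) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        mz = as.numeric(parts[1]), intensity = as.numeric(parts[2]),
        relative_intensity = as.integer(parts[3]), stringsAsFactors = FALSE)
      i <- i + 1L
    }
    if (length(rows)) peaks <- do.call(rbind, rows)
  }
  exact <- field("CH\\$EXACT_MASS")
  num_peak <- field("PK\\$NUM_PEAK")
  list(
    accession = field("ACCESSION"),
    record_title = field("RECORD_TITLE"),
    names = field("CH\\$NAME"),
    formula = field("CH\\$FORMULA"),
    exact_mass = if (is.null(exact)) NULL else as.numeric(exact),
    inchi = field("CH\\$IUPAC"),
    links = link_map,
    instrument = field("AC\\$INSTRUMENT"),
    ms_type = ac_get("MS_TYPE"),
    ion_mode = ac_get("ION_MODE"),
    splash = field("PK\\$SPLASH"),
    num_peak = if (is.null(num_peak)) NULL else as.integer(num_peak),
    peaks = peaks
  )
}

.pb_text_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}

#' Export a mass spectrum as an MSP entry
#'
#' NIST MSP text format as consumed by library-search tools: `Name:`,
#' `InChIKey:`, `Formula:`, `ExactMass:`, `PrecursorMZ:` (fragmentation
#' spectra with a stored precursor), `Num Peaks:` and one `mz intensity`
#' pair per line.
#'
#' @inheritParams export_spectrum_massbank
#' @return MSP text.
#' @export
export_spectrum_msp <- function(store, pf_id) {
  card <- if (inherits(pf_id, "spectrum_card")) pf_id else get_spectrum(store, pf_id)
  if (!is_ms_technique(card$technique)) {
    stop("MSP export applies to MS spectra, not ", card$technique, call. = FALSE)
  }
  comp <- .pb_first_compound(store, card)
  lines <- c(
    paste0("Name: ", if (!is.null(comp)) compound_primary_name(comp) else card$pf_id),
    paste0("DB#: ", card$pf_id)
  )
  if (!is.null(comp)) {
    lines <- c(lines,
      paste0("InChIKey: ", comp$inchikey),
      paste0("Formula: ", comp$formula),
      paste0("ExactMass: ", .pb_num(comp$monoisotopic_mass)))
  }
  if (is_msms_technique(card$technique)) {
    prec <- card$metadata$ionization_method$precursor_mz
    if (!is.null(prec)) {
      lines <- c(lines, paste0("PrecursorMZ: ", .pb_num(as.numeric(prec))))
    }
  }
  lines <- c(lines,
    paste0("Num Peaks: ", nrow(card$peaks)),
    paste(.pb_num(card$peaks$mz), .pb_num(card$peaks$intensity)),
    "")
  paste(lines, collapse = "\n")
}

#' Read an MSP entry
#'
#' @param x MSP text or path (single entry).
#' @return List with `name`, `db_id`, `inchikey`, `formula`, `exact_mass`,
#'   `precursor_mz`, `num_peaks` and `peaks` (data frame `mz`, `intensity`).
#' @export
read_msp <- function(x) {
  lines <- .pb_text_lines(x)
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(hit) == 0) NULL else sub(paste0("^", key, ": "), "", hit[1])
  }
  np_line <- grep("^Num Peaks: ", lines)
  peaks <- data.frame(mz = numeric(0), intensity = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(np_line)) {
    i <- np_line[1] + 1L
    rows <- list()
    while (i <= length(lines) && grepl("^[0-9]", lines[i])) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        mz = as.numeric(parts[1]), intensity = as.numeric(parts[2]),
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
    if (length(rows)) peaks <- do.call(rbind, rows)
  }
  prec <- field("PrecursorMZ")
  exact <- field("ExactMass")
  np <- field("Num Peaks")
  list(
    name = field("Name"),
    db_id = field("DB#"),
    inchikey = field("InChIKey"),
    formula = field("Formula"),
    exact_mass = if (is.null(exact)) NULL else as.numeric(exact),
    precursor_mz = if (is.null(prec)) NULL else as.numeric(prec),
    num_peaks = if (is.null(np)) NULL else as.integer(np),
    peaks = peaks
  )
}

#' Export a 1D NMR spectrum as nmrML-lite XML
#'
#' Writes a documented *subset* of the nmrML interchange format: one
#' `<spectrum>` element carrying the acquisition field strength and pulse
#' sequence, the sample solvent/pH when stored, and a `<peakList>` with one
#' `<peak>` element per chemical-shift peak. This is not full nmrML schema
#' conformance (no raw FID/vendor payloads, 1D peak lists only).
#'
#' @inheritParams export_spectrum_massbank
#' @return XML text.
#' @export
export_spectrum_nmrml_lite <- function(store, pf_id) {
  card <- if (inherits(pf_id, "spectrum_card")) pf_id else get_spectrum(store, pf_id)
  if (!is_nmr1d_technique(card$technique)) {
    stop("nmrML-lite export applies to 1D NMR spectra, not ", card$technique,
         call. = FALSE)
  }
  doc <- xml2::xml_new_root("nmrML", dialect = "peakbase-nmrml-lite")
  spec <- xml2::xml_add_child(doc, "spectrum",
                              id = card$pf_id, technique = card$technique,
                              sampleType = card$sample_type)
  inst <- card$metadata$nmr_instrument
  acq_attrs <- list(fieldStrengthMHz = .pb_num(as.numeric(inst$field_mhz)),
                    pulseSequence = as.character(inst$pulse_sequence))
  if (!is.null(inst$probe)) acq_attrs$probe <- as.character(inst$probe)
  if (!is.null(inst$temperature_k)) {
    acq_attrs$temperatureK <- .pb_num(as.numeric(inst$temperature_k))
  }
  do.call(xml2::xml_add_child, c(list(spec, "acquisition"), acq_attrs))
  smp <- card$metadata$sample
  smp_attrs <- list(label = as.character(smp$label))
  if (!is.null(smp$solvent)) smp_attrs$solvent <- as.character(smp$solvent)
  if (!is.null(smp$ph)) smp_attrs$pH <- .pb_num(as.numeric(smp$ph))
  do.call(xml2::xml_add_child, c(list(spec, "sample"), smp_attrs))
  plist <- xml2::xml_add_child(spec, "peakList", count = as.character(nrow(card$peaks)))
  for (i in seq_len(nrow(card$peaks))) {
    attrs <- list(shiftPpm = .pb_num(card$peaks$shift_ppm[i]))
    ri <- card$peaks$relative_intensity
    if (!is.null(ri) && !is.na(ri[i])) attrs$relativeIntensity <- as.character(ri[i])
    mult <- card$peaks$multiplicity[i]
    if (!is.na(mult)) attrs$multiplicity <- mult
    asg <- card$peaks$atom_assignment[i]
    if (!is.na(asg)) attrs$assignment <- asg
    do.call(xml2::xml_add_child, c(list(plist, "peak"), attrs))
  }
  as.character(doc)
}

#' Read an nmrML-lite document
#'
#' @param x XML text or path produced by [export_spectrum_nmrml_lite()].
#' @return List with `id`, `technique`, `sample_type`, `field_mhz`,
#'   `pulse_sequence`, `solvent`, `ph` and `peaks` (data frame `shift_ppm`,
#'   `relative_intensity`, `multiplicity`, `assignment`).
#' @export
read_nmrml_lite <- function(x) {
  doc <- xml2::read_xml(paste(x, collapse = "\n"))
  spec <- xml2::xml_find_first(doc, "./spectrum")
  acq <- xml2::xml_find_first(spec, "./acquisition")
  smp <- xml2::xml_find_first(spec, "./sample")
  peaks <- xml2::xml_find_all(spec, "./peakList/peak")
  attr_or_na <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NA_character_ else v
  }
  ph <- xml2::xml_attr(smp, "pH")
  list(
    id = xml2::xml_attr(spec, "id"),
    technique = xml2::xml_attr(spec, "technique"),
    sample_type = xml2::xml_attr(spec, "sampleType"),
    field_mhz = as.numeric(xml2::xml_attr(acq, "fieldStrengthMHz")),
    pulse_sequence = xml2::xml_attr(acq, "pulseSequence"),
    solvent = attr_or_na(smp, "solvent"),
    ph = if (is.na(ph)) NA_real_ else as.numeric(ph),
    peaks = data.frame(
      shift_ppm = as.numeric(xml2::xml_attr(peaks, "shiftPpm")),
      relative_intensity = as.integer(xml2::xml_attr(peaks, "relativeIntensity")),
      multiplicity = xml2::xml_attr(peaks, "multiplicity"),
      assignment = xml2::xml_attr(peaks, "assignment"),
      stringsAsFactors = FALSE)
  )
}
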