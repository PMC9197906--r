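#' Supported acquisition techniques
#'
#' @return Character vector of technique codes: LC/FIA/GC/IC mass
#'   spectrometry (full scan and fragmentation) and 1D/2D NMR experiments.
#' @export
techniques <- function() {
  c("LC-MS", "LC-MSMS", "FIA-MS", "FIA-MSMS", "GC-MS", "IC-MS",
    "NMR-1D-1H", "NMR-1D-13C",
    "NMR-2D-JRES", "NMR-2D-COSY", "NMR-2D-TOCSY", "NMR-2D-NOESY",
    "NMR-2D-HSQC", "NMR-2D-HMBC")
}

is_ms_technique <- function(t) t %in% c("LC-MS", "LC-MSMS", "FIA-MS", "FIA-MSMS", "GC-MS", "IC-MS")
is_msms_technique <- function(t) t %in% c("LC-MSMS", "FIA-MSMS")
is_nmr1d_technique <- function(t) t %in% c("NMR-1D-1H", "NMR-1D-13C")
is_nmr2d_technique <- function(t) startsWith(t, "NMR-2D-")

.pb_sample_types <- c("chemical_standard", "standard_mix",
                      "reference_matrix", "biological_matrix")

.pb_multiplicities <- c("s", "d", "t", "q", "quint", "sext", "m",
                        "dd", "dt", "td", "ddd", "br")

#' Metadata group requirements per technique
#'
#' Each spectrum carries technique-dependent metadata groups (sample,
#' chromatography, ionization method, ion analyzer, NMR instrument and
#' software, free "other" metadata). This function returns, per technique,
#' the mandatory groups with their minimal mandatory fields and the groups
#' additionally allowed. The minimal field sets are deliberately small and
#' overridable (pass a modified copy to [validate_metadata()]).
#'
#' @return Named list: per technique, `list(mandatory = list(group =
#'   fields), optional = character vector of group names)`.
#' @export
metadata_requirements <- function() {
  sample <- list(sample = "label")
  ms_common <- list(ionization_method = c("ionization", "polarity"),
                    ion_analyzer = "instrument")
  out <- list(
    "LC-MS" = list(
      mandatory = c(sample, list(liquid_chromatography = c("column_name", "flow_rate")), ms_common),
      optional = "other"),
    "FIA-MS" = list(mandatory = c(sample, ms_common), optional = "other"),
    "GC-MS" = list(
      mandatory = c(sample, list(gas_chromatography = "column_name"), ms_common),
      optional = "other"),
    "IC-MS" = list(
      mandatory = c(sample, list(ion_chromatography = "column_name"), ms_common),
      optional = "other")
  )
  out[["LC-MSMS"]] <- out[["LC-MS"]]
  out[["FIA-MSMS"]] <- out[["FIA-MS"]]
  nmr <- list(
    mandatory = c(sample, list(nmr_instrument = c("field_mhz", "pulse_sequence"))),
    optional = c("nmr_software", "other"))
  for (t in grep("^NMR-", techniques(), value = TRUE)) out[[t]] <- nmr
  out
}

#' Validate spectrum metadata against its technique
#'
#' Checks that exactly the metadata groups applicable to the technique are
#' present and that each mandatory field inside a mandatory group is
#' non-empty. A group that does not apply to the technique (for instance a
#' liquid-chromatography group on a GC-MS spectrum) is itself an issue.
#'
#' @param technique One of [techniques()].
#' @param groups Named list of metadata groups, each a named list of fields.
#' @param requirements Requirement table, by default [metadata_requirements()].
#' @return Data frame of issues with columns `group`, `field`, `severity`,
#'   `message`; zero rows when the metadata is valid.
#' @export
validate_metadata <- function(technique, groups,
                              requirements = metadata_requirements()) {
  if (!technique %in% names(requirements)) {
    stop(sprintf("unknown technique '%s'", technique), call. = FALSE)
  }
  req <- requirements[[technique]]
  issues <- list()
  flag <- function(group, field, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      group = group, field = field, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  if (is.null(groups)) groups <- list()
  for (g in names(req$mandatory)) {
    if (!g %in% names(groups)) {
      flag(g, NA_character_, "error",
           sprintf("mandatory metadata group '%s' is missing for %s", g, technique))
      next
    }
    for (f in req$mandatory[[g]]) {
      v <- groups[[g]][[f]]
      if (is.null(v) || (length(v) == 1 && (is.na(v) || !nzchar(as.character(v))))) {
        flag(g, f, "error",
             sprintf("mandatory field '%s' in group '%s' is missing", f, g))
      }
    }
  }
  allowed <- c(names(req$mandatory), req$optional)
  for (g in setdiff(names(groups), allowed)) {
    flag(g, NA_character_, "error",
         sprintf("metadata group '%s' does not apply to %s", g, technique))
  }
  if (length(issues) == 0) {
    return(data.frame(group = character(0), field = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Register a spectrum
#'
#' Creates a spectrum card from a draft after validating its metadata
#' groups and compound links. Peaks are normalized: sorted by m/z (MS) or
#' chemical shift (1D NMR), relative intensities on the 0..999 MassBank
#' scale computed from raw intensities when absent. For MS techniques a
#' SPLASH identifier is computed; annotated MS peaks on a card with exactly
#' one linked compound get their theoretical m/z and ppm error auto-filled.
#'
#' Draft fields: `technique`, `sample_type` (one of chemical_standard,
#' standard_mix, reference_matrix, biological_matrix), `compound_links`
#' (list of `list(compound = <PFc id or InChIKey>, msi_level = NULL|1..4)`;
#' mandatory and non-empty for chemical standards and standard mixes),
#' `metadata` (named list of groups), `peaks` (data frame; MS: `mz`,
#' `intensity`, optional `annotation`; 1D NMR: `shift_ppm`, optional
#' `intensity`, `multiplicity`, `atom_assignment`; 2D NMR: `shift_f1_ppm`,
#' `shift_f2_ppm`, optional `assignment`).
#'
#' @param store A `pb_store`.
#' @param draft Named list as described above.
#' @return The new spectrum card.
#' @export
register_spectrum <- function(store, draft) {
  .pb_check_store(store)
  technique <- draft$technique
  if (is.null(technique) || !technique %in% techniques()) {
    stop(sprintf("unknown technique '%s'", if (is.null(technique)) "<missing>" else technique),
         call. = FALSE)
  }
  sample_type <- draft$sample_type
  if (is.null(sample_type) || !sample_type %in% .pb_sample_types) {
    stop("sample_type must be one of: ", paste(.pb_sample_types, collapse = ", "),
         call. = FALSE)
  }

  issues <- validate_metadata(technique, draft$metadata)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("metadata validation failed for ", technique, ":\n  ",
         paste(errs$message, collapse = "\n  "), call. = FALSE)
  }

  links <- .pb_resolve_links(store, draft$compound_links)
  if (sample_type %in% c("chemical_standard", "standard_mix") && length(links) == 0) {
    stop(sprintf("%s spectra must link at least one compound", sample_type),
         call. = FALSE)
  }

  peaks <- .pb_normalize_peaks(technique, draft$peaks)

  card <- structure(list(
    pf_id = .pb_next_id(store, "spectrum"),
    technique = technique,
    sample_type = sample_type,
    compound_links = links,
    metadata = draft$metadata,
    peaks = peaks,
    splash = NULL,
    other = draft$other
  ), class = "spectrum_card")

  if (is_ms_technique(technique)) {
    card$splash <- compute_splash(card$peaks)
    card <- .pb_autofill_annotations(store, card)
  }

  store$spectra[[card$pf_id]] <- card
  card
}

.pb_resolve_links <- function(store, links) {
  if (is.null(links)) return(list())
  lapply(links, function(l) {
    if (is.character(l)) l <- list(compound = l)
    card <- tryCatch(get_compound(store, l$compound), error = function(e) {
      stop(sprintf("dangling compound link '%s'", l$compound), call. = FALSE)
    })
    level <- l$msi_level
    if (!is.null(level)) {
      level <- .pb_check_msi(level)
    }
    list(compound = card$pf_id, msi_level = level)
  })
}

.pb_check_msi <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level != as.integer(level) || level < 1 || level > 4) {
    stop("MSI identification level must be an integer in 1..4", call. = FALSE)
  }
  as.integer(level)
}

.pb_normalize_peaks <- function(technique, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    if (is_ms_technique(technique)) {
      stop("MS spectra need at least one peak", call. = FALSE)
    }
    peaks <- if (is_nmr2d_technique(technique)) {
      data.frame(shift_f1_ppm = numeric(0), shift_f2_ppm = numeric(0),
                 assignment = character(0), stringsAsFactors = FALSE)
    } else {
      data.frame(shift_ppm = numeric(0), stringsAsFactors = FALSE)
    }
    return(peaks)
  }
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)

  if (is_ms_technique(technique)) {
    if (!all(c("mz", "intensity") %in% names(peaks))) {
      stop("MS peaks need 'mz' and 'intensity' columns", call. = FALSE)
    }
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
      stop("MS peaks need positive finite m/z", call. = FALSE)
    }
    if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
      stop("MS peak intensities must be non-negative", call. = FALSE)
    }
    peaks <- peaks[order(peaks$mz, peaks$intensity), , drop = FALSE]
    if (!"relative_intensity" %in% names(peaks) ||
        all(is.na(peaks$relative_intensity))) {
      peaks$relative_intensity <- .pb_relative_intensity(peaks$intensity)
    }
    for (col in c("annotation")) {
      if (!col %in% names(peaks)) peaks[[col]] <- NA_character_
    }
    for (col in c("theoretical_mz", "ppm")) {
      if (!col %in% names(peaks)) peaks[[col]] <- NA_real_
    }
  } else if (is_nmr1d_technique(technique)) {
    if (!"shift_ppm" %in% names(peaks)) {
      stop("1D NMR peaks need a 'shift_ppm' column", call. = FALSE)
    }
    if (any(!is.finite(peaks$shift_ppm))) {
      stop("chemical shifts must be finite", call. = FALSE)
    }
    if ("multiplicity" %in% names(peaks)) {
      bad <- setdiff(stats::na.omit(unique(peaks$multiplicity)), .pb_multiplicities)
      if (length(bad)) {
        stop("unknown multiplicity code(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
    } else {
      peaks$multiplicity <- NA_character_
    }
    if (!"atom_assignment" %in% names(peaks)) peaks$atom_assignment <- NA_character_
    if ("intensity" %in% names(peaks) &&
        (!"relative_intensity" %in% names(peaks) || all(is.na(peaks$relative_intensity)))) {
      peaks$relative_intensity <- .pb_relative_intensity(peaks$intensity)
    }
    peaks <- peaks[order(peaks$shift_ppm), , drop = FALSE]
  } else {
    if (!all(c("shift_f1_ppm", "shift_f2_ppm") %in% names(peaks))) {
      stop("2D NMR peaks need 'shift_f1_ppm' and 'shift_f2_ppm' columns",
           call. = FALSE)
    }
    if (any(!is.finite(peaks$shift_f1_ppm)) || any(!is.finite(peaks$shift_f2_ppm))) {
      stop("chemical shifts must be finite", call. = FALSE)
    }
    if (!"assignment" %in% names(peaks)) peaks$assignment <- NA_character_
    peaks <- peaks[order(peaks$shift_f1_ppm, peaks$shift_f2_ppm), , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks
}

# MassBank-style relative intensities: integers 0..999, base peak = 999.
.pb_relative_intensity <- function(intensity) {
  if (length(intensity) == 0) return(integer(0))
  top <- max(intensity)
  if (top <= 0) return(rep(0L, length(intensity)))
  as.integer(round(999 * intensity / top))
}

# Auto-fill theoretical m/z + ppm for annotated peaks when the card links
# exactly one compound (otherwise the neutral molecule is ambiguous).
.pb_autofill_annotations <- function(store, card) {
  if (length(card$compound_links) != 1) return(card)
  comp <- get_compound(store, card$compound_links[[1]]$compound)
  ann <- card$peaks$annotation
  for (i in which(!is.na(ann) & nzchar(ann))) {
    parsed <- tryCatch(parse_ion_annotation(ann[i]), error = function(e) NULL)
    if (is.null(parsed)) next
    theo <- theoretical_mz(comp$formula, parsed)
    card$peaks$theoretical_mz[i] <- theo
    card$peaks$ppm[i] <- ppm_error(card$peaks$mz[i], theo)
  }
  card
}

#' @export
print.spectrum_card <- function(x, ...) {
  cat("<spectrum card> ", x$pf_id, "  ", x$technique, " (", x$sample_type, ")\n",
      "  peaks: ", nrow(x$peaks),
      if (!is.null(x$splash)) paste0("  splash: ", x$splash) else "",
      "\n", sep = "")
  if (length(x$compound_links)) {
    cat("  compounds:",
        paste(vapply(x$compound_links, `[[`, character(1), "compound"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotate a peak on a spectrum card
#'
#' Stores an adduct/ion annotation on one peak. When the card links exactly
#' one compound the theoretical m/z of the annotated ion and the resulting
#' ppm error are filled in; on multi-compound cards (standard mixes) the
#' annotation is stored verbatim without auto-fill, since the neutral
#' molecule is ambiguous. The edit is recorded in the audit trail.
#'
#' @param store A `pb_store`.
#' @param pf_id Spectrum id.
#' @param peak Peak index (row in the card's peak table, 1-based).
#' @param annotation Ion annotation text, e.g. `"[M+H]+"`.
#' @param actor Authenticated user.
#' @return The updated spectrum card.
#' @export
annotate_peak <- function(store, pf_id, peak, annotation, actor) {
  .pb_check_store(store)
  .pb_require_authenticated(store, actor, "annotate peaks")
  card <- get_spectrum(store, pf_id)
  if (!is_ms_technique(card$technique)) {
    stop("ion annotations apply to MS spectra", call. = FALSE)
  }
  if (!is.numeric(peak) || length(peak) != 1 || is.na(peak) ||
      peak < 1 || peak > nrow(card$peaks)) {
    stop(sprintf("peak index out of range (card has %d peaks)", nrow(card$peaks)),
         call. = FALSE)
  }
  parsed <- parse_ion_annotation(annotation) # errors on unparseable text
  card$peaks$annotation[peak] <- format_ion_annotation(parsed)
  if (length(card$compound_links) == 1) {
    comp <- get_compound(store, card$compound_links[[1]]$compound)
    theo <- theoretical_mz(comp$formula, parsed)
    card$peaks$theoretical_mz[peak] <- theo
    card$peaks$ppm[peak] <- ppm_error(card$peaks$mz[peak], theo)
  }
  store$spectra[[card$pf_id]] <- card
  .pb_audit(store, actor, "annotate_peak", card$pf_id,
            from = peak, to = format_ion_annotation(parsed))
  card
}

#' Set the MSI identification level of a compound link
#'
#' Records the Metabolomics Standards Initiative confidence level (1 =
#' confirmed against an authentic chemical standard, 2 = putatively
#' annotated by spectral match, 3 = compound class, 4 = unknown) on the link
#' between a spectrum and a compound.
#'
#' @param store A `pb_store`.
#' @param pf_id Spectrum id.
#' @param compound Linked compound pf_id (or InChIKey).
#' @param level Integer 1..4.
#' @param actor Curator or admin.
#' @return The updated spectrum card.
#' @export
set_msi_level <- function(store, pf_id, compound, level, actor) {
  .pb_check_store(store)
  .pb_require_role(store, actor, c("curator", "admin"), "set MSI levels")
  level <- .pb_check_msi(level)
  card <- get_spectrum(store, pf_id)
  comp_id <- get_compound(store, compound)$pf_id
  idx <- match(comp_id, vapply(card$compound_links, `[[`, character(1), "compound"))
  if (is.na(idx)) {
    stop(sprintf("spectrum %s has no link to compound %s", pf_id, comp_id),
         call. = FALSE)
  }
  old <- card$compound_links[[idx]]$msi_level
  card$compound_links[[idx]]$msi_level <- level
  store$spectra[[card$pf_id]] <- card
  .pb_audit(store, actor, "set_msi_level", paste0(card$pf_id, ":", comp_id),
            from = if (is.null(old)) NA else old, to = level)
  card
}
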