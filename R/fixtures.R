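# Deterministic synthetic-data generator. It emulates the scale and shape of
# a curated demonstrator library (roughly a hundred compounds of biological
# interest and a few hundred spectra across LC/FIA/GC/IC-MS and NMR
# platforms) without reproducing any real library content: InChIKeys are
# format-valid pseudo-keys, NOT chemically derived, and carry the marker
# block "SYNTHKEYS" so nobody mistakes them for real identifiers.

.pb_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.pb_pseudo_inchikey <- function() {
  paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""),
         "-SYNTHKEYSA-N")
}

.pb_random_formula <- function() {
  c_n <- sample(4:30, 1)
  h_n <- max(1L, as.integer(round(1.6 * c_n + stats::rnorm(1, 0, 2))))
  counts <- c(C = c_n, H = h_n)
  n_n <- sample(0:4, 1, prob = c(0.35, 0.3, 0.2, 0.1, 0.05))
  o_n <- sample(0:8, 1)
  if (n_n > 0) counts["N"] <- n_n
  if (o_n > 0) counts["O"] <- o_n
  if (stats::runif(1) < 0.12) counts["S"] <- sample(1:2, 1)
  if (stats::runif(1) < 0.08) counts["P"] <- 1L
  format_formula(counts)
}

#' Generate a synthetic compound batch
#'
#' Produces a deterministic compound batch table: distinct format-valid
#' pseudo-InChIKeys, plausible CHNOPS formulas, names with synonyms, and
#' occasional bank cross-references. The first two rows are fixed anchor
#' compounds used throughout the documentation: hypaphorine (C14H18N2O2)
#' and L-tryptophan (C11H12N2O2), with synthetic keys.
#'
#' @param n Number of distinct compounds (>= 2).
#' @param seed RNG seed; the same seed always yields the same table.
#' @param with_duplicates Number of extra rows that re-import an existing
#'   InChIKey under a new synonym and a conflicting ChEBI id (0 = none);
#'   used to exercise merge/curation paths.
#' @param path Optional file path; when given, the batch CSV is written
#'   there.
#' @return The batch data frame (invisibly when `path` is given).
#' @export
generate_compounds <- function(n = 96, seed = 1, with_duplicates = 0, path = NULL) {
  stopifnot(n >= 2)
  rows <- .pb_with_seed(seed, {
    fixed <- data.frame(
      common_name = c("hypaphorine", "L-tryptophan"),
      inchi = c("InChI=1S/C14H18N2O2/synthetic-fixture",
                "InChI=1S/C11H12N2O2/synthetic-fixture"),
      inchikey = c("HYPAPHORINESYN-SYNTHKEYSA-N", "TRYPTOPHANESYN-SYNTHKEYSA-N"),
      synonyms = c("lenticin", "tryptophan;Trp"),
      formula = c("C14H18N2O2", "C11H12N2O2"),
      smiles = "",
      chebi = c("CHEBI:27434", "CHEBI:16828"),
      pubchem = c("442106", "6305"),
      kegg = "",
      hmdb = "",
      stringsAsFactors = FALSE)

    keys <- character(0)
    rest <- lapply(seq_len(n - 2), function(i) {
      repeat {
        key <- .pb_pseudo_inchikey()
        if (!key %in% keys && !key %in% fixed$inchikey) break
      }
      keys <<- c(keys, key)
      formula <- .pb_random_formula()
      id <- sprintf("%03d", i)
      data.frame(
        common_name = paste0("fixturine-", id),
        inchi = paste0("InChI=1S/", formula, "/synthetic-fixture"),
        inchikey = key,
        synonyms = if (stats::runif(1) < 0.6) {
          paste0("syn-", id, "-a;syn-", id, "-b")
        } else "",
        formula = formula,
        smiles = "",
        chebi = if (stats::runif(1) < 0.5) paste0("CHEBI:", sample(1e4:9e4, 1)) else "",
        pubchem = if (stats::runif(1) < 0.5) as.character(sample(1e3:1e6, 1)) else "",
        kegg = if (stats::runif(1) < 0.3) sprintf("C%05d", sample(1:99999, 1)) else "",
        hmdb = "",
        stringsAsFactors = FALSE)
    })
    out <- rbind(fixed, do.call(rbind, rest))

    if (with_duplicates > 0) {
      src <- out[sample(nrow(out), with_duplicates, replace = with_duplicates > nrow(out)), ,
                 drop = FALSE]
      dups <- do.call(rbind, lapply(seq_len(nrow(src)), function(k) {
        row <- src[k, , drop = FALSE]
        row$common_name <- paste0(row$common_name, " (reimport ", k, ")")
        row$synonyms <- paste0("dup-syn-", k)
        row$chebi <- paste0("CHEBI:", 100000 + k) # conflicts with stored id
        row
      }))
      out <- rbind(out, dups)
    }
    rownames(out) <- NULL
    out
  })
  if (!is.null(path)) {
    write_compound_batch(rows, path)
    return(invisible(rows))
  }
  rows
}

.pb_adducts <- list(
  "+" = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+"),
  "-" = c("[M-H]-", "[M+Cl]-", "[M-H-H2O]-")
)

.pb_fixture_metadata <- function(technique, polarity) {
  meta <- list(sample = list(label = paste0("synthetic ", technique, " standard")))
  if (is_ms_technique(technique)) {
    meta$ionization_method <- list(ionization = "ESI", polarity = polarity)
    meta$ion_analyzer <- list(instrument = "QTOF-sim", analyzer = "TOF")
    if (technique %in% c("LC-MS", "LC-MSMS")) {
      meta$liquid_chromatography <- list(
        column_name = sample(c("C18 Hypersil GOLD 100x2.1", "HILIC BEH amide 150x2.1"), 1),
        flow_rate = "0.3 mL/min",
        retention_time_min = round(stats::runif(1, 0.5, 15), 2))
    } else if (technique == "GC-MS") {
      meta$gas_chromatography <- list(column_name = "DB-5ms 30m")
      meta$ionization_method$ionization <- "EI"
    } else if (technique == "IC-MS") {
      meta$ion_chromatography <- list(column_name = "AS11-HC 250x2")
    }
    if (is_msms_technique(technique)) {
      meta$ionization_method$collision_energy <- sample(c(10, 20, 40), 1)
    }
  } else {
    meta$nmr_instrument <- list(
      field_mhz = sample(c(400, 600, 800), 1),
      pulse_sequence = if (technique == "NMR-2D-HSQC") "hsqcetgp" else "zg30",
      probe = "TCI cryoprobe")
    meta$nmr_software <- list(name = "TopSpin-sim", version = "4.0")
  }
  meta$other <- list(authors = "fixture generator", ownership = "synthetic",
                     raw_file_name = "none")
  meta
}

#' Generate synthetic spectrum drafts
#'
#' Builds deterministic spectrum drafts over a compound batch: MS spectra
#' carry peaks planted at the theoretical m/z of common adducts
#' (`[M+H]+`, `[M+Na]+`, `[M+H-H2O]+` in positive mode; `[M-H]-`,
#' `[M+Cl]-`, `[M-H-H2O]-` in negative mode), perturbed by Gaussian mass
#' noise of `noise_ppm` ppm (standard deviation) and rounded to 6 decimals;
#' intensities are log-normal draws. NMR drafts carry shifts uniform in
#' 0-10 ppm (1H) or 0-200 ppm (13C). Metadata groups are filled per
#' technique so every draft registers without validation errors.
#'
#' @param compounds Compound batch data frame from [generate_compounds()]
#'   (rows with duplicate InChIKeys are ignored here).
#' @param m Number of spectra.
#' @param seed RNG seed.
#' @param technique_mix Named probability vector over [techniques()].
#' @param noise_ppm Gaussian m/z noise (ppm standard deviation); 0 plants
#'   peaks exactly at the theoretical adduct m/z.
#' @param dir Optional directory; when given, each draft is also written as
#'   a template bundle under `dir/spectrum-<i>/`.
#' @return List of spectrum drafts (compound links by InChIKey).
#' @export
generate_spectra <- function(compounds, m = 400, seed = 1,
                             technique_mix = c("LC-MS" = 0.35, "LC-MSMS" = 0.15,
                                               "FIA-MS" = 0.10, "GC-MS" = 0.10,
                                               "IC-MS" = 0.05,
                                               "NMR-1D-1H" = 0.15,
                                               "NMR-1D-13C" = 0.05,
                                               "NMR-2D-HSQC" = 0.05),
                             noise_ppm = 0, dir = NULL) {
  stopifnot(all(names(technique_mix) %in% techniques()))
  compounds <- compounds[!duplicated(compounds$inchikey), , drop = FALSE]
  drafts <- .pb_with_seed(seed, {
    lapply(seq_len(m), function(i) {
      technique <- sample(names(technique_mix), 1, prob = technique_mix)
      row <- compounds[sample(nrow(compounds), 1), , drop = FALSE]
      polarity <- sample(c("+", "-"), 1)
      meta <- .pb_fixture_metadata(technique, polarity)

      if (is_ms_technique(technique)) {
        adducts <- .pb_adducts[[polarity]]
        k <- sample(2:3, 1)
        ann <- sample(adducts, k)
        theo <- vapply(ann, function(a) theoretical_mz(row$formula, a), numeric(1))
        mz <- round(theo * (1 + noise_ppm * 1e-6 * stats::rnorm(length(theo))), 6)
        peaks <- data.frame(
          mz = mz,
          intensity = round(stats::rlnorm(length(mz), meanlog = 8, sdlog = 1), 2),
          annotation = ann,
          stringsAsFactors = FALSE)
        if (is_msms_technique(technique)) {
          meta$ionization_method$precursor_mz <- round(max(theo), 6)
        }
      } else if (is_nmr1d_technique(technique)) {
        k <- sample(4:10, 1)
        top <- if (technique == "NMR-1D-1H") 10 else 200
        peaks <- data.frame(
          shift_ppm = round(sort(stats::runif(k, 0, top)), 4),
          intensity = round(stats::rlnorm(k, 5, 0.8), 2),
          multiplicity = sample(c("s", "d", "t", "m", "dd"), k, replace = TRUE),
          stringsAsFactors = FALSE)
      } else {
        k <- sample(3:8, 1)
        peaks <- data.frame(
          shift_f1_ppm = round(stats::runif(k, 0, 200), 4),
          shift_f2_ppm = round(stats::runif(k, 0, 10), 4),
          stringsAsFactors = FALSE)
      }

      list(
        technique = technique,
        sample_type = "chemical_standard",
        compound_links = list(list(compound = row$inchikey)),
        metadata = meta,
        peaks = peaks
      )
    })
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(drafts)) {
      write_spectrum_bundle(drafts[[i]], file.path(dir, sprintf("spectrum-%04d", i)))
    }
  }
  drafts
}
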