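#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula such as `"C14H18N2O2"` or
#' `"CH3(CH2)2OH"` into an element-count composition. One level of
#' parenthesised groups with an integer multiplier is supported; element
#' symbols are case-sensitive (`Co` is cobalt, `CO` carbon monoxide).
#'
#' @param text Formula string.
#' @return A named integer vector of element counts with class
#'   `"pb_formula"`, elements in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C14H18N2O2")
#' parse_formula("CH3(CH2)2OH")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  counts <- .pb_scan_formula(text, 1L, nchar(text), text)
  as_formula(counts)
}

# Recursive-descent scan over text[from..to]; depth limited to one group level
# by forbidding '(' inside a group.
.pb_scan_formula <- function(text, from, to, full, in_group = FALSE) {
  counts <- integer(0)
  i <- from
  add <- function(sym, n) {
    if (n == 0L) {
      stop(sprintf("zero count for '%s' at position %d in '%s'", sym, i, full),
           call. = FALSE)
    }
    counts[sym] <<- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  while (i <= to) {
    ch <- substr(text, i, i)
    if (ch == "(") {
      if (in_group) {
        stop(sprintf("nested parentheses at position %d in '%s' (one level supported)",
                     i, full), call. = FALSE)
      }
      close <- i
      depth <- 0L
      repeat {
        close <- close + 1L
        if (close > to) {
          stop(sprintf("unclosed '(' at position %d in '%s'", i, full), call. = FALSE)
        }
        cc <- substr(text, close, close)
        if (cc == "(") depth <- depth + 1L
        if (cc == ")") {
          if (depth == 0L) break
          depth <- depth - 1L
        }
      }
      if (depth > 0L || close == i + 1L) {
        stop(sprintf("malformed group at position %d in '%s'", i, full), call. = FALSE)
      }
      inner <- .pb_scan_formula(text, i + 1L, close - 1L, full, in_group = TRUE)
      j <- close + 1L
      num <- ""
      while (j <= to && grepl("^[0-9]$", substr(text, j, j))) {
        num <- paste0(num, substr(text, j, j))
        j <- j + 1L
      }
      mult <- if (nzchar(num)) as.integer(num) else 1L
      if (mult == 0L) {
        stop(sprintf("zero group multiplier at position %d in '%s'", close + 1L, full),
             call. = FALSE)
      }
      for (sym in names(inner)) add(sym, inner[[sym]] * mult)
      i <- j
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (i < to && grepl("^[a-z]$", substr(text, i + 1L, i + 1L))) {
        sym <- paste0(sym, substr(text, i + 1L, i + 1L))
        i <- i + 1L
      }
      if (!sym %in% .pb_elements$symbol) {
        stop(sprintf("unknown element symbol '%s' at position %d in '%s'",
                     sym, i, full), call. = FALSE)
      }
      j <- i + 1L
      num <- ""
      while (j <= to && grepl("^[0-9]$", substr(text, j, j))) {
        num <- paste0(num, substr(text, j, j))
        j <- j + 1L
      }
      add(sym, if (nzchar(num)) as.integer(num) else 1L)
      i <- j
    } else {
      stop(sprintf("unexpected character '%s' at position %d in '%s'", ch, i, full),
           call. = FALSE)
    }
  }
  if (length(counts) == 0L && !in_group) {
    stop(sprintf("empty formula '%s'", full), call. = FALSE)
  }
  counts
}

#' Coerce to a formula composition
#'
#' @param x A formula string, a named integer vector of element counts, or a
#'   `pb_formula` object (returned unchanged).
#' @return A `pb_formula` named integer vector in Hill order.
#' @export
as_formula <- function(x) {
  if (inherits(x, "pb_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.null(x) || length(x) == 0) {
    out <- integer(0)
    class(out) <- "pb_formula"
    return(out)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("element counts must be named by element symbol", call. = FALSE)
  }
  bad <- setdiff(names(x), .pb_elements$symbol)
  if (length(bad)) {
    stop("unknown element symbol: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- as.integer(x)
  if (any(is.na(n)) || any(n < 1L)) {
    stop("element counts must be positive integers", call. = FALSE)
  }
  names(n) <- names(x)
  out <- n[.pb_hill_order(names(n))]
  class(out) <- "pb_formula"
  out
}

# Hill order: C first, H second when carbon present; otherwise all symbols
# alphabetical (H included).
.pb_hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

#' Serialize a composition as a Hill-order formula string
#'
#' @param comp Anything accepted by [as_formula()].
#' @return Single formula string; `""` for the empty composition.
#' @examples
#' format_formula(c(O = 1, H = 2, C = 3))
#' @export
format_formula <- function(comp) {
  comp <- as_formula(comp)
  if (length(comp) == 0) return("")
  paste0(names(comp), ifelse(unclass(comp) == 1L, "", unclass(comp)), collapse = "")
}

#' @export
format.pb_formula <- function(x, ...) format_formula(x)

#' @export
print.pb_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum of the masses of the most abundant isotope of each atom, in Da.
#' Full double precision is retained; any display rounding (4 decimals by
#' convention for m/z) is left to the caller.
#'
#' @param comp Anything accepted by [as_formula()].
#' @return Mass in Da (0 for the empty composition).
#' @examples
#' monoisotopic_mass("C11H12N2O2") # L-tryptophan, 204.0899
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_formula(comp)
  if (length(comp) == 0) return(0)
  sum(unclass(comp) * .pb_mono(names(comp)))
}

#' Average (standard atomic weight) mass of a composition
#'
#' @param comp Anything accepted by [as_formula()].
#' @return Mass in Da using IUPAC standard atomic weights.
#' @examples
#' average_mass("C11H12N2O2") # 204.23
#' @export
average_mass <- function(comp) {
  comp <- as_formula(comp)
  if (length(comp) == 0) return(0)
  sum(unclass(comp) * .pb_avg(names(comp)))
}

#' Validate an InChIKey
#'
#' Syntactic validation of the 14-10-1 hyphenated uppercase-letter layout
#' (e.g. `QIVBCDIJIAJPQS-VIFPVBQESA-N`). Consistency with the InChI string
#' itself is not checked (that requires a chemistry toolkit and is left to
#' an optional enrichment provider).
#'
#' @param text Candidate key.
#' @return The key, unchanged, when valid; otherwise an error of class
#'   `pb_inchikey_error` whose `reason` field is one of `"bad_length"`,
#'   `"bad_hyphenation"`, `"bad_charset"`.
#' @seealso [inchikey_issue()] for a non-throwing check.
#' @export
validate_inchikey <- function(text) {
  reason <- inchikey_issue(text)
  if (!is.na(reason)) {
    cond <- structure(
      class = c("pb_inchikey_error", "error", "condition"),
      list(message = sprintf("invalid InChIKey '%s': %s", text, reason),
           call = sys.call(-1), reason = reason)
    )
    stop(cond)
  }
  text
}

#' Non-throwing InChIKey check
#'
#' @param text Candidate key (length-1 character).
#' @return `NA_character_` when valid, otherwise the rejection reason code:
#'   `"bad_length"`, `"bad_hyphenation"` or `"bad_charset"`.
#' @export
inchikey_issue <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    return("bad_length")
  }
  if (nchar(text) != 27L) return("bad_length")
  if (substr(text, 15, 15) != "-" || substr(text, 26, 26) != "-") {
    return("bad_hyphenation")
  }
  parts <- c(substr(text, 1, 14), substr(text, 16, 25), substr(text, 27, 27))
  if (!all(grepl("^[A-Z]+$", parts))) return("bad_charset")
  NA_character_
}

#' Parse an ion annotation
#'
#' Parses bracketed adduct expressions in the community notation, e.g.
#' `"[M+H]+"`, `"[2M+Na]+"`, `"[M+H-H2O]+"`, `"[M-2H]2-"`. The grammar is
#' `[nM(+|-)species...]z(+|-)` with optional multimer count `n`, one or more
#' signed species terms (each a valid molecular formula, optionally with a
#' leading repeat count as in `-2H`), and optional charge magnitude `z`.
#'
#' @param text Annotation string.
#' @return A list of class `"ion_annotation"` with fields `multimer`,
#'   `terms` (data frame with `sign` in \{-1, 1\} and `species` formula
#'   strings), `charge` (magnitude, >= 1) and `polarity` (`"+"` or `"-"`).
#' @examples
#' parse_ion_annotation("[M+H-H2O]+")
#' @export
parse_ion_annotation <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("ion annotation must be a string", call. = FALSE)
  }
  m <- regmatches(text, regexec("^\\[([0-9]*)M((?:[+-][A-Za-z0-9]+)+)\\]([0-9]*)([+-])$", text))[[1]]
  if (length(m) == 0) {
    stop(sprintf("cannot parse ion annotation '%s' (expected e.g. [M+H]+, [2M+Na]+, [M-2H]2-)",
                 text), call. = FALSE)
  }
  multimer <- if (nzchar(m[2])) as.integer(m[2]) else 1L
  if (multimer < 1L) stop("multimer count must be >= 1", call. = FALSE)
  charge <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  if (charge < 1L) stop("charge magnitude must be >= 1", call. = FALSE)
  term_text <- m[3]
  starts <- gregexpr("[+-]", term_text)[[1]]
  ends <- c(starts[-1] - 1L, nchar(term_text))
  terms <- lapply(seq_along(starts), function(k) {
    chunk <- substr(term_text, starts[k], ends[k])
    sign <- if (substr(chunk, 1, 1) == "+") 1L else -1L
    body <- substr(chunk, 2, nchar(chunk))
    rep_m <- regmatches(body, regexec("^([0-9]+)(.*)$", body))[[1]]
    rep_n <- 1L
    if (length(rep_m) && nzchar(rep_m[2])) {
      rep_n <- as.integer(rep_m[2])
      body <- rep_m[3]
    }
    species <- as_formula(body) # validates element symbols
    if (rep_n > 1L) {
      species <- as_formula(unclass(species) * rep_n)
    }
    list(sign = sign, species = format_formula(species))
  })
  out <- list(
    multimer = multimer,
    terms = data.frame(
      sign = vapply(terms, `[[`, integer(1), "sign"),
      species = vapply(terms, `[[`, character(1), "species"),
      stringsAsFactors = FALSE
    ),
    charge = charge,
    polarity = m[5]
  )
  class(out) <- "ion_annotation"
  out
}

#' Serialize an ion annotation
#'
#' Inverse of [parse_ion_annotation()]: `parse(format(a))` is `a`.
#'
#' @param ann An `ion_annotation`.
#' @return The bracketed annotation string.
#' @export
format_ion_annotation <- function(ann) {
  stopifnot(inherits(ann, "ion_annotation"))
  terms <- paste0(ifelse(ann$terms$sign > 0, "+", "-"), ann$terms$species,
                  collapse = "")
  paste0("[",
         if (ann$multimer > 1L) ann$multimer else "",
         "M", terms, "]",
         if (ann$charge > 1L) ann$charge else "",
         ann$polarity)
}

#' @export
format.ion_annotation <- function(x, ...) format_ion_annotation(x)

#' @export
print.ion_annotation <- function(x, ...) {
  cat("<ion annotation> ", format_ion_annotation(x), "\n", sep = "")
  invisible(x)
}

#' Theoretical m/z of an ionized molecule
#'
#' Computes the mass-to-charge ratio of the ion described by an adduct
#' annotation applied to a neutral molecule:
#' \deqn{m/z = (n \cdot M + \sum s_i \cdot m_i - p \cdot z \cdot m_e) / z}
#' where `n` is the multimer count, `M` the monoisotopic mass of the neutral
#' molecule, `s_i, m_i` the sign and monoisotopic mass of each adduct/loss
#' species, `p` the polarity (+1/-1), `z` the charge magnitude and `m_e` the
#' electron mass. The electron-mass correction makes `[M+H]+` add exactly
#' one proton.
#'
#' @param neutral Neutral molecule formula (anything [as_formula()] takes).
#' @param ann Ion annotation string or `ion_annotation` object.
#' @return m/z in Th (Da per unit charge), full precision.
#' @examples
#' theoretical_mz("C14H18N2O2", "[M+H]+") # 247.1441 at 4 decimals
#' @export
theoretical_mz <- function(neutral, ann) {
  comp <- as_formula(neutral)
  if (is.character(ann)) ann <- parse_ion_annotation(ann)
  stopifnot(inherits(ann, "ion_annotation"))
  pol <- if (ann$polarity == "+") 1 else -1
  species_mass <- 0
  if (nrow(ann$terms) > 0) {
    species_mass <- sum(ann$terms$sign *
                          vapply(ann$terms$species, monoisotopic_mass, numeric(1)))
  }
  mz <- (ann$multimer * monoisotopic_mass(comp) + species_mass -
           pol * ann$charge * .pb_electron_mass) / ann$charge
  if (mz <= 0) {
    stop(sprintf("annotation '%s' yields non-positive m/z for %s",
                 format_ion_annotation(ann), format_formula(comp)), call. = FALSE)
  }
  mz
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z, must be > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(247.1453, 247.1441)
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Mass or chemical-shift tolerance
#'
#' @param value Positive tolerance value.
#' @param unit `"ppm"` or `"Da"` for m/z searches; chemical-shift windows
#'   use plain ppm-of-shift numbers and do not need this type.
#' @return List of class `"mass_tolerance"`.
#' @export
mass_tolerance <- function(value, unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value <= 0) {
    stop("tolerance value must be a positive number", call. = FALSE)
  }
  structure(list(value = value, unit = unit), class = "mass_tolerance")
}

#' @export
format.mass_tolerance <- function(x, ...) paste0(x$value, " ", x$unit)

#' @export
print.mass_tolerance <- function(x, ...) {
  cat("<tolerance> ", format(x), "\n", sep = "")
  invisible(x)
}

# Extract the composition from an InChI's formula layer (second "/" field).
# Multi-component formulas (dot-separated) are rejected.
.pb_formula_from_inchi <- function(inchi) {
  parts <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2 || !grepl("^InChI=", parts[1])) {
    stop("cannot extract formula layer from InChI string", call. = FALSE)
  }
  layer <- parts[2]
  if (grepl(".", layer, fixed = TRUE)) {
    stop("multi-component InChI formula layers are not supported", call. = FALSE)
  }
  parse_formula(layer)
}
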