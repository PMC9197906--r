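#' Element mass table
#'
#' Monoisotopic masses (mass of the most abundant isotope, Da) and standard
#' atomic weights (Da) for the elements commonly seen in metabolites and
#' their salts/adducts. Values are frozen NIST/CODATA 2018-era constants so
#' that every mass computed by the package is reproducible offline.
#'
#' @return A data frame with columns `symbol`, `monoisotopic` and
#'   `average_weight`, one row per supported element.
#' @examples
#' head(element_masses())
#' @export
element_masses <- function() {
  .pb_elements
}

# Frozen table. monoisotopic: most-abundant-isotope mass; average_weight:
# abundance-weighted atomic weight from the NIST isotopic compositions
# (CHNOPS) / IUPAC standard values (the rest). monoisotopic(C) = 12 by
# definition of the unified amu.
.pb_elements <- local({
  x <- rbind(
    c("C",  12.0,           12.0107359),
    c("H",  1.00782503207,  1.00794075),
    c("N",  14.0030740048,  14.0067032),
    c("O",  15.9949146196,  15.9994049),
    c("P",  30.97376163,    30.97376163),
    c("S",  31.97207100,    32.0647872),
    c("Na", 22.9897692809,  22.98976928),
    c("K",  38.96370668,    39.0983),
    c("Cl", 34.96885268,    35.453),
    c("Br", 78.9183371,     79.904),
    c("F",  18.99840322,    18.9984032),
    c("I",  126.904473,     126.90447),
    c("Si", 27.9769265325,  28.0855),
    c("Se", 79.9165213,     78.96),
    c("B",  11.0093054,     10.811),
    c("Li", 7.01600455,     6.941),
    c("Mg", 23.9850417,     24.305),
    c("Al", 26.98153863,    26.9815385),
    c("Ca", 39.96259098,    40.078),
    c("Ti", 47.9479463,     47.867),
    c("V",  50.9439595,     50.9415),
    c("Cr", 51.9405075,     51.9961),
    c("Mn", 54.9380451,     54.938044),
    c("Fe", 55.9349375,     55.845),
    c("Co", 58.9331950,     58.933194),
    c("Ni", 57.9353429,     58.6934),
    c("Cu", 62.9295975,     63.546),
    c("Zn", 63.9291422,     65.38),
    c("As", 74.9215965,     74.921595),
    c("Sr", 87.9056121,     87.62),
    c("Mo", 97.9054082,     95.95),
    c("Ag", 106.905097,     107.8682),
    c("Cd", 113.9033585,    112.414),
    c("Sn", 119.9021947,    118.710),
    c("Ba", 137.9052472,    137.327),
    c("W",  183.9509312,    183.84),
    c("Pt", 194.9647911,    195.084),
    c("Au", 196.9665687,    196.966569),
    c("Hg", 201.970643,     200.592),
    c("Pb", 207.9766521,    207.2)
  )
  d <- data.frame(
    symbol = x[, 1],
    monoisotopic = as.numeric(x[, 2]),
    average_weight = as.numeric(x[, 3]),
    stringsAsFactors = FALSE
  )
  rownames(d) <- d$symbol
  d
})

#' Physical constants used by the ion-mass calculus
#'
#' @return Named list with `electron_mass` and `proton_mass`, both in Da.
#'   The proton mass is defined as mass(H atom) - electron mass so that a
#'   protonated ion \[M+H\]+ weighs exactly M + proton.
#' @export
mass_constants <- function() {
  list(
    electron_mass = .pb_electron_mass,
    proton_mass = .pb_proton_mass
  )
}

.pb_electron_mass <- 0.000548579909
.pb_proton_mass <- 1.00782503207 - 0.000548579909

.pb_mono <- function(symbol) {
  m <- .pb_elements$monoisotopic[match(symbol, .pb_elements$symbol)]
  if (anyNA(m)) {
    stop("unknown element symbol: ",
         paste(symbol[is.na(m)], collapse = ", "), call. = FALSE)
  }
  m
}

.pb_avg <- function(symbol) {
  m <- .pb_elements$average_weight[match(symbol, .pb_elements$symbol)]
  if (anyNA(m)) {
    stop("unknown element symbol: ",
         paste(symbol[is.na(m)], collapse = ", "), call. = FALSE)
  }
  m
}
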