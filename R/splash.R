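#' SPLASH hash of a mass-spectral peak list
#'
#' Computes the SPLASH (SPectraL hASH) identifier, the hashed,
#' order-invariant identifier used by public spectral repositories to match
#' spectra across databases. The identifier has four hyphen-separated
#' blocks: `"splash10"` (spectrum type 1 = MS, version 0); a 4-character
#' base-36 re-encoding of a wrapped 10-bin / 5-Da base-3 intensity histogram
#' of the 10 most intense ions (ties broken by ascending m/z); a
#' 10-character wrapped 10-bin / 100-Da base-10 intensity histogram of the
#' whole spectrum; and the first 20 hex characters of the SHA-256 digest of
#' the canonical peak string (ions sorted by m/z then intensity, each
#' formatted as `trunc(mz * 1e6):trunc(intensity)`).
#'
#' The output is deterministic and invariant under permutation of the input
#' peak list.
#'
#' @param peaks Data frame (or matrix) with columns `mz` and `intensity`;
#'   m/z must be positive, intensities non-negative.
#' @return SPLASH string, e.g. `"splash10-0udi-0900000000-f5bf6f6a4a1520a35d4f"`.
#' @export
compute_splash <- function(peaks) {
  peaks <- .pb_as_peak_matrix(peaks)
  mz <- peaks[, "mz"]
  intensity <- peaks[, "intensity"]

  paste(
    "splash10",
    .pb_splash_prefilter_block(mz, intensity),
    .pb_splash_histogram(mz, intensity, base = 10L, length = 10L, bin_size = 100),
    .pb_splash_hash_block(mz, intensity),
    sep = "-"
  )
}

.pb_as_peak_matrix <- function(peaks) {
  if (is.data.frame(peaks)) {
    if (!all(c("mz", "intensity") %in% names(peaks))) {
      stop("peak list needs 'mz' and 'intensity' columns", call. = FALSE)
    }
    peaks <- cbind(mz = peaks$mz, intensity = peaks$intensity)
  }
  if (!is.matrix(peaks) || nrow(peaks) < 1) {
    stop("peak list must contain at least one peak", call. = FALSE)
  }
  if (any(!is.finite(peaks)) || any(peaks[, "mz"] <= 0) ||
      any(peaks[, "intensity"] < 0)) {
    stop("peaks require positive m/z and non-negative intensity", call. = FALSE)
  }
  peaks
}

.pb_base36 <- c(as.character(0:9), letters)

# Wrapped histogram block: bin = floor(mz / bin_size) mod length, intensities
# summed per bin, scaled to 0..base-1 against the largest bin, emitted as
# base-36 digit characters.
.pb_splash_histogram <- function(mz, intensity, base, length, bin_size) {
  bins <- numeric(length)
  idx <- (trunc(mz / bin_size) %% length) + 1
  for (k in seq_along(mz)) bins[idx[k]] <- bins[idx[k]] + intensity[k]
  top <- max(bins)
  digits <- if (top > 0) {
    as.integer(1e-7 + (base - 1) * bins / top)
  } else {
    integer(length)
  }
  paste(.pb_base36[digits + 1L], collapse = "")
}

# Prefilter block: top-10 ions by intensity (ties: ascending m/z), 5-Da
# base-3 histogram, re-encoded as a base-36 number padded to 4 characters.
.pb_splash_prefilter_block <- function(mz, intensity) {
  ord <- order(-intensity, mz)
  keep <- ord[seq_len(min(10L, length(ord)))]
  hist3 <- .pb_splash_histogram(mz[keep], intensity[keep],
                                base = 3L, length = 10L, bin_size = 5)
  n <- sum(as.integer(strsplit(hist3, "")[[1]]) * 3^(9:0))
  out <- character(0)
  while (n > 0) {
    out <- c(.pb_base36[(n %% 36) + 1L], out)
    n <- n %/% 36
  }
  paste0(paste(rep("0", 4 - length(out)), collapse = ""),
         paste(out, collapse = ""))
}

# Canonical peak string: sort by (mz, intensity) ascending; fixed-point
# encoding with 6 decimals for m/z, 0 for intensity, truncated toward zero
# after a 1e-7 epsilon correction; SHA-256, first 20 hex chars.
.pb_splash_hash_block <- function(mz, intensity) {
  ord <- order(mz, intensity)
  enc <- paste(
    paste0(sprintf("%.0f", trunc((mz[ord] + 1e-7) * 1e6)), ":",
           sprintf("%.0f", trunc(intensity[ord] + 1e-7))),
    collapse = " "
  )
  substr(digest::digest(enc, algo = "sha256", serialize = FALSE), 1, 20)
}
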