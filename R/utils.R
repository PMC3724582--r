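# Internal helpers shared across modules.

# Deterministic 31-bit stream seed derived from a base seed and a character
# key. Uses exact double arithmetic (modulus < 2^31 keeps products < 2^53).
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "\r")
  h <- as.double(seed %% 2147483629)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h)
}

#' Canonical time-domain feature names
#'
#' The ten per-window amplitude statistics the package computes, in a fixed
#' reference order: IEMG, MAV, MAVS, MPV, RMS, SSI, VAR, MV, WL and SSC.
#'
#' @return Character vector of the ten feature identifiers.
#' @export
emg_features <- function() {
  c("MAV", "MAVS", "RMS", "VAR", "WL", "IEMG", "SSC", "MV", "SSI", "MPV")
}

# Case-insensitive feature-name canonicalization.
match_feature <- function(method) {
  stopifnot(is.character(method), length(method) == 1L)
  idx <- match(toupper(method), emg_features())
  if (is.na(idx)) {
    stop("unknown feature '", method, "'; expected one of: ",
         paste(emg_features(), collapse = ", "))
  }
  emg_features()[idx]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
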