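#' Convert FRET efficiency to inter-dye distance
#'
#' Inverts the Förster relation E = 1 / \[1 + (R/R0)^6\]:
#' R = R0 * (1/E - 1)^(1/6). The Förster radius R0 is the distance at
#' which E = 0.5; for the Alexa 555 / Alexa 647 pair used with STIM1 it
#' was calibrated at 5.8 nm.
#'
#' @param E FRET efficiency, strictly inside (0, 1); vectorized.
#' @param r0 Förster radius in nm (default 5.8).
#' @return Distance in nm.
#' @examples
#' fret_to_distance(0.5)        # 5.8 nm: the Förster radius itself
#' fret_to_distance(0.28, 5.8)  # the low-FRET 242:242' peak
#' @export
fret_to_distance <- function(E, r0 = 5.8) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("'r0' must be a positive number (nm)")
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    stop("E must lie strictly inside (0, 1): distance is undefined at 0 and infinite transfer at 1")
  r0 * (1 / E - 1)^(1 / 6)
}

#' Convert inter-dye distance to FRET efficiency
#'
#' The forward Förster relation E = 1 / \[1 + (R/R0)^6\]; the exact
#' inverse of [fret_to_distance()] on (0, 1) x (0, Inf).
#'
#' @param R distance in nm, > 0; vectorized.
#' @inheritParams fret_to_distance
#' @return FRET efficiency in (0, 1).
#' @export
distance_to_fret <- function(R, r0 = 5.8) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("'r0' must be a positive number (nm)")
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be > 0")
  1 / (1 + (R / r0)^6)
}
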