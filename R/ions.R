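# Ion species and m/z arithmetic for singly charged quasi-molecular ions.

.ion_modes <- data.frame(
  mode = c("[M-H]-", "[M+H]+", "[M+COOH]-", "M+"),
  polarity = c("negative", "positive", "negative", "positive"),
  stringsAsFactors = FALSE
)

#' Supported ion species
#'
#' Singly charged species observed in soft electrospray ionisation of natural
#' products: the deprotonated molecule `[M-H]-`, the protonated molecule
#' `[M+H]+`, the formate adduct `[M+COOH]-`, and the intrinsic cation `M+`
#' for permanently charged quaternary alkaloids (the supplied formula is then
#' the cation's own formula and only the electron mass is corrected).
#'
#' @param polarity Optional filter, `"positive"` or `"negative"`.
#' @return Data frame with columns `mode` and `polarity`.
#' @export
ion_modes <- function(polarity = NULL) {
  out <- .ion_modes
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("positive", "negative"))
    out <- out[out$polarity == polarity, , drop = FALSE]
  }
  out
}

#' Theoretical m/z of an ion species
#'
#' Computes the mass-to-charge ratio of a singly charged ion from the neutral
#' (or, for `"M+"`, cationic) molecular formula:
#' `[M-H]-` = M - proton, `[M+H]+` = M + proton,
#' `[M+COOH]-` = M + mass(HCOOH) - proton, `M+` = M - electron.
#'
#' @param formula Formula string or parsed counts. For mode `"M+"` this must
#'   be the cation's formula.
#' @param mode One of `"[M-H]-"`, `"[M+H]+"`, `"[M+COOH]-"`, `"M+"`.
#' @param digits Decimals the returned value is rounded to; the reporting
#'   convention in high-resolution work is 4 decimals. Use `NA` to disable
#'   rounding (always do so before computing ppm errors in bulk).
#' @return m/z value.
#' @export
#' @examples
#' ion_mz("C15H10O5", "[M-H]-")    # 269.0455
#' ion_mz("C20H18NO4", "M+")       # 336.1230
#' ion_mz("C42H72O14", "[M+COOH]-") # 845.4904
ion_mz <- function(formula, mode, digits = 4) {
  mode <- match.arg(mode, .ion_modes$mode)
  m <- monoisotopic_mass(formula)
  mz <- switch(mode,
    "[M-H]-"    = m - .proton_mass,
    "[M+H]+"    = m + .proton_mass,
    "[M+COOH]-" = m + monoisotopic_mass("CH2O2") - .proton_mass,
    "M+"        = m - .electron_mass
  )
  if (!is.na(digits)) mz <- round(mz, digits)
  mz
}

#' Signed parts-per-million mass error
#'
#' @param observed,theoretical m/z values, both positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0)) {
    stop("m/z values must be positive")
  }
  1e6 * (observed - theoretical) / theoretical
}
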