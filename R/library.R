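# Compound library: records carrying name, molecular formula, compound class,
# intrinsic-cation flag and optional reference retention time.

#' Read a compound library
#'
#' @param path CSV with columns `name`, `formula`, `class`,
#'   `intrinsic_cation` (logical; TRUE for permanently charged quaternary
#'   alkaloids whose `formula` is the cation's formula) and optional
#'   `rt_min` reference retention times.
#' @return Data frame of validated compound records.
#' @export
read_compound_library <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "class", "intrinsic_cation")
  if (!all(need %in% names(tab))) {
    stop("library must have columns: ", paste(need, collapse = ", "))
  }
  if (!"rt_min" %in% names(tab)) tab$rt_min <- NA_real_
  tab$intrinsic_cation <- as.logical(tab$intrinsic_cation)
  bad <- setdiff(tab$class, compound_classes())
  if (length(bad)) stop("unknown compound class(es): ", paste(unique(bad), collapse = ", "))
  invisible(lapply(tab$formula, parse_formula))  # validate formulas
  if (anyDuplicated(tab$name)) stop("duplicate compound names in library")
  tab
}

#' Built-in fixture compound library
#'
#' A library of 73 named natural products of the multi-herb decoction
#' workflow - anthraquinones, flavonoids, alkaloids (including the
#' permanently charged protoberberine and aporphine cations), iridoids,
#' triterpenoid saponins, lignans, coumarins, organic acids, phenylethanoid
#' glycosides, amino acids, steroids, phthalides, nucleosides and a stilbene
#' glycoside - with formulas, classes and reference retention times. It
#' deliberately contains unresolvable exact-mass isomer pairs (e.g.
#' cianidanol/epicatechin, angelicin/psoralen, berberine/epiberberine, the
#' three chlorogenic-acid isomers) to exercise retention-time tie-breaking.
#'
#' @return Data frame of compound records.
#' @export
builtin_compound_library <- function() {
  read_compound_library(
    system.file("extdata", "compound_library.csv", package = "herbmet")
  )
}

# Ion species applicable to a library record in a given polarity.
.record_modes <- function(record, polarity) {
  if (isTRUE(record$intrinsic_cation)) {
    if (polarity == "positive") "M+" else character(0)
  } else if (polarity == "positive") {
    "[M+H]+"
  } else {
    c("[M-H]-", "[M+COOH]-")
  }
}
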