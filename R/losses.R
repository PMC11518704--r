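# Neutral-loss vocabulary: named losses with formula and electron-parity flag.

#' Neutral-loss vocabulary
#'
#' The registered neutral losses used by the fragmentation rulebase: small
#' molecules (H2O, CO, CO2, NH3, CH4, CH3OH, ...), odd-electron radicals
#' (H, CH3, OCH3, CHO, COOH - flagged `radical`), glycosyl residues
#' (Glc 162.0528, Rha 146.0579, Ara, Glua), the caffeoyl group, and the
#' larger class-specific neutral fragments seen in retro-Diels-Alder and
#' ring-opening dissociation. `nominal` is the integer mass used in the
#' field's shorthand (e.g. "[M-H-162]-").
#'
#' @return Data frame with columns `name`, `formula`, `radical`, `nominal`,
#'   and `mass` (monoisotopic, u).
#' @export
#' @examples
#' subset(neutral_losses(), name %in% c("Glc", "Rha", "H2O"))
neutral_losses <- function() {
  if (is.null(.herbmet_env$losses)) {
    path <- system.file("extdata", "neutral_losses.tsv", package = "herbmet")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab$mass <- vapply(tab$formula, monoisotopic_mass, numeric(1))
    stopifnot(all(tab$mass > 0), all(round(tab$mass) == tab$nominal),
              !anyDuplicated(tab$name))
    # the radical flag marks exactly the odd-electron losses
    h_par <- vapply(tab$formula, function(f) {
      cts <- parse_formula(f)
      h <- if ("H" %in% names(cts)) cts[["H"]] else 0L
      n <- if ("N" %in% names(cts)) cts[["N"]] else 0L
      (h + n) %% 2L   # odd H+N count => odd-electron neutral
    }, integer(1))
    stopifnot(all((h_par == 1L) == tab$radical))
    .herbmet_env$losses <- tab
  }
  .herbmet_env$losses
}

#' Monoisotopic mass of a registered neutral loss
#'
#' @param name Loss name in the vocabulary, e.g. `"Glc"`, `"CO2"`.
#' @return Mass in u.
#' @export
#' @examples
#' loss_mass("Glc") # 162.0528
loss_mass <- function(name) {
  tab <- neutral_losses()
  i <- match(name, tab$name)
  if (anyNA(i)) {
    stop("unknown neutral loss: ", paste(name[is.na(i)], collapse = ", "))
  }
  stats::setNames(tab$mass[i], name)
}

.loss_formula <- function(name) {
  tab <- neutral_losses()
  i <- match(name, tab$name)
  if (anyNA(i)) stop("unknown neutral loss: ", name)
  tab$formula[i]
}

.loss_radical <- function(name) {
  tab <- neutral_losses()
  tab$radical[match(name, tab$name)]
}

# TRUE when the loss composition can exist as a neutral (degree of
# unsaturation >= 0, or >= -1/2 for odd-electron radicals). A few vocabulary
# entries are printed-label arithmetic rather than real molecules and are
# excluded from de novo path searches.
.loss_plausible <- function(name) {
  tab <- neutral_losses()
  i <- match(name, tab$name)
  vapply(seq_along(i), function(k) {
    cts <- parse_formula(tab$formula[i[k]])
    g <- function(e) if (e %in% names(cts)) cts[[e]] else 0L
    dbe <- g("C") - g("H") / 2 + g("N") / 2 + 1
    dbe >= if (tab$radical[i[k]]) -0.5 else 0
  }, logical(1))
}
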