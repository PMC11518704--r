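# Exact-mass substrate: element masses, physical constants, formula arithmetic.

# CODATA mass of the proton and electron in unified atomic mass units.
.proton_mass <- 1.007276466621
.electron_mass <- 0.000548579909

.herbmet_env <- new.env(parent = emptyenv())

#' Monoisotopic element mass table
#'
#' Returns the table of monoisotopic atomic masses (unified atomic mass
#' units, u) shipped with the package. The table is immutable after load and
#' covers the elements occurring in small-molecule natural products (C, H, N,
#' O, S, P, halogens, common metals).
#'
#' @return A named numeric vector, element symbol to monoisotopic mass.
#' @export
#' @examples
#' element_masses()[c("C", "H", "O")]
element_masses <- function() {
  if (is.null(.herbmet_env$element_masses)) {
    path <- system.file("extdata", "element_masses.tsv", package = "herbmet")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    m <- stats::setNames(tab$monoisotopic_mass, tab$symbol)
    stopifnot(all(m > 0 | names(m) == "C"), m[["C"]] == 12)
    .herbmet_env$element_masses <- m
  }
  .herbmet_env$element_masses
}

#' Mass of the proton, in u
#' @return Numeric scalar.
#' @export
proton_mass <- function() .proton_mass

#' Mass of the electron, in u
#' @return Numeric scalar.
#' @export
electron_mass <- function() .electron_mass

#' Parse a molecular formula string
#'
#' Parses plain-text molecular formulas such as `"C15H10O5"` into a named
#' integer vector of element counts. Two-letter element symbols (Cl, Br, Na,
#' ...) are recognised; an omitted count means one atom. The parse is strict:
#' any text not consumed by the element-count grammar, or an element absent
#' from [element_masses()], is an error.
#'
#' @param text Formula string, e.g. `"C21H20O10"`.
#' @return Named integer vector of element counts (class `mol_formula`).
#' @export
#' @examples
#' parse_formula("C15H10O5")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("[_ ]", "", text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'")
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- as.integer(ifelse(cnts == "", "1", cnts))
  known <- names(element_masses())
  bad <- setdiff(syms, known)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnts, syms, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (sum(counts) < 1L) stop("formula must contain at least one atom")
  structure(counts, class = "mol_formula")
}

#' Write a formula in Hill order
#'
#' Carbon first, then hydrogen, then all other elements alphabetically
#' (plain alphabetical when no carbon is present).
#'
#' @param counts Named integer vector of element counts, as from
#'   [parse_formula()].
#' @return Canonical formula string.
#' @export
formula_string <- function(counts) {
  counts <- counts[counts > 0]
  syms <- names(counts)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

.as_formula <- function(x) {
  if (is.character(x)) parse_formula(x) else x
}

#' Add two molecular formulas
#' @param a,b Formulas (string or parsed counts).
#' @return Combined counts (class `mol_formula`).
#' @export
formula_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  structure(out, class = "mol_formula")
}

#' Subtract a formula from another
#'
#' Elementwise subtraction; returns `NULL` when the loss is not subtractable
#' (any count would go negative, or nothing would remain), which callers use
#' to prune impossible neutral-loss sequences.
#'
#' @param a,b Formulas (string or parsed counts); `b` is removed from `a`.
#' @return Counts of `a - b`, or `NULL` when not subtractable.
#' @export
formula_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  out <- stats::setNames(integer(length(union(names(a), names(b)))),
                         union(names(a), names(b)))
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L) || sum(out) < 1L) return(NULL)
  structure(out[out > 0L], class = "mol_formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the monoisotopic masses of the constituent atoms.
#'
#' @param formula Formula string or parsed counts.
#' @return Mass in u.
#' @export
#' @examples
#' monoisotopic_mass("H2O")      # 18.0106
#' monoisotopic_mass("C15H10O5") # 270.0528
monoisotopic_mass <- function(formula) {
  counts <- .as_formula(formula)
  masses <- element_masses()
  sum(masses[names(counts)] * as.numeric(counts))
}
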