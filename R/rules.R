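# Declarative compound-class fragmentation rules: diagnostic neutral-loss
# chains plus fixed product-ion formulas (retro-Diels-Alder and alpha-cleavage
# ions), scoreable against observed MS/MS peak lists.

#' Compound-class vocabulary
#'
#' The closed vocabulary of compound classes recognised by the rulebase.
#' @return Character vector of class names.
#' @export
compound_classes <- function() {
  names(builtin_rulebase())
}

#' Read a fragmentation rulebase from JSON
#'
#' The rulebase is a human-editable JSON file: per class, a list of ordered
#' neutral-loss `chains` (names resolved in [neutral_losses()]) and a list of
#' class-characteristic product-ion `fragments`, each with the ion's
#' elemental composition and the polarity it is observed in. Every entry
#' carries a non-negative weight (the shipped file uses unit weights; the
#' reference work gives no weighting scheme).
#'
#' @param path Path to a rulebase JSON file.
#' @return Named list of rules (class `frag_rulebase`); each rule has
#'   elements `class`, `chains`, `chain_weights`, `fragments`,
#'   `fragment_weights`, `minimum_hits`.
#' @export
read_rulebase <- function(path) {
  raw <- jsonlite::read_json(path)
  w0 <- if (!is.null(raw$default_weight)) raw$default_weight else 1.0
  min_hits <- if (!is.null(raw$minimum_hits)) raw$minimum_hits else 1L
  loss_names <- neutral_losses()$name
  rules <- lapply(names(raw$classes), function(cl) {
    spec <- raw$classes[[cl]]
    chains <- lapply(spec$chains, function(ch) unlist(ch, use.names = FALSE))
    unknown <- setdiff(unlist(chains), loss_names)
    if (length(unknown)) {
      stop("rule for class '", cl, "' references unregistered losses: ",
           paste(unknown, collapse = ", "))
    }
    if (!length(chains)) stop("rule for class '", cl, "' has no losses")
    frags <- if (length(spec$fragments)) {
      data.frame(
        formula = vapply(spec$fragments, `[[`, character(1), "formula"),
        polarity = vapply(spec$fragments, `[[`, character(1), "polarity"),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(formula = character(0), polarity = character(0))
    }
    list(class = cl,
         chains = chains,
         chain_weights = rep(w0, length(chains)),
         fragments = frags,
         fragment_weights = rep(w0, nrow(frags)),
         minimum_hits = as.integer(min_hits))
  })
  structure(stats::setNames(rules, names(raw$classes)), class = "frag_rulebase")
}

#' Built-in fragmentation rulebase
#'
#' Rules for the 25 compound classes of the profiling workflow, transcribed
#' from the diagnostic dissociation behaviour of each class: e.g. successive
#' CH3/CO/CO2 losses for anthraquinones, glycosidic-bond cleavage plus
#' C-ring retro-Diels-Alder ions for flavonoids, consecutive CO and CO2 for
#' the coumarin lactone, (CH3)2NH / CH3NH2 for aporphine and
#' benzylisoquinoline alkaloids, glycosyl-residue losses followed by CO2/H2O
#' for iridoids and saponins, and successive NH3/HCOOH for amino acids.
#'
#' @return A `frag_rulebase` (see [read_rulebase()]); cached per session.
#' @export
builtin_rulebase <- function() {
  if (is.null(.herbmet_env$rulebase)) {
    path <- system.file("extdata", "rulebase.json", package = "herbmet")
    .herbmet_env$rulebase <- read_rulebase(path)
  }
  .herbmet_env$rulebase
}

# Elemental composition of the intact precursor ion for an ion species.
.precursor_ion_formula <- function(formula, mode) {
  f <- .as_formula(formula)
  switch(mode,
    "[M-H]-"    = formula_subtract(f, "H"),
    "[M+H]+"    = formula_add(f, "H"),
    "[M+COOH]-" = formula_add(f, "CHO2"),
    "M+"        = f,
    stop("unsupported ion mode: ", mode)
  )
}

.mode_polarity <- function(mode) {
  .ion_modes$polarity[match(mode, .ion_modes$mode)]
}

# m/z of a product-ion composition (the composition is the ion itself,
# so only the electron mass is corrected).
.fragment_ion_mz <- function(formula, polarity) {
  m <- monoisotopic_mass(formula)
  if (polarity == "negative") m + .electron_mass else m - .electron_mass
}

#' Expected diagnostic fragments for a precursor under a class rule
#'
#' Expands the rule's declared neutral-loss chains against a precursor,
#' pruning chains that are not elementwise subtractable from the precursor
#' ion's composition, and appends the rule's fixed product-ion formulas that
#' are contained in the precursor ion and match its polarity. Chains longer
#' than `max_depth` are not expanded; `max_depth = 0` returns only the
#' precursor ion itself.
#'
#' @param formula Neutral molecular formula (or cation formula for `"M+"`).
#' @param mode Ion species, see [ion_modes()].
#' @param rule A single class rule from a `frag_rulebase`.
#' @param max_depth Maximum chain length expanded (default 3; the deepest
#'   routinely printed ladders are three steps, a few glycoside ladders need
#'   four).
#' @return Data frame with columns `label`, `kind`
#'   (`precursor`/`loss`/`fragment`), `losses` (slash-separated names),
#'   `depth`, `radical_steps`, `mz` (4 decimals), `weight`.
#' @export
#' @examples
#' rb <- builtin_rulebase()
#' expected_fragments("C15H10O5", "[M-H]-", rb$anthraquinone)
expected_fragments <- function(formula, mode, rule, max_depth = 3) {
  prec_f <- .precursor_ion_formula(formula, mode)
  if (is.null(prec_f)) stop("precursor formula incompatible with ion mode ", mode)
  prec_mz <- ion_mz(formula, mode, digits = NA)
  polarity <- .mode_polarity(mode)

  rows <- list(data.frame(
    label = mode, kind = "precursor", losses = "", depth = 0L,
    radical_steps = 0L, mz = prec_mz, weight = NA_real_,
    stringsAsFactors = FALSE
  ))
  if (max_depth > 0L) {
    for (i in seq_along(rule$chains)) {
      chain <- rule$chains[[i]]
      if (length(chain) > max_depth) next
      f <- prec_f
      ok <- TRUE
      for (nm in chain) {
        f <- formula_subtract(f, .loss_formula(nm))
        if (is.null(f)) { ok <- FALSE; break }
      }
      if (!ok) next
      mz <- prec_mz - sum(loss_mass(chain))
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0("-", paste(chain, collapse = "-")),
        kind = "loss", losses = paste(chain, collapse = "/"),
        depth = length(chain), radical_steps = sum(.loss_radical(chain)),
        mz = mz, weight = rule$chain_weights[i], stringsAsFactors = FALSE
      )
    }
    if (nrow(rule$fragments)) {
      for (i in seq_len(nrow(rule$fragments))) {
        if (rule$fragments$polarity[i] != polarity) next
        frag_f <- parse_formula(rule$fragments$formula[i])
        if (is.null(formula_subtract(prec_f, frag_f))) next
        rows[[length(rows) + 1L]] <- data.frame(
          label = paste0("frag:", rule$fragments$formula[i]),
          kind = "fragment", losses = "", depth = 1L, radical_steps = 0L,
          mz = .fragment_ion_mz(frag_f, polarity),
          weight = rule$fragment_weights[i], stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  # one row per distinct product composition: keep the shallowest route
  out <- out[order(out$depth, out$label), , drop = FALSE]
  out <- out[!duplicated(round(out$mz, 6)), , drop = FALSE]
  out$mz <- round(out$mz, 4)
  rownames(out) <- NULL
  out
}

#' Score a spectrum against a compound-class rule
#'
#' The score is the weight fraction of the rule's diagnostic entries that are
#' matched by an observed fragment peak within `frag_tol_ppm`, taken over the
#' entries applicable to this precursor (chains subtractable from it,
#' polarity-compatible product ions). A spectrum with no applicable entries,
#' or no fragment peaks, scores 0.
#'
#' @param spectrum An `ms2_spectrum` (see [ms2_spectrum()]).
#' @param formula Candidate molecular formula.
#' @param rule A single class rule.
#' @param mode Ion species of the precursor.
#' @param frag_tol_ppm Fragment match tolerance (default 10 ppm; printed
#'   observed-vs-theoretical gaps in reference spectra reach several ppm).
#' @param max_depth Chain expansion depth, as in [expected_fragments()].
#' @return List with `score` in \[0, 1\], `hits` (data frame: one row per
#'   matched entry with theoretical and observed m/z and signed ppm error),
#'   `n_applicable`, and `min_hits_met`.
#' @export
score_class <- function(spectrum, formula, rule, mode,
                        frag_tol_ppm = 10, max_depth = 3) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  if (spectrum$polarity != .mode_polarity(mode)) {
    stop("spectrum polarity does not match ion mode ", mode)
  }
  exp_df <- expected_fragments(formula, mode, rule, max_depth = max_depth)
  exp_df <- exp_df[exp_df$kind != "precursor", , drop = FALSE]
  empty_hits <- data.frame(label = character(0), theoretical_mz = numeric(0),
                           observed_mz = numeric(0), ppm = numeric(0),
                           weight = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(exp_df)) {
    return(list(score = 0, hits = empty_hits, n_applicable = 0L,
                min_hits_met = FALSE))
  }
  peaks <- spectrum$peaks
  if (!nrow(peaks)) {
    warning("spectrum ", spectrum$id, " has no fragment peaks; score 0")
    return(list(score = 0, hits = empty_hits,
                n_applicable = nrow(exp_df), min_hits_met = FALSE))
  }
  hits <- lapply(seq_len(nrow(exp_df)), function(i) {
    tol <- exp_df$mz[i] * frag_tol_ppm * 1e-6
    d <- abs(peaks$mz - exp_df$mz[i])
    j <- which.min(d)
    if (d[j] <= tol) {
      data.frame(label = exp_df$label[i], theoretical_mz = exp_df$mz[i],
                 observed_mz = peaks$mz[j],
                 ppm = ppm_error(peaks$mz[j], exp_df$mz[i]),
                 weight = exp_df$weight[i], stringsAsFactors = FALSE)
    } else NULL
  })
  hits <- do.call(rbind, c(list(empty_hits), hits))
  score <- if (sum(exp_df$weight) > 0) sum(hits$weight) / sum(exp_df$weight) else 0
  list(score = score, hits = hits, n_applicable = nrow(exp_df),
       min_hits_met = nrow(hits) >= rule$minimum_hits)
}
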