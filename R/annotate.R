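# Library-based spectrum annotation with identification-confidence tiers:
# precursor exact-mass candidate search, class-rule scoring of the fragment
# pattern, retention-time confirmation against reference standards, and
# per-peak neutral-loss path explanation.

.tiers <- c("identified_with_standard", "tentatively_characterized", "unmatched")

#' Search a compound library by precursor exact mass
#'
#' Returns every (compound, ion species) pair whose theoretical m/z lies
#' within `precursor_tol_ppm` of the observed precursor, restricted to
#' species compatible with the spectrum polarity (`[M-H]-` and `[M+COOH]-`
#' in negative mode, `[M+H]+` in positive mode, `M+` for intrinsic cations).
#' Exact-mass isomers are never merged; each is returned as its own
#' candidate.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param library Compound records, see [read_compound_library()].
#' @param precursor_tol_ppm Match tolerance (default 5 ppm).
#' @return Data frame of candidates sorted by `|ppm|`: `name`, `formula`,
#'   `class`, `mode`, `theoretical_mz`, `ppm`, `rt_min`.
#' @export
candidate_search <- function(spectrum, library, precursor_tol_ppm = 5) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), nrow(library) > 0)
  out <- list()
  for (i in seq_len(nrow(library))) {
    rec <- library[i, ]
    for (mode in .record_modes(rec, spectrum$polarity)) {
      theo <- ion_mz(rec$formula, mode, digits = NA)
      ppm <- ppm_error(spectrum$precursor_mz, theo)
      if (abs(ppm) <= precursor_tol_ppm) {
        out[[length(out) + 1L]] <- data.frame(
          name = rec$name, formula = rec$formula, class = rec$class,
          mode = mode, theoretical_mz = round(theo, 4), ppm = ppm,
          rt_min = rec$rt_min, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, c(list(data.frame(
    name = character(0), formula = character(0), class = character(0),
    mode = character(0), theoretical_mz = numeric(0), ppm = numeric(0),
    rt_min = numeric(0), stringsAsFactors = FALSE)), out))
  out[order(abs(out$ppm), out$name), , drop = FALSE]
}

#' Annotate a spectrum against a compound library
#'
#' For each precursor-mass candidate the fragment pattern is scored against
#' the candidate class's diagnostic rule, and an identification-confidence
#' tier is assigned in the convention of reference-standard-based profiling:
#'
#' * `identified_with_standard` - the library record carries a reference
#'   retention time, the spectrum's retention time matches it within
#'   `rt_window_min`, at least one diagnostic rule entry is matched, and the
#'   class score reaches `score_threshold`;
#' * `tentatively_characterized` - precursor exact mass matches and at least
#'   one diagnostic rule entry is matched (a spectrum with no fragment peaks
#'   is capped at this tier, flagged by `n_hits = 0`);
#' * `unmatched` - precursor matches but the fragment pattern supports no
#'   class call.
#'
#' Candidates are ranked by tier, then class score, then `|precursor ppm|`,
#' then name (a deterministic total order; exact-mass isomers with identical
#' scores are separated only by retention time via the tier, mirroring how
#' isomer pairs are resolved against standards).
#'
#' @param spectrum An `ms2_spectrum`.
#' @param library Compound records.
#' @param rulebase A `frag_rulebase` (default [builtin_rulebase()]).
#' @param precursor_tol_ppm,frag_tol_ppm Match tolerances (defaults 5 and
#'   10 ppm; printed observed-vs-theoretical deviations in reference data
#'   reach ~3 ppm, so tighter defaults would reject genuine matches).
#' @param rt_window_min Retention-time window for standard confirmation
#'   (default 0.2 min).
#' @param score_threshold Minimum class score for the top tier.
#' @param max_depth Rule-chain expansion depth.
#' @return Data frame, one row per candidate, ranked; columns of
#'   [candidate_search()] plus `score`, `n_hits`, `rt_match`, `tier`, `rank`.
#' @export
annotate <- function(spectrum, library, rulebase = builtin_rulebase(),
                     precursor_tol_ppm = 5, frag_tol_ppm = 10,
                     rt_window_min = 0.2, score_threshold = 0.5,
                     max_depth = 3) {
  cands <- candidate_search(spectrum, library, precursor_tol_ppm)
  if (!nrow(cands)) {
    cands$score <- numeric(0); cands$n_hits <- integer(0)
    cands$rt_match <- logical(0); cands$tier <- character(0)
    cands$rank <- integer(0)
    return(cands)
  }
  score <- numeric(nrow(cands)); n_hits <- integer(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    rule <- rulebase[[cands$class[i]]]
    sc <- if (nrow(spectrum$peaks)) {
      score_class(spectrum, cands$formula[i], rule, cands$mode[i],
                  frag_tol_ppm = frag_tol_ppm, max_depth = max_depth)
    } else {
      list(score = 0, hits = data.frame())
    }
    score[i] <- sc$score
    n_hits[i] <- nrow(sc$hits)
  }
  rt_match <- !is.na(cands$rt_min) & !is.na(spectrum$rt_min) &
    abs(cands$rt_min - spectrum$rt_min) <= rt_window_min
  tier <- ifelse(
    rt_match & n_hits >= 1L & score >= score_threshold,
    "identified_with_standard",
    ifelse(n_hits >= 1L | nrow(spectrum$peaks) == 0L,
           "tentatively_characterized", "unmatched")
  )
  cands$score <- score
  cands$n_hits <- n_hits
  cands$rt_match <- rt_match
  cands$tier <- tier
  o <- order(match(tier, .tiers), -score, abs(cands$ppm), cands$name)
  cands <- cands[o, , drop = FALSE]
  cands$rank <- seq_len(nrow(cands))
  rownames(cands) <- NULL
  cands
}

#' Annotate many spectra
#'
#' @param spectra List of `ms2_spectrum` objects.
#' @param ... Passed to [annotate()].
#' @return One data frame with a leading `spectrum_id` column, one row per
#'   (spectrum, candidate).
#' @export
annotate_all <- function(spectra, ...) {
  out <- lapply(spectra, function(sp) {
    a <- annotate(sp, ...)
    if (nrow(a)) cbind(spectrum_id = sp$id, a, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Explain fragment peaks as neutral-loss paths
#'
#' Breadth-first search over the registered neutral-loss vocabulary from the
#' assigned precursor composition: each fragment peak is annotated with the
#' minimum-length loss path whose m/z matches within `tol_ppm` (ties among
#' equal-length paths broken by smaller `|ppm|`), or left unassigned. At most
#' `max_radical` odd-electron steps are allowed per path, which matches
#' observed radical-ladder depth and prevents combinatorial blow-up.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param formula Assigned molecular formula (cation formula for `"M+"`).
#' @param mode Ion species of the precursor.
#' @param losses Loss names searched (default: full vocabulary).
#' @param max_depth Maximum path length (default 3).
#' @param tol_ppm Fragment tolerance (default 10).
#' @param max_radical Maximum odd-electron steps per path (default 1).
#' @return List with `peaks` (data frame: `mz`, `intensity`, `path`, `ppm`,
#'   `assigned`) and `intensity_explained`, the assigned fraction of total
#'   intensity (precursor peak counts as assigned with an empty path).
#' @export
explain_peaks <- function(spectrum, formula, mode,
                          losses = neutral_losses()$name,
                          max_depth = 3, tol_ppm = 10, max_radical = 1) {
  prec_f <- .precursor_ion_formula(formula, mode)
  prec_mz <- ion_mz(formula, mode, digits = NA)
  # drop valence-impossible compositions (negative rings-plus-double-bonds;
  # a few exist in the vocabulary only as printed-label arithmetic), then
  # try heavier (glycoside) losses first
  losses <- losses[.loss_plausible(losses)]
  losses <- losses[order(-loss_mass(losses))]
  loss_m <- loss_mass(losses)
  loss_r <- .loss_radical(losses)

  # BFS levels keyed by product composition; first arrival = shortest path.
  states <- list(list(f = prec_f, mz = prec_mz, path = character(0), nrad = 0L))
  seen <- formula_string(prec_f)
  all_states <- states
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in states) {
      for (k in seq_along(losses)) {
        nrad <- st$nrad + loss_r[k]
        if (nrad > max_radical) next
        f2 <- formula_subtract(st$f, .loss_formula(losses[k]))
        if (is.null(f2)) next
        key <- formula_string(f2)
        if (key %in% seen) next
        seen <- c(seen, key)
        nxt[[length(nxt) + 1L]] <- list(f = f2, mz = st$mz - loss_m[[k]],
                                        path = c(st$path, losses[k]),
                                        nrad = nrad)
      }
    }
    if (!length(nxt)) break
    all_states <- c(all_states, nxt)
    states <- nxt
  }
  state_mz <- vapply(all_states, `[[`, numeric(1), "mz")
  state_depth <- lengths(lapply(all_states, `[[`, "path"))

  pk <- spectrum$peaks
  path <- character(nrow(pk)); ppm <- rep(NA_real_, nrow(pk))
  assigned <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    d <- abs(state_mz - pk$mz[i])
    ok <- d <= state_mz * tol_ppm * 1e-6
    if (any(ok)) {
      idx <- which(ok)
      idx <- idx[order(state_depth[idx], d[idx])][1]
      path[i] <- paste(all_states[[idx]]$path, collapse = "-")
      ppm[i] <- ppm_error(pk$mz[i], state_mz[idx])
      assigned[i] <- TRUE
    }
  }
  frac <- if (nrow(pk) && sum(pk$intensity) > 0) {
    sum(pk$intensity[assigned]) / sum(pk$intensity)
  } else NA_real_
  list(peaks = data.frame(mz = pk$mz, intensity = pk$intensity,
                          path = path, ppm = ppm, assigned = assigned,
                          stringsAsFactors = FALSE),
       intensity_explained = frac)
}
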