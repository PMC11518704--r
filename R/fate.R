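# Sequential-metabolism fate assignment from presence/absence of prototype
# compounds across the six in vitro / in vivo sample matrices downstream of
# the dosed extract: artificial gastric juice, mesenteric-vein plasma
# (intestinal metabolism), femoral-vein plasma (hepatic metabolism), systemic
# plasma, urine and feces.

#' Sample-matrix vocabulary
#'
#' The fixed ordered set of matrices of the sequential-metabolism design.
#' `extract` is the prototype universe: every compound is present there.
#' @return Character vector of matrix names.
#' @export
fate_matrices <- function() {
  c("extract", "gastric", "intestinal", "hepatic", "systemic", "urine", "feces")
}

#' Classify the metabolic fate of one compound
#'
#' Deterministic truth-table mapping from a complete presence/absence row to
#' a fate label:
#'
#' * `gastric_stable` - detected after gastric-juice incubation;
#' * `absorbed` - detected in any plasma-derived matrix (intestinal, hepatic
#'   or systemic sampling routes are pooled, as the routes are complementary);
#' * site flags: `degraded_in_stomach` (absent from gastric juice),
#'   `intestinal_barrier_or_metabolism` (survived the stomach but absent from
#'   mesenteric-vein plasma), `hepatic_metabolism` (present in mesenteric-vein
#'   but absent from femoral-vein plasma, i.e. removed on first hepatic pass),
#'   `cleared_from_systemic` (present post-hepatically but absent from
#'   systemic plasma);
#' * `excretion` - subset of `{urine, feces}`, or `none_detected`.
#'
#' @param present Named logical vector over [fate_matrices()]; `extract`
#'   must be `TRUE`.
#' @param compound Compound id used in error messages.
#' @return List with elements `gastric_stable`, `absorbed`, `site_flags`
#'   (character vector), `excretion` (character vector).
#' @export
#' @examples
#' classify_fate(c(extract = TRUE, gastric = TRUE, intestinal = TRUE,
#'                 hepatic = FALSE, systemic = FALSE, urine = FALSE,
#'                 feces = TRUE))
classify_fate <- function(present, compound = "compound") {
  mats <- fate_matrices()
  missing <- setdiff(mats, names(present))
  if (length(missing)) {
    stop("missing matrix value(s) for ", compound, ": ",
         paste(missing, collapse = ", "))
  }
  present <- as.logical(present[mats])
  if (anyNA(present)) stop("NA presence value for ", compound)
  if (!present[1]) stop(compound, " absent from the extract (prototype universe)")
  p <- stats::setNames(as.list(present), mats)
  site <- c(
    if (!p$gastric) "degraded_in_stomach",
    if (p$gastric && !p$intestinal) "intestinal_barrier_or_metabolism",
    if (p$intestinal && !p$hepatic) "hepatic_metabolism",
    if (p$hepatic && !p$systemic) "cleared_from_systemic"
  )
  excretion <- c(if (p$urine) "urine", if (p$feces) "feces")
  if (!length(excretion)) excretion <- "none_detected"
  list(gastric_stable = p$gastric,
       absorbed = p$intestinal || p$hepatic || p$systemic,
       site_flags = if (is.null(site)) character(0) else site,
       excretion = excretion)
}

#' Fate table for a presence matrix
#'
#' Applies [classify_fate()] to every row.
#'
#' @param presence Data frame with a `compound` column and one logical column
#'   per matrix in [fate_matrices()].
#' @return Data frame, one row per compound, with logical fate columns and a
#'   comma-separated `excretion` field.
#' @export
fate_table <- function(presence) {
  stopifnot("compound" %in% names(presence))
  rows <- lapply(seq_len(nrow(presence)), function(i) {
    pr <- unlist(presence[i, fate_matrices()])
    f <- classify_fate(pr, compound = presence$compound[i])
    data.frame(
      compound = presence$compound[i],
      gastric_stable = f$gastric_stable,
      absorbed = f$absorbed,
      degraded_in_stomach = "degraded_in_stomach" %in% f$site_flags,
      intestinal_barrier_or_metabolism =
        "intestinal_barrier_or_metabolism" %in% f$site_flags,
      hepatic_metabolism = "hepatic_metabolism" %in% f$site_flags,
      cleared_from_systemic = "cleared_from_systemic" %in% f$site_flags,
      excretion = paste(f$excretion, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-matrix counts and fate tallies
#'
#' @param presence Presence matrix as in [fate_table()].
#' @return List with `matrix_counts` (named column sums), `n_compounds`,
#'   `n_absorbed`, `n_gastric_stable`, and `fate_tallies` (named counts of
#'   the four site flags and the excretion categories).
#' @export
summarize_presence <- function(presence) {
  ft <- fate_table(presence)
  list(
    n_compounds = nrow(presence),
    matrix_counts = vapply(fate_matrices(),
                           function(m) sum(presence[[m]]), numeric(1)),
    n_gastric_stable = sum(ft$gastric_stable),
    n_absorbed = sum(ft$absorbed),
    fate_tallies = c(
      degraded_in_stomach = sum(ft$degraded_in_stomach),
      intestinal_barrier_or_metabolism = sum(ft$intestinal_barrier_or_metabolism),
      hepatic_metabolism = sum(ft$hepatic_metabolism),
      cleared_from_systemic = sum(ft$cleared_from_systemic),
      excreted_urine = sum(grepl("urine", ft$excretion)),
      excreted_feces = sum(grepl("feces", ft$excretion)),
      excretion_none_detected = sum(ft$excretion == "none_detected")
    )
  )
}

#' Read a presence matrix from TSV/CSV
#'
#' @param path File with a `compound` column plus the seven logical matrix
#'   columns; separator inferred from the extension.
#' @return Data frame suitable for [fate_table()].
#' @export
read_presence_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("compound", fate_matrices())
  if (!all(need %in% names(tab))) {
    stop("presence table must have columns: ", paste(need, collapse = ", "))
  }
  for (m in fate_matrices()) tab[[m]] <- as.logical(tab[[m]])
  tab
}
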