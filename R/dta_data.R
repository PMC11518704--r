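# Activity-table curation and dataset splitting for the drug-target
# interaction screening stage.

#' Curate a raw activity table into binary-labelled records
#'
#' Applies the curation contract used when preparing public bioassay data:
#' duplicate (molecule, target) pairs are dropped keeping the first; records
#' whose line notation contains a multi-component separator (`.`, mixtures)
#' or no carbon atom (inorganic materials) are removed; the activity category
#' `"Active"` maps to label 1 and every other category (`Inactive`,
#' `Inclusive`, `Unspecified`) to label 0.
#'
#' @param table Data frame with columns `smiles`, `target_id`, `sequence`,
#'   `category`, and optionally `substance_id`.
#' @return The curated data frame with a `label` column; dropped records are
#'   reported via message.
#' @export
curate_activity <- function(table) {
  need <- c("smiles", "target_id", "sequence", "category")
  if (!all(need %in% names(table))) {
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  }
  n0 <- nrow(table)
  dup <- duplicated(table[, c("smiles", "target_id")])
  table <- table[!dup, , drop = FALSE]
  mixture <- grepl(".", table$smiles, fixed = TRUE)
  # strip two-letter symbols whose first letter is C before testing for carbon
  stripped <- gsub("Cl|Ca|Cd|Cu|Cr|Co|Ce|Cs|Cn", "", table$smiles)
  no_carbon <- !grepl("[Cc]", stripped)
  empty <- !nzchar(trimws(table$smiles))
  drop <- mixture | no_carbon | empty
  if (any(drop) || any(dup)) {
    message(sum(dup), " duplicate, ", sum(mixture), " mixture, ",
            sum(no_carbon | empty), " carbon-free/empty records removed (",
            n0, " -> ", sum(!drop), ")")
  }
  table <- table[!drop, , drop = FALSE]
  table$label <- as.integer(table$category == "Active")
  rownames(table) <- NULL
  table
}

# Largest-remainder apportionment of n items into fractions; ties in the
# fractional remainders are resolved in favour of the later split.
.lr_sizes <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  exact <- n * fractions
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    rem <- exact - sizes
    o <- order(-rem, -seq_along(rem))  # larger remainder first; later split wins ties
    sizes[o[seq_len(left)]] <- sizes[o[seq_len(left)]] + 1
  }
  as.integer(sizes)
}

#' Split records into train/validation/test partitions
#'
#' Partition sizes follow largest-remainder rounding of the fractions; the
#' assignment is a seeded random shuffle, optionally stratified by label so
#' both classes appear in every partition at close to their global
#' prevalence (the default, since low-prevalence activity data can otherwise
#' leave a partition single-class).
#'
#' @param records Curated data frame with a `label` column.
#' @param fractions Numeric vector summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @param stratify Stratify by `label` (default `TRUE`).
#' @return List of data frames `train`, `validation`, `test`; disjoint and
#'   exhaustive.
#' @export
split_records <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1,
                          stratify = TRUE) {
  stopifnot(nrow(records) >= length(fractions))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)
  # shuffle, then cut by largest-remainder sizes
  assign_part <- function(idx) {
    sizes <- .lr_sizes(length(idx), fractions)
    idx <- sample(idx)
    split(idx, rep(seq_along(fractions), times = sizes))
  }
  parts <- if (stratify && "label" %in% names(records)) {
    by_class <- split(seq_len(nrow(records)), records$label)
    merged <- vector("list", length(fractions))
    for (cls in by_class) {
      p <- assign_part(cls)
      for (k in seq_along(fractions)) {
        merged[[k]] <- c(merged[[k]], p[[as.character(k)]])
      }
    }
    merged
  } else {
    p <- assign_part(seq_len(nrow(records)))
    lapply(as.character(seq_along(fractions)), function(k) p[[k]])
  }
  out <- lapply(parts, function(i) records[sort(i), , drop = FALSE])
  names(out) <- c("train", "validation", "test")[seq_along(out)]
  out
}
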