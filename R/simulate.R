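# Seeded synthetic-data generators with ground truth for every pipeline
# stage: rule-consistent MS/MS spectra with ppm-scale mass noise and decoy
# peaks, presence/absence matrices with known fate proportions, and
# drug-target pairs whose activity follows a plantable pharmacophore/motif
# co-occurrence rule with symmetric label noise.

# Ionisation polarity a class is typically observed in, used when simulating.
.class_polarity <- function(class) {
  positive <- c("amino_acid", "nucleoside", "steroid", "phthalide", "lignan",
                "coumarin", "isoflavone", "tetrahydroprotoberberine",
                "protoberberine", "aporphine", "benzylisoquinoline")
  ifelse(class %in% positive, "positive", "negative")
}

#' Simulate an MS/MS spectrum for a library compound
#'
#' Peaks are the precursor ion plus the compound class's rule-expanded
#' diagnostic fragments, each perturbed multiplicatively by
#' `mz * (1 + delta)`, `delta ~ N(0, ppm_sigma * 1e-6)`. Decoy peaks (one
#' per true peak with probability `decoy_fraction / (1 - decoy_fraction)`,
#' so the expected decoy share of the final peak list equals
#' `decoy_fraction`) are placed uniformly below the precursor and at least
#' 20 ppm away from every true fragment. Intensities are cosmetic
#' (annotation is m/z-driven) and drawn from an exponential or uniform
#' model. The spectrum's retention time is the library reference plus
#' `N(0, rt_jitter_min)` noise.
#'
#' @param record One-row data frame from a compound library.
#' @param rulebase A `frag_rulebase`.
#' @param ppm_sigma Gaussian m/z noise, in ppm (default 2).
#' @param decoy_fraction Expected decoy share of the peak list, in
#'   \[0, 1) (default 0).
#' @param intensity_model `"exponential"` or `"uniform"`.
#' @param max_depth Rule-chain expansion depth.
#' @param rt_jitter_min SD of retention-time noise, minutes.
#' @param id Spectrum identifier.
#' @return List: `spectrum` (an `ms2_spectrum`) and `truth` (compound name,
#'   ion mode, data frame of true peaks with loss labels, decoy m/z values).
#' @export
simulate_spectrum <- function(record, rulebase = builtin_rulebase(),
                              ppm_sigma = 2, decoy_fraction = 0,
                              intensity_model = c("exponential", "uniform"),
                              max_depth = 3, rt_jitter_min = 0.05,
                              id = record$name) {
  stopifnot(decoy_fraction >= 0, decoy_fraction < 1, ppm_sigma >= 0)
  intensity_model <- match.arg(intensity_model)
  polarity <- .class_polarity(record$class)
  mode <- .record_modes(record, polarity)[1]
  rule <- rulebase[[record$class]]
  if (is.null(rule)) stop("no rule for class ", record$class)
  exp_df <- expected_fragments(record$formula, mode, rule, max_depth = max_depth)
  true_mz <- exp_df$mz * (1 + stats::rnorm(nrow(exp_df), 0, ppm_sigma * 1e-6))
  prec_obs <- true_mz[exp_df$kind == "precursor"]

  n_decoy <- if (decoy_fraction > 0) {
    stats::rbinom(1, nrow(exp_df), decoy_fraction / (1 - decoy_fraction))
  } else 0L
  decoys <- numeric(0)
  while (length(decoys) < n_decoy) {
    cand <- stats::runif(1, 100, prec_obs)
    if (all(abs(cand - exp_df$mz) > exp_df$mz * 20e-6)) {
      decoys <- c(decoys, cand)
    }
  }
  frag_mz <- c(true_mz[exp_df$kind != "precursor"], decoys)
  intens <- switch(intensity_model,
    exponential = stats::rexp(length(frag_mz)),
    uniform = stats::runif(length(frag_mz))
  )
  intens <- if (length(intens)) intens / max(intens) else intens
  sp <- ms2_spectrum(
    id = id, polarity = polarity, precursor_mz = prec_obs,
    mz = frag_mz, intensity = intens,
    rt_min = if (is.na(record$rt_min)) NA_real_ else
      record$rt_min + stats::rnorm(1, 0, rt_jitter_min)
  )
  list(spectrum = sp,
       truth = list(name = record$name, mode = mode,
                    peaks = data.frame(label = exp_df$label,
                                       theoretical_mz = exp_df$mz,
                                       observed_mz = true_mz,
                                       stringsAsFactors = FALSE),
                    decoys = decoys))
}

#' Simulate a batch of spectra from a library
#'
#' Samples `n` compounds (with replacement) from the library and simulates
#' one spectrum each; seeded and deterministic.
#'
#' @param library Compound records.
#' @param n Number of spectra.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_spectrum()].
#' @return List with `spectra` (list of `ms2_spectrum`) and `truth`
#'   (data frame: `spectrum_id`, `name`, `mode`).
#' @export
simulate_spectra <- function(library, n, seed = 1, ...) {
  set.seed(seed)
  picks <- sample(nrow(library), n, replace = TRUE)
  sims <- lapply(seq_len(n), function(k) {
    simulate_spectrum(library[picks[k], ], id = paste0("sim_", k), ...)
  })
  list(
    spectra = lapply(sims, `[[`, "spectrum"),
    truth = data.frame(
      spectrum_id = paste0("sim_", seq_len(n)),
      name = library$name[picks],
      mode = vapply(sims, function(s) s$truth$mode, character(1)),
      stringsAsFactors = FALSE
    )
  )
}

#' The 64 possible downstream presence patterns
#'
#' All combinations of presence over the six matrices downstream of the
#' extract (which is always present).
#' @return Data frame of 64 logical rows, columns `gastric` ... `feces`.
#' @export
fate_pattern_space <- function() {
  mats <- setdiff(fate_matrices(), "extract")
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(mats)))
  names(patterns) <- mats
  patterns
}

# Default pattern distribution: a sequential-passage chain emulating an
# orally dosed herbal extract - high gastric stability, majority intestinal
# absorption, partial hepatic extraction and systemic clearance, and
# excretion odds that differ between absorbed and unabsorbed compounds.
.default_fate_probs <- function() {
  pat <- fate_pattern_space()
  p <- numeric(nrow(pat))
  for (i in seq_len(nrow(pat))) {
    g <- pat$gastric[i]; it <- pat$intestinal[i]; h <- pat$hepatic[i]
    s <- pat$systemic[i]; u <- pat$urine[i]; fe <- pat$feces[i]
    pg <- if (g) 0.95 else 0.05
    pi_ <- if (!g) { if (it) 0 else 1 } else if (it) 0.70 else 0.30
    ph <- if (!it) { if (h) 0 else 1 } else if (h) 0.80 else 0.20
    ps <- if (!h) { if (s) 0 else 1 } else if (s) 0.85 else 0.15
    absorbed <- it || h || s
    pu <- if (absorbed) { if (u) 0.55 else 0.45 } else if (u) 0.05 else 0.95
    pf <- if (absorbed) { if (fe) 0.50 else 0.50 } else if (fe) 0.80 else 0.20
    p[i] <- pg * pi_ * ph * ps * pu * pf
  }
  p / sum(p)
}

#' Simulate a presence/absence matrix with known fate ground truth
#'
#' Rows are drawn i.i.d. from a probability vector over the 64 downstream
#' presence patterns ([fate_pattern_space()]); `extract` is always `TRUE`.
#' The default distribution emulates an orally dosed extract with high
#' gastric stability and majority intestinal absorption.
#'
#' @param n Number of compounds.
#' @param pattern_probs Length-64 probability vector over
#'   [fate_pattern_space()] rows (default: built-in chain model).
#' @param seed Integer seed.
#' @return List: `presence` (data frame with `compound` plus the seven
#'   matrix columns), `pattern_counts` (drawn count per pattern), and
#'   `expected_tallies` (exact fate tallies implied by the drawn patterns -
#'   the generator's bookkeeping, which [summarize_presence()] must
#'   recover).
#' @export
simulate_presence <- function(n, pattern_probs = NULL, seed = 1) {
  pat <- fate_pattern_space()
  if (is.null(pattern_probs)) pattern_probs <- .default_fate_probs()
  stopifnot(length(pattern_probs) == nrow(pat),
            abs(sum(pattern_probs) - 1) < 1e-8, all(pattern_probs >= 0))
  set.seed(seed)
  draw <- sample(nrow(pat), n, replace = TRUE, prob = pattern_probs)
  presence <- cbind(
    data.frame(compound = sprintf("cpd_%04d", seq_len(n)),
               extract = TRUE, stringsAsFactors = FALSE),
    pat[draw, , drop = FALSE]
  )
  rownames(presence) <- NULL
  counts <- tabulate(draw, nbins = nrow(pat))
  bookkeeping <- summarize_presence(presence)
  list(presence = presence, pattern_counts = counts,
       expected_tallies = bookkeeping$fate_tallies,
       n_absorbed = bookkeeping$n_absorbed)
}

# -- drug-target pair generator ---------------------------------------------

.dta_fragments <- c("C", "CC", "CCO", "CN", "CO", "C(=O)", "C(C)", "c1ccccc1")
.dta_pharmacophore <- "C(=O)NC(=O)"   # imide substructure, only plantable
.dta_motif <- "WHKCW"                 # rare 5-mer planted into proteins

#' Simulate drug-target activity pairs with a plantable interaction rule
#'
#' Molecules are random SMILES chains over a small fragment alphabet; with
#' molecule-dependent probability an imide pharmacophore token is inserted
#' (the fragment alphabet cannot produce it by accident). Proteins are
#' uniform random amino-acid sequences; with probability 1/2 a fixed 5-mer
#' motif is planted. The interaction rule is the co-occurrence
#' `pharmacophore AND motif`; the observed label is `rule XOR
#' Bernoulli(label_noise)`. The pharmacophore probability is solved from
#' `balance` and `label_noise` so that the expected positive fraction equals
#' `balance`.
#'
#' Because the noise is symmetric, no scorer can exceed an expected AUROC of
#' `1 - label_noise` against the noisy labels; that closed-form ceiling is
#' returned as `bayes_auroc_noisy`. The noise-free `rule` column is the
#' ground-truth sidecar against which discrimination is measured.
#'
#' @param n Number of pairs.
#' @param balance Expected positive-label fraction (default 0.13, the
#'   prevalence regime of curated public senolytic-activity data).
#' @param label_noise Symmetric flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @param protein_length Range of protein lengths (default 80-150).
#' @param mol_tokens Range of fragment tokens per molecule.
#' @return List with `records` (data frame: `substance_id`, `smiles`,
#'   `target_id`, `sequence`, `category`, `label`, `rule`),
#'   `bayes_auroc_noisy`, and the generator settings.
#' @export
simulate_dta <- function(n, balance = 0.13, label_noise = 0.05, seed = 1,
                         protein_length = c(80, 150), mol_tokens = c(3, 8)) {
  stopifnot(label_noise >= 0, label_noise < 0.5, balance > 0, balance < 1)
  p_motif <- 0.5
  p_both <- (balance - label_noise) / (1 - 2 * label_noise)
  if (p_both <= 0 || p_both > p_motif) {
    stop("balance not reachable with this label_noise")
  }
  p_pharm <- p_both / p_motif
  set.seed(seed)
  aa20 <- setdiff(protein_alphabet(), c("B", "Z", "X"))

  has_pharm <- stats::runif(n) < p_pharm
  has_motif <- stats::runif(n) < p_motif
  smiles <- vapply(seq_len(n), function(i) {
    k <- sample(mol_tokens[1]:mol_tokens[2], 1)
    toks <- sample(.dta_fragments, k, replace = TRUE)
    if (has_pharm[i]) {
      pos <- sample(k + 1L, 1)
      toks <- append(toks, .dta_pharmacophore, after = pos - 1L)
    }
    paste(toks, collapse = "")
  }, character(1))
  sequence <- vapply(seq_len(n), function(i) {
    len <- sample(protein_length[1]:protein_length[2], 1)
    s <- sample(aa20, len, replace = TRUE)
    if (has_motif[i]) {
      at <- sample(len - nchar(.dta_motif) + 1L, 1)
      s[at:(at + nchar(.dta_motif) - 1L)] <- strsplit(.dta_motif, "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))

  rule <- as.integer(has_pharm & has_motif)
  flip <- stats::rbinom(n, 1, label_noise)
  label <- as.integer(xor(rule == 1L, flip == 1L))
  neg_cats <- c("Inactive", "Inclusive", "Unspecified")
  records <- data.frame(
    substance_id = sprintf("SID%06d", seq_len(n)),
    smiles = smiles,
    target_id = sprintf("T%04d", seq_len(n)),
    sequence = sequence,
    category = ifelse(label == 1L, "Active",
                      sample(neg_cats, n, replace = TRUE,
                             prob = c(0.8, 0.1, 0.1))),
    label = label,
    rule = rule,
    stringsAsFactors = FALSE
  )

  # closed-form expected AUROC of the Bayes-optimal scorer vs noisy labels
  eps <- label_noise
  pos <- eps + p_both * (1 - 2 * eps)
  q <- if (pos > 0) p_both * (1 - eps) / pos else 0          # P(rule=1 | y=1)
  r <- if (pos < 1) p_both * eps / (1 - pos) else 0          # P(rule=1 | y=0)
  bayes <- q * (1 - r) + 0.5 * (q * r + (1 - q) * (1 - r))
  list(records = records, bayes_auroc_noisy = bayes,
       p_pharmacophore = p_pharm, p_motif = p_motif,
       motif = .dta_motif, pharmacophore = .dta_pharmacophore,
       balance = balance, label_noise = label_noise, seed = seed)
}
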