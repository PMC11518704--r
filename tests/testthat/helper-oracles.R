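# Shared helpers: tolerance expectations and independent brute-force oracles.

expect_within_ppm <- function(actual, expected, ppm) {
  expect_lte(abs(1e6 * (actual - expected) / expected), ppm)
}

# Independent monoisotopic-mass oracle: a literal sum over IUPAC atomic
# masses, written without the package's formula machinery.
oracle_masses <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                   O = 15.9949146196, S = 31.9720710015, P = 30.973761632)
oracle_mass <- function(counts) {
  sum(oracle_masses[names(counts)] * counts)
}

# Brute-force AUROC: average pairwise comparison over all (positive,
# negative) score pairs, ties worth 1/2.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force average precision: walk every distinct threshold, computing
# the confusion matrix by explicit counting.
oracle_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  prev_recall <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    recall <- tp / np
    precision <- tp / (tp + fp)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Brute-force best-F1 operating point.
oracle_f1 <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  best <- list(f1 = -1)
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- np - tp; tn <- nn - fp
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best$f1) {
      best <- list(f1 = f1, sensitivity = tp / np, specificity = tn / nn,
                   accuracy = (tp + tn) / (np + nn), threshold = t)
    }
  }
  best
}

# Small reusable fixtures.
fixture_library <- function() builtin_compound_library()
fixture_record <- function(name) {
  lib <- fixture_library()
  lib[lib$name == name, , drop = FALSE]
}
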