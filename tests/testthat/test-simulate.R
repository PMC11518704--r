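# Seeded generators: rule-consistent spectra, presence matrices, activity pairs.

test_that("a noiseless, decoy-free spectrum is exactly the rule ladder", {
  rec <- fixture_record("emodin")
  sim <- simulate_spectrum(rec, ppm_sigma = 0, decoy_fraction = 0)
  exp_df <- expected_fragments(rec$formula, "[M-H]-",
                               builtin_rulebase()$anthraquinone)
  expect_equal(sim$spectrum$precursor_mz,
               exp_df$mz[exp_df$kind == "precursor"], tolerance = 1e-6)
  expect_setequal(round(sim$spectrum$peaks$mz, 4),
                  exp_df$mz[exp_df$kind != "precursor"])
  expect_true(all(c(241.0506, 225.0557, 197.0608) %in%
                    round(sim$spectrum$peaks$mz, 4)))
  # ground truth records every true peak's loss path
  expect_equal(nrow(sim$truth$peaks), nrow(exp_df))
  expect_length(sim$truth$decoys, 0)
})

test_that("decoys arrive at the configured rate, off-grid", {
  rec <- fixture_record("ginsenoside_Re")
  set.seed(11)
  counts <- replicate(40, {
    sim <- simulate_spectrum(rec, ppm_sigma = 0, decoy_fraction = 0.3)
    c(length(sim$truth$decoys), nrow(sim$truth$peaks))
  })
  n_true <- counts[2, 1]
  # decoy count ~ binomial(n_true, f/(1-f)): expected peak-list share ~0.3
  share <- sum(counts[1, ]) / sum(counts[1, ] + counts[2, ])
  expect_gt(share, 0.2); expect_lt(share, 0.4)
  sim <- simulate_spectrum(rec, ppm_sigma = 0, decoy_fraction = 0.3)
  for (d in sim$truth$decoys) {
    expect_true(all(abs(d - sim$truth$peaks$theoretical_mz) >
                      sim$truth$peaks$theoretical_mz * 20e-6))
  }
})

test_that("spectrum batches are seed-deterministic down to the MGF bytes", {
  lib <- fixture_library()
  a <- simulate_spectra(lib, 10, seed = 21, ppm_sigma = 2, decoy_fraction = 0.3)
  b <- simulate_spectra(lib, 10, seed = 21, ppm_sigma = 2, decoy_fraction = 0.3)
  fa <- tempfile(fileext = ".mgf"); fb <- tempfile(fileext = ".mgf")
  write_mgf(a$spectra, fa); write_mgf(b$spectra, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$truth, b$truth)
})

test_that("annotation of noiseless simulated spectra recovers every fixture compound", {
  lib <- fixture_library()
  rb <- builtin_rulebase()
  set.seed(4)
  for (i in seq_len(nrow(lib))) {
    sim <- simulate_spectrum(lib[i, ], ppm_sigma = 0, decoy_fraction = 0,
                             rt_jitter_min = 0)
    ann <- annotate(sim$spectrum, lib, rb)
    expect_equal(ann$name[1], lib$name[i])
    expect_equal(ann$score[1], 1.0)
  }
})

test_that("point-mass presence patterns behave as configured", {
  pat <- fate_pattern_space()
  all_present <- which(apply(pat, 1, all))
  p <- numeric(64); p[all_present] <- 1
  sim <- simulate_presence(50, pattern_probs = p, seed = 1)
  expect_equal(summarize_presence(sim$presence)$n_absorbed, 50)

  gastric_absent <- which(apply(!pat, 1, all))
  p2 <- numeric(64); p2[gastric_absent] <- 1
  sim2 <- simulate_presence(30, pattern_probs = p2, seed = 1)
  ft <- fate_table(sim2$presence)
  expect_true(all(ft$degraded_in_stomach))
  expect_false(any(ft$absorbed))
})

test_that("summaries recover the generator's exact bookkeeping, and mixed tallies sit within binomial noise", {
  sim <- simulate_presence(10000, seed = 17)
  s <- summarize_presence(sim$presence)
  expect_identical(s$fate_tallies, sim$expected_tallies)
  expect_identical(s$n_absorbed, sim$n_absorbed)
  # drawn pattern counts within 3 sigma of the sampling distribution
  probs <- herbmet:::.default_fate_probs()
  for (k in which(probs > 0.005)) {
    expected <- 10000 * probs[k]
    sigma <- sqrt(10000 * probs[k] * (1 - probs[k]))
    expect_lt(abs(sim$pattern_counts[k] - expected), 3 * sigma + 1)
  }
})

test_that("activity-pair generation honours balance, noise and seeding", {
  clean <- simulate_dta(400, balance = 0.2, label_noise = 0, seed = 5)
  expect_equal(clean$bayes_auroc_noisy, 1.0)
  expect_identical(clean$records$label, clean$records$rule)

  sim <- simulate_dta(2000, balance = 0.13, label_noise = 0.05, seed = 5)
  expect_gt(mean(sim$records$label), 0.13 - 3 * sqrt(0.13 * 0.87 / 2000))
  expect_lt(mean(sim$records$label), 0.13 + 3 * sqrt(0.13 * 0.87 / 2000))
  # symmetric-noise ceiling is below 1 and computed in closed form
  expect_lt(sim$bayes_auroc_noisy, 1)
  # label = rule XOR flip at the configured rate
  flips <- mean(sim$records$label != sim$records$rule)
  expect_lt(abs(flips - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  again <- simulate_dta(2000, balance = 0.13, label_noise = 0.05, seed = 5)
  expect_identical(sim$records, again$records)
  # the planted motif appears exactly in motif-bearing proteins
  has_motif <- grepl(sim$motif, sim$records$sequence, fixed = TRUE)
  has_pharm <- grepl(sim$pharmacophore, sim$records$smiles, fixed = TRUE)
  expect_identical(sim$records$rule, as.integer(has_motif & has_pharm))
})
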