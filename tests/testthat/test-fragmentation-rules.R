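# Rulebase structure, fragment-ladder expansion, and class scoring.

test_that("every compound class has a rule whose losses resolve", {
  rb <- builtin_rulebase()
  expect_setequal(
    names(rb),
    c("anthraquinone", "flavone", "isoflavone", "flavanone", "flavonol",
      "flavanol", "tetrahydroprotoberberine", "protoberberine", "aporphine",
      "benzylisoquinoline", "iridoid", "triterpenoid", "triterpenoid_saponin",
      "lignan", "coumarin", "quinic_acid_derivative", "phenolic_acid",
      "aliphatic_acid", "phenylethanoid_glycoside", "amino_acid", "steroid",
      "phthalide", "nucleoside", "stilbene", "other")
  )
  vocab <- neutral_losses()$name
  for (rule in rb) {
    expect_gte(length(rule$chains), 1)
    expect_true(all(unlist(rule$chains) %in% vocab))
    expect_true(all(rule$chain_weights >= 0))
  }
  chain_txt <- function(cl) vapply(rb[[cl]]$chains, paste, "", collapse = "+")
  expect_true(all(c("CH3", "CO", "CO2", "CO+CO2") %in% chain_txt("anthraquinone")))
  expect_true(all(c("CO", "CO2", "CO+CO", "CO+CO2") %in% chain_txt("coumarin")))
  expect_true(all(c("caffeoyl", "Rha", "Glc", "H2O") %in%
                    chain_txt("phenylethanoid_glycoside")))
})

test_that("chain expansion enumerates subtractable sequences with exact m/z", {
  rb <- builtin_rulebase()
  em <- expected_fragments("C15H10O5", "[M-H]-", rb$anthraquinone)
  expect_true(all(c(241.0506, 225.0557) %in% em$mz))
  # depth zero keeps only the precursor
  d0 <- expected_fragments("C15H10O5", "[M-H]-", rb$anthraquinone, max_depth = 0)
  expect_identical(d0$kind, "precursor")
  # unsubtractable chains are pruned, not an error: amino-acid NH3 losses
  # cannot leave a nitrogen-free anthraquinone precursor
  aa <- expected_fragments("C15H10O5", "[M-H]-", rb$amino_acid)
  expect_false(any(grepl("NH3", aa$label)))
  # iridoid glycoside ladder reaches the four-step loss at depth 4
  gen <- expected_fragments("C16H22O10", "[M-H]-", rb$iridoid, max_depth = 4)
  expect_true(all(c(211.0612, 167.0714, 149.0608, 123.0452) %in% gen$mz))
  # product compositions are unique
  expect_false(any(duplicated(gen$mz)))
})

test_that("class scoring is the matched weight fraction over applicable entries", {
  rb <- builtin_rulebase()
  rec <- fixture_record("emodin")
  # noiseless synthetic spectrum from the rule itself scores 1
  sim <- simulate_spectrum(rec, ppm_sigma = 0, decoy_fraction = 0)
  sc <- score_class(sim$spectrum, rec$formula, rb$anthraquinone, "[M-H]-")
  expect_equal(sc$score, 1.0)
  expect_true(sc$min_hits_met)
  expect_true(all(abs(sc$hits$ppm) < 0.5))
  # the same spectrum carries no amino-acid diagnostics
  sc0 <- score_class(sim$spectrum, rec$formula, rb$amino_acid, "[M-H]-")
  expect_equal(sc0$score, 0)
  # half the applicable peaks at equal weights scores 1/2
  full <- expected_fragments(rec$formula, "[M-H]-", rb$anthraquinone)
  frag <- full[full$kind != "precursor", ]
  half <- frag[seq_len(nrow(frag)) <= nrow(frag) / 2, ]
  sp_half <- ms2_spectrum("half", "negative", full$mz[full$kind == "precursor"],
                          mz = half$mz)
  sc_half <- score_class(sp_half, rec$formula, rb$anthraquinone, "[M-H]-")
  expect_equal(sc_half$score, nrow(half) / nrow(frag))
})

test_that("adding a matched diagnostic peak never decreases the score", {
  rb <- builtin_rulebase()
  rec <- fixture_record("rutin")
  full <- expected_fragments(rec$formula, "[M-H]-", rb$flavonol)
  prec <- full$mz[full$kind == "precursor"]
  frag_mz <- full$mz[full$kind != "precursor"]
  prev <- -1
  for (k in seq_along(frag_mz)) {
    sp <- ms2_spectrum("inc", "negative", prec, mz = sort(frag_mz[seq_len(k)]))
    sc <- score_class(sp, rec$formula, rb$flavonol, "[M-H]-")
    expect_gte(sc$score, prev)
    prev <- sc$score
  }
  expect_equal(prev, 1.0)
})

test_that("scoring identical inputs is deterministic", {
  rb <- builtin_rulebase()
  rec <- fixture_record("cosmosiin")
  set.seed(5)
  sim <- simulate_spectrum(rec, ppm_sigma = 2, decoy_fraction = 0.3)
  a <- score_class(sim$spectrum, rec$formula, rb$flavone, "[M-H]-")
  b <- score_class(sim$spectrum, rec$formula, rb$flavone, "[M-H]-")
  expect_identical(a, b)
})

test_that("an empty spectrum scores zero with a warning", {
  rb <- builtin_rulebase()
  sp <- ms2_spectrum("empty", "negative", 269.0455)
  expect_warning(sc <- score_class(sp, "C15H10O5", rb$anthraquinone, "[M-H]-"),
                 "no fragment peaks")
  expect_equal(sc$score, 0)
})
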