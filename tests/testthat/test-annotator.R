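# Candidate search, confidence tiers, ranking, and peak explanation.

test_that("candidate search matches precursor mass within tolerance and polarity", {
  lib <- fixture_library()
  sp <- ms2_spectrum("s1", "negative", 269.0456)
  hits <- candidate_search(sp, lib)
  expect_true("emodin" %in% hits$name)
  expect_true(all(abs(hits$ppm) <= 5))
  # same m/z in positive mode: deprotonated species are not considered
  sp_pos <- ms2_spectrum("s2", "positive", 269.0456)
  expect_false("emodin" %in% candidate_search(sp_pos, lib)$name)
  # exact-mass isomers are both returned, never merged
  sp_iso <- ms2_spectrum("s3", "negative", 289.0720)
  iso <- candidate_search(sp_iso, lib)
  expect_true(all(c("cianidanol", "epicatechin") %in% iso$name))
})

test_that("tightening the tolerance never adds candidates", {
  lib <- fixture_library()
  sp <- ms2_spectrum("s", "negative", 269.0460)  # ~1.7 ppm off emodin
  for (tol in c(10, 5, 2, 1, 0.5)) {
    loose <- candidate_search(sp, lib, precursor_tol_ppm = tol * 2)$name
    tight <- candidate_search(sp, lib, precursor_tol_ppm = tol)$name
    expect_true(all(tight %in% loose))
  }
})

test_that("annotation tiers follow the standard-confirmation rules", {
  lib <- fixture_library()
  rec <- fixture_record("cosmosiin")
  # rule-derived spectrum without RT: tentative, cosmosiin on top
  frag <- expected_fragments(rec$formula, "[M-H]-", builtin_rulebase()$flavone)
  sp <- ms2_spectrum("c1", "negative", frag$mz[frag$kind == "precursor"],
                     mz = frag$mz[frag$kind != "precursor"])
  ann <- annotate(sp, lib)
  expect_equal(ann$name[1], "cosmosiin")
  expect_equal(ann$tier[1], "tentatively_characterized")
  # adding a matching retention time promotes to the standard tier
  sp_rt <- ms2_spectrum("c2", "negative", frag$mz[frag$kind == "precursor"],
                        mz = frag$mz[frag$kind != "precursor"],
                        rt_min = rec$rt_min + 0.05)
  ann_rt <- annotate(sp_rt, lib)
  expect_equal(ann_rt$tier[ann_rt$name == "cosmosiin"], "identified_with_standard")
  expect_equal(ann_rt$name[1], "cosmosiin")
})

test_that("retention time separates exact-mass isomer candidates", {
  lib <- fixture_library()
  rec <- fixture_record("epicatechin")  # isomer of cianidanol, same class
  frag <- expected_fragments(rec$formula, "[M-H]-", builtin_rulebase()$flavanol)
  sp <- ms2_spectrum("iso", "negative", frag$mz[frag$kind == "precursor"],
                     mz = frag$mz[frag$kind != "precursor"],
                     rt_min = rec$rt_min)
  ann <- annotate(sp, lib)
  expect_equal(ann$name[1], "epicatechin")
  expect_true(ann$rank[ann$name == "epicatechin"] <
                ann$rank[ann$name == "cianidanol"])
})

test_that("a peakless spectrum yields a precursor-only tentative match", {
  lib <- fixture_library()
  sp <- ms2_spectrum("bare", "negative", 269.0455)
  ann <- annotate(sp, lib)
  expect_true(nrow(ann) >= 1)
  expect_true(all(ann$tier == "tentatively_characterized"))
  expect_true(all(ann$n_hits == 0))
})

test_that("annotation is invariant to peak input order", {
  lib <- fixture_library()
  rec <- fixture_record("rutin")
  frag <- expected_fragments(rec$formula, "[M-H]-", builtin_rulebase()$flavonol)
  mzs <- frag$mz[frag$kind != "precursor"]
  prec <- frag$mz[frag$kind == "precursor"]
  a <- annotate(ms2_spectrum("o1", "negative", prec, mz = mzs), lib)
  set.seed(2)
  b <- annotate(ms2_spectrum("o2", "negative", prec, mz = sample(mzs)), lib)
  expect_equal(a$name, b$name)
  expect_equal(a$score, b$score)
})

test_that("peak explanation finds minimal loss paths and flags decoys", {
  # rutin radical aglycone: three-step path Glc, Rha, H
  sp <- ms2_spectrum("r", "negative", 609.1461, mz = c(300.0273, 555.5555))
  ex <- explain_peaks(sp, "C27H30O16", "[M-H]-")
  expect_equal(ex$peaks$path[1], "Glc-Rha-H")
  expect_false(ex$peaks$assigned[2])  # off-grid decoy stays unassigned
  # the precursor peak itself carries an empty path
  sp2 <- ms2_spectrum("p", "negative", 609.1461, mz = 609.1461)
  ex2 <- explain_peaks(sp2, "C27H30O16", "[M-H]-")
  expect_true(ex2$peaks$assigned[1])
  expect_equal(ex2$peaks$path[1], "")
})

test_that("MGF output round-trips spectra losslessly", {
  rec <- fixture_record("geniposidic_acid")
  set.seed(9)
  sim <- simulate_spectrum(rec, ppm_sigma = 2, decoy_fraction = 0.3)
  path <- tempfile(fileext = ".mgf")
  write_mgf(sim$spectrum, path)
  back <- read_mgf(path)[[1]]
  expect_equal(back$polarity, sim$spectrum$polarity)
  expect_equal(back$precursor_mz, sim$spectrum$precursor_mz, tolerance = 1e-6)
  expect_equal(back$peaks$mz, sim$spectrum$peaks$mz, tolerance = 1e-6)
  expect_equal(back$rt_min, sim$spectrum$rt_min, tolerance = 1e-4)
})

test_that("the peak-table CSV dialect reads into spectra", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    id = c("a", "a", "b"), polarity = c("negative", "negative", "positive"),
    precursor_mz = c(269.0455, 269.0455, 166.0863),
    mz = c(225.0557, 241.0506, 120.0808),
    intensity = c(0.5, 1, 1), rt_min = c(13.5, 13.5, 2.8)
  ), path, row.names = FALSE)
  sps <- read_peaks_csv(path)
  expect_length(sps, 2)
  expect_equal(nrow(sps[["a"]]$peaks), 2)
  expect_equal(sps[["b"]]$polarity, "positive")
})
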