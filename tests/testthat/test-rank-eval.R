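# Multi-fingerprint similarity, round-trip ranking, the top-k protocol's
# mechanics, and challenge filtering/scoring.

test_that("typical similarity is the max over encodings, symmetric, 1 on identity", {
  id <- typical_similarity("CCO", "OCC")  # same molecule, different writing
  expect_equal(id$score, 1.0)
  expect_true(all(id$per_encoding == 1.0))

  a <- "c1ccccc1"; b <- "c1ccncc1"
  ts <- typical_similarity(a, b)
  per <- vapply(names(ts$per_encoding), function(enc) tanimoto(a, b, enc),
                numeric(1))
  expect_equal(unname(ts$score), max(per))
  expect_identical(unname(ts$encoding), names(per)[which.max(per)])
  expect_true(all(ts$score >= per))

  ts_ba <- typical_similarity(b, a)
  expect_equal(ts$score, ts_ba$score)
  expect_equal(ts$per_encoding, ts_ba$per_encoding)
})

test_that("each individual encoding scores 1 on self and within [0,1] across fixtures", {
  smis <- utils::head(fixture_smiles(10), 4)
  for (enc in c("path", "atom_pair", "torsion", "maccs", "circular",
                "pattern")) {
    expect_equal(tanimoto(smis[1], smis[1], enc), 1.0, label = enc)
    s <- tanimoto(smis[1], smis[2], enc)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("round-trip ranking puts a candidate first against its own spectrum", {
  smis <- fixture_smiles(5)
  sp <- fragment_molecule(smis[2])
  rr <- roundtrip_rank(smis, sp$peaks)
  expect_identical(rr$smiles[1], smis[2])
  expect_equal(rr$score[1], 1.0)
  expect_identical(rr$rank, seq_along(smis))
  expect_false(is.unsorted(rev(rr$score)))
})

test_that("round-trip ranking matches a dense-vector cosine table", {
  smis <- fixture_smiles(5)
  query <- fragment_molecule(smis[1])$peaks
  qbins <- as.integer(encode_spectrum(query, max_bins = 10000L))
  expected <- vapply(smis, function(s) {
    cb <- as.integer(encode_spectrum(fragment_molecule(s)$peaks,
                                     max_bins = 10000L))
    oracle_cosine_dense(cb, qbins)
  }, numeric(1))
  rr <- roundtrip_rank(smis, query)
  expect_equal(rr$score, unname(sort(expected, decreasing = TRUE)),
               tolerance = 1e-12)
})

test_that("duplicate candidates tie deterministically and failures score zero", {
  smis <- fixture_smiles(3)
  query <- fragment_molecule(smis[1])$peaks
  rr <- roundtrip_rank(c(smis[1], smis[1], smis[2]), query)
  expect_equal(rr$score[1], rr$score[2])
  expect_identical(rr$smiles[1], rr$smiles[2])
  expect_warning(rr2 <- roundtrip_rank(c(smis[1], "C1CC"), query), "failed")
  expect_equal(rr2$score[rr2$smiles == "C1CC"], 0)
})

test_that("top-k iterations use ascending-m/z inputs of the k most intense peaks", {
  # an untrained model suffices to exercise the protocol mechanics
  m <- build_model(model_config(n_encoder_layers = 1, n_decoder_layers = 1,
                                d_model = 16, n_heads = 2, d_ff = 32,
                                dropout = 0, vocab_size = 69,
                                max_output_len = 6), seed = 2)
  mz <- c(120.05, 80.03, 150.1, 60.02)
  int <- c(5, 100, 40, 100)  # tie at 100: lower m/z wins
  sp <- ms2mol:::new_experimental_spectrum(mz, int, max(mz), "positive")
  tk <- topk_procedure(sp, m, target_formula = "C4H4O4",
                       config = eval_config(n_runs_per_k = 2), seed = 1)
  expect_length(tk$per_k, 4L)
  expect_identical(tk$per_k[[1]]$bins, as.integer(encode_spectrum(60.02)))
  expect_identical(tk$per_k[[2]]$bins,
                   as.integer(encode_spectrum(c(60.02, 80.03))))
  for (rec in tk$per_k) expect_false(is.unsorted(rec$bins))
  expect_identical(tk$per_k[[4]]$bins,
                   as.integer(encode_spectrum(mz)))

  no_int <- ms2mol:::new_experimental_spectrum(mz, rep(NA_real_, 4),
                                               max(mz), "positive")
  expect_error(topk_procedure(no_int, m, target_formula = "C4H4O4"),
               "intensities")
})

test_that("oversized prediction-time spectra are truncated to the most intense peaks", {
  pk <- data.frame(mz = seq(50, by = 0.5, length.out = 120),
                   intensity = rev(seq_len(120)))
  expect_warning(kept <- ms2mol:::truncate_to_top_peaks(pk, 100L),
                 "truncating")
  expect_identical(nrow(kept), 100L)
  # the dropped peaks are the 20 least intense ones
  expect_true(all(kept$intensity >= 21))
  # under the cap the input is untouched
  expect_identical(ms2mol:::truncate_to_top_peaks(pk[1:10, ], 100L),
                   pk[1:10, ])
})

test_that("challenge filtering counts rejections per rule in order", {
  challenges <- list(
    list(peaks = c(100.1, 200.2), ion_mode = "positive", smiles = "CCO"),
    list(peaks = c(100.1), ion_mode = "NEGATIVE", smiles = "CCO"),
    list(peaks = c(100.1, 512.3), ion_mode = "positive", smiles = "CCO"),
    list(peaks = seq(50, 450, length.out = 100), ion_mode = "positive",
         smiles = "CCO"),
    list(peaks = c(100.1), ion_mode = "positive",
         smiles = paste(rep("C", 100), collapse = "")),
    list(peaks = NULL, ion_mode = "positive", smiles = "CCO")
  )
  out <- suppressWarnings(casmi_filter(challenges))
  expect_length(out$eligible, 1L)
  expect_identical(unname(out$rejections[c("ion_mode", "mz_range", "n_peaks",
                                           "smiles_length", "malformed")]),
                   rep(1L, 5))
  # purity: identical inputs give identical outputs
  out2 <- suppressWarnings(casmi_filter(challenges))
  expect_identical(out$rejections, out2$rejections)
})

test_that("challenge scoring distinguishes correct, unknown, and no-prediction", {
  truth <- "OCC"
  hit <- casmi_score(c(canonicalize("CCO"), "CCC"), truth)
  expect_identical(hit$category, "correct")
  expect_equal(hit$best_ts, 1.0)

  near <- casmi_score(c("CCN"), truth)
  expect_identical(near$category, "unknown")
  expect_lt(near$best_ts, 1.0)

  none <- casmi_score(character(0), truth)
  expect_identical(none$category, "no_prediction")
  expect_true(is.na(none$best_ts))

  # the typical-similarity variant reports at least the path-based score
  near_typ <- casmi_score(c("CCN"), truth, ts_method = "typical")
  expect_gte(near_typ$best_ts, near$best_ts)
})

test_that("candidate expansion hook defaults to the seed and merges uniquely", {
  expect_identical(expand_candidates("CCO"), "CCO")
  got <- expand_candidates("CCO", function(s) c("CCN", "CCO"))
  expect_setequal(got, c("CCO", "CCN"))
})
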