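# Filtering, vocabulary/tokenization, augmentation multiplicity, splitting,
# and the fixture-molecule generator.

test_that("molecule filter applies its rules in order with reason codes", {
  cfg <- filter_config()
  seen <- new.env(parent = emptyenv())

  ok <- molecule_record("CCO")
  expect_true(filter_molecule(ok, spectrum = 1:10, config = cfg,
                              seen = seen)$pass)
  # duplicate of an accepted molecule
  dup <- filter_molecule(ok, config = cfg, seen = seen)
  expect_false(dup$pass)
  expect_identical(dup$reason, "duplicate")

  # heavy molecule: protonated ion above 500
  heavy <- molecule_record(paste(rep("C", 40), collapse = ""))
  expect_identical(filter_molecule(heavy, config = cfg)$reason,
                   "max_precursor_mz")

  # peak count just over the cap
  expect_identical(filter_molecule(ok, spectrum = seq_len(101),
                                   config = cfg)$reason, "max_peaks")
  expect_true(filter_molecule(ok, spectrum = seq_len(100),
                              config = cfg)$pass)
})

test_that("the vocabulary has 69 tokens with specials pinned at ids 0-3", {
  v <- smiles_vocabulary()
  expect_identical(v$size, 69L)
  expect_identical(length(v$tokens), 69L)
  expect_identical(v$tokens[1:4], c("<sos>", "<eos>", "<unk>", "<pad>"))
  expect_identical(unname(v$ids[c("<sos>", "<eos>", "<unk>", "<pad>")]),
                   0:3)
  expect_false(anyDuplicated(v$tokens) > 0)
  expect_identical(unname(v$ids[v$tokens]), seq_along(v$tokens) - 1L)
})

test_that("tokenization round-trips and treats two-letter elements as single tokens", {
  v <- smiles_vocabulary()
  ids <- tokenize("CCO", v)
  expect_identical(ids[c(1, length(ids))], c(v$sos, v$eos))
  expect_identical(detokenize(ids, v), "CCO")
  expect_identical(length(tokenize("CCl", v)), 4L)  # sos, C, Cl, eos
  expect_identical(tokenize("", v), structure(c(0L, 1L), n_unknown = 0L),
                   ignore_attr = TRUE)

  two <- v$tokens[nchar(v$tokens) == 2 & !grepl("^<", v$tokens)]
  panel <- c("CCl", "BrCCBr", "C(Cl)(Cl)Cl", "[Si](C)(C)C", "[Na+].[Cl-]",
             "ClCCSeCC")
  for (s in panel) {
    got <- tokenize(s, v)
    expect_identical(detokenize(got, v), s, label = s)
    expect_identical(length(got) - 2L, length(oracle_tokenize(s, two)),
                     label = s)
  }
})

test_that("unknown symbols map to <unk> and are counted", {
  v <- smiles_vocabulary()
  ids <- tokenize("C*C", v)
  expect_identical(attr(ids, "n_unknown"), 1L)
  expect_true(v$unk %in% ids)
})

test_that("tokenization round-trips for every fixture molecule", {
  v <- smiles_vocabulary()
  for (s in fixture_smiles(50)) {
    ids <- tokenize(s, v)
    expect_identical(attr(ids, "n_unknown"), 0L, label = s)
    expect_identical(detokenize(ids, v), s, label = s)
  }
})

test_that("augmentation yields one sample per depth whose peak list fits", {
  mols <- fixture_molecules(10)
  ds <- build_dataset(mols)
  per_mol <- table(vapply(ds$samples, `[[`, character(1), "smiles"))
  # expected multiplicity from the depth series directly
  for (rec in mols) {
    series <- depth_series(rec$smiles_canonical)
    expected <- sum(vapply(series, function(sp)
      length(unique(bin_index(sp$peaks))) <= 100, logical(1)))
    expect_identical(as.integer(per_mol[[rec$smiles_canonical]]), expected,
                     label = rec$smiles_canonical)
  }
  expect_true(all(vapply(ds$samples, `[[`, integer(1), "depth") %in% 1:3))
  # targets decode back to the molecule
  for (s in ds$samples[1:5])
    expect_identical(detokenize(s$target, ds$vocab), s$smiles)
})

test_that("a sample whose peak list overflows is dropped individually", {
  # filter with a tiny peak cap: deep spectra are dropped, shallow kept
  mols <- fixture_molecules(10)
  sizes <- vapply(mols, function(r)
    length(fragment_molecule(r$smiles_canonical)$peaks), integer(1))
  target <- mols[[which.max(sizes)]]
  series <- depth_series(target$smiles_canonical)
  cap <- length(series[[2]]$peaks)  # depth 1-2 fit, depth 3 may not
  ds <- build_dataset(list(target), filt = filter_config(max_peaks = cap))
  expected <- sum(vapply(series, function(sp) length(sp$peaks) <= cap,
                         logical(1)))
  expect_identical(length(ds$samples), expected)
})

test_that("dataset build drops duplicates and is deterministic", {
  mols <- fixture_molecules(5)
  ds1 <- build_dataset(c(mols, mols[1]))
  ds2 <- build_dataset(c(mols, mols[1]))
  expect_identical(ds1$drop_log[["duplicate"]], 1L)
  expect_identical(ds1$samples, ds2$samples)
  expect_length(build_dataset(list())$samples, 0L)
})

test_that("splitting is molecule-disjoint, exhaustive, and seeded", {
  ds <- build_dataset(fixture_molecules(20))
  sp1 <- split_dataset(ds, 12, seed = 5)
  sp2 <- split_dataset(ds, 12, seed = 5)
  expect_identical(sp1$validation$samples, sp2$validation$samples)
  expect_identical(length(sp1$train$samples) + length(sp1$validation$samples),
                   length(ds$samples))
  tm <- unique(vapply(sp1$train$samples, `[[`, character(1), "smiles"))
  vm <- unique(vapply(sp1$validation$samples, `[[`, character(1), "smiles"))
  expect_length(intersect(tm, vm), 0L)
  expect_gte(length(sp1$validation$samples), 12L)
  expect_error(split_dataset(ds, length(ds$samples)), "smaller")
})

test_that("datasets round-trip through the TSV/JSON serialization", {
  ds <- build_dataset(fixture_molecules(5))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(length(back$samples), length(ds$samples))
  for (i in seq_along(ds$samples)) {
    expect_identical(back$samples[[i]]$bins, ds$samples[[i]]$bins)
    expect_identical(as.integer(back$samples[[i]]$target),
                     as.integer(ds$samples[[i]]$target))
    expect_identical(back$samples[[i]]$smiles, ds$samples[[i]]$smiles)
  }
})

test_that("fixture generation is reproducible and contract-compliant", {
  a <- generate_fixture_molecules(15, seed = 3)
  b <- generate_fixture_molecules(15, seed = 3)
  sa <- vapply(a, `[[`, character(1), "smiles_canonical")
  expect_identical(sa, vapply(b, `[[`, character(1), "smiles_canonical"))
  expect_identical(length(unique(sa)), 15L)
  for (rec in a) {
    expect_lt(rec$monoisotopic_mass + PROTON_MASS, 500)
    expect_true(filter_molecule(rec)$pass)
    # fragments cleanly at depth 3
    sp <- fragment_molecule(rec$smiles_canonical)
    expect_gte(length(sp$peaks), 1L)
  }
})
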