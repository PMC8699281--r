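# In silico fragmentation: bond eligibility, single breaks, recursive
# spectra, and equivalence with the brute-force enumeration oracle.

cfg0 <- fragmentation_config(min_fragment_mass = 0)

test_that("bond eligibility follows the single/non-aromatic rule", {
  expect_identical(nrow(eligible_bonds("c1ccccc1")), 0L)  # all aromatic
  expect_identical(nrow(eligible_bonds("CC")), 1L)
  expect_identical(nrow(eligible_bonds("C1CCCCC1")), 6L)
  expect_identical(nrow(eligible_bonds("C=C")), 0L)       # double bond
  eb <- eligible_bonds("CCO")
  expect_false(is.unsorted(eb$a1))                        # canonical order
})

test_that("breaking a bond splits or ring-opens with frozen hydrogens", {
  m <- mol_graph("CC")
  ch <- break_bond(m, root_fragment(m), 1L)
  expect_length(ch, 2L)
  expect_setequal(vapply(ch, `[[`, character(1), "formula"), "CH3")
  expect_true(all(vapply(ch, `[[`, integer(1), "depth") == 1L))

  ring <- mol_graph("C1CCCCC1")
  opened <- break_bond(ring, root_fragment(ring), 1L)
  expect_length(opened, 1L)
  expect_identical(opened[[1]]$formula, "C6H12")   # same atoms, no H gained
  expect_identical(opened[[1]]$depth, 1L)

  ether <- mol_graph("COC")
  pieces <- break_bond(ether, root_fragment(ether), 1L)
  expect_setequal(vapply(pieces, `[[`, character(1), "formula"),
                  c("CH3", "CH3O"))

  expect_error(break_bond(m, root_fragment(m), 99L), "not part")
})

test_that("a molecule with no breakable bonds yields only its protonated ion", {
  sp <- fragment_molecule("C", cfg0)
  expect_equal(sp$peaks, round(monoisotopic_mass("CH4") + PROTON_MASS, 5))
  expect_equal(sp$peaks, 17.03858)
})

test_that("fragment spectra match the brute-force oracle on small molecules", {
  small <- Filter(function(s) n_heavy_atoms(s) <= 7, fixture_smiles(25))
  mols <- c("CCO", "COC", "CC(=O)O", "C1CCC1", utils::head(small, 4))
  for (smi in mols) {
    for (d in 1:2) {
      got <- fragment_molecule(smi, fragmentation_config(max_depth = d,
                                                         min_fragment_mass = 0))
      expect_equal(got$peaks, oracle_fragment_peaks(smi, d, min_mass = 0),
                   label = paste(smi, "depth", d))
    }
  }
})

test_that("min fragment mass discards light fragments but never the precursor", {
  sp <- fragment_molecule("CCO", fragmentation_config(max_depth = 2,
                                                      min_fragment_mass = 30))
  expect_true(all(sp$peaks >= 30 + PROTON_MASS))
  expect_true(sp$precursor_mz %in% sp$peaks)
  light <- fragment_molecule("CO", fragmentation_config(min_fragment_mass = 500))
  expect_equal(light$peaks, light$precursor_mz)  # precursor survives anyway
})

test_that("depth series is nested, contains the molecular ion, and matches single runs", {
  for (smi in utils::head(fixture_smiles(10), 4)) {
    series <- depth_series(smi, cfg0)
    expect_length(series, 3L)
    for (i in 1:3)
      expect_true(series[[i]]$precursor_mz %in% series[[i]]$peaks)
    expect_true(all(series[[1]]$peaks %in% series[[2]]$peaks))
    expect_true(all(series[[2]]$peaks %in% series[[3]]$peaks))
    full <- fragment_molecule(smi, fragmentation_config(max_depth = 3,
                                                        min_fragment_mass = 0))
    expect_equal(series[[3]]$peaks, full$peaks)
  }
})

test_that("fragment formulas are sub-multisets of the parent and peaks bounded by precursor", {
  for (smi in utils::head(fixture_smiles(10), 5)) {
    sp <- fragment_molecule(smi, cfg0)
    parent <- as_formula(formula_of(smi))
    for (f in unique(sp$provenance$formula)) {
      counts <- as_formula(f)
      expect_true(all(names(counts) %in% names(parent)))
      expect_true(all(counts <= parent[names(counts)]))
    }
    expect_true(all(sp$peaks <= sp$precursor_mz + 1e-9))
  }
})

test_that("spectra are invariant to how the input SMILES is written", {
  pairs <- list(c("CCO", "OCC"),
                c("CC(C)=O", "O=C(C)C"),
                c("c1ccccc1CCO", "OCCc1ccccc1"))
  for (p in pairs) {
    s1 <- fragment_molecule(p[1], cfg0)
    s2 <- fragment_molecule(p[2], cfg0)
    expect_identical(s1$peaks, s2$peaks, label = paste(p, collapse = " vs "))
  }
})

test_that("MSP and CSV writers produce parseable output", {
  sp <- fragment_molecule("CCO", cfg0)
  msp <- withr::local_tempfile(fileext = ".msp")
  write_msp(sp, msp)
  back <- parse_peaks(msp, format = "msp")
  expect_equal(back$peaks$mz, sp$peaks, tolerance = 1e-9)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-9)

  csv <- withr::local_tempfile(fileext = ".csv")
  df <- write_spectra_csv(sp, csv)
  expect_true(all(c("smiles", "mz", "formula", "depth") %in% names(df)))
})
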