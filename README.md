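# ms2mol

Small-molecule identification from positive-electrospray tandem mass
spectra, by in silico fragmentation and sequence-to-sequence translation.

## The problem

Given an MS/MS peak list, which molecule produced it? Spectral libraries
cover only a tiny corner of chemical space, so lookup fails for most real
metabolomics features. The *forward* problem is far easier: from a known
structure, breaking the weaker bonds in silico yields a usable theoretical
spectrum. `ms2mol` builds on that asymmetry:

1. **Fragment** molecules recursively (single, non-aromatic bonds, depth
   ≤ 3, protonated adducts) into theoretical spectra — millions of
   (structure, spectrum) training pairs can be generated rather than
   measured.
2. **Translate** binned peak lists (0.01 Da bins over m/z < 500, at most
   100 peaks) into SMILES token sequences with a standard encoder–decoder
   attention network (~404 M parameters at full scale; a few hundred
   thousand at the desk scale exercised here).
3. **Post-process** candidates: repeated stochastic decoding with
   canonical deduplication, molecular-formula filtering from the exact
   precursor mass, spectral **round-tripping** (re-fragment each candidate
   and rank by binned cosine similarity

   cosine(a, b) = |a ∩ b| / √(|a| · |b|)

   over binary bin-occurrence vectors), Tanimoto similarity as the maximum
   Jaccard coefficient over six fingerprint encodings, and challenge-style
   scoring in which an answer is *correct* (canonical-SMILES equality),
   *unknown*, or an explicit *no prediction*.

Molecular formulas are recovered from exact mass by exhaustive enumeration
over {C,H,N,O} within a ppm window (RDBE = C − H/2 + N/2 + 1 ≥ 0), e.g. a
5 ppm window at 500 Da is 0.0025 Da.

The package is aimed at computational metabolomics researchers who want a
fully inspectable, deterministic implementation of this pipeline — every
stage from SMILES to theoretical spectrum to token sequence to ranked
candidate is a plain R object.

## Worked example

```r
library(ms2mol)

# a molecule and its theoretical spectrum
rec <- molecule_record("OCC(=O)C1(O)CCC2C1(C)CC(O)C1C2CCC2=CC(=O)CCC12C")
rec
#> <molecule_record> OCC(=O)C1(O)CCC2C1(C)CC(O)C1C2CCC2=CC(=O)CCC12C
#>   formula: C21H30O5  monoisotopic mass: 362.20932 Da

sp <- fragment_molecule(rec$smiles_canonical)
length(sp$peaks); sp$precursor_mz
#> [1] 149
#> [1] 363.2166

# formula candidates from the exact neutral mass, 5 ppm
head(enumerate_formulas(362.2093241, ppm = 5), 2)
#>    formula     mass deviation_da deviation_ppm rdbe
#> 1 C21H30O5 362.2093   -3.250e-08 -8.972711e-05  7.0
#> 2 C20H24N7 362.2093   -5.298e-06 -1.462690e-02 12.5

# round-trip ranking: the true molecule scores 1.0 against its own spectrum
cands <- vapply(generate_fixture_molecules(4, seed = 1),
                `[[`, character(1), "smiles_canonical")
rr <- roundtrip_rank(c(rec$smiles_canonical, cands), sp$peaks)
rr[1, c("smiles", "score", "rank")]
#>                                            smiles score rank
#> 1 OCC(=O)C1(O)CCC2C1(C)CC(O)C1C2CCC2=CC(=O)CCC12C     1    1

# similarity between two candidates, maximum over six encodings
typical_similarity("c1ccccc1", "c1ccncc1")
#> <typical_similarity> 0.5000 (atom_pair)
```

The first ranked row says the query spectrum is exactly reproduced by
re-fragmenting the candidate (cosine 1.0): with theoretical spectra,
round-tripping is a perfect self-check, which is the property the test
suite verifies across all fixtures. The 149 peaks are every distinct
protonated fragment mass reachable in ≤ 3 breaks of single non-aromatic
bonds with fragments ≥ 50 Da.

A thin CLI covers the file-level operations:

```sh
exec/ms2mol fragment --smiles-file molecules.smi --depth 3 --out spectra.msp
exec/ms2mol encode   --in peaks.mgf --out bins.txt
exec/ms2mol rank     --candidates candidates.smi --peaks query.mgf
```

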