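# Training-set assembly: molecule filtering, depth-wise augmentation (one
# sample per bond-breaking generation), SMILES tokenization against a frozen
# vocabulary, reproducible molecule-level train/validation splitting, and a
# bundled generator of small fixture molecules.

# Run code with a private, restorable RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Dataset filtering thresholds
#'
#' @param max_precursor_mz Maximum protonated molecular-ion m/z (default 500).
#' @param max_smiles_len Maximum canonical SMILES length in characters
#'   (default 99).
#' @param max_peaks Maximum number of peaks/bins per sample (default 100).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(max_precursor_mz = 500, max_smiles_len = 99L,
                          max_peaks = 100L) {
  stopifnot(max_precursor_mz > 0, max_smiles_len > 0, max_peaks > 0)
  structure(list(max_precursor_mz = max_precursor_mz,
                 max_smiles_len = as.integer(max_smiles_len),
                 max_peaks = as.integer(max_peaks)),
            class = "filter_config")
}

#' Filter one molecule against the dataset rules
#'
#' A molecule fails if its protonated molecular ion exceeds
#' `max_precursor_mz`, its canonical SMILES is longer than `max_smiles_len`,
#' its spectrum has more than `max_peaks` peaks, or its canonical SMILES has
#' been seen before; the reason names the first failing rule.
#'
#' @param record A `molecule_record`.
#' @param spectrum Optional spectrum whose peak count is checked (a
#'   `theoretical_spectrum`, `experimental_spectrum`, or peak vector).
#' @param config A [filter_config()].
#' @param seen Optional environment tracking canonical SMILES already
#'   accepted (for duplicate removal across a stream of molecules).
#' @return List with `pass` (logical) and `reason` (one of `"pass"`,
#'   `"max_precursor_mz"`, `"max_smiles_len"`, `"max_peaks"`,
#'   `"duplicate"`).
#' @export
filter_molecule <- function(record, spectrum = NULL,
                            config = filter_config(), seen = NULL) {
  fail <- function(reason) list(pass = FALSE, reason = reason)
  if (record$monoisotopic_mass + PROTON_MASS > config$max_precursor_mz)
    return(fail("max_precursor_mz"))
  if (nchar(record$smiles_canonical) > config$max_smiles_len)
    return(fail("max_smiles_len"))
  if (!is.null(spectrum)) {
    n <- if (is.numeric(spectrum)) length(spectrum)
    else if (inherits(spectrum, "theoretical_spectrum")) length(spectrum$peaks)
    else nrow(spectrum$peaks)
    if (n > config$max_peaks) return(fail("max_peaks"))
  }
  if (!is.null(seen)) {
    if (!is.null(get0(record$smiles_canonical, envir = seen)))
      return(fail("duplicate"))
    assign(record$smiles_canonical, TRUE, envir = seen)
  }
  list(pass = TRUE, reason = "pass")
}

# -- Vocabulary ---------------------------------------------------------------

#' The frozen SMILES output vocabulary
#'
#' 69 tokens: the four special tokens `<sos>`, `<eos>`, `<unk>`, `<pad>` at
#' fixed ids 0-3, followed by 65 content tokens covering organic-subset and
#' bracket atoms (two-letter element symbols such as `Cl` and `Br` are
#' single tokens), aromatic lowercase atoms, ring-closure digits, the `%`
#' two-digit ring marker, and bond/branch/charge/bracket punctuation.
#'
#' @return List of class `smiles_vocabulary`: `tokens` (character vector in
#'   id order), `ids` (named integer vector token -> 0-based id), `size`,
#'   and the four special ids `sos`, `eos`, `unk`, `pad`.
#' @export
smiles_vocabulary <- function() {
  specials <- c("<sos>", "<eos>", "<unk>", "<pad>")
  content <- c(
    # aromatic atoms
    "c", "n", "o", "s", "p",
    # aliphatic organic and halogen atoms
    "B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
    # bracket-atom hydrogen
    "H",
    # ring-closure digits
    "0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
    # punctuation: brackets, branches, bonds, charges, stereo, ring marker
    "[", "]", "(", ")", "=", "#", "-", "+", ".", "/", "\\", ":", "@", "%",
    # additional bracket elements
    "Si", "Se", "Na", "K", "Li", "Mg", "Ca", "Fe", "Zn", "Cu", "Mn", "Co",
    "Ni", "As", "Al", "Ag", "Au", "Hg", "Sn", "Sb", "Ti", "Cr", "Cd", "Ba",
    "Pt"
  )
  tokens <- c(specials, content)
  stopifnot(length(tokens) == 69L, !anyDuplicated(tokens))
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, ids = ids, size = length(tokens),
                 sos = 0L, eos = 1L, unk = 2L, pad = 3L),
            class = "smiles_vocabulary")
}

#' Tokenize a SMILES string to vocabulary ids
#'
#' Splits the string into element symbols and other characters, matching
#' two-letter element symbols (`Cl`, `Br`, `Si`, ...) greedily as single
#' tokens, and wraps the result in `<sos>`/`<eos>`. Symbols outside the
#' vocabulary map to `<unk>`.
#'
#' @param smiles SMILES string.
#' @param vocab A [smiles_vocabulary()].
#' @return Integer vector of 0-based token ids beginning with `<sos>` and
#'   ending with `<eos>`, with attribute `n_unknown`.
#' @export
tokenize <- function(smiles, vocab = smiles_vocabulary()) {
  two <- vocab$tokens[nchar(vocab$tokens) == 2L & !grepl("^<", vocab$tokens)]
  chars <- strsplit(smiles, "")[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    pair <- if (i < length(chars)) paste0(chars[i], chars[i + 1L]) else ""
    if (pair %in% two) {
      toks <- c(toks, pair)
      i <- i + 2L
    } else {
      toks <- c(toks, chars[i])
      i <- i + 1L
    }
  }
  ids <- vocab$ids[toks]
  unknown <- is.na(ids)
  ids[unknown] <- vocab$unk
  out <- c(vocab$sos, unname(ids), vocab$eos)
  attr(out, "n_unknown") <- sum(unknown)
  out
}

#' Convert token ids back to a SMILES string
#'
#' Inverse of [tokenize()] for strings free of `<unk>`: special tokens are
#' dropped and the remaining tokens concatenated.
#'
#' @param ids Integer vector of 0-based token ids.
#' @param vocab A [smiles_vocabulary()].
#' @return SMILES string.
#' @export
detokenize <- function(ids, vocab = smiles_vocabulary()) {
  ids <- as.integer(ids)
  keep <- ids > 3L
  paste(vocab$tokens[ids[keep] + 1L], collapse = "")
}

# -- Dataset assembly ---------------------------------------------------------

#' Build spectrum/SMILES training samples with depth-wise augmentation
#'
#' Each retained molecule contributes up to three samples, one per
#' fragmentation depth (its depth-1, depth-2 and depth-3 theoretical
#' spectra), pairing the binned peak list with the tokenized canonical
#' SMILES. Samples whose peak list exceeds `max_peaks` distinct bins are
#' dropped individually; molecules failing [filter_molecule()] (including
#' duplicates) are dropped entirely.
#'
#' @param molecules List of `molecule_record`s or character vector of SMILES.
#' @param frag_config A [fragmentation_config()] (`max_depth` >= 3).
#' @param filt A [filter_config()].
#' @param vocab A [smiles_vocabulary()].
#' @param binning A [binning_config()].
#' @return List of class `training_dataset`: `samples` (each with `bins`,
#'   `target`, `depth`, `smiles`, `formula`, `precursor_mz`), `vocab`,
#'   `configs`, and `drop_log` (reason counts).
#' @export
build_dataset <- function(molecules,
                          frag_config = fragmentation_config(),
                          filt = filter_config(),
                          vocab = smiles_vocabulary(),
                          binning = binning_config()) {
  if (is.character(molecules))
    molecules <- lapply(molecules, molecule_record)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  drops <- c(max_precursor_mz = 0L, max_smiles_len = 0L, max_peaks = 0L,
             duplicate = 0L, sample_too_long = 0L)
  samples <- list()
  for (rec in molecules) {
    verdict <- filter_molecule(rec, spectrum = NULL, config = filt,
                               seen = seen)
    if (!verdict$pass) {
      drops[[verdict$reason]] <- drops[[verdict$reason]] + 1L
      next
    }
    series <- depth_series(rec$smiles_canonical, frag_config)
    target <- tokenize(rec$smiles_canonical, vocab)
    for (d in seq_along(series)) {
      bins <- tryCatch(
        encode_spectrum(series[[d]]$peaks, binning, max_bins = filt$max_peaks),
        error = function(e) NULL)
      if (is.null(bins)) {
        drops[["sample_too_long"]] <- drops[["sample_too_long"]] + 1L
        next
      }
      samples[[length(samples) + 1L]] <- list(
        bins = as.integer(bins), target = target, depth = d,
        smiles = rec$smiles_canonical, formula = rec$formula,
        precursor_mz = series[[d]]$precursor_mz)
    }
  }
  structure(list(samples = samples, vocab = vocab,
                 configs = list(frag = frag_config, filter = filt,
                                binning = binning),
                 drop_log = drops),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat("<training_dataset> ", length(x$samples), " samples from ",
      length(unique(vapply(x$samples, `[[`, character(1), "smiles"))),
      " molecules\n", sep = "")
  invisible(x)
}

#' Split a dataset into train and validation sets by molecule
#'
#' All depth-augmented samples of one molecule land on the same side, so
#' validation loss measures generalization to unseen molecules rather than
#' unseen depths. Molecules are assigned to validation in random order until
#' at least `n_validation` samples are reserved.
#'
#' @param dataset A `training_dataset`.
#' @param n_validation Number of samples to reserve (must be smaller than
#'   the dataset).
#' @param seed Integer seed making the split reproducible.
#' @return List with `train` and `validation`, both `training_dataset`s.
#' @export
split_dataset <- function(dataset, n_validation, seed = 1L) {
  n <- length(dataset$samples)
  if (n_validation >= n)
    stop("n_validation (", n_validation, ") must be smaller than the dataset (",
         n, ")")
  mols <- vapply(dataset$samples, `[[`, character(1), "smiles")
  unique_mols <- unique(mols)
  val_mols <- character(0)
  with_seed(seed, {
    order_mols <- sample(unique_mols)
    taken <- 0L
    for (m in order_mols) {
      if (taken >= n_validation) break
      val_mols <- c(val_mols, m)
      taken <- taken + sum(mols == m)
    }
  })
  in_val <- mols %in% val_mols
  subset_ds <- function(keep) {
    out <- dataset
    out$samples <- dataset$samples[keep]
    out
  }
  list(train = subset_ds(!in_val), validation = subset_ds(in_val))
}

#' Serialize a training dataset to disk
#'
#' Writes `samples.tsv` (columns: tab-separated within-field by spaces --
#' `bins` space-joined, `smiles`, `depth`) and `config.json` (vocabulary
#' and filter/binning settings) into `dir`.
#'
#' @param dataset A `training_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(
    bins = vapply(dataset$samples, function(s) paste(s$bins, collapse = " "),
                  character(1)),
    smiles = vapply(dataset$samples, `[[`, character(1), "smiles"),
    depth = vapply(dataset$samples, `[[`, integer(1), "depth"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(vocab = dataset$vocab$tokens,
         filter = unclass(dataset$configs$filter),
         binning = unclass(dataset$configs$binning)),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a training dataset written by [write_dataset()]
#'
#' @param dir Directory holding `samples.tsv` and `config.json`.
#' @param vocab A [smiles_vocabulary()]; must match the sidecar token list.
#' @return A `training_dataset`.
#' @export
read_dataset <- function(dir, vocab = smiles_vocabulary()) {
  df <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("character",
                                                        "character",
                                                        "integer"))
  side <- jsonlite::fromJSON(file.path(dir, "config.json"))
  if (!identical(unlist(side$vocab), vocab$tokens))
    stop("vocabulary in ", dir, " does not match the supplied vocabulary")
  samples <- lapply(seq_len(nrow(df)), function(i) {
    list(bins = as.integer(strsplit(df$bins[i], " ", fixed = TRUE)[[1]]),
         target = tokenize(df$smiles[i], vocab),
         depth = df$depth[i], smiles = df$smiles[i],
         formula = NA_character_, precursor_mz = NA_real_)
  })
  structure(list(samples = samples, vocab = vocab,
                 configs = list(filter = side$filter, binning = side$binning),
                 drop_log = NULL),
            class = "training_dataset")
}

# -- Fixture molecules --------------------------------------------------------

# Small C/H/N/O chemistry grammar: scaffold templates with substituent
# slots. Kept deliberately simple so fixture molecules stay below m/z 500,
# tokenize without <unk>, and fragment quickly at depth 3.
fixture_templates <- c(
  "c1ccc(%s)cc1", "c1ccc(%s)nc1", "c1cc(%s)co1", "c1cc(%s)[nH]c1",
  "C1CCC(%s)CC1", "C1CC(%s)OC1", "C1CC(%s)NC1",
  "c1cc(%s)ccc1%s", "C1CC(%s)CC1%s",
  "CC(%s)%s", "CCC(%s)%s", "OCC(%s)%s", "NCC(%s)%s", "CC(C)(%s)%s",
  "C(%s)%s", "OC(%s)%s"
)

fixture_substituents <- c(
  "C", "CC", "CCC", "CCO", "CO", "CN", "C(C)C",
  "O", "OC", "OCC", "N", "NC", "N(C)C",
  "C=O", "C(=O)O", "C(=O)N", "C(=O)C", "C#N", "OC=O"
)

#' Generate reproducible fixture molecules
#'
#' Draws small, valid C/H/N/O molecules from a bundled scaffold/substituent
#' grammar: unique canonical SMILES, protonated molecular ion below 500 Da,
#' tokenizable without `<unk>`, and fragmentable at depth 3. Uniqueness
#' extends to the depth-3 theoretical spectrum: constitutional isomers
#' whose fragment mass sets coincide exactly are indistinguishable to any
#' spectrum-based method, so only the first of such a pair is kept and
#' spectrum-vs-molecule identities stay well posed across the set. Sizes
#' span roughly 4-14 heavy atoms so that both tiny oracle-checkable
#' structures and ring-bearing ones are represented.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @return List of `n` `molecule_record` objects (source tag `"fixture"`).
#' @export
generate_fixture_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  out <- list()
  seen <- character(0)
  seen_spectra <- character(0)
  with_seed(seed, {
    attempts <- 0L
    while (length(out) < n && attempts < n * 200L) {
      attempts <- attempts + 1L
      tpl <- sample(fixture_templates, 1L)
      n_slots <- lengths(regmatches(tpl, gregexpr("%s", tpl, fixed = TRUE)))
      subs <- sample(fixture_substituents, n_slots, replace = TRUE)
      smi <- do.call(sprintf, c(list(tpl), as.list(subs)))
      rec <- tryCatch(molecule_record(smi, source_tag = "fixture"),
                      error = function(e) NULL)
      if (is.null(rec)) next
      if (rec$smiles_canonical %in% seen) next
      if (rec$monoisotopic_mass + PROTON_MASS >= 500) next
      toks <- tokenize(rec$smiles_canonical)
      if (attr(toks, "n_unknown") > 0L) next
      spec_key <- paste(fragment_molecule(rec$smiles_canonical)$peaks,
                        collapse = ",")
      if (spec_key %in% seen_spectra) next
      seen <- c(seen, rec$smiles_canonical)
      seen_spectra <- c(seen_spectra, spec_key)
      out[[length(out) + 1L]] <- rec
    }
  })
  if (length(out) < n)
    stop("could not generate ", n, " unique fixture molecules")
  out
}
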