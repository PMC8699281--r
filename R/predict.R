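# Decoding: greedy reconstruction, repeated stochastic sampling with
# canonical deduplication (the model's "certainty" signal), and molecular
# formula filtering of predictions.

# Encoder pass over raw bin lists (no targets needed).
encode_inputs <- function(model, bins_list) {
  B <- length(bins_list)
  lens <- lengths(bins_list)
  Se <- max(lens, 1L)
  enc <- matrix(model$config$n_bins + 1L, B, Se)
  enc_mask <- matrix(FALSE, B, Se)
  for (b in seq_len(B)) {
    if (lens[b] > 0L) {
      enc[b, seq_len(lens[b])] <- as.integer(bins_list[[b]]) + 1L
      enc_mask[b, seq_len(lens[b])] <- TRUE
    }
  }
  batch <- list(enc = enc, enc_mask = enc_mask, B = B, Se = Se)
  list(memory = encoder_fwd(model, batch)$memory, batch = batch)
}

# Synchronous batched decoding. Returns a list of 0-based token id vectors
# (without <sos>, truncated before <eos>).
decode_tokens <- function(model, bins_list, vocab,
                          mode = c("greedy", "sample"), temperature = 1.0,
                          max_len = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_len)) max_len <- model$config$max_output_len
  enc <- encode_inputs(model, bins_list)
  B <- enc$batch$B
  seqs <- matrix(vocab$sos + 1L, B, 1L)
  finished <- rep(FALSE, B)
  eos_row <- vocab$eos + 1L
  for (t in seq_len(max_len)) {
    batch <- list(enc = enc$batch$enc, enc_mask = enc$batch$enc_mask,
                  dec_in = seqs, dec_mask = matrix(TRUE, B, ncol(seqs)),
                  B = B, Sd = ncol(seqs), Se = enc$batch$Se)
    dec <- decoder_fwd(model, batch, enc$memory)
    last <- dec$logits[seq_len(B) * ncol(seqs), , drop = FALSE]
    nxt <- integer(B)
    if (mode == "greedy") {
      nxt <- max.col(last, ties.method = "first")
    } else {
      z <- last / temperature
      z <- z - apply(z, 1L, max)
      P <- exp(z)
      P <- P / rowSums(P)
      u <- stats::runif(B)
      cum <- t(apply(P, 1L, cumsum))
      nxt <- max.col(cum >= u, ties.method = "first")
    }
    nxt[finished] <- vocab$pad + 1L
    seqs <- cbind(seqs, nxt)
    finished <- finished | nxt == eos_row
    if (all(finished)) break
  }
  lapply(seq_len(B), function(b) {
    ids <- seqs[b, -1L] - 1L
    stop_at <- which(ids == vocab$eos)
    if (length(stop_at)) ids <- ids[seq_len(stop_at[1L] - 1L)]
    ids
  })
}

#' Greedy SMILES reconstruction from binned spectra
#'
#' Decodes each input with argmax token selection; useful for checking that
#' a trained model has the capacity to reproduce its training molecules.
#'
#' @param model A trained `seq2seq_model`.
#' @param bins_list List of binned spectra (integer bin vectors).
#' @param vocab A [smiles_vocabulary()].
#' @return Character vector of decoded SMILES strings (not validity-checked).
#' @export
greedy_decode <- function(model, bins_list, vocab = smiles_vocabulary()) {
  ids <- decode_tokens(model, bins_list, vocab, mode = "greedy")
  vapply(ids, detokenize, character(1), vocab = vocab)
}

#' Repeated stochastic prediction with canonical deduplication
#'
#' Runs the model `n_runs` times on the same input with multinomial
#' (temperature-scaled) sampling, discards outputs that do not parse as
#' SMILES, canonicalizes the survivors and tallies their frequencies. A
#' confident model produces few unique predictions relative to `n_runs`; an
#' unsure one produces nearly as many unique outputs as runs, which is the
#' qualitative certainty signal reported as `uniqueness_ratio`.
#'
#' @param model A trained `seq2seq_model`.
#' @param bins A binned spectrum (integer bin vector), non-empty.
#' @param n_runs Number of independent decodes (default 100).
#' @param seed RNG seed.
#' @param temperature Softmax temperature (default 1.0).
#' @param vocab A [smiles_vocabulary()].
#' @return List of class `prediction_set`: `raw_outputs`, `n_runs`,
#'   `n_invalid`, `unique_canonical` (named frequency vector over canonical
#'   SMILES of the valid outputs), `uniqueness_ratio` (distinct raw outputs
#'   over `n_runs`, always in (0, 1]).
#' @export
sample_predictions <- function(model, bins, n_runs = 100L, seed = 1L,
                               temperature = 1.0,
                               vocab = smiles_vocabulary()) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (!length(bins)) stop("cannot predict from an empty spectrum")
  raw <- with_seed(seed, {
    ids <- decode_tokens(model, rep(list(bins), n_runs), vocab,
                         mode = "sample", temperature = temperature)
    vapply(ids, detokenize, character(1), vocab = vocab)
  })
  tally <- table(raw)
  canon_map <- vapply(names(tally), function(s)
    tryCatch(canonicalize(s), error = function(e) NA_character_),
    character(1))
  n_invalid <- sum(tally[is.na(canon_map)])
  freq <- tapply(as.integer(tally[!is.na(canon_map)]),
                 canon_map[!is.na(canon_map)], sum)
  unique_canonical <- as.integer(freq)
  names(unique_canonical) <- names(freq)
  unique_canonical <- sort(unique_canonical, decreasing = TRUE)
  structure(list(raw_outputs = raw, n_runs = as.integer(n_runs),
                 n_invalid = as.integer(n_invalid),
                 unique_canonical = unique_canonical,
                 uniqueness_ratio = length(tally) / n_runs),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", x$n_runs, " runs, ",
      length(x$unique_canonical), " unique canonical SMILES (",
      x$n_invalid, " invalid)\n", sep = "")
  if (length(x$unique_canonical))
    print(utils::head(x$unique_canonical, 5))
  invisible(x)
}

#' Filter predictions by molecular formula
#'
#' Retains predictions compatible with the known molecular ion: either
#' exact element-count equality with `target_formula`, or (when only the
#' precursor m/z is known) a protonated monoisotopic mass within the ppm
#' window of `precursor_mz`. An empty result is meaningful: the model made
#' no prediction with the correct formula.
#'
#' @param pred A `prediction_set`.
#' @param precursor_mz Protonated molecular-ion m/z (used when
#'   `target_formula` is NULL).
#' @param target_formula Optional formula string or count vector for exact
#'   matching.
#' @param ppm Mass tolerance in ppm (default 5).
#' @return The `prediction_set` with added fields `formula_filtered` (named
#'   frequency vector) and `no_prediction` (logical).
#' @export
formula_filter <- function(pred, precursor_mz = NULL, target_formula = NULL,
                           ppm = 5) {
  keep <- logical(length(pred$unique_canonical))
  if (length(pred$unique_canonical)) {
    formulas <- vapply(names(pred$unique_canonical), function(s)
      tryCatch(format_formula(formula_of(s)), error = function(e) NA_character_),
      character(1))
    if (!is.null(target_formula)) {
      target <- format_formula(as_formula(target_formula))
      keep <- !is.na(formulas) & formulas == target
    } else {
      if (is.null(precursor_mz))
        stop("supply precursor_mz or target_formula")
      masses <- vapply(formulas, function(f)
        if (is.na(f)) NA_real_ else monoisotopic_mass(f) + PROTON_MASS,
        numeric(1))
      keep <- !is.na(masses) &
        abs(masses - precursor_mz) <= ppm_window(precursor_mz, ppm)
    }
  }
  pred$formula_filtered <- pred$unique_canonical[keep]
  pred$no_prediction <- length(pred$formula_filtered) == 0L
  pred
}
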