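# Candidate post-processing: spectral round-trip ranking, the top-k
# intensity iteration protocol for experimental peak lists, and
# challenge-style filtering and scoring.

#' Evaluation settings
#'
#' @param ts_close_cutoff Tanimoto similarity below which a
#'   formula-matching but wrong prediction is called "unknown" (default
#'   0.8).
#' @param ts_high_cutoff Similarity regarded as structurally very close
#'   (default 0.9).
#' @param n_runs_per_k Decodes per top-k iteration (default 300).
#' @param encodings Fingerprint encodings for [typical_similarity()].
#' @return List of class `eval_config`.
#' @export
eval_config <- function(ts_close_cutoff = 0.8, ts_high_cutoff = 0.9,
                        n_runs_per_k = 300L, encodings = FP_ENCODINGS) {
  stopifnot(ts_close_cutoff > 0, ts_close_cutoff <= 1,
            ts_high_cutoff > 0, ts_high_cutoff <= 1, n_runs_per_k >= 1)
  structure(list(ts_close_cutoff = ts_close_cutoff,
                 ts_high_cutoff = ts_high_cutoff,
                 n_runs_per_k = as.integer(n_runs_per_k),
                 encodings = encodings),
            class = "eval_config")
}

#' Rank candidate molecules by spectral round-tripping
#'
#' Each candidate is fragmented in silico, its theoretical spectrum binned,
#' and scored by binned cosine similarity against the query spectrum.
#' Candidates are ordered by score (descending), then prediction frequency
#' (descending), then canonical SMILES (ascending) so the ranking is total
#' and deterministic. A candidate that fails to fragment scores 0 with a
#' warning.
#'
#' @param candidates Character vector of SMILES, or a `prediction_set`
#'   (whose frequencies are used for tie-breaking).
#' @param query A binned spectrum (integer bins) or numeric peak m/z vector.
#' @param frag_config A [fragmentation_config()].
#' @param binning A [binning_config()].
#' @return Data frame of class `ranked_candidates`: `smiles`, `score`,
#'   `frequency`, `rank`.
#' @export
roundtrip_rank <- function(candidates, query,
                           frag_config = fragmentation_config(),
                           binning = binning_config()) {
  freq <- NULL
  if (inherits(candidates, "prediction_set")) {
    freq <- candidates$unique_canonical
    candidates <- names(freq)
  }
  if (!length(candidates)) stop("no candidates to rank")
  if (is.null(freq)) freq <- stats::setNames(rep(0L, length(candidates)),
                                             candidates)
  qbins <- if (is.double(query)) encode_spectrum(query, binning,
                                                 max_bins = .Machine$integer.max)
  else as.integer(query)
  scores <- vapply(candidates, function(smi) {
    tryCatch({
      sp <- fragment_molecule(smi, frag_config)
      cosine_bins(encode_spectrum(sp$peaks, binning,
                                  max_bins = .Machine$integer.max), qbins)
    }, error = function(e) {
      warning("candidate ", smi, " failed round-trip: ",
              conditionMessage(e), call. = FALSE)
      0
    })
  }, numeric(1))
  ord <- order(-scores, -freq[candidates], candidates)
  out <- data.frame(smiles = candidates[ord], score = unname(scores[ord]),
                    frequency = unname(as.integer(freq[candidates][ord])),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("ranked_candidates", "data.frame")
  out
}

# At dataset building, spectra with too many peaks are rejected outright;
# at prediction time a real spectrum should not hard-fail, so it is
# truncated to the most intense peaks (ties toward lower m/z), mirroring
# the top-k philosophy.
truncate_to_top_peaks <- function(peaks, max_peaks = 100L) {
  if (nrow(peaks) <= max_peaks) return(peaks)
  warning("spectrum has ", nrow(peaks), " peaks; truncating to the ",
          max_peaks, " most intense", call. = FALSE)
  keep <- order(-peaks$intensity, peaks$mz)[seq_len(max_peaks)]
  peaks[sort(keep), , drop = FALSE]
}

#' Top-k intensity iteration over an experimental spectrum
#'
#' High-intensity peaks tend to be real; low-intensity ones grow
#' increasingly noisy. The procedure therefore predicts from nested peak
#' subsets: for k = 1 .. n_peaks it takes the k most intense peaks (ties
#' broken toward lower m/z), sorts them ascending in m/z, samples
#' `n_runs_per_k` predictions and formula-filters them. Surviving
#' predictions are pooled with summed frequencies and the most frequent
#' canonical SMILES is the final candidate (lexicographic tie-break).
#'
#' @param spectrum An `experimental_spectrum` with intensities.
#' @param model A trained `seq2seq_model`.
#' @param target_formula Formula string of the molecular ion (exact
#'   filtering), or NULL to filter by `precursor_mz`.
#' @param precursor_mz Protonated molecular-ion m/z (used when
#'   `target_formula` is NULL).
#' @param config An [eval_config()].
#' @param binning A [binning_config()].
#' @param vocab A [smiles_vocabulary()].
#' @param seed RNG seed; iteration k uses `seed + k`.
#' @param ppm Mass tolerance for precursor filtering (default 5).
#' @return List of class `topk_result`: `aggregated` (named frequency
#'   vector), `final` (most frequent canonical SMILES or NA),
#'   `no_prediction`, `per_k` (one record per iteration with the bins
#'   used and survivor count).
#' @export
topk_procedure <- function(spectrum, model, target_formula = NULL,
                           precursor_mz = NULL,
                           config = eval_config(),
                           binning = binning_config(),
                           vocab = smiles_vocabulary(), seed = 1L,
                           ppm = 5) {
  stopifnot(inherits(spectrum, "experimental_spectrum"))
  pk <- spectrum$peaks
  if (!nrow(pk)) stop("empty spectrum")
  if (anyNA(pk$intensity))
    stop("top-k iteration needs peak intensities; supply an ordered peak ",
         "list or intensities")
  pk <- truncate_to_top_peaks(pk, 100L)
  ord <- order(-pk$intensity, pk$mz)
  agg <- integer(0)
  per_k <- vector("list", nrow(pk))
  for (k in seq_len(nrow(pk))) {
    mz_k <- sort(pk$mz[ord[seq_len(k)]])
    bins <- encode_spectrum(mz_k, binning)
    pred <- sample_predictions(model, bins, n_runs = config$n_runs_per_k,
                               seed = seed + k, vocab = vocab)
    pred <- formula_filter(pred, precursor_mz = precursor_mz,
                           target_formula = target_formula, ppm = ppm)
    surv <- pred$formula_filtered
    for (nm in names(surv)) {
      agg[nm] <- (if (nm %in% names(agg)) agg[[nm]] else 0L) + surv[[nm]]
    }
    per_k[[k]] <- list(k = k, bins = as.integer(bins),
                       n_survivors = length(surv),
                       n_invalid = pred$n_invalid)
  }
  final <- NA_character_
  if (length(agg)) {
    best <- max(agg)
    final <- sort(names(agg)[agg == best])[1L]
    agg <- agg[order(-agg, names(agg))]
  }
  structure(list(aggregated = agg, final = final,
                 no_prediction = !length(agg), per_k = per_k),
            class = "topk_result")
}

#' @export
print.topk_result <- function(x, ...) {
  if (x$no_prediction) {
    cat("<topk_result> no prediction with the correct formula\n")
  } else {
    cat("<topk_result> final candidate: ", x$final, " (frequency ",
        x$aggregated[[1L]], ")\n", sep = "")
  }
  invisible(x)
}

#' Filter challenge records for evaluation
#'
#' Retains challenges acquired in positive ion mode whose peaks are all
#' below 500 m/z, with fewer than 100 peaks and a SMILES shorter than 100
#' characters; rejections are counted per rule in application order.
#'
#' @param challenges List of records, each with `peaks` (numeric m/z vector
#'   or data frame with an `mz` column), `ion_mode`, `smiles`.
#' @return List with `eligible` (retained records) and `rejections` (named
#'   counts: `malformed`, `ion_mode`, `mz_range`, `n_peaks`,
#'   `smiles_length`).
#' @export
casmi_filter <- function(challenges) {
  rej <- c(malformed = 0L, ion_mode = 0L, mz_range = 0L, n_peaks = 0L,
           smiles_length = 0L)
  eligible <- list()
  for (ch in challenges) {
    mz <- tryCatch({
      if (is.data.frame(ch$peaks)) ch$peaks$mz else as.numeric(ch$peaks)
    }, error = function(e) NULL)
    if (is.null(mz) || !length(mz) || anyNA(mz) ||
        is.null(ch$ion_mode) || is.null(ch$smiles)) {
      warning("malformed challenge record skipped", call. = FALSE)
      rej[["malformed"]] <- rej[["malformed"]] + 1L
      next
    }
    if (!grepl("^pos", tolower(ch$ion_mode))) {
      rej[["ion_mode"]] <- rej[["ion_mode"]] + 1L
      next
    }
    if (any(mz >= 500)) {
      rej[["mz_range"]] <- rej[["mz_range"]] + 1L
      next
    }
    if (length(mz) >= 100L) {
      rej[["n_peaks"]] <- rej[["n_peaks"]] + 1L
      next
    }
    if (nchar(ch$smiles) >= 100L) {
      rej[["smiles_length"]] <- rej[["smiles_length"]] + 1L
      next
    }
    eligible[[length(eligible) + 1L]] <- ch
  }
  list(eligible = eligible, rejections = rej)
}

#' Score a prediction set against a known structure
#'
#' The outcome is `correct` when some formula-matching prediction equals
#' the truth as canonical SMILES (same-formula predictions are isomers of
#' one another, so equality after canonicalization is the decisive test);
#' `no_prediction` when the formula-filtered set is empty; otherwise
#' `unknown`, with the best Tanimoto similarity reported for diagnosis.
#'
#' @param pred A `prediction_set` that has been through [formula_filter()],
#'   or a named frequency vector / character vector of candidate SMILES.
#' @param truth_smiles The true structure's SMILES.
#' @param config An [eval_config()].
#' @param ts_method `"path"` scores with the single path-based fingerprint;
#'   `"typical"` uses the six-encoding maximum.
#' @return List of class `casmi_outcome`: `category` (one of `"correct"`,
#'   `"unknown"`, `"no_prediction"`), `best_ts`, `best_candidate`.
#' @export
casmi_score <- function(pred, truth_smiles, config = eval_config(),
                        ts_method = c("path", "typical")) {
  ts_method <- match.arg(ts_method)
  cands <- if (inherits(pred, "prediction_set")) {
    if (is.null(pred$formula_filtered))
      stop("apply formula_filter() before scoring")
    names(pred$formula_filtered)
  } else if (!is.null(names(pred))) names(pred) else as.character(pred)
  if (!length(cands)) {
    return(structure(list(category = "no_prediction", best_ts = NA_real_,
                          best_candidate = NA_character_),
                     class = "casmi_outcome"))
  }
  truth <- canonicalize(truth_smiles)
  if (truth %in% cands) {
    return(structure(list(category = "correct", best_ts = 1.0,
                          best_candidate = truth),
                     class = "casmi_outcome"))
  }
  ts <- vapply(cands, function(s) {
    if (ts_method == "path") tanimoto(truth, s, "path")
    else typical_similarity(truth, s, config$encodings)$score
  }, numeric(1))
  best <- which.max(ts)
  structure(list(category = "unknown", best_ts = ts[[best]],
                 best_candidate = cands[best]),
            class = "casmi_outcome")
}

#' @export
print.casmi_outcome <- function(x, ...) {
  cat("<casmi_outcome> ", x$category,
      if (!is.na(x$best_ts)) sprintf(" (best TS %.3f)", x$best_ts),
      "\n", sep = "")
  invisible(x)
}

#' Hook for external candidate expansion
#'
#' Placeholder for a generative neighbour search (for example a latent-space
#' autoencoder) that proposes molecules structurally close to a seed
#' candidate. The default returns the seed alone; supply your own function
#' to plug an external generator into the ranking pipeline.
#'
#' @param smiles Seed candidate SMILES.
#' @param expander Function `smiles -> character vector` (default identity).
#' @return Character vector of candidate SMILES including the seed.
#' @export
expand_candidates <- function(smiles, expander = NULL) {
  if (is.null(expander)) return(smiles)
  unique(c(smiles, expander(smiles)))
}
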