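# Peak-list IO and encoding: m/z binning to model input tokens, binned
# cosine similarity, and readers for MGF, MSP, bare numeric peak lists and
# GNPS-style JSON spectral-library records.

#' Binning settings for spectrum encoding
#'
#' Peaks below `mz_max` are mapped to integer bins of width `1/scale` Da.
#' The defaults give 50,000 bins of width 0.01 Da over [0, 500): at m/z 500
#' a 5 ppm instrument window is 0.0025 Da, so 0.01 Da bins do not lose
#' information relative to the mass accuracy assumed of the data.
#'
#' @param mz_max Upper (exclusive) m/z bound, default 500.
#' @param scale Integer bins per Da, default 100.
#' @return List of class `binning_config` with `mz_max`, `scale`, `n_bins`.
#' @export
binning_config <- function(mz_max = 500, scale = 100L) {
  stopifnot(mz_max > 0, scale >= 1L)
  n_bins <- mz_max * scale
  stopifnot(n_bins == as.integer(n_bins))
  structure(list(mz_max = mz_max, scale = as.integer(scale),
                 n_bins = as.integer(n_bins)),
            class = "binning_config")
}

#' Bin index of an m/z value
#'
#' @param mz m/z value(s) in Da, each in (0, mz_max).
#' @param config A [binning_config()].
#' @return Integer bin index/indices in `[0, n_bins)`: `floor(mz * scale)`.
#' @export
bin_index <- function(mz, config = binning_config()) {
  if (any(mz <= 0)) stop("m/z must be positive")
  if (any(mz >= config$mz_max))
    stop("m/z out of range: peaks must be below ", config$mz_max)
  as.integer(floor(mz * config$scale))
}

#' Encode a peak list as a sorted binned spectrum
#'
#' @param mz Numeric vector of peak m/z values (any order, duplicates fine).
#' @param config A [binning_config()].
#' @param max_bins Maximum number of distinct bins allowed (default 100, the
#'   model's maximum input length).
#' @return Integer vector of class `binned_spectrum`: strictly ascending,
#'   deduplicated bin indices.
#' @export
encode_spectrum <- function(mz, config = binning_config(), max_bins = 100L) {
  if (!length(mz)) return(structure(integer(0), class = "binned_spectrum"))
  bins <- sort(unique(bin_index(mz, config)))
  if (length(bins) > max_bins)
    stop("spectrum has ", length(bins), " distinct bins; at most ",
         max_bins, " are supported")
  structure(bins, class = "binned_spectrum")
}

#' Cosine similarity of two binned spectra
#'
#' Spectra are treated as binary occurrence vectors over the bin range, so
#' the score is `|a intersect b| / (sqrt(|a|) * sqrt(|b|))`.
#'
#' @param a,b Binned spectra (integer bin vectors), both non-empty.
#' @return Score in [0, 1].
#' @export
cosine_bins <- function(a, b) {
  if (!length(a) || !length(b)) stop("cannot score an empty spectrum")
  length(intersect(a, b)) / sqrt(length(unique(a)) * length(unique(b)))
}

# -- Peak-list parsing --------------------------------------------------------

new_experimental_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                                      ion_mode = NA_character_) {
  ord <- order(mz)
  structure(list(
    peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
    precursor_mz = precursor_mz,
    ion_mode = ion_mode
  ), class = "experimental_spectrum")
}

#' @export
print.experimental_spectrum <- function(x, ...) {
  cat("<experimental_spectrum> ", nrow(x$peaks), " peaks",
      if (!is.na(x$precursor_mz))
        paste0(", precursor m/z ", format(x$precursor_mz)),
      if (!is.na(x$ion_mode)) paste0(", ", x$ion_mode, " mode"),
      "\n", sep = "")
  invisible(x)
}

parse_numeric_or_stop <- function(tok, line_no) {
  v <- suppressWarnings(as.numeric(tok))
  if (any(is.na(v)))
    stop("non-numeric token ", sQuote(tok[which(is.na(v))[1]]),
         " on line ", line_no)
  v
}

parse_mgf_text <- function(lines) {
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (!length(begins) || length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  lapply(seq_along(begins), function(i) {
    block <- seq.int(begins[i] + 1L, ends[i] - 1L)
    precursor <- NA_real_
    mode <- NA_character_
    mz <- numeric(0); int <- numeric(0)
    for (j in block) {
      ln <- trimws(lines[j])
      if (!nzchar(ln)) next
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        key <- toupper(kv[1])
        if (key == "PEPMASS")
          precursor <- parse_numeric_or_stop(strsplit(trimws(kv[2]),
                                                      "[ \t]+")[[1]][1], j)
        if (key == "CHARGE")
          mode <- if (grepl("-", kv[2], fixed = TRUE)) "negative" else "positive"
        next
      }
      tok <- strsplit(ln, "[ \t,]+")[[1]]
      vals <- parse_numeric_or_stop(tok, j)
      mz <- c(mz, vals[1])
      int <- c(int, if (length(vals) > 1) vals[2] else NA_real_)
    }
    new_experimental_spectrum(mz, int, precursor, mode)
  })
}

parse_msp_text <- function(lines) {
  name_lines <- grep("^NAME:", lines, ignore.case = TRUE)
  if (!length(name_lines)) stop("malformed MSP: no NAME field")
  bounds <- c(name_lines, length(lines) + 1L)
  lapply(seq_along(name_lines), function(i) {
    block <- seq.int(bounds[i], bounds[i + 1L] - 1L)
    precursor <- NA_real_
    mode <- NA_character_
    mz <- numeric(0); int <- numeric(0)
    for (j in block) {
      ln <- trimws(lines[j])
      if (!nzchar(ln)) next
      if (grepl("^[A-Za-z]", ln)) {
        kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
        key <- toupper(trimws(kv[1]))
        if (key %in% c("PRECURSORMZ", "PRECURSOR_MZ"))
          precursor <- parse_numeric_or_stop(trimws(kv[2]), j)
        if (key %in% c("IONMODE", "ION_MODE"))
          mode <- tolower(trimws(kv[2]))
        next
      }
      tok <- strsplit(ln, "[ \t,;]+")[[1]]
      vals <- parse_numeric_or_stop(tok, j)
      mz <- c(mz, vals[1])
      int <- c(int, if (length(vals) > 1) vals[2] else NA_real_)
    }
    new_experimental_spectrum(mz, int, precursor, mode)
  })
}

parse_bare_peaks <- function(text) {
  tok <- strsplit(gsub("[(),;\n\t]+", " ", paste(text, collapse = " ")),
                  "[ ]+")[[1]]
  tok <- tok[nzchar(tok)]
  if (!length(tok)) stop("empty peak list")
  vals <- parse_numeric_or_stop(tok, 1L)
  # bare lists may interleave mz/intensity pairs or be mz-only; values are
  # treated as m/z unless exactly half look like relative intensities, which
  # cannot be decided reliably, so mz-only is assumed
  new_experimental_spectrum(vals, rep(NA_real_, length(vals)),
                            precursor_mz = max(vals))
}

#' Parse a peak list from text or file
#'
#' Recognizes MGF blocks (`BEGIN IONS`/`END IONS`), MSP blocks (`NAME:` ...)
#' and bare numeric lists (whitespace-, comma- or parenthesis-separated m/z
#' values). For bare lists the precursor is taken as the largest m/z.
#'
#' @param source A file path or character vector of text lines.
#' @param format One of `"auto"`, `"mgf"`, `"msp"`, `"bare"`.
#' @return A single `experimental_spectrum` (if the source holds exactly
#'   one), otherwise a list of them.
#' @export
parse_peaks <- function(source, format = c("auto", "mgf", "msp", "bare")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  if (!length(lines) || !any(nzchar(trimws(lines)))) stop("empty peak list")
  if (format == "auto") {
    format <- if (any(grepl("^BEGIN IONS", lines))) "mgf"
    else if (any(grepl("^NAME:", lines, ignore.case = TRUE))) "msp"
    else "bare"
  }
  out <- switch(format,
                mgf = parse_mgf_text(lines),
                msp = parse_msp_text(lines),
                bare = list(parse_bare_peaks(lines)))
  if (length(out) == 1L) out[[1L]] else out
}

# -- GNPS-style JSON records --------------------------------------------------

#' Parse and filter GNPS-style JSON spectral-library records
#'
#' Each record must carry a SMILES string, an ion mode and a peak array
#' (`[[mz, intensity], ...]`). Records are retained only when all fields are
#' present (no `"N/A"`), the ion mode is positive, every peak m/z is below
#' `mz_max`, the SMILES length is at most `max_smiles_len` and there are at
#' most `max_peaks` peaks -- the same filters applied when assembling
#' training data.
#'
#' @param source Path to a JSON file, a JSON string, or an already-parsed
#'   list of records.
#' @param mz_max Peak m/z upper bound (default 500).
#' @param max_smiles_len Maximum SMILES length in characters (default 99).
#' @param max_peaks Maximum peak count (default 100).
#' @return List with `pairs` (list of `list(molecule, spectrum)` for
#'   retained records) and `rejections` (named counts per filter, in
#'   application order: `missing`, `ion_mode`, `mz_range`, `smiles_length`,
#'   `n_peaks`, `invalid_smiles`).
#' @export
parse_gnps_records <- function(source, mz_max = 500, max_smiles_len = 99L,
                               max_peaks = 100L) {
  records <- if (is.character(source)) {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  } else source
  rej <- c(missing = 0L, ion_mode = 0L, mz_range = 0L,
           smiles_length = 0L, n_peaks = 0L, invalid_smiles = 0L)
  pairs <- list()
  get_field <- function(rec, names) {
    for (nm in names) if (!is.null(rec[[nm]])) return(rec[[nm]])
    NULL
  }
  for (rec in records) {
    smiles <- get_field(rec, c("smiles", "SMILES", "Smiles"))
    mode <- get_field(rec, c("ion_mode", "Ion_Mode", "ionmode", "IonMode"))
    peaks <- get_field(rec, c("peaks", "peaks_json", "Peaks"))
    if (is.null(smiles) || is.null(mode) || is.null(peaks) ||
        identical(toupper(as.character(smiles)), "N/A") ||
        identical(toupper(as.character(mode)), "N/A")) {
      rej[["missing"]] <- rej[["missing"]] + 1L
      next
    }
    if (!grepl("^pos", tolower(as.character(mode)))) {
      rej[["ion_mode"]] <- rej[["ion_mode"]] + 1L
      next
    }
    pk <- if (is.character(peaks)) jsonlite::fromJSON(peaks) else
      do.call(rbind, lapply(peaks, unlist))
    pk <- matrix(as.numeric(pk), ncol = 2)
    if (any(pk[, 1] >= mz_max)) {
      rej[["mz_range"]] <- rej[["mz_range"]] + 1L
      next
    }
    if (nchar(smiles) > max_smiles_len) {
      rej[["smiles_length"]] <- rej[["smiles_length"]] + 1L
      next
    }
    if (nrow(pk) > max_peaks) {
      rej[["n_peaks"]] <- rej[["n_peaks"]] + 1L
      next
    }
    record <- tryCatch(molecule_record(smiles, source_tag = "gnps"),
                       error = function(e) NULL)
    if (is.null(record)) {
      rej[["invalid_smiles"]] <- rej[["invalid_smiles"]] + 1L
      next
    }
    spectrum <- new_experimental_spectrum(pk[, 1], pk[, 2],
                                          precursor_mz = max(pk[, 1]),
                                          ion_mode = "positive")
    pairs[[length(pairs) + 1L]] <- list(molecule = record,
                                        spectrum = spectrum)
  }
  list(pairs = pairs, rejections = rej)
}
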