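# Core chemistry: canonical SMILES, molecular formulas, monoisotopic masses,
# and exhaustive formula enumeration from an exact neutral mass.

#' Monoisotopic masses of the most abundant isotope, in Da
#'
#' Sources: CODATA-consistent values to >= 6 decimal places. The proton mass
#' (`"p"`) is included for adduct arithmetic.
#' @format Named numeric vector, one entry per element symbol.
#' @export
MONOISOTOPIC_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  F  = 18.9984031627,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904468,
  Si = 27.9769265327,
  Na = 22.98976928,
  K  = 38.9637064864,
  B  = 11.0093054,
  Se = 79.9165218,
  p  = 1.00727646
)

#' Mass of a proton in Da (positive-mode adduct shift)
#' @export
PROTON_MASS <- 1.00727646

# -- SMILES canonicalization --------------------------------------------------

# Textually remove stereo bond markers and isotope labels. "[C@@H]" -> "[CH]"
# keeps the explicit hydrogen count, so composition is unaffected.
strip_stereo_isotopes <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("/", "", s, fixed = TRUE)
  s <- gsub("\\", "", s, fixed = TRUE)
  # isotope label: digits immediately after an opening bracket
  gsub("\\[([0-9]+)", "[", s)
}

ob_convert <- function(from, to, source, options = NULL) {
  out <- suppressWarnings(
    if (is.null(options)) ChemmineOB::convertFormat(from, to, source)
    else ChemmineOB::convertFormat(from, to, source, options = options)
  )
  out
}

#' Canonicalize a SMILES string
#'
#' Returns the unique canonical form of a molecule's connectivity, with all
#' stereochemical and isotopic annotations removed. Two SMILES denoting the
#' same connectivity map to the same output string; the operation is
#' idempotent.
#'
#' @param smiles A single SMILES string.
#' @return The canonical, stereo-free SMILES string.
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- strip_stereo_isotopes(trimws(smiles))
  if (!nzchar(s)) stop("cannot parse SMILES: ", sQuote(smiles))
  out <- ob_convert("SMI", "CAN", s)
  out <- strsplit(out, "[\t\n ]")[[1]][1]
  if (is.na(out) || !nzchar(out)) stop("cannot parse SMILES: ", sQuote(smiles))
  out
}

# -- Molecular formulas -------------------------------------------------------

#' Parse a molecular formula string into element counts
#'
#' @param x A formula string in Hill notation, e.g. `"C21H30O5"`, or an
#'   already-parsed named count vector (returned unchanged).
#' @return Named integer vector of element counts.
#' @export
as_formula <- function(x) {
  if (is.numeric(x)) {
    stopifnot(!is.null(names(x)), all(x >= 0))
    counts <- as.integer(round(x))
    names(counts) <- names(x)
    return(counts[counts > 0L])
  }
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (!nzchar(x) || paste(parts, collapse = "") != x)
    stop("cannot parse formula: ", sQuote(x))
  el <- sub("[0-9]+$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[out > 0L]
}

#' Format element counts as a Hill-order formula string
#'
#' Carbon first, then hydrogen, then all other elements alphabetically.
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string such as `"C21H30O5"`.
#' @export
format_formula <- function(counts) {
  counts <- as_formula(counts)
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

#' Element composition of a molecule
#'
#' Counts every element including implicit hydrogens. Formal charges on
#' zwitterionic structures (e.g. carnitines) cancel and do not alter counts.
#'
#' @param smiles A SMILES string.
#' @return Named integer vector of element counts.
#' @export
formula_of <- function(smiles) {
  g <- mol_graph(smiles)
  counts <- table(g$atoms$element)
  out <- as.integer(counts)
  names(out) <- names(counts)
  nH <- sum(g$atoms$nH)
  out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + nH
  as_formula(out)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the per-element most-abundant-isotope masses.
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- as_formula(formula)
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

#' Absolute mass window for a relative ppm tolerance
#'
#' @param mass Mass in Da (>= 0).
#' @param ppm Tolerance in parts per million (> 0, default 5).
#' @return Half-width of the window in Da: `mass * ppm * 1e-6`.
#' @export
ppm_window <- function(mass, ppm = 5) {
  stopifnot(ppm > 0)
  if (any(mass < 0)) stop("mass must be non-negative")
  mass * ppm * 1e-6
}

# -- Formula enumeration ------------------------------------------------------

#' Enumerate molecular formulas consistent with an exact neutral mass
#'
#' Exhaustively lists element-count combinations whose monoisotopic mass lies
#' within a ppm window of the query mass. Candidates must have a non-negative
#' ring-plus-double-bond equivalent (RDBE = C - H/2 + N/2 + 1); no other
#' heuristic (nitrogen rule, isotope patterns) is applied. With
#' high-resolution data each fragment mass is compatible with only a handful
#' of formulae over C/H/N/O, which is what makes formula filtering effective.
#'
#' @param neutral_mass Neutral (uncharged) monoisotopic mass in Da, > 0.
#' @param ppm Relative tolerance in ppm (default 5).
#' @param elements Character vector of element symbols to consider
#'   (default `c("C","H","N","O")`; sulfur, phosphorus and halogens may be
#'   added explicitly).
#' @param max_counts Optional named integer vector of per-element upper
#'   bounds; defaults to `floor(mass / element mass)`.
#' @return Data frame with columns `formula`, `mass`, `deviation_da`,
#'   `deviation_ppm`, `rdbe`, sorted by absolute mass deviation.
#' @export
enumerate_formulas <- function(neutral_mass, ppm = 5,
                               elements = c("C", "H", "N", "O"),
                               max_counts = NULL) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1L || neutral_mass <= 0)
    stop("neutral_mass must be a single positive number")
  stopifnot(length(elements) > 0)
  unknown <- setdiff(elements, names(MONOISOTOPIC_MASS))
  if (length(unknown)) stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))

  win <- ppm_window(neutral_mass, ppm)
  masses <- MONOISOTOPIC_MASS[elements]
  bounds <- pmin(
    floor((neutral_mass + win) / masses),
    if (is.null(max_counts)) Inf else
      ifelse(elements %in% names(max_counts), max_counts[elements], Inf)
  )
  # order heaviest-first so hydrogen (finest grain) is innermost
  ord <- order(masses, decreasing = TRUE)
  elements <- elements[ord]; masses <- masses[ord]; bounds <- bounds[ord]
  k <- length(elements)
  counts <- integer(k)
  hits <- list()

  recurse <- function(i, remaining) {
    if (i == k) {
      n <- round(remaining / masses[k])
      for (cand in unique(pmax(0L, c(n - 1L, n, n + 1L)))) {
        if (cand > bounds[k]) next
        counts[k] <<- as.integer(cand)
        total_dev <- cand * masses[k] - remaining
        if (abs(total_dev) <= win) {
          f <- counts; names(f) <- elements
          hits[[length(hits) + 1L]] <<- f
        }
      }
      counts[k] <<- 0L
      return(invisible())
    }
    nmax <- min(bounds[i], floor((remaining + win) / masses[i]))
    for (n in 0:nmax) {
      counts[i] <<- as.integer(n)
      recurse(i + 1L, remaining - n * masses[i])
    }
    counts[i] <<- 0L
    invisible()
  }
  recurse(1L, neutral_mass)

  if (!length(hits)) {
    return(data.frame(formula = character(), mass = numeric(),
                      deviation_da = numeric(), deviation_ppm = numeric(),
                      rdbe = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(hits, function(f) {
    f <- f[f > 0L]
    if (!length(f)) return(NULL)
    get <- function(e) if (e %in% names(f)) f[[e]] else 0L
    rdbe <- get("C") - get("H") / 2 - get("F") / 2 - get("Cl") / 2 -
      get("Br") / 2 - get("I") / 2 + get("N") / 2 + get("P") / 2 + 1
    if (rdbe < 0) return(NULL)
    m <- monoisotopic_mass(f)
    data.frame(formula = format_formula(f), mass = m,
               deviation_da = m - neutral_mass,
               deviation_ppm = (m - neutral_mass) / neutral_mass * 1e6,
               rdbe = rdbe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    return(data.frame(formula = character(), mass = numeric(),
                      deviation_da = numeric(), deviation_ppm = numeric(),
                      rdbe = numeric(), stringsAsFactors = FALSE))
  }
  out <- out[order(abs(out$deviation_da), out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- Molecule records ---------------------------------------------------------

#' Build a molecule record from a SMILES string
#'
#' Canonicalizes the structure and attaches its formula and monoisotopic
#' mass. The canonical SMILES carries no stereo or isotope markings.
#'
#' @param smiles SMILES string.
#' @param source_tag Free-text provenance label.
#' @return A list of class `molecule_record` with elements `smiles_raw`,
#'   `smiles_canonical`, `formula` (string), `monoisotopic_mass`, and
#'   `source_tag`.
#' @export
molecule_record <- function(smiles, source_tag = "") {
  can <- canonicalize(smiles)
  f <- formula_of(can)
  structure(list(
    smiles_raw = smiles,
    smiles_canonical = can,
    formula = format_formula(f),
    monoisotopic_mass = monoisotopic_mass(f),
    source_tag = source_tag
  ), class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$smiles_canonical, "\n",
      "  formula: ", x$formula,
      "  monoisotopic mass: ", sprintf("%.5f", x$monoisotopic_mass), " Da\n",
      sep = "")
  invisible(x)
}

#' Read SMILES strings from a text or CSV file
#'
#' @param path Path to a file with one SMILES per line, or a CSV.
#' @param smiles_column For CSV input, the column holding SMILES
#'   (default `"smiles"`). Plain-text input is detected by the absence of the
#'   column header.
#' @return Character vector of SMILES strings.
#' @export
read_smiles <- function(path, smiles_column = "smiles") {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (grepl(",", first) || tolower(first) == tolower(smiles_column)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_column %in% names(df))
      stop("CSV has no column ", sQuote(smiles_column))
    return(df[[smiles_column]])
  }
  lines <- trimws(readLines(path))
  lines[nzchar(lines)]
}

#' Write molecule records as a CSV table
#'
#' Columns: `smiles_canonical`, `formula`, `monoisotopic_mass`.
#'
#' @param records List of `molecule_record` objects.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_molecule_table <- function(records, path) {
  df <- data.frame(
    smiles_canonical = vapply(records, `[[`, character(1), "smiles_canonical"),
    formula = vapply(records, `[[`, character(1), "formula"),
    monoisotopic_mass = vapply(records, `[[`, numeric(1), "monoisotopic_mass"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
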