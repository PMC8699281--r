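# Molecular graph representation used by the fragmentation engine and the
# in-package fingerprints. Heavy atoms only; hydrogens are folded into a
# per-atom count so that fragment compositions can be read off atom subsets.

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' The molecule is first canonicalized, so the resulting atom numbering is
#' independent of how the input SMILES was written. Hydrogens are made
#' explicit during perception and then collapsed onto their heavy-atom
#' neighbours as an `nH` count; aromaticity is perceived so that bond
#' eligibility for fragmentation ("single and non-aromatic") is well defined.
#'
#' @param smiles SMILES string.
#' @return A list of class `mol_graph`: `smiles` (canonical form), `atoms`
#'   (data frame: `element`, `nH`, `aromatic`), `bonds` (data frame: `a1`,
#'   `a2`, `type` in `{"1","2","3","am","ar"}`, with `a1 < a2`, sorted).
#' @export
mol_graph <- function(smiles) {
  can <- canonicalize(smiles)
  txt <- ob_convert("SMI", "MOL2", can,
                    options = data.frame(names = "h", args = ""))
  if (is.na(txt) || !nzchar(txt)) stop("cannot parse SMILES: ", sQuote(smiles))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sec <- function(tag) {
    i <- match(paste0("@<TRIPOS>", tag), lines)
    if (is.na(i)) stop("MOL2 conversion missing ", tag, " section")
    j <- grep("^@<TRIPOS>", lines)
    j <- j[j > i]
    end <- if (length(j)) min(j) - 1L else length(lines)
    lines[seq.int(i + 1L, end)]
  }
  atom_lines <- sec("ATOM")
  atom_fields <- strsplit(trimws(atom_lines), "[ \t]+")
  type <- vapply(atom_fields, `[[`, character(1), 6L)
  element <- sub("\\..*$", "", type)

  bond_lines <- sec("BOND")
  bf <- strsplit(trimws(bond_lines), "[ \t]+")
  b1 <- vapply(bf, function(x) as.integer(x[2]), integer(1))
  b2 <- vapply(bf, function(x) as.integer(x[3]), integer(1))
  btype <- vapply(bf, `[[`, character(1), 4L)

  heavy <- which(element != "H")
  idx_map <- integer(length(element))
  idx_map[heavy] <- seq_along(heavy)

  nH <- integer(length(heavy))
  is_h1 <- element[b1] == "H"
  is_h2 <- element[b2] == "H"
  for (i in which(is_h1 | is_h2)) {
    heavy_end <- if (is_h1[i]) b2[i] else b1[i]
    if (element[heavy_end] != "H") {
      nH[idx_map[heavy_end]] <- nH[idx_map[heavy_end]] + 1L
    }
  }

  keep <- !(is_h1 | is_h2)
  a1 <- idx_map[b1[keep]]; a2 <- idx_map[b2[keep]]; bt <- btype[keep]
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  ord <- order(a1, a2)

  aromatic_atom <- grepl("\\.ar$", type[heavy])

  el <- element[heavy]
  unknown <- setdiff(unique(el), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  el_f <- factor(el)
  structure(list(
    smiles = can,
    atoms = data.frame(element = el, nH = nH,
                       aromatic = aromatic_atom, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = a1[ord], a2 = a2[ord], type = bt[ord],
                       stringsAsFactors = FALSE),
    # caches for the fragmentation engine
    el_f = el_f,
    atom_mass = unname(MONOISOTOPIC_MASS[el]) + nH * MONOISOTOPIC_MASS[["H"]],
    adj_nbr = lapply(seq_along(heavy), function(i)
      c(a2[ord][a1[ord] == i], a1[ord][a2[ord] == i])),
    adj_bond = lapply(seq_along(heavy), function(i)
      c(which(a1[ord] == i), which(a2[ord] == i)))
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms in a molecule
#' @param mol A `mol_graph` or SMILES string.
#' @return Integer count.
#' @export
n_heavy_atoms <- function(mol) {
  if (is.character(mol)) mol <- mol_graph(mol)
  nrow(mol$atoms)
}

# Neutral monoisotopic mass of a subset of graph atoms (with their frozen
# hydrogen counts).
atom_subset_mass <- function(mol, atom_idx) {
  sum(mol$atom_mass[atom_idx])
}

# Element counts of a subset of graph atoms.
atom_subset_formula <- function(mol, atom_idx) {
  lev <- levels(mol$el_f)
  out <- tabulate(mol$el_f[atom_idx], nbins = length(lev))
  names(out) <- lev
  nH <- sum(mol$atoms$nH[atom_idx])
  out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + nH
  as_formula(out)
}

# Hill-order formula string for an atom subset, avoiding string re-parsing.
atom_subset_formula_string <- function(mol, atom_idx) {
  lev <- levels(mol$el_f)
  counts <- tabulate(mol$el_f[atom_idx], nbins = length(lev))
  names(counts) <- lev
  counts["H"] <- (if ("H" %in% lev) counts[["H"]] else 0L) +
    sum(mol$atoms$nH[atom_idx])
  counts <- counts[counts > 0L]
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}
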