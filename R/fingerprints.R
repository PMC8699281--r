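# Molecular fingerprints and Tanimoto (Jaccard) similarity. Six encodings
# are available: linear-path (FP2), MACCS-type keys and SMARTS
# substructure-pattern keys (FP4) from OpenBabel; atom pairs from ChemmineR;
# and topological-torsion and circular radius-2 identifier sets computed on
# the package's own molecular graph. Every encoding is reduced to a set of
# "on" features so the same Jaccard metric applies uniformly.

FP_ENCODINGS <- c("path", "atom_pair", "torsion", "maccs", "circular",
                  "pattern")

ob_fingerprint_bits <- function(smiles, name) {
  out <- ChemmineOB::forEachMol("SMILES", smiles, function(mol)
    ChemmineOB::fingerprint_OB(list(mol), name))
  v <- out[[1]]
  which(v != 0)
}

atom_pair_bits <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  apset <- ChemmineR::sdf2ap(sdf)
  unique(ChemmineR::ap(apset[[1]]))
}

circular_bits <- function(mol, radius = 2L) {
  g <- if (is.character(mol)) mol_graph(mol) else mol
  n <- nrow(g$atoms)
  ids <- paste(g$atoms$element, g$atoms$nH,
               vapply(g$adj_nbr, length, integer(1)),
               as.integer(g$atoms$aromatic), sep = "_")
  all_ids <- ids
  bond_type_of <- function(a, i) g$bonds$type[g$adj_bond[[a]][i]]
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(a) {
      nbrs <- g$adj_nbr[[a]]
      if (!length(nbrs)) return(paste0("r", r, ":", ids[a]))
      env <- sort(paste0(vapply(seq_along(nbrs), bond_type_of, character(1),
                                a = a), "~", ids[nbrs]))
      paste0("r", r, ":", ids[a], "(", paste(env, collapse = "|"), ")")
    }, character(1))
    all_ids <- c(all_ids, ids)
  }
  unique(all_ids)
}

torsion_bits <- function(mol) {
  g <- if (is.character(mol)) mol_graph(mol) else mol
  atype <- paste(g$atoms$element, as.integer(g$atoms$aromatic),
                 vapply(g$adj_nbr, length, integer(1)), sep = "_")
  out <- character(0)
  for (i in seq_len(nrow(g$bonds))) {
    b <- g$bonds$a1[i]; c_ <- g$bonds$a2[i]
    for (a in setdiff(g$adj_nbr[[b]], c_)) {
      for (d in setdiff(g$adj_nbr[[c_]], b)) {
        if (a == d) next
        fwd <- paste(atype[c(a, b, c_, d)], collapse = "-")
        rev_ <- paste(atype[c(d, c_, b, a)], collapse = "-")
        out <- c(out, min(fwd, rev_))
      }
    }
  }
  unique(out)
}

#' Fingerprint feature set of a molecule
#'
#' @param smiles SMILES string.
#' @param encoding One of `"path"` (linear paths, FP2), `"atom_pair"`,
#'   `"torsion"` (topological torsions), `"maccs"` (MACCS-type keys),
#'   `"circular"` (radius-2 neighbourhood identifiers), `"pattern"`
#'   (SMARTS substructure keys, FP4).
#' @return Vector of on-features (integers or identifier strings).
#' @export
fingerprint_bits <- function(smiles, encoding = FP_ENCODINGS) {
  encoding <- match.arg(encoding)
  switch(encoding,
         path = ob_fingerprint_bits(smiles, "FP2"),
         maccs = ob_fingerprint_bits(smiles, "MACCS"),
         pattern = ob_fingerprint_bits(smiles, "FP4"),
         atom_pair = atom_pair_bits(smiles),
         circular = circular_bits(smiles),
         torsion = torsion_bits(smiles))
}

jaccard_sets <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Tanimoto similarity under one fingerprint encoding
#'
#' @param a,b SMILES strings.
#' @param encoding Fingerprint encoding (see [fingerprint_bits()]); default
#'   `"path"`.
#' @return Jaccard coefficient of the two feature sets, in [0, 1].
#' @export
tanimoto <- function(a, b, encoding = "path") {
  jaccard_sets(fingerprint_bits(a, encoding), fingerprint_bits(b, encoding))
}

#' Maximum Tanimoto similarity over several fingerprint encodings
#'
#' Molecular similarity depends strongly on the encoding, so this score
#' computes the Jaccard coefficient under each configured encoding and
#' takes the largest, reporting which encoding attained it. Encodings that
#' fail on either molecule are skipped with a warning.
#'
#' @param a,b SMILES strings.
#' @param encodings Character vector of encodings (default all six).
#' @return List of class `typical_similarity`: `score` (the maximum),
#'   `encoding` (which attained it), `per_encoding` (named vector).
#' @export
typical_similarity <- function(a, b, encodings = FP_ENCODINGS) {
  stopifnot(length(encodings) >= 1L)
  scores <- vapply(encodings, function(enc) {
    tryCatch(tanimoto(a, b, enc), error = function(e) {
      warning("encoding ", enc, " failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  if (all(is.na(scores))) stop("all fingerprint encodings failed")
  best <- which.max(scores)
  structure(list(score = scores[[best]], encoding = encodings[best],
                 per_encoding = scores),
            class = "typical_similarity")
}

#' @export
print.typical_similarity <- function(x, ...) {
  cat("<typical_similarity> ", sprintf("%.4f", x$score),
      " (", x$encoding, ")\n", sep = "")
  invisible(x)
}
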