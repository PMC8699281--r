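# Recursive in silico fragmentation. Bonds are broken serially and
# recursively: each break yields two fragments, or one fragment for a
# ring-opening break. Hydrogen counts are frozen at their parent values
# (homolytic bookkeeping, no rearrangements), and each surviving fragment is
# shifted by the configured adduct masses to give theoretical peak m/z values.

#' Fragmentation settings
#'
#' @param max_depth Maximum recursion depth (number of successive bond-break
#'   generations), default 3.
#' @param min_fragment_mass Fragments lighter than this neutral mass (Da) are
#'   discarded and not fragmented further; default 50. The intact molecule is
#'   always retained.
#' @param bond_types MOL2 bond types a breakable bond may have. The default
#'   `c("1", "am")` restricts fragmentation to single, non-aromatic bonds
#'   (amide bonds are single bonds); all graph bonds join heavy atoms.
#' @param adducts Named numeric vector of adduct mass shifts in Da applied to
#'   each neutral fragment; default protonation only.
#' @param dedup_decimals Peaks are deduplicated after rounding m/z to this
#'   many decimal places (default 5).
#' @return A list of class `fragmentation_config`.
#' @export
fragmentation_config <- function(max_depth = 3L,
                                 min_fragment_mass = 50,
                                 bond_types = c("1", "am"),
                                 adducts = c("[M+H]+" = 1.00727646),
                                 dedup_decimals = 5L) {
  stopifnot(max_depth >= 1L, min_fragment_mass >= 0,
            length(adducts) >= 1L, !is.null(names(adducts)),
            dedup_decimals >= 0L)
  structure(list(max_depth = as.integer(max_depth),
                 min_fragment_mass = min_fragment_mass,
                 bond_types = bond_types,
                 adducts = adducts,
                 dedup_decimals = as.integer(dedup_decimals)),
            class = "fragmentation_config")
}

#' Bonds eligible for fragmentation
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param config A [fragmentation_config()].
#' @return Data frame with columns `bond_id`, `a1`, `a2`, `type`, in
#'   ascending `(a1, a2)` order. Aromatic and multiple bonds are excluded.
#' @export
eligible_bonds <- function(mol, config = fragmentation_config()) {
  if (is.character(mol)) mol <- mol_graph(mol)
  keep <- which(mol$bonds$type %in% config$bond_types)
  out <- cbind(bond_id = keep, mol$bonds[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Root fragment of a molecule (the intact structure, depth 0)
#'
#' @param mol A `mol_graph` or SMILES string.
#' @return A list of class `mol_fragment`: `atoms` (heavy-atom indices),
#'   `bond_ids` (remaining bonds, indices into the parent bond table),
#'   `broken` (bond ids broken so far), `depth`, `neutral_mass`, `formula`.
#' @export
root_fragment <- function(mol) {
  if (is.character(mol)) mol <- mol_graph(mol)
  new_fragment(mol, seq_len(nrow(mol$atoms)), seq_len(nrow(mol$bonds)),
               integer(0), 0L)
}

new_fragment <- function(mol, atoms, bond_ids, broken, depth) {
  structure(list(atoms = atoms, bond_ids = bond_ids, broken = broken,
                 depth = depth,
                 neutral_mass = atom_subset_mass(mol, atoms),
                 formula = atom_subset_formula_string(mol, atoms)),
            class = "mol_fragment")
}

# Fast internal split: remove `bond_id` from a fragment state and return the
# resulting child states (plain lists without formula strings). A BFS from
# one endpoint of the removed bond decides between a ring opening (other
# endpoint still reachable: one child, same atoms) and a true split (two
# children partitioning the atom set).
split_bond <- function(mol, atoms, bond_ids, bond_id, depth, broken) {
  rem <- bond_ids[bond_ids != bond_id]
  inb <- logical(nrow(mol$bonds))
  inb[rem] <- TRUE
  from <- mol$bonds$a1[bond_id]
  to <- mol$bonds$a2[bond_id]
  vis <- logical(nrow(mol$atoms))
  vis[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- mol$adj_nbr[[v]]
      keep <- inb[mol$adj_bond[[v]]] & !vis[nb]
      if (any(keep)) {
        nn <- nb[keep]
        vis[nn] <- TRUE
        nxt <- c(nxt, nn)
      }
    }
    frontier <- nxt
  }
  d <- depth + 1L
  brk <- c(broken, bond_id)
  if (vis[to]) {
    return(list(list(atoms = atoms, bond_ids = rem, depth = d, broken = brk)))
  }
  in1 <- vis[atoms]
  a1s <- atoms[in1]
  a2s <- atoms[!in1]
  side <- vis[mol$bonds$a1[rem]]
  list(list(atoms = a1s, bond_ids = rem[side], depth = d, broken = brk),
       list(atoms = a2s, bond_ids = rem[!side], depth = d, broken = brk))
}

#' Break one bond of a fragment
#'
#' Removing a bond either disconnects the fragment graph, giving two child
#' fragments that partition the atom set, or (for a bond inside a ring)
#' leaves it connected, giving a single ring-opened child with the same
#' atoms. Either way the child depth is one more than the parent's and all
#' per-atom hydrogen counts are inherited unchanged.
#'
#' @param mol The parent `mol_graph`.
#' @param fragment A `mol_fragment`.
#' @param bond_id Bond to break (index into `mol$bonds`); must be present in
#'   the fragment.
#' @return List of one or two `mol_fragment` objects.
#' @export
break_bond <- function(mol, fragment, bond_id) {
  if (!bond_id %in% fragment$bond_ids)
    stop("bond ", bond_id, " is not part of this fragment")
  children <- split_bond(mol, fragment$atoms, fragment$bond_ids, bond_id,
                         fragment$depth, fragment$broken)
  lapply(children, function(ch)
    new_fragment(mol, ch$atoms, ch$bond_ids, ch$broken, ch$depth))
}

#' Generate a theoretical fragmentation spectrum
#'
#' Applies [break_bond()] breadth-first to every eligible bond of every
#' fragment until `max_depth`, discarding fragments below
#' `min_fragment_mass`. Identical fragment states (same atom set and same
#' remaining bonds) reached by different break orders are expanded once, at
#' their minimum depth; the peak list is unchanged by this because peaks are
#' deduplicated. Each adduct shift is added to every surviving fragment's
#' neutral mass; the protonated (first-adduct) molecular ion is always
#' present.
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param config A [fragmentation_config()].
#' @return A list of class `theoretical_spectrum`: `peaks` (sorted unique
#'   m/z), `precursor_mz`, `provenance` (data frame: `mz`, `formula`,
#'   `depth`, `n_bonds_broken`, `bonds_broken`, `adduct`), `smiles`.
#' @export
fragment_molecule <- function(mol, config = fragmentation_config()) {
  if (is.character(mol)) mol <- mol_graph(mol)
  elig <- eligible_bonds(mol, config)$bond_id
  root <- root_fragment(mol)

  visited <- new.env(parent = emptyenv(), hash = TRUE)
  state_key <- function(f) paste(paste(f$atoms, collapse = ","),
                                 paste(f$bond_ids, collapse = ","), sep = "|")
  root_state <- list(atoms = root$atoms, bond_ids = root$bond_ids,
                     depth = 0L, broken = integer(0))
  assign(state_key(root_state), 0L, envir = visited)

  in_elig <- logical(nrow(mol$bonds))
  in_elig[elig] <- TRUE
  frags <- list(root)
  queue <- list(root_state)
  head <- 1L
  while (head <= length(queue)) {
    f <- queue[[head]]; head <- head + 1L
    if (f$depth >= config$max_depth) next
    for (b in f$bond_ids[in_elig[f$bond_ids]]) {
      for (child in split_bond(mol, f$atoms, f$bond_ids, b,
                               f$depth, f$broken)) {
        if (sum(mol$atom_mass[child$atoms]) < config$min_fragment_mass) next
        key <- state_key(child)
        if (!is.null(get0(key, envir = visited))) next
        assign(key, child$depth, envir = visited)
        frags[[length(frags) + 1L]] <-
          new_fragment(mol, child$atoms, child$bond_ids, child$broken,
                       child$depth)
        if (child$depth < config$max_depth)
          queue[[length(queue) + 1L]] <- child
      }
    }
  }

  na <- length(config$adducts)
  masses <- vapply(frags, `[[`, numeric(1), "neutral_mass")
  prov <- data.frame(
    mz = round(rep(masses, each = na) + rep(unname(config$adducts),
                                            length(frags)),
               config$dedup_decimals),
    formula = rep(vapply(frags, `[[`, character(1), "formula"), each = na),
    depth = rep(vapply(frags, `[[`, integer(1), "depth"), each = na),
    n_bonds_broken = rep(vapply(frags, function(f) length(f$broken),
                                integer(1)), each = na),
    bonds_broken = rep(vapply(frags, function(f)
      paste(f$broken, collapse = ";"), character(1)), each = na),
    adduct = rep(names(config$adducts), length(frags)),
    stringsAsFactors = FALSE
  )
  prov <- prov[order(prov$mz, prov$depth), , drop = FALSE]
  structure(list(
    peaks = sort(unique(prov$mz)),
    precursor_mz = round(root$neutral_mass + config$adducts[[1L]],
                         config$dedup_decimals),
    provenance = prov,
    smiles = mol$smiles
  ), class = "theoretical_spectrum")
}

#' @export
print.theoretical_spectrum <- function(x, ...) {
  cat("<theoretical_spectrum> ", x$smiles, "\n  ",
      length(x$peaks), " peaks, precursor m/z ",
      sprintf("%.5f", x$precursor_mz), "\n", sep = "")
  invisible(x)
}

#' Depth-wise series of theoretical spectra
#'
#' One spectrum per bond-breaking generation up to three, mirroring the
#' depth-wise augmentation used to build training data: shallow depths mimic
#' the high-intensity early breaks of a real instrument, deeper ones add
#' progressively noisier secondary fragments. Every element contains the
#' protonated molecular ion.
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param config A [fragmentation_config()] with `max_depth >= 3`.
#' @return List of three `theoretical_spectrum` objects (depths 1, 2, 3).
#' @export
depth_series <- function(mol, config = fragmentation_config()) {
  stopifnot(config$max_depth >= 3L)
  if (is.character(mol)) mol <- mol_graph(mol)
  lapply(1:3, function(d) {
    cfg <- config
    cfg$max_depth <- d
    fragment_molecule(mol, cfg)
  })
}

#' Write theoretical spectra as MSP blocks
#'
#' Each spectrum becomes a `NAME`/`PRECURSORMZ`/`Num Peaks` block with one
#' `m/z intensity` line per peak (intensity 100 throughout: the engine
#' predicts presence or absence of peaks, not abundances).
#'
#' @param spectra A `theoretical_spectrum` or list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(spectra, path) {
  if (inherits(spectra, "theoretical_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      paste0("NAME: ", sp$smiles),
      paste0("PRECURSORMZ: ", format(sp$precursor_mz, nsmall = 5)),
      paste0("Num Peaks: ", length(sp$peaks)),
      paste(format(sp$peaks, trim = TRUE, nsmall = 5), "100"),
      ""
    ), con)
  }
  invisible(path)
}

#' Write theoretical spectra in long CSV form
#'
#' Columns: `smiles`, `mz`, `formula`, `depth`, `bonds_broken`.
#'
#' @param spectra A `theoretical_spectrum` or list of them.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "theoretical_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, function(sp) {
    cbind(smiles = sp$smiles,
          sp$provenance[, c("mz", "formula", "depth", "bonds_broken")])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
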