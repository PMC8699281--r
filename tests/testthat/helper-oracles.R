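# Independent oracles and shared fixtures. Each oracle deliberately takes a
# different algorithmic route from the package implementation it checks.

# Fixture molecules are generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture_molecules <- function(n = 50L, seed = 7L) {
  key <- paste0("m", n, "_", seed)
  got <- get0(key, envir = .fixture_cache)
  if (is.null(got)) {
    got <- generate_fixture_molecules(n, seed = seed)
    assign(key, got, envir = .fixture_cache)
  }
  got
}

fixture_smiles <- function(n = 50L, seed = 7L) {
  vapply(fixture_molecules(n, seed), `[[`, character(1), "smiles_canonical")
}

# Brute-force fragmentation oracle: enumerates every sequence of at most
# `depth` eligible-bond removals (no deduplication, no breadth-first
# bookkeeping) and collects the protonated masses of all surviving
# fragments. Connectivity is decided by iterative label propagation, not
# the package's BFS split.
oracle_fragment_peaks <- function(smiles, depth, min_mass = 50,
                                  proton = PROTON_MASS, decimals = 5L) {
  g <- mol_graph(smiles)
  atom_mass <- MONOISOTOPIC_MASS[g$atoms$element] +
    g$atoms$nH * MONOISOTOPIC_MASS[["H"]]
  components <- function(atoms, bonds) {
    lab <- stats::setNames(seq_along(atoms), atoms)
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(bonds))) {
        l1 <- lab[[as.character(bonds$a1[i])]]
        l2 <- lab[[as.character(bonds$a2[i])]]
        if (l1 != l2) {
          lab[lab == max(l1, l2)] <- min(l1, l2)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    unname(split(atoms, lab))
  }
  masses <- sum(atom_mass)  # intact molecule, always kept
  recurse <- function(atoms, bonds, d) {
    if (d >= depth) return(invisible())
    idx <- which(bonds$type %in% c("1", "am"))
    for (i in idx) {
      rem <- bonds[-i, , drop = FALSE]
      for (comp in components(atoms, rem)) {
        m <- sum(atom_mass[comp])
        if (m < min_mass) next
        masses <<- c(masses, m)
        cb <- rem[rem$a1 %in% comp & rem$a2 %in% comp, , drop = FALSE]
        recurse(comp, cb, d + 1L)
      }
    }
    invisible()
  }
  recurse(seq_len(nrow(g$atoms)), g$bonds, 0L)
  sort(unique(round(masses + proton, decimals)))
}

# Exhaustive nested-loop formula enumerator over C/H/N/O.
oracle_enumerate_chno <- function(mass, ppm = 5) {
  win <- mass * ppm * 1e-6
  mC <- MONOISOTOPIC_MASS[["C"]]; mH <- MONOISOTOPIC_MASS[["H"]]
  mN <- MONOISOTOPIC_MASS[["N"]]; mO <- MONOISOTOPIC_MASS[["O"]]
  out <- character(0)
  for (c_ in 0:floor((mass + win) / mC))
    for (n in 0:floor((mass + win) / mN))
      for (o in 0:floor((mass + win) / mO))
        for (h in 0:floor((mass + win) / mH)) {
          m <- c_ * mC + h * mH + n * mN + o * mO
          if (abs(m - mass) > win) next
          if (c_ - h / 2 + n / 2 + 1 < 0) next
          if (c_ + h + n + o == 0) next
          f <- integer(0)
          if (c_) f["C"] <- c_
          if (h) f["H"] <- h
          if (n) f["N"] <- n
          if (o) f["O"] <- o
          out <- c(out, format_formula(f))
        }
  sort(out)
}

# Regex-based SMILES splitter (single pass, alternation), independent of
# the package's greedy two-character scanner.
oracle_tokenize <- function(smiles, two_letter) {
  if (!nzchar(smiles)) return(character(0))
  pat <- paste0("(", paste(two_letter, collapse = "|"), "|.)")
  regmatches(smiles, gregexpr(pat, smiles))[[1]]
}

# Dense-vector cosine on explicit 0/1 occurrence vectors.
oracle_cosine_dense <- function(a, b, n_bins = 50000L) {
  va <- numeric(n_bins); vb <- numeric(n_bins)
  va[a + 1L] <- 1; vb[b + 1L] <- 1
  sum(va * vb) / sqrt(sum(va) * sum(vb))
}

# Graph isomorphism with element/hydrogen colours, via igraph's VF2.
oracle_same_molecule <- function(s1, s2) {
  g1 <- mol_graph(s1); g2 <- mol_graph(s2)
  if (nrow(g1$atoms) != nrow(g2$atoms)) return(FALSE)
  colour <- function(g) as.integer(factor(paste(g$atoms$element, g$atoms$nH),
    levels = unique(c(paste(g1$atoms$element, g1$atoms$nH),
                      paste(g2$atoms$element, g2$atoms$nH)))))
  ig <- function(g, col) igraph::graph_from_edgelist(
    as.matrix(g$bonds[, c("a1", "a2")]), directed = FALSE)
  igraph::isomorphic(ig(g1), ig(g2), method = "vf2",
                     vertex.color1 = colour(g1), vertex.color2 = colour(g2))
}

# Closed-form parameter count written out long-hand, independent of
# count_parameters().
oracle_param_count <- function(ne, nd, d, dff, n_bins, v) {
  emb <- (n_bins + 1) * d + v * d
  one_attn <- (3 * d * d + 3 * d) + (d * d + d)
  one_ffn <- (d * dff + dff) + (dff * d + d)
  one_ln <- d + d
  enc <- ne * (one_attn + one_ffn + 2 * one_ln)
  dec <- nd * (2 * one_attn + one_ffn + 3 * one_ln)
  proj <- d * v + v
  emb + enc + dec + proj
}

# Small, fast model/training setup shared by model tests.
tiny_model_config <- function(...) {
  defaults <- list(n_encoder_layers = 1L, n_decoder_layers = 1L,
                   d_model = 16L, n_heads = 2L, d_ff = 32L, dropout = 0,
                   n_bins = 100L, vocab_size = 12L, max_input_len = 10L,
                   max_output_len = 12L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_vocab <- function() {
  tokens <- c("<sos>", "<eos>", "<unk>", "<pad>", "C", "N", "O", "(", ")",
              "=", "1", "2")
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, ids = ids, size = length(tokens),
                 sos = 0L, eos = 1L, unk = 2L, pad = 3L),
            class = "smiles_vocabulary")
}

tiny_samples <- function() {
  list(list(bins = c(5L, 40L, 77L), target = c(0L, 4L, 4L, 6L, 1L)),
       list(bins = c(12L, 60L), target = c(0L, 5L, 4L, 1L)),
       list(bins = c(3L, 33L, 66L, 90L), target = c(0L, 6L, 4L, 5L, 4L, 1L)))
}
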