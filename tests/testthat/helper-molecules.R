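# Shared test helpers: random molecule generation, brute-force oracles,
# atom permutation.

# Random connected molecular graph (single bonds, C/N/O), optionally with
# one extra ring-closing edge. Deterministic under the given seed.
rand_mol <- function(n_atoms, seed, ring = FALSE) {
  set.seed(seed)
  elements <- sample(c("C", "C", "C", "N", "O"), n_atoms, replace = TRUE)
  atoms <- tibble::tibble(
    element = elements, charge = 0L, isotope = NA_integer_,
    hcount = 0L, aromatic = FALSE, chiral = NA_character_
  )
  bonds <- if (n_atoms > 1L) {
    tibble::tibble(
      from = 2:n_atoms,
      to = vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L), integer(1)),
      order = 1L, aromatic = FALSE, stereo = NA_character_
    )
  } else qsarkit:::empty_bonds()
  if (ring && n_atoms >= 4L) {
    repeat {
      cand <- sort(sample.int(n_atoms, 2L))
      exists <- any((bonds$from == cand[2L] & bonds$to == cand[1L]) |
                      (bonds$from == cand[1L] & bonds$to == cand[2L]))
      if (!exists) {
        bonds <- dplyr::bind_rows(bonds, tibble::tibble(
          from = cand[1L], to = cand[2L], order = 1L, aromatic = FALSE,
          stereo = NA_character_
        ))
        break
      }
    }
  }
  m <- qsarkit:::new_mol_graph(atoms, bonds)
  m$atoms$hcount <- qsarkit:::implicit_hcount(m)
  m
}

# Apply an atom permutation: new index of old atom i is perm[i].
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[inv, , drop = FALSE]
  bonds <- mol$bonds
  bonds$from <- perm[bonds$from]
  bonds$to <- perm[bonds$to]
  qsarkit:::new_mol_graph(atoms, bonds, mol$name, mol$props)
}

# Brute-force all-pairs shortest paths by breadth-first search, independent
# of igraph.
bfs_distances <- function(mol) {
  keep <- which(mol$atoms$element != "H")
  n <- length(keep)
  map <- match(seq_len(nrow(mol$atoms)), keep)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    u <- map[mol$bonds$from[i]]; v <- map[mol$bonds$to[i]]
    if (is.na(u) || is.na(v)) next
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# Independent simple-path count via igraph enumeration from every vertex.
igraph_path_count <- function(mol, len) {
  keep <- which(mol$atoms$element != "H")
  g <- qsarkit:::mol_graph_heavy(mol)
  total <- 0L
  for (v in seq_along(keep)) {
    paths <- igraph::all_simple_paths(g, from = v, cutoff = len)
    total <- total + sum(lengths(paths) == len + 1L)
  }
  total %/% 2L
}

# OpenBabel canonical SMILES, used as an independent canonicalization
# oracle (equality semantics only).
obabel_canonical <- function(smiles) {
  out <- suppressWarnings(system2(
    "obabel", c(paste0("-:", shQuote(smiles)), "-ocan"),
    stdout = TRUE, stderr = FALSE
  ))
  trimws(out[length(out)])
}
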