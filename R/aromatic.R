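# Ring perception and the aromatic <-> Kekule interconversion.

# Smallest set of smallest rings (practically: the shortest cycle through
# every cycle edge, de-duplicated). Returns a list of atom-index vectors in
# ring order.
perceive_rings <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L || nrow(mol$bonds) == 0L) return(list())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  bridges <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(bridges))
  rings <- list()
  seen <- character()
  for (e in cyc_edges) {
    gg <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(
      gg, from = mol$bonds$from[e], to = mol$bonds$to[e]
    )$vpath[[1]])
    if (length(sp) < 3L) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

ring_bond_rows <- function(mol, ring) {
  pairs <- cbind(ring, c(ring[-1L], ring[1L]))
  apply(pairs, 1L, function(p) {
    which((mol$bonds$from == p[1] & mol$bonds$to == p[2]) |
            (mol$bonds$from == p[2] & mol$bonds$to == p[1]))[1L]
  })
}

# Does this atom, inside an aromatic system, contribute a lone pair
# (pyrrole/furan type) rather than requiring an in-ring double bond?
aromatic_lone_pair_donor <- function(mol, a, degree) {
  el <- mol$atoms$element[a]
  ch <- mol$atoms$charge[a]
  h <- mol$atoms$hcount[a]
  if (el %in% c("O", "S") && ch <= 0L) return(TRUE)
  if (el %in% c("N", "P")) {
    if (ch < 0L) return(TRUE)
    if (ch == 0L && (h >= 1L || degree[a] == 3L)) return(TRUE)
    return(FALSE)
  }
  if (el == "C" && ch < 0L) return(TRUE)
  FALSE
}

#' Resolve aromatic flags into an explicit Kekule bond assignment
#'
#' Aromatic-flagged bonds are replaced by alternating single/double bonds.
#' Atoms that donate a lone pair into the ring (pyrrole-type N, furan O,
#' thiophene S, anionic C) and atoms already carrying an exocyclic double
#' bond are excluded from the double-bond matching. Each aromatic ring is
#' additionally checked against the Hueckel 4n+2 electron count; rings that
#' fail (e.g. an aromatic-flagged cyclobutadiene) raise an error.
#'
#' The operation is idempotent: a kekulized molecule passes through
#' unchanged.
#'
#' @param mol a `mol_graph`.
#' @return A kekulized `mol_graph` (no aromatic flags remain).
#' @export
#' @examples
#' kekulize(parse_smiles("c1ccccc1"))$bonds$order
kekulize <- function(mol) {
  if (is_kekulized(mol)) {
    mol$atoms$aromatic <- FALSE
    return(mol)
  }
  arom_bond <- which(mol$bonds$aromatic)
  arom_atom <- sort(unique(c(mol$bonds$from[arom_bond],
                             mol$bonds$to[arom_bond])))
  degree <- atom_degree(mol)

  exo_double <- vapply(arom_atom, function(a) {
    rows <- which((mol$bonds$from == a | mol$bonds$to == a) &
                    !mol$bonds$aromatic & mol$bonds$order >= 2L)
    length(rows) > 0L
  }, logical(1))
  donor <- vapply(arom_atom, aromatic_lone_pair_donor,
                  logical(1), mol = mol, degree = degree)
  cation_c <- mol$atoms$element[arom_atom] == "C" &
    mol$atoms$charge[arom_atom] > 0L
  needs_double <- !(donor | exo_double | cation_c)
  need <- arom_atom[needs_double]

  # candidate partners: aromatic bonds whose two ends both need a double bond
  cand <- lapply(need, function(a) {
    rows <- arom_bond[(mol$bonds$from[arom_bond] == a &
                         mol$bonds$to[arom_bond] %in% need) |
                        (mol$bonds$to[arom_bond] == a &
                           mol$bonds$from[arom_bond] %in% need)]
    other <- ifelse(mol$bonds$from[rows] == a,
                    mol$bonds$to[rows], mol$bonds$from[rows])
    cbind(other, rows)
  })
  names(cand) <- as.character(need)

  matched <- integer(0) # bond rows carrying the double bonds
  assign_match <- function(unmatched, matched) {
    if (length(unmatched) == 0L) return(matched)
    counts <- vapply(unmatched, function(a) {
      m <- cand[[as.character(a)]]
      sum(m[, 1L] %in% unmatched)
    }, numeric(1))
    if (any(counts == 0L)) return(NULL)
    a <- unmatched[which.min(counts)]
    m <- cand[[as.character(a)]]
    for (k in which(m[, 1L] %in% unmatched)) {
      res <- assign_match(setdiff(unmatched, c(a, m[k, 1L])),
                          c(matched, m[k, 2L]))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  matched <- assign_match(need, integer(0))
  if (is.null(matched) && length(need) > 0L) {
    stop("aromaticity error: no valid Kekule assignment for '",
         write_smiles(mol, canonical = FALSE), "'", call. = FALSE)
  }

  # Hueckel check ring by ring before rewriting flags
  rings <- perceive_rings(mol)
  for (ring in rings) {
    rows <- ring_bond_rows(mol, ring)
    if (anyNA(rows) || !all(mol$bonds$aromatic[rows])) next
    contrib <- vapply(ring, function(a) {
      i <- match(a, arom_atom)
      if (donor[i]) 2 else if (a %in% need) {
        1 # every needed atom ended up matched (matching is perfect)
      } else 0
    }, numeric(1))
    pi_e <- sum(contrib)
    if ((pi_e - 2) %% 4 != 0) {
      stop("aromaticity error: ring fails the Hueckel rule (",
           pi_e, " pi electrons)", call. = FALSE)
    }
  }

  mol$bonds$order[arom_bond] <- 1L
  mol$bonds$order[matched] <- 2L
  mol$bonds$aromatic <- FALSE
  mol$atoms$aromatic <- FALSE
  mol
}

#' Perceive aromatic rings on a kekulized molecule
#'
#' Rings whose atoms are all sp2-compatible (carry an in-ring double bond,
#' donate a lone pair, or bear an exocyclic double bond) and whose pi
#' electron count satisfies the Hueckel 4n+2 rule are flagged aromatic.
#' Inverse of [kekulize()] for the common aromatic systems.
#'
#' @param mol a kekulized `mol_graph`.
#' @return A `mol_graph` with aromatic flags set.
#' @export
aromatize <- function(mol) {
  mol <- kekulize(mol)
  rings <- perceive_rings(mol)
  if (length(rings) == 0L) return(mol)
  degree <- atom_degree(mol)
  double_partner <- rep(NA_integer_, n_atoms(mol))
  dbl <- which(mol$bonds$order == 2L)
  double_partner[mol$bonds$from[dbl]] <- mol$bonds$to[dbl]
  double_partner[mol$bonds$to[dbl]] <- mol$bonds$from[dbl]

  aromatic_rings <- list()
  for (ring in rings) {
    if (length(ring) < 5L || length(ring) > 7L) next
    if (!all(mol$atoms$element[ring] %in% c("B", "C", "N", "O", "P", "S"))) next
    rows <- ring_bond_rows(mol, ring)
    if (anyNA(rows)) next
    if (any(mol$bonds$order[rows] == 3L)) next
    contrib <- rep(NA_real_, length(ring))
    ok <- TRUE
    for (k in seq_along(ring)) {
      a <- ring[k]
      dp <- double_partner[a]
      if (!is.na(dp) && dp %in% ring) {
        contrib[k] <- 1
      } else if (!is.na(dp)) {
        contrib[k] <- 0 # exocyclic double bond (quinone-type)
      } else if (aromatic_lone_pair_donor(mol, a, degree)) {
        contrib[k] <- 2
      } else if (mol$atoms$element[a] == "C" && mol$atoms$charge[a] > 0L) {
        contrib[k] <- 0
      } else {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    pi_e <- sum(contrib)
    if (pi_e > 2 && (pi_e - 2) %% 4 == 0 && !any(contrib == 0)) {
      aromatic_rings[[length(aromatic_rings) + 1L]] <- list(ring, rows)
    }
  }
  for (r in aromatic_rings) {
    mol$atoms$aromatic[r[[1L]]] <- TRUE
    mol$bonds$aromatic[r[[2L]]] <- TRUE
    mol$bonds$order[r[[2L]]] <- 1L
  }
  mol
}
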