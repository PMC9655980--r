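#' Molecular graph objects
#'
#' A `mol_graph` is the in-memory substrate of every computation in qsarkit:
#' a hydrogen-suppressed labelled graph with per-atom element, formal charge,
#' isotope, attached-hydrogen count, aromatic flag and tetrahedral tag, and
#' per-bond order, aromatic flag and cis/trans direction mark.
#'
#' @param atoms data frame with columns `element` (character), `charge`
#'   (integer), `isotope` (integer, `NA` for natural abundance), `hcount`
#'   (integer, attached hydrogens), `aromatic` (logical), `chiral`
#'   (character `"@"`/`"@@"` or `NA`).
#' @param bonds data frame with columns `from`, `to` (integer atom indices),
#'   `order` (integer 1-3), `aromatic` (logical), `stereo` (character
#'   `"/"`/`"\\"` or `NA`, direction read from `from` to `to`).
#' @param name molecule name.
#' @param props named list of additional text properties.
#' @return An object of class `mol_graph`.
#' @keywords internal
new_mol_graph <- function(atoms, bonds, name = "", props = list()) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) > 0L) {
    bad <- bonds$from < 1L | bonds$to < 1L |
      bonds$from > nrow(atoms) | bonds$to > nrow(atoms)
    if (any(bad)) stop("bond refers to an atom index outside the atom table")
    if (any(bonds$from == bonds$to)) stop("self-bond is not allowed")
  }
  stopifnot(is.numeric(atoms$charge), all(atoms$charge == round(atoms$charge)))
  structure(
    list(atoms = atoms, bonds = bonds, name = name, props = props),
    class = "mol_graph"
  )
}

empty_atoms <- function() {
  tibble::tibble(
    element = character(), charge = integer(), isotope = integer(),
    hcount = integer(), aromatic = logical(), chiral = character()
  )
}

empty_bonds <- function() {
  tibble::tibble(
    from = integer(), to = integer(), order = integer(),
    aromatic = logical(), stereo = character()
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %s: %d atoms, %d bonds%s\n",
    if (nzchar(x$name)) x$name else "(unnamed)",
    n_atoms(x), nrow(x$bonds),
    if (is_kekulized(x)) " (kekulized)" else ""
  ))
  invisible(x)
}

#' @export
format.mol_graph <- function(x, ...) write_smiles(x)

n_atoms <- function(mol) nrow(mol$atoms)

heavy_idx <- function(mol) which(mol$atoms$element != "H")

#' Is every aromatic flag resolved to an explicit Kekule assignment?
#' @param mol a `mol_graph`.
#' @return `TRUE` when no bond carries an aromatic flag.
#' @export
is_kekulized <- function(mol) {
  nrow(mol$bonds) == 0L || !any(mol$bonds$aromatic)
}

#' Integer degree (heavy connections) per atom.
#' @noRd
atom_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    t1 <- tabulate(mol$bonds$from, nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds$to, nbins = n_atoms(mol))
    d <- t1 + t2
  }
  d
}

# Sum of bond orders incident to each atom; aromatic bonds count 1 each plus
# one extra unit for C/N/P/B centres (the in-ring double bond), matching the
# implicit-hydrogen model used when reading SMILES.
valence_sum <- function(mol) {
  n <- n_atoms(mol)
  v <- numeric(n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    ord <- ifelse(b$aromatic, 1, b$order)
    for (i in seq_len(nrow(b))) {
      v[b$from[i]] <- v[b$from[i]] + ord[i]
      v[b$to[i]] <- v[b$to[i]] + ord[i]
    }
  }
  has_arom <- rep(FALSE, n)
  if (nrow(b) > 0L && any(b$aromatic)) {
    has_arom[unique(c(b$from[b$aromatic], b$to[b$aromatic]))] <- TRUE
  }
  extra <- has_arom & mol$atoms$element %in% c("C", "N", "P", "B")
  v + as.numeric(extra)
}

# Neighbour list: for atom i, integer vector of (atom index, bond row).
neighbour_list <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) {
      nb[[b$from[i]]] <- rbind(nb[[b$from[i]]], c(b$to[i], i))
      nb[[b$to[i]]] <- rbind(nb[[b$to[i]]], c(b$from[i], i))
    }
  }
  lapply(nb, function(m) if (is.null(m)) matrix(integer(), ncol = 2) else m)
}

# igraph over heavy atoms with vertex count forced to length(keep)
mol_graph_heavy <- function(mol) {
  keep <- heavy_idx(mol)
  map <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds
  el <- matrix(integer(), ncol = 2)
  if (nrow(b) > 0L) {
    sel <- !is.na(map[b$from]) & !is.na(map[b$to])
    el <- cbind(map[b$from[sel]], map[b$to[sel]])
  }
  igraph::make_empty_graph(n = length(keep), directed = FALSE) |>
    igraph::add_edges(t(el))
}

# Connected fragments over all atoms; list of integer atom index vectors,
# in order of first appearance.
mol_fragments <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(list())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  }
  comp <- igraph::components(g)$membership
  split(seq_len(n), comp)[unique(comp)] |> unname()
}

# Extract the sub-molecule induced by the given atom indices.
subset_mol <- function(mol, idx) {
  idx <- sort(unique(idx))
  map <- match(seq_len(n_atoms(mol)), idx)
  b <- mol$bonds
  keep_b <- if (nrow(b) > 0L) !is.na(map[b$from]) & !is.na(map[b$to]) else logical()
  b <- b[keep_b, , drop = FALSE]
  b$from <- map[b$from]
  b$to <- map[b$to]
  new_mol_graph(mol$atoms[idx, , drop = FALSE], b, mol$name, mol$props)
}

# Default valences used for the implicit-hydrogen model and valence checks.
DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
  F = 1, Cl = 1, Br = 1, I = 1
)

# Alternate (hypervalent) states accepted as usual: N 5 (the neutral
# N(=O)=O nitro spelling), P 5, S 4 and 6.
ALT_VALENCE <- list(N = c(3, 5), P = c(3, 5), S = c(2, 4, 6))

# Allowed valence for an element/charge pair. Charge shifts valence for the
# common cases: N+ 4, O+ 3, O- 1, S- 1, C- 3, N- 2, halogen+ 2.
allowed_valences <- function(element, charge) {
  base <- ALT_VALENCE[[element]]
  if (is.null(base)) base <- unname(DEFAULT_VALENCE[element])
  if (is.na(base[1])) return(NA_real_)
  if (charge == 0) return(base)
  if (element %in% c("N", "P")) return(base + charge)
  if (element %in% c("O", "S")) return(base + charge)
  if (element == "C") return(base - abs(charge))
  if (element == "B") return(base + abs(charge))
  base
}
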