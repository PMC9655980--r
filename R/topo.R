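#' Topological distance matrix over heavy atoms
#'
#' Shortest-path length in bonds between every pair of non-hydrogen atoms,
#' computed with igraph. Disconnected pairs are `Inf` (a sentinel larger
#' than any real distance; descriptor code treats such pairs as absent).
#'
#' @param mol a `mol_graph`.
#' @return A symmetric numeric matrix with zero diagonal, one row per heavy
#'   atom (in atom order); dimnames carry the heavy-atom indices.
#' @export
#' @examples
#' topological_distance_matrix(parse_smiles("CCO"))
topological_distance_matrix <- function(mol) {
  keep <- heavy_idx(mol)
  g <- mol_graph_heavy(mol)
  d <- igraph::distances(g)
  dimnames(d) <- list(keep, keep)
  d
}

# Number of simple paths of exactly `len` bonds in the heavy-atom graph,
# each undirected path counted once. Depth-first enumeration; molecular
# graphs have bounded degree so this is linear-ish in the path count.
count_simple_paths <- function(mol, len) {
  keep <- heavy_idx(mol)
  n <- length(keep)
  if (n == 0L || len < 1L) return(0L)
  map <- match(seq_len(n_atoms(mol)), keep)
  adj <- vector("list", n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) {
      u <- map[b$from[i]]; v <- map[b$to[i]]
      if (!is.na(u) && !is.na(v)) {
        adj[[u]] <- c(adj[[u]], v)
        adj[[v]] <- c(adj[[v]], u)
      }
    }
  }
  total <- 0L
  visited <- rep(FALSE, n)
  walk <- function(v, depth) {
    if (depth == len) {
      total <<- total + 1L
      return(invisible())
    }
    visited[v] <<- TRUE
    for (w in adj[[v]]) if (!visited[w]) walk(w, depth + 1L)
    visited[v] <<- FALSE
  }
  for (v in seq_len(n)) walk(v, 0L)
  total %/% 2L
}
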