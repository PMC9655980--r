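#' Write a molecular graph as a SMILES string
#'
#' With `canonical = TRUE` atoms are emitted in canonical rank order
#' (see [canonical_key()]), so equal graphs produce equal strings whatever
#' the input atom numbering. Tetrahedral tags and bond direction marks are
#' re-expressed for the output ordering.
#'
#' @param mol a `mol_graph`.
#' @param canonical emit atoms in canonical order (default) or input order.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol, canonical = TRUE) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  ranks <- if (canonical) canonical_ranks(mol) else seq_len(n)
  nb <- neighbour_list(mol)
  frags <- mol_fragments(mol)
  out <- vapply(
    frags,
    function(idx) write_fragment(mol, idx, ranks, nb),
    character(1)
  )
  if (canonical) out <- sort(out)
  paste(out, collapse = ".")
}

write_fragment <- function(mol, idx, ranks, nb) {
  root <- idx[which.min(ranks[idx])]

  parent <- rep(NA_integer_, n_atoms(mol))
  children <- vector("list", n_atoms(mol))
  ring_open <- vector("list", n_atoms(mol))  # digit numbers opened at atom
  ring_close <- vector("list", n_atoms(mol)) # digit numbers closed at atom
  ring_partner <- list()                     # digit -> c(open, close, bond row)
  visited <- rep(FALSE, n_atoms(mol))
  order_seen <- integer(0)
  n_digit <- 0L

  # pass 1: DFS in rank order; classify tree edges and ring closures
  dfs <- function(a) {
    visited[a] <<- TRUE
    order_seen <<- c(order_seen, a)
    nbrs <- nb[[a]]
    if (nrow(nbrs) == 0L) return(invisible())
    ord <- order(ranks[nbrs[, 1L]])
    for (k in ord) {
      b <- nbrs[k, 1L]
      bondrow <- nbrs[k, 2L]
      if (!visited[b]) {
        parent[b] <<- a
        children[[a]] <<- c(children[[a]], b)
        dfs(b)
      } else if (!identical(parent[a], b)) {
        already <- any(vapply(ring_partner, function(r) r[3L] == bondrow,
                              logical(1)))
        if (!already) {
          n_digit <<- n_digit + 1L
          ring_partner[[n_digit]] <<- c(b, a, bondrow)
          ring_open[[b]] <<- c(ring_open[[b]], n_digit)
          ring_close[[a]] <<- c(ring_close[[a]], n_digit)
        }
      }
    }
  }
  dfs(root)

  bond_row <- function(a, b) {
    m <- nb[[a]]
    m[m[, 1L] == b, 2L][1L]
  }

  emit <- function(a) {
    tok <- atom_token(mol, a, written_order(a))
    pieces <- tok
    for (d in ring_open[[a]]) pieces <- paste0(pieces, digit_token(d))
    for (d in ring_close[[a]]) {
      r <- ring_partner[[d]]
      pieces <- paste0(pieces, bond_token(mol, r[3L], from = a), digit_token(d))
    }
    ch <- children[[a]]
    nch <- length(ch)
    for (k in seq_along(ch)) {
      sub <- paste0(bond_token(mol, bond_row(a, ch[k]), from = a), emit(ch[k]))
      pieces <- paste0(
        pieces,
        if (k < nch) paste0("(", sub, ")") else sub
      )
    }
    pieces
  }

  # neighbour order as the parser of the emitted string will see it
  written_order <- function(a) {
    w <- integer()
    if (!is.na(parent[a])) w <- c(w, parent[a])
    if (mol$atoms$hcount[a] > 0L && !is.na(mol$atoms$chiral[a])) w <- c(w, 0L)
    for (d in ring_open[[a]]) w <- c(w, ring_partner[[d]][2L])
    for (d in ring_close[[a]]) w <- c(w, ring_partner[[d]][1L])
    c(w, children[[a]])
  }

  emit(root)
}

digit_token <- function(d) if (d > 9L) sprintf("%%%02d", d) else as.character(d)

bond_token <- function(mol, row, from) {
  b <- mol$bonds[row, ]
  if (b$aromatic) {
    return("")
  }
  if (!is.na(b$stereo)) {
    sym <- b$stereo
    if (b$to == from) sym <- setdiff(c("/", "\\"), sym)
    return(sym)
  }
  if (b$order == 2L) return("=")
  if (b$order == 3L) return("#")
  # explicit single bond between two aromatic atoms (e.g. biphenyl link)
  if (mol$atoms$aromatic[b$from] && mol$atoms$aromatic[b$to]) return("-")
  ""
}

atom_token <- function(mol, a, written_nbrs) {
  at <- mol$atoms[a, ]
  sym <- at$element
  if (at$aromatic) sym <- tolower(sym)
  plain_ok <- if (at$aromatic) {
    tolower(at$element) %in% AROMATIC_ORGANIC
  } else {
    at$element %in% ORGANIC_SUBSET
  }
  default_h <- implicit_hcount(mol)[a]
  needs_bracket <- !plain_ok || at$charge != 0L || !is.na(at$isotope) ||
    !is.na(at$chiral) || at$hcount != default_h || at$element == "H"
  if (at$element == "*" && at$charge == 0L && is.na(at$isotope) &&
      is.na(at$chiral)) {
    needs_bracket <- FALSE
    sym <- "*"
  }
  if (!needs_bracket) return(sym)

  tag <- ""
  if (!is.na(at$chiral)) {
    ref <- sort(c(written_nbrs))
    tag <- at$chiral
    if (length(written_nbrs) >= 3L &&
        perm_sign(ref, written_nbrs) < 0L) {
      tag <- flip_tag(tag)
    }
  }
  hpart <- if (at$hcount == 0L) "" else if (at$hcount == 1L) "H" else
    paste0("H", at$hcount)
  cpart <- if (at$charge == 0L) "" else if (at$charge == 1L) "+" else
    if (at$charge == -1L) "-" else sprintf("%+d", at$charge)
  ipart <- if (is.na(at$isotope)) "" else as.character(at$isotope)
  paste0("[", ipart, sym, tag, hpart, cpart, "]")
}
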