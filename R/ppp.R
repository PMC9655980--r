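# Potential pharmacophore point (PPP) typing. The rule set is deliberately
# explicit and published through ppp_rules() so that the SHED descriptors
# computed from it are reproducible and auditable.

#' The pharmacophore typing rules, as data
#'
#' @return A tibble with columns `label` and `rule` describing every rule
#'   applied by [assign_ppp()], in order.
#' @export
ppp_rules <- function() {
  tibble::tibble(
    label = c("D", "A", "A", "A", "A", "P", "N", "N", "N", "L"),
    rule = c(
      "donor: N or O bearing at least one hydrogen",
      "acceptor: any O with charge <= 0",
      "acceptor excluded: N with positive formal charge",
      "acceptor excluded: amide-like N (single-bonded to C=O or C=S)",
      "acceptor excluded: pyrrole-type aromatic N (lone pair in ring) and nitro N",
      "positive: any atom with formal charge > 0",
      "negative: any atom with formal charge < 0",
      "negative: O atoms of carboxylic, sulfonic or phosphoric acid groups",
      "negative: ring N atoms of an (acidic) tetrazole",
      "lipophilic: C or halogen not bonded to any D, A or N atom"
    )
  )
}

#' Assign pharmacophore point labels to every heavy atom
#'
#' Labels are drawn from {D donor, A acceptor, P positive, N negative,
#' L lipophilic}; an atom can carry several. The assignment is a pure
#' function of the (kekulized, aromaticity-perceived) graph; see
#' [ppp_rules()] for the exact rule set.
#'
#' @param mol a `mol_graph`.
#' @return A tibble with columns `atom` (index), `element`, and logical
#'   columns `D`, `A`, `P`, `N`, `L`.
#' @export
#' @examples
#' assign_ppp(parse_smiles("CCO"))
assign_ppp <- function(mol) {
  m <- tryCatch(aromatize(mol), error = function(e) mol)
  n <- n_atoms(m)
  el <- m$atoms$element
  ch <- m$atoms$charge
  h <- m$atoms$hcount
  nb <- neighbour_list(m)

  has_double_to <- function(a, elements) {
    nbrs <- nb[[a]]
    any(vapply(seq_len(nrow(nbrs)), function(r) {
      m$bonds$order[nbrs[r, 2L]] == 2L && !m$bonds$aromatic[nbrs[r, 2L]] &&
        el[nbrs[r, 1L]] %in% elements
    }, logical(1)))
  }
  amide_like_n <- function(a) {
    nbrs <- nb[[a]]
    any(vapply(seq_len(nrow(nbrs)), function(r) {
      c_at <- nbrs[r, 1L]
      el[c_at] == "C" && m$bonds$order[nbrs[r, 2L]] == 1L &&
        has_double_to(c_at, c("O", "S"))
    }, logical(1)))
  }
  nitro_n <- function(a) {
    nbrs <- nb[[a]]
    el[a] == "N" &&
      sum(el[nbrs[, 1L]] == "O" &
            atom_degree(m)[nbrs[, 1L]] == 1L) >= 2L
  }
  pyrrole_type <- function(a) {
    m$atoms$aromatic[a] && el[a] %in% c("N", "P") &&
      (h[a] >= 1L || atom_degree(m)[a] == 3L)
  }

  deg <- atom_degree(m)
  # acid-group oxygens: O attached to a C/S/P centre that carries =O
  acid_oxygen <- vapply(seq_len(n), function(a) {
    if (el[a] != "O" || deg[a] != 1L) return(FALSE)
    nbrs <- nb[[a]]
    centre <- nbrs[1L, 1L]
    el[centre] %in% c("C", "S", "P") && has_double_to(centre, "O") &&
      (h[a] >= 1L || ch[a] < 0L ||
         (m$bonds$order[nbrs[1L, 2L]] == 2L && any(vapply(
           seq_len(nrow(nb[[centre]])), function(r) {
             o2 <- nb[[centre]][r, 1L]
             o2 != a && el[o2] == "O" && deg[o2] == 1L &&
               (h[o2] >= 1L || ch[o2] < 0L)
           }, logical(1)))))
  }, logical(1))

  rings <- perceive_rings(m)
  tetrazole_n <- rep(FALSE, n)
  for (ring in rings) {
    if (length(ring) == 5L && sum(el[ring] == "N") == 4L &&
        sum(el[ring] == "C") == 1L) {
      tetrazole_n[ring[el[ring] == "N"]] <- TRUE
    }
  }

  D <- el %in% c("N", "O") & h >= 1L
  A <- logical(n)
  for (a in seq_len(n)) {
    if (el[a] == "O" && ch[a] <= 0L) A[a] <- TRUE
    if (el[a] == "N" && ch[a] <= 0L && !amide_like_n(a) && !nitro_n(a) &&
        !pyrrole_type(a)) {
      A[a] <- TRUE
    }
  }
  P <- ch > 0L
  Neg <- ch < 0L | acid_oxygen | tetrazole_n
  polar <- D | A | Neg
  L <- logical(n)
  for (a in seq_len(n)) {
    if (!el[a] %in% c("C", "F", "Cl", "Br", "I")) next
    nbrs <- nb[[a]]
    touches_polar <- nrow(nbrs) > 0L && any(polar[nbrs[, 1L]])
    L[a] <- !polar[a] && !touches_polar
  }

  tibble::tibble(
    atom = seq_len(n), element = el,
    D = D, A = A, P = P, N = Neg, L = L
  )
}
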