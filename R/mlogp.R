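#' Moriguchi octanol-water partition coefficient
#'
#' The published 13-parameter regression on topological structural
#' parameters: weighted carbon/halogen count (CX), N/O count (NO),
#' proximity of N/O pairs (PRX), unsaturation (UB), an intramolecular
#' hydrogen-bond dummy (HB), polar substituents on aromatic rings (POL),
#' amphoteric character (AMP), a hydrocarbon dummy (ALK), non-aromatic
#' rings (RNG), quaternary nitrogen (QN), nitro groups (NO2),
#' iso/thiocyanates (NCS) and beta-lactam (BLM):
#'
#' `logP = 1.244 CX^0.6 - 1.017 NO^0.9 + 0.406 PRX - 0.145 UB^0.8
#'  + 0.511 HB + 0.268 POL - 2.215 AMP + 0.912 ALK - 0.392 RNG
#'  - 3.684 QN + 0.474 NO2 + 1.582 NCS + 0.773 BLM - 1.041`
#'
#' The HB and AMP dummies are detected with documented structural
#' heuristics (see the methods vignette). `calc_mlogp2()` is the squared
#' value used as a BBB-permeability feature.
#'
#' @param mol a `mol_graph`.
#' @return Numeric logP estimate.
#' @export
#' @examples
#' calc_mlogp(parse_smiles("c1ccccc1")) # benzene: about 2.26
calc_mlogp <- function(mol) {
  k <- tryCatch(kekulize(mol), error = function(e) mol)
  m <- tryCatch(aromatize(k), error = function(e) k)
  el <- m$atoms$element
  ch <- m$atoms$charge
  h <- m$atoms$hcount
  nb <- neighbour_list(m)
  deg <- atom_degree(m)

  hal_w <- c(F = 0.5, Cl = 1.0, Br = 1.5, I = 2.0)
  CX <- sum(el == "C") + sum(hal_w[el[el %in% names(hal_w)]])
  NO <- sum(el %in% c("N", "O"))

  heavy <- heavy_idx(m)
  dmat <- topological_distance_matrix(m)
  no_idx <- which(el[heavy] %in% c("N", "O"))
  PRX <- 0
  if (length(no_idx) >= 2L) {
    sub <- dmat[no_idx, no_idx, drop = FALSE]
    d <- sub[upper.tri(sub)]
    PRX <- 2 * sum(d == 1) + sum(d == 2)
  }

  # nitro groups: N bonded to two terminal oxygens
  nitro_n <- which(vapply(seq_len(n_atoms(m)), function(a) {
    el[a] == "N" && nrow(nb[[a]]) >= 2L &&
      sum(el[nb[[a]][, 1L]] == "O" & deg[nb[[a]][, 1L]] == 1L) >= 2L
  }, logical(1)))
  NO2 <- length(nitro_n)

  kb <- kekulize(m)$bonds
  unsat <- kb$order >= 2L
  # exclude the N=O bonds of nitro groups
  if (NO2 > 0L) {
    in_nitro <- (kb$from %in% nitro_n & el[kb$to] == "O" & deg[kb$to] == 1L) |
      (kb$to %in% nitro_n & el[kb$from] == "O" & deg[kb$from] == 1L)
    unsat <- unsat & !in_nitro
  }
  UB <- sum(unsat)

  # polar substituents attached directly to an aromatic atom
  POL <- sum(vapply(seq_len(n_atoms(m)), function(a) {
    if (m$atoms$aromatic[a]) return(FALSE)
    if (!el[a] %in% c("N", "O", "S", "F", "Cl", "Br", "I")) return(FALSE)
    any(m$atoms$aromatic[nb[[a]][, 1L]])
  }, logical(1)))

  # intramolecular H bond: donor and acceptor 3 bonds apart across an
  # unsaturated/aromatic path (the ortho-effect heuristic)
  donors <- which(el %in% c("N", "O") & h >= 1L)
  acceptors <- which(el %in% c("N", "O"))
  HB <- 0
  for (dA in donors) {
    for (aA in acceptors) {
      if (dA == aA) next
      pd <- match(dA, heavy); pa <- match(aA, heavy)
      if (is.na(pd) || is.na(pa)) next
      if (is.finite(dmat[pd, pa]) && dmat[pd, pa] == 3) {
        g <- mol_graph_heavy(m)
        path <- igraph::shortest_paths(g, pd, pa)$vpath[[1]]
        mid <- heavy[as.integer(path)[2:3]]
        if (any(m$atoms$aromatic[mid]) ||
            any(kb$order[kb$from %in% mid | kb$to %in% mid] >= 2L)) {
          HB <- 1
        }
      }
    }
    if (HB == 1) break
  }

  # amphoteric: alpha-amino acid 1.0; amino- or aza-aromatic acid 0.5
  AMP <- 0
  cooh <- which(vapply(seq_len(n_atoms(m)), function(a) {
    el[a] == "C" && any(el[nb[[a]][, 1L]] == "O" & deg[nb[[a]][, 1L]] == 1L &
                          h[nb[[a]][, 1L]] >= 1L) &&
      any(el[nb[[a]][, 1L]] == "O" & deg[nb[[a]][, 1L]] == 1L &
            h[nb[[a]][, 1L]] == 0L & ch[nb[[a]][, 1L]] == 0L)
  }, logical(1)))
  amine_n <- which(el == "N" & ch >= 0L & h >= 1L & !m$atoms$aromatic)
  if (length(cooh) > 0L) {
    for (cc in cooh) {
      alpha <- nb[[cc]][, 1L][el[nb[[cc]][, 1L]] == "C"]
      if (any(vapply(alpha, function(ca) {
        any(amine_n %in% nb[[ca]][, 1L])
      }, logical(1)))) {
        AMP <- max(AMP, 1)
      }
      if (any(m$atoms$aromatic[nb[[cc]][, 1L]])) {
        ring_ok <- any(el == "N" & m$atoms$aromatic) ||
          any(vapply(amine_n, function(na_) {
            any(m$atoms$aromatic[nb[[na_]][, 1L]])
          }, logical(1)))
        if (ring_ok) AMP <- max(AMP, 0.5)
      }
    }
  }

  ALK <- as.numeric(
    all(el == "C") && sum(kb$order == 2L) <= 1L && !any(kb$order == 3L) &&
      !any(m$atoms$aromatic)
  )

  rings <- perceive_rings(m)
  RNG <- as.numeric(any(vapply(rings, function(r) {
    !(all(m$atoms$aromatic[r]) && all(el[r] == "C"))
  }, logical(1))))

  QN <- 0
  if (calc_nssssnp(m) > 0L) QN <- 1
  else {
    n_oxide <- any(vapply(seq_len(n_atoms(m)), function(a) {
      el[a] == "N" && ch[a] == 1L &&
        any(el[nb[[a]][, 1L]] == "O" & ch[nb[[a]][, 1L]] == -1L &
              deg[nb[[a]][, 1L]] == 1L)
    }, logical(1)))
    if (n_oxide) QN <- 0.5
  }

  NCS <- 0
  for (a in which(el == "C")) {
    nbrs <- nb[[a]][, 1L]
    if (any(el[nbrs] == "N") && any(el[nbrs] == "S")) {
      rows <- nb[[a]][, 2L]
      ords <- kb$order[rows]
      if (all(ords == 2L) && length(rows) == 2L) NCS <- max(NCS, 1.0) # N=C=S
      if (any(ords == 3L)) NCS <- max(NCS, 0.5) # S-C#N
    }
  }

  BLM <- as.numeric(any(vapply(rings, function(r) {
    length(r) == 4L && any(el[r] == "N") &&
      any(vapply(r[el[r] == "C"], function(cc) {
        any(el[nb[[cc]][, 1L]] == "O" & kb$order[nb[[cc]][, 2L]] == 2L)
      }, logical(1)))
  }, logical(1))))

  1.244 * CX^0.6 - 1.017 * NO^0.9 + 0.406 * PRX - 0.145 * UB^0.8 +
    0.511 * HB + 0.268 * POL - 2.215 * AMP + 0.912 * ALK - 0.392 * RNG -
    3.684 * QN + 0.474 * NO2 + 1.582 * NCS + 0.773 * BLM - 1.041
}

#' @rdname calc_mlogp
#' @return `calc_mlogp2()`: the squared logP estimate.
#' @export
calc_mlogp2 <- function(mol) calc_mlogp(mol)^2
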