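#' Topological polar surface area (total variant, including S and P)
#'
#' Fragment-additive polar surface area: each N, O, S and P atom contributes
#' a published surface increment determined by its bonding environment
#' (hybridization, attached hydrogens, charge, aromaticity, 3-ring
#' membership). Environments outside the published table contribute 0.
#'
#' @param mol a `mol_graph`.
#' @return Surface area in squared Angstroms.
#' @export
#' @examples
#' calc_tpsa(parse_smiles("c1ccncc1")) # pyridine: 12.89
calc_tpsa <- function(mol) {
  m <- tryCatch(aromatize(mol), error = function(e) mol)
  nb <- neighbour_list(m)
  el <- m$atoms$element
  in3ring <- rep(FALSE, n_atoms(m))
  for (ring in perceive_rings(m)) {
    if (length(ring) == 3L) in3ring[ring] <- TRUE
  }
  total <- 0
  for (a in seq_len(n_atoms(m))) {
    if (!el[a] %in% c("N", "O", "S", "P")) next
    rows <- nb[[a]][, 2L]
    na <- sum(m$bonds$aromatic[rows])
    ns <- sum(!m$bonds$aromatic[rows] & m$bonds$order[rows] == 1L)
    nd <- sum(!m$bonds$aromatic[rows] & m$bonds$order[rows] == 2L)
    nt <- sum(!m$bonds$aromatic[rows] & m$bonds$order[rows] == 3L)
    total <- total + tpsa_contrib(
      el[a], m$atoms$charge[a], m$atoms$hcount[a],
      m$atoms$aromatic[a], na, ns, nd, nt, in3ring[a]
    )
  }
  total
}

tpsa_contrib <- function(el, ch, h, arom, na, ns, nd, nt, ring3) {
  env <- paste(na, ns, nd, nt, sep = ",")
  if (el == "N" && !arom && ch == 0L) {
    if (h == 0L) {
      if (env == "0,3,0,0") return(if (ring3) 3.01 else 3.24)
      if (env == "0,1,1,0") return(12.36)
      if (env == "0,0,0,1") return(23.79)
      if (env == "0,1,2,0") return(11.68)
      if (env == "0,0,1,1") return(13.60)
    }
    if (h == 1L) {
      if (env == "0,2,0,0") return(if (ring3) 21.94 else 12.03)
      if (env == "0,0,1,0") return(23.85)
    }
    if (h == 2L && env == "0,1,0,0") return(26.02)
  }
  if (el == "N" && !arom && ch == 1L) {
    if (h == 0L) {
      if (env == "0,4,0,0") return(0.00)
      if (env == "0,2,1,0") return(3.01)
      if (env == "0,1,0,1") return(4.36)
    }
    if (h == 1L) {
      if (env == "0,3,0,0") return(4.44)
      if (env == "0,1,1,0") return(13.97)
    }
    if (h == 2L) {
      if (env == "0,2,0,0") return(16.61)
      if (env == "0,0,1,0") return(25.59)
    }
    if (h == 3L && env == "0,1,0,0") return(27.64)
  }
  if (el == "N" && arom) {
    if (ch == 0L) {
      if (h == 0L) {
        if (env == "2,0,0,0") return(12.89)
        if (env == "3,0,0,0") return(4.41)
        if (env == "2,1,0,0") return(4.93)
        if (env == "2,0,1,0") return(8.39)
      }
      if (h == 1L && env == "2,0,0,0") return(15.79)
    }
    if (ch == 1L) {
      if (h == 0L) {
        if (env == "3,0,0,0") return(4.10)
        if (env == "2,1,0,0") return(3.88)
      }
      if (h == 1L && env == "2,0,0,0") return(14.14)
    }
  }
  if (el == "O") {
    if (arom && env == "2,0,0,0") return(13.14)
    if (ch == 0L) {
      if (h == 0L) {
        if (env == "0,2,0,0") return(if (ring3) 12.53 else 9.23)
        if (env == "0,0,1,0") return(17.07)
      }
      if (h == 1L && env == "0,1,0,0") return(20.23)
    }
    if (ch == -1L && h == 0L && env == "0,1,0,0") return(23.06)
  }
  if (el == "S") {
    if (arom) {
      if (env == "2,0,0,0") return(28.24)
      if (env == "2,0,1,0") return(21.70)
    }
    if (ch == 0L) {
      if (h == 0L) {
        if (env == "0,2,0,0") return(25.30)
        if (env == "0,0,1,0") return(32.09)
        if (env == "0,2,1,0") return(19.21)
        if (env == "0,2,2,0") return(8.38)
      }
      if (h == 1L && env == "0,1,0,0") return(38.80)
    }
  }
  if (el == "P" && ch == 0L) {
    if (h == 0L) {
      if (env == "0,3,0,0") return(13.59)
      if (env == "0,1,1,0") return(34.14)
      if (env == "0,3,1,0") return(9.81)
    }
    if (h == 1L && env == "0,2,1,0") return(23.47)
  }
  0
}
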