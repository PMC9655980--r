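#' Bit fingerprint objects
#'
#' @param bits logical vector.
#' @param kind `"maccs166"` or `"ecfp"`.
#' @param params list of generation parameters (`radius`, `length` for ecfp).
#' @return An object of class `bit_fp`.
#' @keywords internal
new_bit_fp <- function(bits, kind, params = list()) {
  structure(list(bits = as.logical(bits), kind = kind, params = params),
            class = "bit_fp")
}

#' @export
print.bit_fp <- function(x, ...) {
  cat(sprintf("<bit_fp %s> %d/%d bits set\n", x$kind, sum(x$bits),
              length(x$bits)))
  invisible(x)
}

#' Hex encoding of a fingerprint (most-significant bit first)
#' @param fp a `bit_fp`.
#' @return A hex string.
#' @export
fp_hex <- function(fp) {
  bits <- fp$bits
  pad <- (8L - length(bits) %% 8L) %% 8L
  bits <- c(bits, rep(FALSE, pad))
  bytes <- matrix(bits, nrow = 8L)
  paste(sprintf("%02x", colSums(bytes * 2^(7:0))), collapse = "")
}

# ---- MACCS 166 structural keys --------------------------------------------
# Generated through the OpenBabel command-line tool, whose MACCS
# implementation evaluates the public 166-key SMARTS dictionary. Its packed
# hex output decodes as: printed 32-bit words from most significant to
# least; overall bit b (0-based) corresponds to MACCS key b+1.

obabel_maccs_raw <- function(smiles) {
  if (Sys.which("obabel") == "") {
    stop("the 'obabel' executable is required for MACCS fingerprints ",
         "but was not found on PATH", call. = FALSE)
  }
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(smiles, infile)
  out <- suppressWarnings(system2(
    "obabel", c(infile, "-ofpt", "-xfMACCS", "-xh"),
    stdout = TRUE, stderr = FALSE
  ))
  starts <- grep("^>", out)
  if (length(starts) != length(smiles)) {
    stop("OpenBabel returned ", length(starts), " fingerprints for ",
         length(smiles), " molecules", call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(out))
  lapply(seq_along(starts), function(k) {
    body <- out[(starts[k] + 1L):ends[k]]
    body <- body[grepl("^[0-9a-f ]+$", body)] # drop e.g. superstructure notes
    hex <- gsub("[^0-9a-f]", "", paste(body, collapse = ""))
    # words are printed most significant first; reverse so that overall
    # bit b = word b %/% 32, bit b %% 32 reads off in ascending order
    words <- rev(substring(hex, seq(1L, nchar(hex), 8L),
                           seq(8L, nchar(hex), 8L)))
    unlist(lapply(words, function(w) {
      bytes <- strtoi(substring(w, c(1L, 3L, 5L, 7L), c(2L, 4L, 6L, 8L)), 16L)
      unlist(lapply(rev(bytes), function(bb) {
        as.logical(bitwAnd(bb, 2L^(0:7)))
      }))
    }))
  })
}

#' MACCS 166-key structural fingerprint
#'
#' Bit i is set iff structural key i of the public MACCS dictionary matches
#' the molecule (evaluation delegated to OpenBabel). Bit numbering: key k
#' (1-based) is element k of the returned vector.
#'
#' @param mol a `mol_graph`.
#' @return A `bit_fp` of length 166.
#' @export
maccs166 <- function(mol) {
  new_bit_fp(maccs166_matrix_smiles(write_smiles(mol))[1L, ], "maccs166")
}

maccs166_matrix_smiles <- function(smiles) {
  raw <- obabel_maccs_raw(smiles)
  m <- do.call(rbind, lapply(raw, function(bits) bits[1:166]))
  colnames(m) <- paste0("K", 1:166)
  m
}

#' MACCS fingerprint matrix for a molecule table
#'
#' @param table a molecule table.
#' @return Logical matrix, one row per molecule, 166 columns (`K1`..`K166`).
#' @export
maccs166_matrix <- function(table) {
  m <- maccs166_matrix_smiles(vapply(table$mol, write_smiles, character(1)))
  rownames(m) <- table$id
  m
}

# ---- Extended-connectivity (Morgan) fingerprint ---------------------------

HASH_MOD <- 2147483647 # 2^31-1; exact in doubles

hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% HASH_MOD)) %% HASH_MOD
  h
}

ecfp_environment_hashes <- function(mol, radius) {
  keep <- heavy_idx(mol)
  n <- length(keep)
  if (n == 0L) return(numeric())
  map <- match(seq_len(n_atoms(mol)), keep)
  adj <- vector("list", n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) {
      u <- map[b$from[i]]; v <- map[b$to[i]]
      if (is.na(u) || is.na(v)) next
      code <- if (b$aromatic[i]) 4 else b$order[i]
      adj[[u]] <- rbind(adj[[u]], c(v, code))
      adj[[v]] <- rbind(adj[[v]], c(u, code))
    }
  }
  in_ring <- rep(0, n)
  for (ring in perceive_rings(mol)) {
    in_ring[map[ring][!is.na(map[ring])]] <- 1
  }
  at <- mol$atoms[keep, ]
  elcode <- match(at$element, c(STANDARD_ATOM_SET, "*"), nomatch = 99L)
  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(elcode[i], length(adj[[i]] %||% integer()) / 2,
                at$hcount[i], at$charge[i] + 10, as.numeric(at$aromatic[i]),
                in_ring[i]))
  }, numeric(1))
  all_hashes <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      m <- adj[[i]]
      if (is.null(m)) return(hash_ints(c(r, inv[i])))
      nbr <- m[order(m[, 2L], inv[m[, 1L]]), , drop = FALSE]
      hash_ints(c(r, inv[i], t(cbind(nbr[, 2L], inv[nbr[, 1L]]))))
    }, numeric(1))
    all_hashes <- c(all_hashes, inv)
  }
  unique(all_hashes) # identical environment hashes counted once
}

#' Extended-connectivity (circular, Morgan) fingerprint
#'
#' Circular atom environments are grown radially from every heavy atom up
#' to `radius` bond shells via iterative neighbourhood hashing with standard
#' atom invariants (element, degree, hydrogen count, charge, aromaticity,
#' ring membership); duplicate environment hashes are counted once and the
#' surviving hashes are folded modulo `length`. `radius = 3` with
#' `length = 2048` corresponds to the common ECFP6/2048 configuration.
#'
#' @param mol a `mol_graph`.
#' @param radius maximum environment radius in bonds (>= 0).
#' @param length fingerprint length; a power of two.
#' @return A `bit_fp` with `params = list(radius, length)`.
#' @export
ecfp <- function(mol, radius = 3L, length = 2048L) {
  stopifnot(radius >= 0L, length >= 2L, bitwAnd(length, length - 1L) == 0L)
  hashes <- ecfp_environment_hashes(mol, radius)
  bits <- rep(FALSE, length)
  bits[(hashes %% length) + 1L] <- TRUE
  new_bit_fp(bits, "ecfp", params = list(radius = radius, length = length))
}

#' ECFP fingerprint matrix for a molecule table
#'
#' @param table a molecule table.
#' @inheritParams ecfp
#' @return Logical matrix, one row per molecule.
#' @export
ecfp_matrix <- function(table, radius = 3L, length = 2048L) {
  m <- do.call(rbind, lapply(table$mol, function(mol) {
    ecfp(mol, radius, length)$bits
  }))
  rownames(m) <- table$id
  colnames(m) <- paste0("E", seq_len(length))
  m
}

#' Jaccard-Tanimoto distance between two fingerprints
#'
#' `d = 1 - |a AND b| / |a OR b|`, with `d = 0` when both fingerprints are
#' empty (identical objects).
#'
#' @param a,b `bit_fp` objects of the same kind and parameters, or plain
#'   logical vectors of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  if (inherits(a, "bit_fp") || inherits(b, "bit_fp")) {
    stopifnot(inherits(a, "bit_fp"), inherits(b, "bit_fp"))
    if (!identical(a$kind, b$kind) || !identical(a$params, b$params)) {
      stop("fingerprints have mismatched kind or parameters", call. = FALSE)
    }
    a <- a$bits
    b <- b$bits
  }
  stopifnot(length(a) == length(b))
  un <- sum(a | b)
  if (un == 0L) return(0)
  1 - sum(a & b) / un
}

# Tanimoto cross-distance matrix between the rows of two 0/1 matrices.
tanimoto_cross <- function(A, B) {
  A <- A * 1; B <- B * 1
  inter <- tcrossprod(A, B)
  un <- outer(rowSums(A), rowSums(B), `+`) - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  d
}
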