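# A deliberately small structural-pattern engine: the subset of
# SMARTS/reaction-SMARTS needed by the rule-based standardizers. Supported
# atom primitives: element symbol (uppercase = any, lowercase = aromatic),
# `*`, `D<n>` (heavy-atom degree), `H<n>` (attached hydrogens), formal
# charge (`+`, `-`, `+n`, `-n`, `+0`), conjunction with `;` or `&`, and an
# atom map `:n`. Supported bonds: `~` (any), `-`, `=`, `#`, `:` and the
# default (single-or-aromatic). Branches and ring closures work as in
# SMILES.

parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  nch <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  stack <- integer()
  pending <- NULL
  rings <- list()
  fail <- function(msg) stop("SMARTS parse error in '", pattern, "': ", msg,
                             call. = FALSE)

  add_atom <- function(constr) {
    atoms[[length(atoms) + 1L]] <<- constr
    cur <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(
        from = prev, to = cur, type = pending %||% "default"
      )
    }
    pending <<- NULL
    prev <<- cur
    cur
  }

  parse_bracket_body <- function(body) {
    constr <- list(element = NA_character_, aromatic = NA, degree = NA_integer_,
                   hcount = NA_integer_, charge = NA_integer_,
                   map = NA_integer_)
    mp <- regmatches(body, regexec(":([0-9]+)$", body))[[1]]
    if (length(mp) == 2L) {
      constr$map <- as.integer(mp[2])
      body <- sub(":[0-9]+$", "", body)
    }
    for (prim in strsplit(body, "[;&]")[[1]]) {
      if (prim == "*") {
      } else if (grepl("^[A-Z][a-z]?$", prim)) {
        constr$element <- prim
      } else if (grepl("^[a-z]{1,2}$", prim)) {
        constr$element <- paste0(toupper(substr(prim, 1, 1)),
                                 substring(prim, 2))
        constr$aromatic <- TRUE
      } else if (grepl("^\\*?[+-][0-9]*$", prim)) {
        p <- sub("^\\*", "", prim)
        sign <- if (substr(p, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", p)
        constr$charge <- if (nzchar(digits)) sign * as.integer(digits) else
          sign * nchar(p)
      } else if (grepl("^D[0-9]+$", prim)) {
        constr$degree <- as.integer(substring(prim, 2))
      } else if (grepl("^H[0-9]*$", prim)) {
        constr$hcount <- if (prim == "H") 1L else as.integer(substring(prim, 2))
      } else {
        fail(paste0("unsupported primitive '", prim, "'"))
      }
    }
    constr
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("~", "-", "=", "#", ":")) {
      pending <- c(`~` = "any", `-` = "single", `=` = "double",
                   `#` = "triple", `:` = "aromatic")[[ch]]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(rings[[key]])) {
        bonds[[length(bonds) + 1L]] <- list(
          from = rings[[key]]$atom, to = prev,
          type = pending %||% rings[[key]]$sym %||% "default"
        )
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, sym = pending)
      }
      pending <- NULL
      i <- i + 1L
    } else if (ch == "[") {
      j <- i
      while (j <= nch && chars[j] != "]") j <- j + 1L
      if (j > nch) fail("unterminated bracket")
      add_atom(parse_bracket_body(paste(chars[(i + 1L):(j - 1L)],
                                        collapse = "")))
      i <- j + 1L
    } else if (ch == "*") {
      add_atom(parse_bracket_body("*"))
      i <- i + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(parse_bracket_body(two)); i <- i + 2L
      } else {
        add_atom(parse_bracket_body(ch)); i <- i + 1L
      }
    } else {
      fail(paste0("unexpected character '", ch, "'"))
    }
  }
  if (length(rings) > 0L) fail("unclosed ring bond")
  if (length(atoms) == 0L) fail("no atoms")
  list(atoms = atoms, bonds = bonds)
}

atom_matches <- function(mol, a, constr, degree) {
  at <- mol$atoms[a, ]
  if (!is.na(constr$element) && at$element != constr$element) return(FALSE)
  if (!is.na(constr$aromatic) && isTRUE(constr$aromatic) && !at$aromatic) {
    return(FALSE)
  }
  if (!is.na(constr$degree) && degree[a] != constr$degree) return(FALSE)
  if (!is.na(constr$hcount) && at$hcount != constr$hcount) return(FALSE)
  if (!is.na(constr$charge) && at$charge != constr$charge) return(FALSE)
  TRUE
}

bond_matches <- function(mol, row, type) {
  b <- mol$bonds[row, ]
  switch(type,
    any = TRUE,
    single = !b$aromatic && b$order == 1L,
    double = !b$aromatic && b$order == 2L,
    triple = !b$aromatic && b$order == 3L,
    aromatic = isTRUE(b$aromatic),
    default = b$aromatic || b$order == 1L
  )
}

# All embeddings of `pat` (a parse_smarts() result) into `mol`, as a list of
# integer vectors: position k = molecule atom matched to pattern atom k.
match_smarts <- function(mol, pat) {
  np <- length(pat$atoms)
  degree <- atom_degree(mol)
  nb <- neighbour_list(mol)

  # pattern adjacency
  padj <- vector("list", np)
  for (bi in seq_along(pat$bonds)) {
    b <- pat$bonds[[bi]]
    padj[[b$from]] <- rbind(padj[[b$from]], c(b$to, bi))
    padj[[b$to]] <- rbind(padj[[b$to]], c(b$from, bi))
  }

  results <- list()
  assign <- rep(NA_integer_, np)
  extend <- function(k) {
    if (k > np) {
      results[[length(results) + 1L]] <<- assign
      return(invisible())
    }
    anchored <- if (!is.null(padj[[k]])) {
      m <- padj[[k]]
      m[!is.na(assign[m[, 1L]]), , drop = FALSE]
    } else matrix(integer(), ncol = 2)
    cands <- if (nrow(anchored) > 0L) {
      first <- anchored[1L, ]
      nbrs <- nb[[assign[first[1L]]]]
      nbrs[, 1L][vapply(seq_len(nrow(nbrs)), function(r) {
        bond_matches(mol, nbrs[r, 2L], pat$bonds[[first[2L]]]$type)
      }, logical(1))]
    } else seq_len(n_atoms(mol))
    for (a in cands) {
      if (a %in% assign) next
      if (!atom_matches(mol, a, pat$atoms[[k]], degree)) next
      ok <- TRUE
      if (nrow(anchored) > 1L) {
        for (r in 2:nrow(anchored)) {
          pa <- anchored[r, ]
          row <- mol_bond_between(mol, a, assign[pa[1L]])
          if (is.na(row) ||
              !bond_matches(mol, row, pat$bonds[[pa[2L]]]$type)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      assign[k] <<- a
      extend(k + 1L)
      assign[k] <<- NA_integer_
    }
  }
  extend(1L)
  results
}

mol_bond_between <- function(mol, a, b) {
  row <- which((mol$bonds$from == a & mol$bonds$to == b) |
                 (mol$bonds$from == b & mol$bonds$to == a))
  if (length(row) == 0L) NA_integer_ else row[1L]
}

#' Parse a reaction-SMARTS transformation
#'
#' `reactant>>product` rules in the restricted dialect used by the custom
#' standardizers: mapped atoms on the product side redefine the charge,
#' hydrogen count and (optionally) element of the corresponding reactant
#' atom, and product bonds between mapped atoms redefine bond orders.
#'
#' @param pattern transformation string, e.g.
#'   `"[N;D3:1](~[O;D1:2])(~[O;D1:3])>>[*+0;H0:1](=[*+0;H0:2])=[*+0;H0:3]"`.
#' @return An object of class `smirks_rule`.
#' @export
parse_smirks <- function(pattern) {
  pattern <- gsub("−", "-", pattern) # normalize typographic minus
  halves <- strsplit(pattern, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("custom standardizer pattern must be 'reactant>>product': got '",
         pattern, "'", call. = FALSE)
  }
  lhs <- parse_smarts(halves[1L])
  rhs <- parse_smarts(halves[2L])
  lmaps <- vapply(lhs$atoms, function(a) a$map, integer(1))
  rmaps <- vapply(rhs$atoms, function(a) a$map, integer(1))
  if (anyNA(rmaps) || !all(rmaps %in% lmaps)) {
    stop("every product atom must carry an atom map present on the ",
         "reactant side: '", pattern, "'", call. = FALSE)
  }
  structure(list(pattern = pattern, lhs = lhs, rhs = rhs,
                 lmaps = lmaps, rmaps = rmaps),
            class = "smirks_rule")
}

# Apply a smirks_rule once to the first embedding whose rewrite changes the
# molecule. Returns list(mol=, changed=).
apply_smirks_once <- function(mol, rule) {
  matches <- match_smarts(mol, rule$lhs)
  for (mt in matches) {
    cand <- rewrite_match(mol, rule, mt)
    if (!identical(cand, mol)) return(list(mol = cand, changed = TRUE))
  }
  list(mol = mol, changed = FALSE)
}

rewrite_match <- function(mol, rule, mt) {
  for (k in seq_along(rule$rhs$atoms)) {
    ra <- rule$rhs$atoms[[k]]
    target <- mt[match(ra$map, rule$lmaps)]
    if (!is.na(ra$charge)) mol$atoms$charge[target] <- ra$charge
    if (!is.na(ra$hcount)) mol$atoms$hcount[target] <- ra$hcount
    if (!is.na(ra$element)) mol$atoms$element[target] <- ra$element
  }
  for (b in rule$rhs$bonds) {
    m1 <- mt[match(rule$rhs$atoms[[b$from]]$map, rule$lmaps)]
    m2 <- mt[match(rule$rhs$atoms[[b$to]]$map, rule$lmaps)]
    row <- mol_bond_between(mol, m1, m2)
    if (is.na(row)) next
    type <- if (b$type %in% c("default", "any")) "single" else b$type
    mol$bonds$order[row] <- c(single = 1L, double = 2L, triple = 3L,
                              aromatic = 1L)[[type]]
    mol$bonds$aromatic[row] <- type == "aromatic"
  }
  mol
}

#' Apply a reaction-SMARTS rule to fixed point
#'
#' @param mol a `mol_graph`.
#' @param rule a `smirks_rule` from [parse_smirks()] (or its pattern string).
#' @param max_iter safety bound on rewrites.
#' @return The transformed `mol_graph`.
#' @export
apply_smirks <- function(mol, rule, max_iter = 100L) {
  if (is.character(rule)) rule <- parse_smirks(rule)
  for (i in seq_len(max_iter)) {
    res <- apply_smirks_once(mol, rule)
    if (!res$changed) return(res$mol)
    mol <- res$mol
  }
  mol
}
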