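# SMARTS subset parser and subgraph matcher.
#
# Reactant templates in make-on-demand reaction definitions are small,
# acyclic patterns over reaction-handle functional groups, so the engine
# supports the subset those templates need:
#
#   atoms:  organic-subset shorthand (C, c, N, O, ...), bracket atoms with
#           element or '#n', 'a'/'A', '*', H<n>, X<n>, D<n>, charge, '!'
#           negation, ',' (OR), ';' and '&' (AND), and atom maps ':n'
#   bonds:  - = # : ~ and the default single-or-aromatic bond
#   plus branches in parentheses.
#
# Ring-closure digits and recursive SMARTS are not supported; patterns are
# trees. This is deliberate: templates describe the local environment of a
# reaction handle, not ring systems.

smarts_error <- function(s, msg) {
  stop(sprintf("unsupported SMARTS '%s': %s", s, msg), call. = FALSE)
}

# A pattern is a list with:
#   atoms: list of constraint lists (OR-of-AND normal form)
#   amap : integer atom map per pattern atom (0 = unmapped)
#   bond_a, bond_b, bond_type: character ("-","=","#",":","~","")
parse_smarts <- function(smarts) {
  chars <- strsplit(smarts, "", fixed = TRUE)[[1]]
  np <- length(chars)
  atoms <- list(); amap <- integer()
  bond_a <- integer(); bond_b <- integer(); bond_type <- character()
  prev <- 0L; pending <- ""; stack <- integer()

  add_atom <- function(constraints, map) {
    atoms[[length(atoms) + 1L]] <<- constraints
    amap[[length(amap) + 1L]] <<- map
    idx <- length(atoms)
    if (prev > 0L) {
      bond_a[[length(bond_a) + 1L]] <<- prev
      bond_b[[length(bond_b) + 1L]] <<- idx
      bond_type[[length(bond_type) + 1L]] <<- pending
    }
    pending <<- ""
    prev <<- idx
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smarts_error(smarts, "unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      smarts_error(smarts, "ring-closure digits are not supported")
    } else if (ch == "[") {
      j <- i + 1L; depth <- 1L
      while (j <= np && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        if (depth > 0L) j <- j + 1L
      }
      if (j > np) smarts_error(smarts, "unterminated '['")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_smarts_atom(body, smarts)
      add_atom(at$constraints, at$map)
      i <- j + 1L
    } else {
      two <- if (i < np) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(list(list(kind = "elem", value = two, arom = FALSE,
                                negate = FALSE))), 0L)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(list(list(list(kind = "elem", value = ch, arom = FALSE,
                                negate = FALSE))), 0L)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(list(list(list(kind = "elem", value = toupper(ch),
                                arom = TRUE, negate = FALSE))), 0L)
        i <- i + 1L
      } else if (ch == "*") {
        add_atom(list(list(list(kind = "any", negate = FALSE))), 0L)
        i <- i + 1L
      } else if (ch == "a") {
        add_atom(list(list(list(kind = "arom", value = TRUE,
                                negate = FALSE))), 0L)
        i <- i + 1L
      } else if (ch == "A") {
        add_atom(list(list(list(kind = "arom", value = FALSE,
                                negate = FALSE))), 0L)
        i <- i + 1L
      } else {
        smarts_error(smarts, paste0("unexpected character '", ch, "'"))
      }
    }
  }
  if (length(stack) > 0L) smarts_error(smarts, "unbalanced '('")
  if (length(atoms) == 0L) smarts_error(smarts, "no atoms")
  list(atoms = atoms, amap = amap,
       bond_a = bond_a, bond_b = bond_b, bond_type = bond_type)
}

# Bracket atom: ';'-separated clauses are ANDed, each clause is a ','-OR of
# '&'/juxtaposition-AND primitive runs. Returns OR-of-AND constraint lists.
parse_smarts_atom <- function(body, smarts) {
  if (grepl("$", body, fixed = TRUE)) {
    smarts_error(smarts, "recursive SMARTS ($(...)) is not supported")
  }
  map <- 0L
  mm <- regmatches(body, regexpr(":[0-9]+$", body))
  if (length(mm) == 1L) {
    map <- as.integer(substring(mm, 2L))
    body <- sub(":[0-9]+$", "", body)
  }
  clauses <- strsplit(body, ";", fixed = TRUE)[[1]]
  if (length(clauses) == 0L) smarts_error(smarts, "empty bracket atom")
  # Each clause: OR over alternatives; overall atom: AND over clauses.
  # Normalize to OR-of-AND by taking the cartesian product of clauses.
  per_clause <- lapply(clauses, function(cl) {
    alts <- strsplit(cl, ",", fixed = TRUE)[[1]]
    lapply(alts, function(alt) parse_primitive_run(alt, smarts))
  })
  combos <- list(list())
  for (alts in per_clause) {
    combos <- unlist(
      lapply(combos, function(acc) lapply(alts, function(a) c(acc, a))),
      recursive = FALSE
    )
  }
  list(constraints = combos, map = map)
}

# One run of primitives joined by '&' or juxtaposition, e.g. "CX3", "!H0"
parse_primitive_run <- function(run, smarts) {
  run <- gsub("&", "", run, fixed = TRUE)
  prims <- list()
  i <- 1L
  n <- nchar(run)
  while (i <= n) {
    negate <- FALSE
    if (substring(run, i, i) == "!") {
      negate <- TRUE
      i <- i + 1L
      if (i > n) smarts_error(smarts, "dangling '!'")
    }
    rest <- substring(run, i)
    consumed <- 0L
    prim <- NULL
    if (grepl("^(Cl|Br)", rest)) {
      sym <- substring(rest, 1L, 2L)
      prim <- list(kind = "elem", value = sym, arom = FALSE, negate = negate)
      consumed <- 2L
    } else if (grepl("^#[0-9]+", rest)) {
      num <- regmatches(rest, regexpr("^#[0-9]+", rest))
      prim <- list(kind = "elnum", value = as.integer(substring(num, 2L)),
                   negate = negate)
      consumed <- nchar(num)
    } else if (grepl("^H[0-9]?", rest) && substring(rest, 1L, 1L) == "H") {
      tok <- regmatches(rest, regexpr("^H[0-9]?", rest))
      cnt <- if (nchar(tok) == 1L) 1L else as.integer(substring(tok, 2L))
      prim <- list(kind = "hcount", value = cnt, negate = negate)
      consumed <- nchar(tok)
    } else if (grepl("^X[0-9]+", rest)) {
      tok <- regmatches(rest, regexpr("^X[0-9]+", rest))
      prim <- list(kind = "conn", value = as.integer(substring(tok, 2L)),
                   negate = negate)
      consumed <- nchar(tok)
    } else if (grepl("^D[0-9]+", rest)) {
      tok <- regmatches(rest, regexpr("^D[0-9]+", rest))
      prim <- list(kind = "degree", value = as.integer(substring(tok, 2L)),
                   negate = negate)
      consumed <- nchar(tok)
    } else if (grepl("^R0", rest)) {
      prim <- list(kind = "ring", value = FALSE, negate = negate)
      consumed <- 2L
    } else if (grepl("^R", rest)) {
      prim <- list(kind = "ring", value = TRUE, negate = negate)
      consumed <- 1L
    } else if (grepl("^[+-][0-9]*", rest) && substring(rest, 1L, 1L) %in% c("+", "-")) {
      tok <- regmatches(rest, regexpr("^[+-][0-9]*", rest))
      sgn <- if (substring(tok, 1L, 1L) == "+") 1L else -1L
      dig <- substring(tok, 2L)
      prim <- list(kind = "charge",
                   value = if (nchar(dig) > 0L) sgn * as.integer(dig) else sgn,
                   negate = negate)
      consumed <- nchar(tok)
    } else if (grepl("^[A-Z][a-z]?", rest)) {
      sym <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
      # two-letter match could swallow the next primitive (e.g. "Ca" is
      # calcium but "CH" is carbon+H); only accept known elements
      if (!(sym %in% names(ELEMENT_NUMBERS))) sym <- substring(sym, 1L, 1L)
      if (sym == "A") {
        prim <- list(kind = "arom", value = FALSE, negate = negate)
      } else {
        prim <- list(kind = "elem", value = sym, arom = FALSE, negate = negate)
      }
      consumed <- nchar(sym)
    } else if (grepl("^[bcnops]", rest)) {
      sym <- substring(rest, 1L, 1L)
      prim <- if (sym == "a") NULL else
        list(kind = "elem", value = toupper(sym), arom = TRUE, negate = negate)
      consumed <- 1L
    } else if (grepl("^a", rest)) {
      prim <- list(kind = "arom", value = TRUE, negate = negate)
      consumed <- 1L
    } else if (grepl("^\\*", rest)) {
      prim <- list(kind = "any", negate = negate)
      consumed <- 1L
    } else {
      smarts_error(smarts, paste0("unsupported primitive at '", rest, "'"))
    }
    prims[[length(prims) + 1L]] <- prim
    i <- i + consumed
  }
  prims
}

# --- matching ---------------------------------------------------------------

atom_matches <- function(mol, ai, constraints, ring_atoms, conn, deg) {
  for (alt in constraints) { # OR over alternatives
    ok <- TRUE
    for (p in alt) { # AND over primitives
      val <- switch(p$kind,
        any = TRUE,
        elem = {
          m <- mol$elem[ai] == p$value
          if (!is.null(p$arom) && m) m <- mol$arom[ai] == p$arom
          m
        },
        elnum = unname(ELEMENT_NUMBERS[mol$elem[ai]]) == p$value,
        arom = mol$arom[ai] == p$value,
        hcount = mol$hcount[ai] == p$value,
        conn = conn[ai] == p$value,
        degree = deg[ai] == p$value,
        ring = (ai %in% ring_atoms) == p$value,
        charge = mol$charge[ai] == p$value,
        FALSE
      )
      if (is.na(val)) val <- FALSE
      if (p$negate) val <- !val
      if (!val) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

bond_matches <- function(order, type, arom_pair) {
  switch(type,
    "-" = order == 1,
    "=" = order == 2,
    "#" = order == 3,
    ":" = order == 1.5,
    "~" = TRUE,
    # default bond: single or aromatic
    order == 1 || order == 1.5
  )
}

#' Find all matches of a SMARTS pattern in a molecule
#'
#' Enumerates all distinct injective mappings of the pattern atoms onto
#' molecule atoms, in deterministic (atom-index) order. Patterns are
#' restricted to the tree-shaped SMARTS subset described in
#' `vignette("synthevolve-methods")`.
#'
#' @param mol A `sev_mol` graph (from [parse_smiles()]).
#' @param pattern A parsed pattern (from `parse_smarts()`) or a SMARTS string.
#' @param max_matches Stop after this many matches.
#' @return A list of integer vectors; element `k` of a match is the molecule
#'   atom index matched by pattern atom `k`.
#' @export
smarts_matches <- function(mol, pattern, max_matches = 256L) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  natp <- length(pattern$atoms)
  nmol <- n_atoms(mol)
  if (nmol < natp) return(list())

  adj <- mol_adjacency(mol)
  deg <- heavy_degree(mol)
  conn <- deg + mol$hcount
  ring_atoms <- mol_ring_atoms(mol)

  # pattern adjacency (a tree: parent order = DFS from atom 1 by construction)
  padj <- vector("list", natp)
  ptype <- vector("list", natp)
  for (i in seq_along(pattern$bond_a)) {
    a <- pattern$bond_a[i]; b <- pattern$bond_b[i]; t <- pattern$bond_type[i]
    padj[[a]] <- c(padj[[a]], b); ptype[[a]] <- c(ptype[[a]], t)
    padj[[b]] <- c(padj[[b]], a); ptype[[b]] <- c(ptype[[b]], t)
  }
  # parent of each pattern atom in input order (patterns are connected trees)
  parent <- rep(NA_integer_, natp)
  parent_type <- rep("", natp)
  for (i in seq_along(pattern$bond_a)) {
    a <- pattern$bond_a[i]; b <- pattern$bond_b[i]
    if (b > a && is.na(parent[b])) {
      parent[b] <- a
      parent_type[b] <- pattern$bond_type[i]
    }
  }

  bond_order_of <- function(ma, mb) {
    for (i in seq_along(mol$bond_a)) {
      if ((mol$bond_a[i] == ma && mol$bond_b[i] == mb) ||
          (mol$bond_a[i] == mb && mol$bond_b[i] == ma)) {
        return(mol$bond_order[i])
      }
    }
    NA_real_
  }

  matches <- list()
  assignment <- integer(natp)

  recurse <- function(k) {
    if (length(matches) >= max_matches) return()
    if (k > natp) {
      matches[[length(matches) + 1L]] <<- assignment
      return()
    }
    if (k == 1L) {
      candidates <- seq_len(nmol)
    } else {
      candidates <- adj[[assignment[parent[k]]]]
    }
    for (cand in candidates) {
      if (cand %in% assignment[seq_len(k - 1L)]) next
      if (!atom_matches(mol, cand, pattern$atoms[[k]], ring_atoms, conn, deg)) next
      if (k > 1L) {
        o <- bond_order_of(assignment[parent[k]], cand)
        if (is.na(o) || !bond_matches(o, parent_type[k])) next
      }
      assignment[k] <<- cand
      recurse(k + 1L)
      if (length(matches) >= max_matches) return()
    }
  }
  recurse(1L)
  matches
}

# atoms belonging to at least one cycle (2-core minus bridge/linker atoms
# would be exact; for template matching the 2-core is refined by checking
# each 2-core atom keeps degree >= 2 inside its component of the 2-core,
# which holds for cycle atoms and fails only for isolated linker paths --
# linkers between rings still sit on cycles? no: use proper cycle test)
mol_ring_atoms <- function(mol) {
  # an atom is in a ring iff removing it does not disconnect... simpler and
  # exact: an edge is a ring edge iff it lies on a cycle; atoms of ring
  # edges are ring atoms. Find bridges via DFS (small graphs: do it by
  # edge-removal reachability).
  n <- n_atoms(mol)
  ne <- length(mol$bond_a)
  if (ne == 0L) return(integer(0))
  adj_e <- vector("list", n)
  for (i in seq_len(ne)) {
    adj_e[[mol$bond_a[i]]] <- c(adj_e[[mol$bond_a[i]]], i)
    adj_e[[mol$bond_b[i]]] <- c(adj_e[[mol$bond_b[i]]], i)
  }
  reachable_without <- function(src, dst, skip_edge) {
    seen <- logical(n); seen[src] <- TRUE; stack <- src
    while (length(stack) > 0L) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (a == dst) return(TRUE)
      for (ei in adj_e[[a]]) {
        if (ei == skip_edge) next
        b <- if (mol$bond_a[ei] == a) mol$bond_b[ei] else mol$bond_a[ei]
        if (!seen[b]) { seen[b] <- TRUE; stack <- c(stack, b) }
      }
    }
    FALSE
  }
  ring <- logical(n)
  core <- mol_two_core(mol) # cheap pre-filter: ring edges live in the 2-core
  core_set <- logical(n); core_set[core] <- TRUE
  for (i in seq_len(ne)) {
    a <- mol$bond_a[i]; b <- mol$bond_b[i]
    if (!core_set[a] || !core_set[b]) next
    if (ring[a] && ring[b]) next
    if (reachable_without(a, b, i)) { ring[a] <- TRUE; ring[b] <- TRUE }
  }
  which(ring)
}
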