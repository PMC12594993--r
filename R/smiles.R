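# Minimal molecular graph + SMILES reader/writer.
#
# The graph representation carries exactly what product assembly and
# extended-connectivity fingerprints need: element, aromatic flag, formal
# charge, hydrogen count, and a bond list with orders 1, 2, 3 or 1.5
# (aromatic). Canonicalization is delegated to OpenBabel (ChemmineOB);
# this reader only has to accept valid SMILES, including OpenBabel's
# canonical output and the fully bracketed SMILES emitted by mol_to_smiles().

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ELEMENT_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
  I = 53
)

# Default valences used to infer implicit hydrogen counts on unbracketed
# atoms. Multi-valent elements list all allowed valences, smallest first.
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

new_mol <- function(elem = character(), arom = logical(), charge = integer(),
                    hcount = integer(), bond_a = integer(), bond_b = integer(),
                    bond_order = numeric()) {
  structure(
    list(
      elem = elem, arom = arom, charge = charge, hcount = hcount,
      bond_a = bond_a, bond_b = bond_b, bond_order = bond_order
    ),
    class = "sev_mol"
  )
}

n_atoms <- function(mol) length(mol$elem)

#' @export
print.sev_mol <- function(x, ...) {
  cat(
    "<molecule: ", n_atoms(x), " heavy atoms, ",
    length(x$bond_a), " bonds>\n",
    sep = ""
  )
  invisible(x)
}

# adjacency as list of integer vectors (heavy neighbours)
mol_adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_along(mol$bond_a)) {
    a <- mol$bond_a[i]
    b <- mol$bond_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

heavy_degree <- function(mol) {
  deg <- integer(n_atoms(mol))
  tb <- tabulate(c(mol$bond_a, mol$bond_b), nbins = n_atoms(mol))
  deg + tb
}

# sum of bond orders incident to each atom (aromatic counted as 1.5)
bond_order_sum <- function(mol) {
  s <- numeric(n_atoms(mol))
  for (i in seq_along(mol$bond_a)) {
    s[mol$bond_a[i]] <- s[mol$bond_a[i]] + mol$bond_order[i]
    s[mol$bond_b[i]] <- s[mol$bond_b[i]] + mol$bond_order[i]
  }
  s
}

smiles_error <- function(smiles, msg) {
  stop(sprintf("invalid SMILES '%s': %s", smiles, msg), call. = FALSE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms (element, aromatic lowercase,
#' `H` counts, formal charges; isotopes and stereo marks are accepted and
#' ignored), branches, ring-closure digits (including `%nn`), dot-separated
#' fragments, and bond symbols `- = # : / \`. Implicit hydrogen counts are
#' inferred from default valences; aromatic atoms follow the usual
#' convention (unbracketed aromatic carbon with two ring neighbours carries
#' one hydrogen, aromatic nitrogen written without brackets carries none).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `sev_mol`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  np <- length(chars)

  elem <- character(); arom <- logical(); charge <- integer()
  hexp <- integer() # explicit H from brackets, NA = implicit
  bond_a <- integer(); bond_b <- integer(); bond_order <- numeric()

  prev <- 0L            # index of previous atom (0 = none, e.g. after '.')
  pending_bond <- NA    # bond symbol awaiting next atom
  stack <- integer()    # branch stack
  rings <- list()       # open ring closures: digit -> c(atom, order or NA)

  add_atom <- function(e, ar, ch, hc) {
    elem[[length(elem) + 1L]] <<- e
    arom[[length(arom) + 1L]] <<- ar
    charge[[length(charge) + 1L]] <<- ch
    hexp[[length(hexp) + 1L]] <<- hc
    length(elem)
  }
  add_bond <- function(a, b, sym) {
    ord <- if (is.na(sym)) {
      if (arom[a] && arom[b]) 1.5 else 1
    } else {
      switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1,
             smiles_error(smiles, paste0("unknown bond '", sym, "'")))
    }
    bond_a[[length(bond_a) + 1L]] <<- a
    bond_b[[length(bond_b) + 1L]] <<- b
    bond_order[[length(bond_order) + 1L]] <<- ord
  }
  attach_atom <- function(idx) {
    if (prev > 0L) add_bond(prev, idx, pending_bond)
    pending_bond <<- NA
    prev <<- idx
  }
  ring_closure <- function(key) {
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      sym <- if (!is.na(open$sym)) open$sym else pending_bond
      add_bond(open$atom, prev, sym)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, sym = pending_bond)
    }
    pending_bond <<- NA
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_error(smiles, "unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L
      pending_bond <- NA
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) smiles_error(smiles, "ring closure before any atom")
      ring_closure(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > np) smiles_error(smiles, "truncated %nn ring closure")
      ring_closure(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) smiles_error(smiles, "unterminated bracket atom")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$elem, at$arom, at$charge, at$hcount)
      attach_atom(idx)
      i <- j + 1L
    } else {
      # organic-subset shorthand atom (two-letter Cl/Br first)
      two <- if (i < np) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE, 0L, NA_integer_)
        attach_atom(idx)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE, 0L, NA_integer_)
        attach_atom(idx)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_)
        attach_atom(idx)
        i <- i + 1L
      } else {
        smiles_error(smiles, paste0("unexpected character '", ch, "'"))
      }
    }
  }
  if (length(stack) > 0L) smiles_error(smiles, "unbalanced '('")
  if (length(rings) > 0L && any(!vapply(rings, is.null, logical(1)))) {
    smiles_error(smiles, "unclosed ring bond")
  }
  if (length(elem) == 0L) smiles_error(smiles, "no atoms")

  mol <- new_mol(elem, arom, charge, hcount = rep(0L, length(elem)),
                 bond_a, bond_b, bond_order)
  mol$hcount <- infer_hydrogens(mol, hexp, smiles)
  mol
}

# bracket atom body, e.g. "CH3", "O-", "nH", "13CH2", "N+", "S@@H"
parse_bracket_atom <- function(body, smiles) {
  rest <- sub("^[0-9]+", "", body) # drop isotope
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[bcnops])", rest))
  if (length(m) == 0L) smiles_error(smiles, paste0("bad bracket atom [", body, "]"))
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  arom <- sym %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (arom) toupper(sym) else sym
  rest <- gsub("@", "", rest, fixed = TRUE) # ignore stereo

  hcount <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1L) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*|[+]+|[-]+", rest))
  if (length(cm) == 1L) {
    sign <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cm)
    charge <- if (nchar(digits) > 0L) sign * as.integer(digits)
              else sign * nchar(cm)
  }
  list(elem = elem, arom = arom, charge = charge, hcount = hcount)
}

# Implicit hydrogen counts for atoms written without brackets.
infer_hydrogens <- function(mol, hexp, smiles) {
  bsum <- bond_order_sum(mol)
  deg <- heavy_degree(mol)
  h <- integer(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    if (!is.na(hexp[i])) {
      h[i] <- hexp[i]
    } else if (mol$arom[i]) {
      # unbracketed aromatic atoms: c gets one H at two ring neighbours,
      # aromatic n/o/s get none (pyrrole-type NH must be written [nH])
      h[i] <- if (mol$elem[i] == "C") max(0L, 3L - deg[i]) else 0L
    } else {
      vals <- DEFAULT_VALENCES[[mol$elem[i]]]
      if (is.null(vals)) {
        h[i] <- 0L
      } else {
        v <- vals[vals >= bsum[i]]
        h[i] <- if (length(v) == 0L) 0L else as.integer(v[1] - bsum[i])
      }
    }
  }
  h
}

#' Write a molecular graph as a (non-canonical) SMILES string
#'
#' Every atom is written in brackets with its explicit hydrogen count, so
#' the output is valence-unambiguous; aromatic atoms are written lowercase
#' with `:` ring bonds. Feed the result to [canonical_smiles()] for a
#' canonical form.
#'
#' @param mol A `sev_mol` graph.
#' @return A SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  visited <- logical(n)
  ring_digit <- 0L
  ring_labels <- vector("list", n) # atom -> ring-closure digit tokens

  bond_sym <- function(o) {
    if (o == 1) "" else if (o == 2) "=" else if (o == 3) "#"
    else if (o == 1.5) ":" else ""
  }
  atom_token <- function(i) {
    sym <- mol$elem[i]
    if (mol$arom[i]) sym <- tolower(sym)
    h <- mol$hcount[i]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- mol$charge[i]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
    paste0("[", sym, hs, cs, "]")
  }

  # recursive construction is fine: molecules here are small; the DFS
  # follows exactly the spanning-tree edges found in the pre-pass below,
  # ring (back) edges are emitted as closure digits only
  emit_component <- function(root) {
    build <- function(a) {
      visited[a] <<- TRUE
      s <- atom_token(a)
      if (!is.null(ring_labels[[a]])) {
        s <- paste0(s, paste0(ring_labels[[a]], collapse = ""))
      }
      parts <- character(0)
      for (ei in edge_index[[a]]) {
        if (!tree_edge[ei]) next
        b <- if (mol$bond_a[ei] == a) mol$bond_b[ei] else mol$bond_a[ei]
        if (visited[b]) next # the edge we came in on
        parts <- c(parts, paste0(bond_sym(mol$bond_order[ei]), build(b)))
      }
      if (length(parts) == 0L) return(s)
      branches <- if (length(parts) > 1L) {
        paste0("(", parts[-length(parts)], ")", collapse = "")
      } else ""
      paste0(s, branches, parts[length(parts)])
    }
    build(root)
  }

  # pre-pass: mark spanning-tree edges; the remaining (back) edges become
  # ring closures and get digit labels on both endpoints
  tree_edge <- logical(length(mol$bond_a))
  seen2 <- logical(n)
  edge_index <- vector("list", n)
  for (i in seq_along(mol$bond_a)) {
    a <- mol$bond_a[i]; b <- mol$bond_b[i]
    edge_index[[a]] <- c(edge_index[[a]], i)
    edge_index[[b]] <- c(edge_index[[b]], i)
  }
  for (root in seq_len(n)) {
    if (seen2[root]) next
    seen2[root] <- TRUE
    stack <- root
    while (length(stack) > 0L) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ei in edge_index[[a]]) {
        b <- if (mol$bond_a[ei] == a) mol$bond_b[ei] else mol$bond_a[ei]
        if (!seen2[b]) {
          seen2[b] <- TRUE
          tree_edge[ei] <- TRUE
          stack <- c(stack, b)
        }
      }
    }
  }
  ring_edges <- which(!tree_edge)
  for (ei in ring_edges) {
    ring_digit <- ring_digit + 1L
    dig <- if (ring_digit < 10L) as.character(ring_digit)
           else paste0("%", ring_digit)
    o <- mol$bond_order[ei]
    sym <- if (o == 2) "=" else if (o == 3) "#" else ""
    a <- mol$bond_a[ei]; b <- mol$bond_b[ei]
    ring_labels[[a]] <- c(ring_labels[[a]], paste0(sym, dig))
    ring_labels[[b]] <- c(ring_labels[[b]], paste0(sym, dig))
  }

  comps <- character(0)
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (!visited[root]) comps <- c(comps, emit_component(root))
  }
  paste0(comps, collapse = ".")
}

# connected components; returns integer component id per atom
mol_components <- function(mol) {
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  comp <- integer(n)
  cid <- 0L
  for (root in seq_len(n)) {
    if (comp[root] > 0L) next
    cid <- cid + 1L
    stack <- root
    comp[root] <- cid
    while (length(stack) > 0L) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (b in adj[[a]]) {
        if (comp[b] == 0L) {
          comp[b] <- cid
          stack <- c(stack, b)
        }
      }
    }
  }
  comp
}

# subset a molecule to the given atom indices (bonds inside the subset kept)
mol_subset <- function(mol, keep) {
  keep <- sort(unique(keep))
  map <- integer(n_atoms(mol))
  map[keep] <- seq_along(keep)
  bkeep <- map[mol$bond_a] > 0L & map[mol$bond_b] > 0L
  new_mol(
    elem = mol$elem[keep], arom = mol$arom[keep],
    charge = mol$charge[keep], hcount = mol$hcount[keep],
    bond_a = map[mol$bond_a[bkeep]], bond_b = map[mol$bond_b[bkeep]],
    bond_order = mol$bond_order[bkeep]
  )
}

# atoms that are part of any cycle plus linker atoms between cycles:
# the 2-core of the heavy-atom graph (iteratively strip degree-1 atoms)
mol_two_core <- function(mol) {
  n <- n_atoms(mol)
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    for (i in seq_along(mol$bond_a)) {
      a <- mol$bond_a[i]; b <- mol$bond_b[i]
      if (alive[a] && alive[b]) {
        deg[a] <- deg[a] + 1L
        deg[b] <- deg[b] + 1L
      }
    }
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  which(alive)
}
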