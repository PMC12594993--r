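# Reaction SMARTS application.
#
# A reaction is written `template1.template2...>>product` with k >= 2
# reactant templates. Semantics follow the usual SMIRKS conventions for the
# supported subset:
#   * atoms mapped on both sides are kept, together with everything attached
#     to them that the templates do not mention;
#   * reactant-template atoms whose map is absent from the product side
#     (including unmapped template atoms) are removed - these are the
#     leaving groups;
#   * bonds drawn between mapped atoms on the product side are created or
#     set to the drawn order; template bonds between mapped atoms that are
#     absent from the product side are broken;
#   * hydrogen counts on mapped atoms are adjusted by the change in their
#     heavy-bond order sum, so e.g. an amine nitrogen loses one H when it
#     gains the amide bond.
# Product-side atoms without a map (atom additions) are not supported.

#' Parse a reaction SMARTS
#'
#' @param smarts Reaction SMARTS string with `>>` separating reactants from
#'   the product and `.` separating reactant templates.
#' @return An object of class `sev_reaction` with parsed templates.
#' @export
parse_reaction_smarts <- function(smarts) {
  halves <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("reaction SMARTS must contain exactly one '>>': ", smarts,
         call. = FALSE)
  }
  templ_src <- split_top_level(halves[1])
  if (length(templ_src) < 2L) {
    stop("reaction must have at least two reactant templates: ", smarts,
         call. = FALSE)
  }
  templates <- lapply(templ_src, parse_smarts)
  prod_src <- split_top_level(halves[2])
  if (length(prod_src) != 1L) {
    stop("multi-component product templates are not supported: ", smarts,
         call. = FALSE)
  }
  product <- parse_smarts(prod_src)
  if (any(product$amap == 0L)) {
    stop("product template atoms must all carry atom maps: ", smarts,
         call. = FALSE)
  }
  all_maps <- unlist(lapply(templates, function(t) t$amap))
  all_maps <- all_maps[all_maps > 0L]
  if (anyDuplicated(all_maps)) {
    stop("duplicate atom map on reactant side: ", smarts, call. = FALSE)
  }
  if (!all(product$amap %in% all_maps)) {
    stop("product template uses atom maps missing from reactants: ", smarts,
         call. = FALSE)
  }
  structure(
    list(smarts = smarts, templates = templates, product = product,
         arity = length(templates)),
    class = "sev_reaction"
  )
}

# split on '.' outside any bracket/parenthesis nesting
split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("[", "(")) depth <- depth + 1L
    if (chars[i] %in% c("]", ")")) depth <- depth - 1L
    if (chars[i] == "." && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k) {
    paste0(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
}

#' @export
print.sev_reaction <- function(x, ...) {
  cat("<reaction (", x$arity, " components): ", x$smarts, ">\n", sep = "")
  invisible(x)
}

assembly_error <- function(msg, genotype = NULL) {
  structure(
    class = c("assembly_error", "error", "condition"),
    list(message = msg, call = NULL, genotype = genotype)
  )
}

#' Apply a reaction to reagent molecules
#'
#' Matches each reactant template against the reagent at the same position
#' and builds the product graph(s). When templates match in several ways,
#' every combination (up to `max_variants`) is built; the caller picks the
#' canonically smallest product.
#'
#' @param rxn A `sev_reaction`.
#' @param mols List of `sev_mol` reagents, one per reactant position.
#' @param max_variants Cap on match combinations explored.
#' @return A list of product `sev_mol` graphs (possibly with duplicates
#'   differing only in atom order); empty on chemical failure is signalled
#'   as an `assembly_error` condition.
#' @export
apply_reaction <- function(rxn, mols, max_variants = 16L) {
  stopifnot(inherits(rxn, "sev_reaction"))
  k <- rxn$arity
  if (length(mols) != k) {
    stop(assembly_error(sprintf(
      "reaction expects %d reagents, got %d", k, length(mols)
    )))
  }
  match_sets <- vector("list", k)
  for (i in seq_len(k)) {
    m <- smarts_matches(mols[[i]], rxn$templates[[i]], max_matches = max_variants)
    if (length(m) == 0L) {
      stop(assembly_error(sprintf(
        "reagent at position %d does not match its reactant template", i
      )))
    }
    match_sets[[i]] <- m
  }
  combos <- list(integer(0))
  for (i in seq_len(k)) {
    combos <- unlist(
      lapply(combos, function(acc) {
        lapply(seq_along(match_sets[[i]]), function(j) c(acc, j))
      }),
      recursive = FALSE
    )
    if (length(combos) > max_variants) combos <- combos[seq_len(max_variants)]
  }
  products <- list()
  for (combo in combos) {
    matches <- lapply(seq_len(k), function(i) match_sets[[i]][[combo[i]]])
    p <- try(build_product(rxn, mols, matches), silent = TRUE)
    if (!inherits(p, "try-error")) products[[length(products) + 1L]] <- p
  }
  if (length(products) == 0L) {
    stop(assembly_error("no match combination yields a connected product"))
  }
  products
}

build_product <- function(rxn, mols, matches) {
  k <- rxn$arity
  offsets <- cumsum(c(0L, vapply(mols, n_atoms, integer(1))))[seq_len(k)]
  # combined graph
  elem <- unlist(lapply(mols, `[[`, "elem"))
  arom <- unlist(lapply(mols, `[[`, "arom"))
  charge <- unlist(lapply(mols, `[[`, "charge"))
  hcount <- unlist(lapply(mols, `[[`, "hcount"))
  bond_a <- unlist(lapply(seq_len(k), function(i) mols[[i]]$bond_a + offsets[i]))
  bond_b <- unlist(lapply(seq_len(k), function(i) mols[[i]]$bond_b + offsets[i]))
  bond_order <- unlist(lapply(mols, `[[`, "bond_order"))
  if (is.null(bond_a)) { bond_a <- integer(0); bond_b <- integer(0); bond_order <- numeric(0) }

  # map number -> combined atom index; matched-but-unmapped atoms -> delete
  map_atom <- integer(0)
  delete <- integer(0)
  matched_pairs <- list() # list of c(combined_a, combined_b, template bond present)
  for (i in seq_len(k)) {
    tpl <- rxn$templates[[i]]
    mt <- matches[[i]] + offsets[i]
    for (a in seq_along(tpl$amap)) {
      if (tpl$amap[a] > 0L) {
        map_atom[tpl$amap[a]] <- mt[a]
      } else {
        delete <- c(delete, mt[a])
      }
    }
    # template bonds between mapped atoms: candidates for breaking
    for (bi in seq_along(tpl$bond_a)) {
      ta <- tpl$bond_a[bi]; tb <- tpl$bond_b[bi]
      if (tpl$amap[ta] > 0L && tpl$amap[tb] > 0L) {
        matched_pairs[[length(matched_pairs) + 1L]] <-
          c(tpl$amap[ta], tpl$amap[tb])
      }
    }
  }
  # maps whose atoms are absent from the product side get deleted too
  kept_maps <- rxn$product$amap
  for (mp in seq_along(map_atom)) {
    if (!is.na(map_atom[mp]) && map_atom[mp] > 0L && !(mp %in% kept_maps)) {
      delete <- c(delete, map_atom[mp])
    }
  }

  old_bsum <- numeric(length(elem))
  for (i in seq_along(bond_a)) {
    old_bsum[bond_a[i]] <- old_bsum[bond_a[i]] + bond_order[i]
    old_bsum[bond_b[i]] <- old_bsum[bond_b[i]] + bond_order[i]
  }

  find_bond <- function(a, b) {
    for (i in seq_along(bond_a)) {
      if ((bond_a[i] == a && bond_b[i] == b) ||
          (bond_a[i] == b && bond_b[i] == a)) return(i)
    }
    0L
  }
  # break template bonds between mapped atoms not drawn in the product
  prod_bond_key <- character(0)
  for (bi in seq_along(rxn$product$bond_a)) {
    m1 <- rxn$product$amap[rxn$product$bond_a[bi]]
    m2 <- rxn$product$amap[rxn$product$bond_b[bi]]
    prod_bond_key <- c(prod_bond_key, paste(sort(c(m1, m2)), collapse = "-"))
  }
  drop_bond <- logical(length(bond_a))
  for (pr in matched_pairs) {
    key <- paste(sort(pr), collapse = "-")
    if (!(key %in% prod_bond_key)) {
      bi <- find_bond(map_atom[pr[1]], map_atom[pr[2]])
      if (bi > 0L) drop_bond[bi] <- TRUE
    }
  }
  if (any(drop_bond)) {
    bond_a <- bond_a[!drop_bond]; bond_b <- bond_b[!drop_bond]
    bond_order <- bond_order[!drop_bond]
  }
  # create / retype product bonds
  for (bi in seq_along(rxn$product$bond_a)) {
    m1 <- rxn$product$amap[rxn$product$bond_a[bi]]
    m2 <- rxn$product$amap[rxn$product$bond_b[bi]]
    a <- map_atom[m1]; b <- map_atom[m2]
    type <- rxn$product$bond_type[bi]
    ord <- switch(type, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "~" = NA_real_, 1)
    ex <- find_bond(a, b)
    if (ex > 0L) {
      if (!is.na(ord)) bond_order[ex] <- ord
    } else {
      if (is.na(ord)) ord <- 1
      bond_a <- c(bond_a, a); bond_b <- c(bond_b, b)
      bond_order <- c(bond_order, ord)
    }
  }

  # hydrogen bookkeeping on mapped, kept atoms
  new_bsum <- numeric(length(elem))
  alive <- rep(TRUE, length(elem)); alive[delete] <- FALSE
  for (i in seq_along(bond_a)) {
    if (alive[bond_a[i]] && alive[bond_b[i]]) {
      new_bsum[bond_a[i]] <- new_bsum[bond_a[i]] + bond_order[i]
      new_bsum[bond_b[i]] <- new_bsum[bond_b[i]] + bond_order[i]
    }
  }
  for (mp in kept_maps) {
    a <- map_atom[mp]
    dh <- round(old_bsum[a] - new_bsum[a])
    hcount[a] <- max(0L, hcount[a] + as.integer(dh))
  }

  mol <- new_mol(elem, arom, charge, hcount, bond_a, bond_b, bond_order)
  mol <- mol_subset(mol, which(alive))
  # keep the component holding the mapped atoms
  keep_idx <- which(alive)
  remap <- integer(length(elem)); remap[keep_idx] <- seq_along(keep_idx)
  comp <- mol_components(mol)
  mapped_comps <- unique(comp[remap[map_atom[kept_maps]]])
  if (length(mapped_comps) != 1L) {
    stop("product mapped atoms are not in a single connected component")
  }
  mol_subset(mol, which(comp == mapped_comps))
}
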