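# Chemistry utilities: canonical SMILES (via OpenBabel), product assembly,
# heavy atom counts, Bemis-Murcko scaffolds, SMILES file I/O.

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings with OpenBabel. Vectorized; unparsable
#' entries return `NA` with a warning.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, same length as the input.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  src <- paste0(smiles, " sev", seq_len(n), collapse = "\n")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = paste0(src, "\n"))
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, n)
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2L && grepl("^sev[0-9]+$", p[2])) {
        idx <- as.integer(substring(p[2], 4L))
        res[idx] <- p[1]
      }
    }
  }
  if (anyNA(res)) {
    warning(sum(is.na(res)), " SMILES failed to canonicalize", call. = FALSE)
  }
  res
}

#' Product molecule descriptor
#'
#' Bundles the canonical SMILES of an assembled product with its heavy-atom
#' count and fingerprint.
#'
#' @param canonical SMILES string (already canonical).
#' @param config A [fingerprint_config()].
#' @return A `product_molecule` list with fields `canonical_smiles`,
#'   `heavy_atoms`, `fingerprint`.
#' @export
product_molecule <- function(canonical, config = fingerprint_config()) {
  mol <- parse_smiles(canonical)
  structure(
    list(
      canonical_smiles = canonical,
      heavy_atoms = heavy_atom_count(mol),
      fingerprint = ecfp_bits(mol, config)
    ),
    class = "product_molecule"
  )
}

#' Number of non-hydrogen atoms
#'
#' @param molecule A `sev_mol`, `product_molecule`, or SMILES string.
#' @return Positive integer heavy-atom count.
#' @export
heavy_atom_count <- function(molecule) {
  if (inherits(molecule, "product_molecule")) return(molecule$heavy_atoms)
  if (is.character(molecule)) molecule <- parse_smiles(molecule)
  n_atoms(molecule)
}

#' Assemble the product molecule of a genotype
#'
#' Runs the genotype's reaction on its synthons and returns the canonical
#' product. If the templates match in more than one way the canonically
#' smallest SMILES is returned, making assembly deterministic.
#'
#' @param genotype A [ligand_genotype()].
#' @param library A [combinatorial_library][load_library].
#' @return A `product_molecule`.
#' @export
assemble_product <- function(genotype, library) {
  res <- assemble_products(library, list(genotype))[[1]]
  if (inherits(res, "assembly_error")) stop(res)
  res
}

# Batch assembly: one OpenBabel canonicalization call for all candidate
# products of all genotypes. Results are memoized in the library cache, so
# repeated genotypes (ubiquitous during evolution) cost a lookup.
# Returns a list of product_molecule or assembly_error per genotype.
assemble_products <- function(library, genotypes) {
  cache <- library$cache
  keys <- vapply(genotypes, genotype_key, character(1))
  out <- vector("list", length(genotypes))
  todo <- integer(0)
  for (i in seq_along(genotypes)) {
    hit <- cache$products[[keys[i]]]
    if (!is.null(hit)) out[[i]] <- hit else todo <- c(todo, i)
  }
  todo <- todo[!duplicated(keys[todo])]
  if (length(todo) == 0L) {
    return(fill_from_cache(out, cache, keys))
  }
  cand_smiles <- character(0)
  cand_owner <- integer(0)
  failures <- vector("list", length(genotypes))
  for (i in todo) {
    g <- genotypes[[i]]
    rxn <- library$reactions[[g$reaction_id]]
    mols <- lapply(seq_along(g$synthon_ids), function(p) {
      library$synthon_mols[[rxn$position_index[[p]][g$synthon_ids[p]]]]
    })
    prods <- tryCatch(
      apply_reaction(rxn$parsed, mols),
      assembly_error = function(e) e
    )
    if (inherits(prods, "assembly_error")) {
      failures[[i]] <- prods
      next
    }
    raw <- vapply(prods, mol_to_smiles, character(1))
    cand_smiles <- c(cand_smiles, raw)
    cand_owner <- c(cand_owner, rep(i, length(raw)))
  }
  cans <- if (length(cand_smiles) > 0L) canonical_smiles(cand_smiles)
          else character(0)
  for (i in todo) {
    if (!is.null(failures[[i]])) {
      cache$products[[keys[i]]] <- failures[[i]]
      next
    }
    mine <- cans[cand_owner == i]
    mine <- mine[!is.na(mine)]
    if (length(mine) == 0L) {
      cache$products[[keys[i]]] <-
        assembly_error("product failed canonicalization", genotypes[[i]])
      next
    }
    best <- sort(mine)[1]
    pm <- cache$molecules[[best]]
    if (is.null(pm)) {
      pm <- product_molecule(best, library$fingerprint_config)
      cache$molecules[[best]] <- pm
    }
    cache$products[[keys[i]]] <- pm
  }
  fill_from_cache(out, cache, keys)
}

fill_from_cache <- function(out, cache, keys) {
  for (i in seq_along(out)) {
    if (is.null(out[[i]])) out[[i]] <- cache$products[[keys[i]]]
  }
  out
}

#' Bemis-Murcko scaffold
#'
#' Ring systems plus the linkers connecting them, with side chains removed;
#' substituents attached to the scaffold by double or triple bonds are kept
#' (the classic framework definition). Acyclic molecules have the empty
#' scaffold `""`.
#'
#' @param molecule A `sev_mol`, `product_molecule` or SMILES string.
#' @return Canonical scaffold SMILES (`""` for acyclic molecules).
#' @export
murcko_scaffold <- function(molecule) {
  if (inherits(molecule, "product_molecule")) {
    molecule <- molecule$canonical_smiles
  }
  if (is.character(molecule)) molecule <- parse_smiles(molecule)
  core <- mol_two_core(molecule)
  if (length(core) == 0L) return("")
  keep <- logical(n_atoms(molecule))
  keep[core] <- TRUE
  # retain atoms multiply bonded to the core (exocyclic =O etc.)
  for (i in seq_along(molecule$bond_a)) {
    if (molecule$bond_order[i] >= 2) {
      a <- molecule$bond_a[i]; b <- molecule$bond_b[i]
      if (keep[a] || keep[b]) { keep[a] <- TRUE; keep[b] <- TRUE }
    }
  }
  sub <- mol_subset(molecule, which(keep))
  # hydrogens freed by cutting side chains
  bs_old <- bond_order_sum(molecule)[sort(which(keep))]
  bs_new <- bond_order_sum(sub)
  sub$hcount <- sub$hcount + as.integer(round(bs_old - bs_new))
  canonical_smiles(mol_to_smiles(sub))
}

#' Read/write SMILES files
#'
#' One record per line: SMILES, tab, identifier.
#'
#' @param path File path.
#' @return `read_smiles_file`: data.frame with columns `smiles`, `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE
  )
}

#' @param smiles Character vector of SMILES.
#' @param ids Identifiers, recycled against `smiles`.
#' @rdname read_smiles_file
#' @export
write_smiles_file <- function(smiles, ids, path) {
  writeLines(paste(smiles, ids, sep = "\t"), path)
  invisible(path)
}
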