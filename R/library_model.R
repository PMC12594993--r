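# Combinatorial library: reactions plus per-position synthon lists.
#
# File dialect (tab-separated, header row):
#   reactions file: reaction_id, smarts, n_positions
#   reagents file:  smiles, synthon_id, reaction_id, position   (0-based)

#' Construct a reaction record
#'
#' Low-level constructor used by [load_library()] and by code that only
#' needs product counting (positions may then hold bare synthon-id
#' vectors). `validate = TRUE` additionally requires a parsed reaction of
#' matching arity.
#'
#' @param reaction_id Opaque identifier.
#' @param smarts Reaction SMARTS (`k >= 2` reactant templates).
#' @param positions List of length `k`; each element a character vector of
#'   synthon ids (file order).
#' @param parsed Optional pre-parsed `sev_reaction`.
#' @param validate Check arity and position count.
#' @return A `reaction_record`.
#' @export
reaction_record <- function(reaction_id, smarts, positions, parsed = NULL,
                            validate = TRUE) {
  if (validate) {
    if (is.null(parsed)) parsed <- parse_reaction_smarts(smarts)
    if (parsed$arity < 2L) {
      stop("reaction '", reaction_id, "' has fewer than two components",
           call. = FALSE)
    }
    if (length(positions) != parsed$arity) {
      stop("reaction '", reaction_id, "': ", length(positions),
           " reagent positions for ", parsed$arity, " templates",
           call. = FALSE)
    }
  }
  structure(
    list(
      reaction_id = reaction_id,
      smarts = smarts,
      parsed = parsed,
      arity = length(positions),
      positions = positions,
      position_index = NULL, # filled by load_library
      product_count = prod(vapply(positions, length, integer(1)))
    ),
    class = "reaction_record"
  )
}

#' Number of products a reaction can form
#'
#' The product of its position-list lengths; no enumeration.
#'
#' @param reaction A `reaction_record`.
#' @return Non-negative count (double, to allow > 2^31).
#' @export
count_products <- function(reaction) {
  stopifnot(inherits(reaction, "reaction_record"))
  prod(vapply(reaction$positions, length, integer(1)))
}

#' Ligand genotype: a molecule as (reaction, ordered synthons)
#'
#' @param reaction_id Reaction identifier.
#' @param synthon_ids Character vector, one synthon id per reactant position.
#' @param library Optional library; when given, closure is checked: the
#'   reaction must exist and each synthon must belong to its position list.
#' @return A `ligand_genotype`.
#' @export
ligand_genotype <- function(reaction_id, synthon_ids, library = NULL) {
  g <- structure(
    list(reaction_id = reaction_id, synthon_ids = as.character(synthon_ids)),
    class = "ligand_genotype"
  )
  if (!is.null(library)) {
    rxn <- library$reactions[[reaction_id]]
    if (is.null(rxn)) {
      stop("genotype references unknown reaction '", reaction_id, "'",
           call. = FALSE)
    }
    if (length(synthon_ids) != rxn$arity) {
      stop("genotype for '", reaction_id, "' needs ", rxn$arity,
           " synthons, got ", length(synthon_ids), call. = FALSE)
    }
    for (p in seq_along(synthon_ids)) {
      if (!(synthon_ids[p] %in% rxn$positions[[p]])) {
        stop("synthon '", synthon_ids[p], "' is not in position ", p,
             " of reaction '", reaction_id, "'", call. = FALSE)
      }
    }
  }
  g
}

genotype_key <- function(genotype) {
  paste0(genotype$reaction_id, "::",
         paste(genotype$synthon_ids, collapse = "|"))
}

#' @export
print.ligand_genotype <- function(x, ...) {
  cat("<genotype ", genotype_key(x), ">\n", sep = "")
  invisible(x)
}

#' Load a combinatorial library from reaction and reagent files
#'
#' Parses every reagent SMILES, verifies it against the reactant template
#' of its position, and computes its fingerprint once. Synthons that fail
#' to parse or do not match their template are dropped with a warning and
#' counted in the returned object's `dropped` field.
#'
#' @param reactions_source Path to the reactions TSV
#'   (`reaction_id`, `smarts`, `n_positions`).
#' @param reagents_source Path to the reagents TSV
#'   (`smiles`, `synthon_id`, `reaction_id`, `position` 0-based).
#' @param config A [fingerprint_config()] used for all fingerprints.
#' @return A `combinatorial_library`.
#' @export
load_library <- function(reactions_source, reagents_source,
                         config = fingerprint_config()) {
  for (f in c(reactions_source, reagents_source)) {
    if (!file.exists(f)) stop("cannot read file: ", f, call. = FALSE)
  }
  rx <- utils::read.delim(reactions_source, stringsAsFactors = FALSE)
  rg <- utils::read.delim(reagents_source, stringsAsFactors = FALSE)
  need_rx <- c("reaction_id", "smarts", "n_positions")
  need_rg <- c("smiles", "synthon_id", "reaction_id", "position")
  if (!all(need_rx %in% names(rx))) {
    stop("reactions file must have columns: ", paste(need_rx, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_rg %in% names(rg))) {
    stop("reagents file must have columns: ", paste(need_rg, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rx$reaction_id)) {
    stop("duplicate reaction ids in ", reactions_source, call. = FALSE)
  }

  synthon_mols <- list()
  synthon_fps <- list()
  syn_tab <- list()
  reactions <- list()
  dropped <- 0L

  for (r in seq_len(nrow(rx))) {
    rid <- rx$reaction_id[r]
    parsed <- parse_reaction_smarts(rx$smarts[r])
    if (parsed$arity != rx$n_positions[r]) {
      stop("reaction '", rid, "': n_positions=", rx$n_positions[r],
           " but SMARTS has ", parsed$arity, " templates", call. = FALSE)
    }
    positions <- vector("list", parsed$arity)
    pos_index <- vector("list", parsed$arity)
    for (p in seq_len(parsed$arity)) {
      rows <- rg[rg$reaction_id == rid & rg$position == p - 1L, , drop = FALSE]
      ids <- character(0); idx <- integer(0)
      for (q in seq_len(nrow(rows))) {
        mol <- tryCatch(parse_smiles(rows$smiles[q]), error = function(e) NULL)
        ok <- !is.null(mol) &&
          length(smarts_matches(mol, parsed$templates[[p]],
                                max_matches = 1L)) > 0L
        if (!ok) {
          dropped <- dropped + 1L
          next
        }
        gi <- length(synthon_mols) + 1L
        synthon_mols[[gi]] <- mol
        synthon_fps[[gi]] <- ecfp_bits(mol, config)
        syn_tab[[gi]] <- data.frame(
          synthon_id = rows$synthon_id[q], smiles = rows$smiles[q],
          reaction_id = rid, position = p, stringsAsFactors = FALSE
        )
        ids <- c(ids, rows$synthon_id[q])
        idx <- c(idx, gi)
      }
      if (length(ids) == 0L) {
        stop("reaction '", rid, "' position ", p,
             " has no valid synthons", call. = FALSE)
      }
      positions[[p]] <- ids
      names(idx) <- ids
      pos_index[[p]] <- idx
    }
    rec <- reaction_record(rid, rx$smarts[r], positions, parsed = parsed)
    rec$position_index <- pos_index
    reactions[[rid]] <- rec
  }
  if (dropped > 0L) {
    warning(dropped, " synthon(s) dropped (unparsable SMILES or template",
            " mismatch)", call. = FALSE)
  }
  total <- sum(vapply(reactions, count_products, numeric(1)))
  if (total < 1) stop("library contains no products", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  cache$products <- new.env(parent = emptyenv())  # genotype key -> product
  cache$molecules <- new.env(parent = emptyenv()) # canonical -> product

  structure(
    list(
      reactions = reactions,
      synthons = do.call(rbind, syn_tab),
      synthon_mols = synthon_mols,
      synthon_fps = synthon_fps,
      fingerprint_config = config,
      total_products = total,
      dropped = dropped,
      cache = cache
    ),
    class = "combinatorial_library"
  )
}

#' @export
print.combinatorial_library <- function(x, ...) {
  cat("<combinatorial library: ", length(x$reactions), " reactions, ",
      format(x$total_products, big.mark = ","), " products>\n", sep = "")
  invisible(x)
}

#' Library digest for provenance
#'
#' A JSON snapshot of reaction ids, position sizes and the total product
#' count. Re-loading identical files yields an identical digest.
#'
#' @param library A `combinatorial_library`.
#' @param path Optional path to write the JSON to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
library_digest <- function(library, path = NULL) {
  reactions <- lapply(library$reactions, function(r) {
    list(
      reaction_id = r$reaction_id,
      position_sizes = vapply(r$positions, length, integer(1)),
      product_count = count_products(r),
      synthon_ids = r$positions
    )
  })
  js <- jsonlite::toJSON(
    list(
      reactions = unname(reactions),
      total_products = library$total_products,
      fingerprint = unclass(library$fingerprint_config)
    ),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Sample random genotypes (product-count weighted)
#'
#' A reaction is drawn with probability proportional to its product count,
#' then one synthon per position uniformly at random -- the sampler used
#' both for the starting population and for the random screening baseline.
#'
#' @param library A `combinatorial_library`.
#' @param n Number of independent draws.
#' @return A list of `ligand_genotype` (for `sample_random_genotype`, a
#'   single genotype).
#' @export
sample_random_genotypes <- function(library, n) {
  stopifnot(n >= 1L)
  if (length(library$reactions) == 0L || library$total_products < 1) {
    stop("cannot sample from an empty library", call. = FALSE)
  }
  counts <- vapply(library$reactions, count_products, numeric(1))
  ridx <- sample.int(length(counts), n, replace = TRUE, prob = counts)
  lapply(ridx, function(r) {
    rxn <- library$reactions[[r]]
    syn <- vapply(rxn$positions, function(ids) {
      ids[sample.int(length(ids), 1L)]
    }, character(1))
    ligand_genotype(rxn$reaction_id, syn)
  })
}

#' @rdname sample_random_genotypes
#' @export
sample_random_genotype <- function(library) {
  sample_random_genotypes(library, 1L)[[1]]
}

#' Enumerate every genotype of a reaction
#'
#' Lexicographic in position-list (file) order, first position slowest;
#' the first genotype uses the first synthon at every position.
#'
#' @param reaction A `reaction_record` (from a loaded library).
#' @return List of `ligand_genotype`, length [count_products()].
#' @export
enumerate_genotypes <- function(reaction) {
  stopifnot(inherits(reaction, "reaction_record"))
  sizes <- vapply(reaction$positions, length, integer(1))
  grid <- do.call(expand.grid, c(
    rev(lapply(sizes, seq_len)),
    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ))
  grid <- grid[, rev(seq_along(sizes)), drop = FALSE] # first position slowest
  lapply(seq_len(nrow(grid)), function(i) {
    syn <- vapply(seq_along(sizes), function(p) {
      reaction$positions[[p]][grid[i, p]]
    }, character(1))
    ligand_genotype(reaction$reaction_id, syn)
  })
}
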