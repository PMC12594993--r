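# Fitness evaluation: ligand-efficiency normalization, duplicate caching,
# similarity penalty, and the two docking-free backends.

#' Ligand-efficiency normalized score
#'
#' `raw_energy / heavy_atoms^(1/n)`. `n = 1` is classic ligand efficiency
#' per heavy atom; the default `n = 2` (square-root normalization) is the
#' geometric mean of raw energy and ligand efficiency, balancing affinity
#' against molecular size.
#'
#' @param raw_energy Interface-energy-like score, lower is better.
#' @param heavy_atoms Positive integer heavy-atom count (vectorized).
#' @param n Root order, one of 1, 2, 3, 4.
#' @return Normalized fitness, same shape as the inputs.
#' @export
lid_rootn <- function(raw_energy, heavy_atoms, n = 2L) {
  if (!all(n %in% 1:4)) stop("n must be in {1, 2, 3, 4}", call. = FALSE)
  if (any(heavy_atoms < 1)) {
    stop("heavy_atoms must be >= 1", call. = FALSE)
  }
  raw_energy / heavy_atoms^(1 / n)
}

#' Similarity penalty across a population
#'
#' Processes molecules best-first (ascending pre-penalty fitness, ties by
#' molecule key): each molecule's fingerprint is compared against all
#' already-stored fingerprints and receives `step` penalty for every stored
#' fingerprint with Tanimoto similarity strictly above `threshold`; its own
#' fingerprint is then stored regardless. Three identical molecules thus
#' receive penalties 0, `step`, `2 * step`. Keeps takeover of a population
#' by one well-scoring molecule in check while still letting it appear a
#' few times.
#'
#' @param fitness Pre-penalty fitness vector (lower = better).
#' @param fingerprints List of on-bit fingerprint vectors, same length.
#' @param molecule_keys Canonical SMILES used for deterministic tie-breaks.
#' @param threshold Similarity above which (strictly) a penalty applies.
#' @param step Penalty added per matching stored fingerprint.
#' @param n_bits Fingerprint bit length.
#' @return Numeric penalty vector aligned with the input order.
#' @export
apply_similarity_penalty <- function(fitness, fingerprints, molecule_keys,
                                     threshold = 0.95, step = 0.5,
                                     n_bits = 2048L) {
  n <- length(fitness)
  stopifnot(length(fingerprints) == n, length(molecule_keys) == n)
  if (n == 0L) return(numeric(0))
  ord <- order(fitness, molecule_keys)
  sims <- tanimoto_cross(fingerprints, fingerprints, n_bits)
  penalty <- numeric(n)
  for (r in seq_along(ord)) {
    i <- ord[r]
    if (r > 1L) {
      stored <- ord[seq_len(r - 1L)]
      penalty[i] <- step * sum(sims[i, stored] > threshold)
    }
  }
  penalty
}

#' Score cache
#'
#' Maps canonical molecule keys to raw energies so a molecule seen in any
#' earlier generation is never re-scored, and counts backend invocations.
#'
#' @return A `score_cache` environment.
#' @export
new_score_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$scores <- new.env(parent = emptyenv())
  e$backend_calls <- 0L
  e$worst_fitness <- -Inf
  class(e) <- "score_cache"
  e
}

#' Deterministic surrogate energy backend
#'
#' A docking stand-in for tests and demonstrations: the energy of a
#' molecule is a weighted sum over its fingerprint's on-bits (each bit
#' carries a fixed pseudo-random weight derived from the bit index and the
#' backend seed) plus a mild size term, scaled into a docking-like negative
#' range. Molecules sharing substructures therefore receive correlated
#' energies, giving the optimizer a navigable landscape, and a fixed seed
#' gives identical scores across runs.
#'
#' @param seed Integer controlling the per-bit weights (a property of the
#'   simulated target, not of any optimization run).
#' @param n_bits Fingerprint bit length the backend expects.
#' @param base,size_coef,bit_coef Scale parameters of the pseudo-energy.
#' @return A `fitness_backend`.
#' @export
surrogate_backend <- function(seed = 42L, n_bits = 2048L, base = -12,
                              size_coef = -0.3, bit_coef = 2.2) {
  weights <- vapply(seq_len(n_bits), function(b) {
    2 * hash01(c(b, seed)) - 1
  }, numeric(1))
  structure(
    list(
      id = sprintf("surrogate(seed=%d)", seed),
      evaluate = function(molecules) {
        vapply(molecules, function(m) {
          base + size_coef * m$heavy_atoms + bit_coef * sum(weights[m$fingerprint])
        }, numeric(1))
      }
    ),
    class = "fitness_backend"
  )
}

#' Lookup-table fitness backend
#'
#' Serves raw energies from a pre-computed score table (the pre-docked
#' benchmark mode, where coverage of every enumerable product is
#' guaranteed). An unknown molecule key is an error.
#'
#' @param score_table Path to a CSV with columns `canonical_smiles`,
#'   `raw_energy`, or a data.frame with those columns.
#' @return A `fitness_backend`.
#' @export
lookup_backend <- function(score_table) {
  if (is.character(score_table)) {
    score_table <- utils::read.csv(score_table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("canonical_smiles", "raw_energy") %in% names(score_table)))
  tab <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(score_table))) {
    tab[[score_table$canonical_smiles[i]]] <- score_table$raw_energy[i]
  }
  structure(
    list(
      id = "lookup",
      evaluate = function(molecules) {
        vapply(molecules, function(m) {
          v <- tab[[m$canonical_smiles]]
          if (is.null(v)) {
            stop("no score for molecule key '", m$canonical_smiles, "'",
                 call. = FALSE)
          }
          v
        }, numeric(1))
      }
    ),
    class = "fitness_backend"
  )
}

#' Write/read a score table
#'
#' @param scores data.frame with `canonical_smiles`, `raw_energy`.
#' @param path CSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores[, c("canonical_smiles", "raw_energy")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a population of individuals
#'
#' Assembles each genotype's product (memoized in the library), invokes the
#' backend exactly once per distinct molecule key not already in the score
#' cache, normalizes raw energies with [lid_rootn()], and applies the
#' similarity penalty over the population in best-first order. Genotypes
#' whose assembly or scoring fails receive a worst-score sentinel
#' (`sentinel_offset` above the worst fitness seen so far) and a warning;
#' the run continues.
#'
#' @param pop Individuals data.frame (see [make_individuals()]).
#' @param library A `combinatorial_library`.
#' @param backend A `fitness_backend`.
#' @param cache A [new_score_cache()].
#' @param lid_n Root order for the normalization.
#' @param penalty_threshold,penalty_step Similarity-penalty parameters.
#' @param sentinel_offset Added above the worst observed fitness for
#'   failures.
#' @return `pop` with `molecule_key`, `heavy_atoms`, `raw_energy`,
#'   `fitness`, `penalty` filled in.
#' @export
evaluate_population <- function(pop, library, backend, cache = new_score_cache(),
                                lid_n = 2L, penalty_threshold = 0.95,
                                penalty_step = 0.5, sentinel_offset = 10) {
  n <- nrow(pop)
  genotypes <- pop_genotypes(pop)
  prods <- assemble_products(library, genotypes)
  failed <- vapply(prods, inherits, logical(1), "assembly_error")

  keys <- rep(NA_character_, n)
  heavy <- rep(NA_integer_, n)
  keys[!failed] <- vapply(prods[!failed], `[[`, character(1), "canonical_smiles")
  heavy[!failed] <- vapply(prods[!failed], `[[`, integer(1), "heavy_atoms")

  raw <- rep(NA_real_, n)
  ok_idx <- which(!failed)
  if (length(ok_idx) > 0L) {
    uk <- unique(keys[ok_idx])
    missing <- uk[!vapply(uk, function(k) !is.null(cache$scores[[k]]),
                          logical(1))]
    if (length(missing) > 0L) {
      mols <- lapply(missing, function(k) library$cache$molecules[[k]])
      vals <- tryCatch(backend$evaluate(mols), error = function(e) e)
      if (inherits(vals, "error")) {
        # score molecules one by one so a single failure stays local
        vals <- vapply(mols, function(m) {
          tryCatch(backend$evaluate(list(m)), error = function(e) NA_real_)
        }, numeric(1))
      }
      for (j in seq_along(missing)) cache$scores[[missing[j]]] <- vals[j]
      cache$backend_calls <- cache$backend_calls + length(missing)
    }
    raw[ok_idx] <- vapply(keys[ok_idx], function(k) cache$scores[[k]],
                          numeric(1))
  }
  score_failed <- !failed & is.na(raw)
  failed <- failed | score_failed

  fitness <- rep(NA_real_, n)
  fitness[!failed] <- lid_rootn(raw[!failed], heavy[!failed], lid_n)
  if (any(is.finite(fitness))) {
    cache$worst_fitness <- max(cache$worst_fitness, fitness[!failed])
  }
  if (any(failed)) {
    sentinel <- (if (is.finite(cache$worst_fitness)) cache$worst_fitness
                 else 0) + sentinel_offset
    fitness[failed] <- sentinel
    keys[failed] <- paste0("failed::", vapply(genotypes[failed],
                                              genotype_key, character(1)))
    warning(sum(failed), " individual(s) received the failure sentinel ",
            "score", call. = FALSE)
  }

  fps <- vector("list", n)
  fps[!failed] <- lapply(prods[!failed], `[[`, "fingerprint")
  fps[failed] <- list(integer(0))
  penalty <- apply_similarity_penalty(
    fitness, fps, keys,
    threshold = penalty_threshold, step = penalty_step,
    n_bits = library$fingerprint_config$n_bits
  )

  pop$molecule_key <- keys
  pop$heavy_atoms <- heavy
  pop$raw_energy <- raw
  pop$fitness <- fitness
  pop$penalty <- penalty
  pop
}

#' Individuals data.frame
#'
#' One row per individual: genotype (reaction id plus `|`-separated synthon
#' ids), lineage, generation, and score columns filled by
#' [evaluate_population()].
#'
#' @param genotypes List of `ligand_genotype`.
#' @param generation Generation of birth.
#' @param factory Producing factory label.
#' @param parent1,parent2 Row ids of the parents (`NA` for the random start).
#' @return data.frame.
#' @export
make_individuals <- function(genotypes, generation = 0L, factory = "random",
                             parent1 = NA_integer_, parent2 = NA_integer_) {
  n <- length(genotypes)
  data.frame(
    id = rep(NA_integer_, n),
    generation = rep(as.integer(generation), n),
    reaction_id = vapply(genotypes, `[[`, character(1), "reaction_id"),
    synthons = vapply(genotypes, function(g) {
      paste(g$synthon_ids, collapse = "|")
    }, character(1)),
    molecule_key = NA_character_,
    heavy_atoms = NA_integer_,
    raw_energy = NA_real_,
    fitness = NA_real_,
    penalty = NA_real_,
    factory = rep(factory, length.out = n),
    parent1 = rep(parent1, length.out = n),
    parent2 = rep(parent2, length.out = n),
    evaluated = TRUE,
    stringsAsFactors = FALSE
  )
}

# reconstruct genotype objects from an individuals data.frame
pop_genotypes <- function(pop) {
  syn <- strsplit(pop$synthons, "|", fixed = TRUE)
  lapply(seq_len(nrow(pop)), function(i) {
    ligand_genotype(pop$reaction_id[i], syn[[i]])
  })
}

# all-zero fingerprints for failures never exceed the similarity threshold
# against real molecules but match each other exactly; keyed sentinel keys
# keep them distinct in dedup statistics.
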