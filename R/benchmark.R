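# Pre-docked benchmark construction, random baseline, hit rates and
# enrichment factors.

#' Greedy diversity selection of fragments
#'
#' Seeds the list with a uniformly chosen candidate, then repeatedly adds
#' the candidate with the lowest mean Tanimoto similarity to everything
#' already selected (ties broken by id order), until `n` are picked. This
#' builds a deliberately rugged similarity landscape.
#'
#' @param fps List of candidate fingerprints.
#' @param ids Candidate identifiers (same length).
#' @param n Number to select, `1 <= n <= length(ids)`.
#' @param n_bits Fingerprint bit length.
#' @return Character vector of selected ids, in greedy order.
#' @export
diversity_select_fragments <- function(fps, ids, n, n_bits = 2048L) {
  m <- length(ids)
  if (n < 1L || n > m) {
    stop("cannot select ", n, " from ", m, " candidates", call. = FALSE)
  }
  sims <- tanimoto_cross(fps, fps, n_bits)
  selected <- integer(0)
  seed <- sample.int(m, 1L)
  selected <- seed
  while (length(selected) < n) {
    rest <- setdiff(seq_len(m), selected)
    mean_sim <- rowMeans(sims[rest, selected, drop = FALSE])
    ord <- order(mean_sim, ids[rest])
    selected <- c(selected, rest[ord[1]])
  }
  ids[selected]
}

#' Greedy diversity selection of reactions
#'
#' Seeds with a uniformly chosen reaction, then repeatedly adds the
#' reaction whose pooled fragments have the lowest mean Tanimoto similarity
#' to the pooled fragments of all reactions already selected.
#'
#' @param library A `combinatorial_library`.
#' @param n Number of reactions to select.
#' @return Character vector of reaction ids, in greedy order.
#' @export
diversity_select_reactions <- function(library, n) {
  rids <- names(library$reactions)
  if (n < 1L || n > length(rids)) {
    stop("cannot select ", n, " from ", length(rids), " reactions",
         call. = FALSE)
  }
  rxn_fps <- lapply(rids, function(rid) {
    idx <- unlist(library$reactions[[rid]]$position_index)
    library$synthon_fps[idx]
  })
  selected <- sample.int(length(rids), 1L)
  while (length(selected) < n) {
    rest <- setdiff(seq_along(rids), selected)
    pool_fps <- do.call(c, rxn_fps[selected])
    mean_sim <- vapply(rest, function(r) {
      mean(tanimoto_cross(rxn_fps[[r]], pool_fps,
                          library$fingerprint_config$n_bits))
    }, numeric(1))
    ord <- order(mean_sim, rids[rest])
    selected <- c(selected, rest[ord[1]])
  }
  rids[selected]
}

# reduce a library to n_reactions x n_fragments-per-position using the two
# greedy diversity selectors; returns a new combinatorial_library
reduce_library <- function(library, n_reactions, n_fragments) {
  rids <- diversity_select_reactions(library, n_reactions)
  reactions <- list()
  for (rid in rids) {
    rxn <- library$reactions[[rid]]
    positions <- vector("list", rxn$arity)
    pos_index <- vector("list", rxn$arity)
    for (p in seq_len(rxn$arity)) {
      idx <- rxn$position_index[[p]]
      keep <- diversity_select_fragments(
        library$synthon_fps[idx], names(idx), n_fragments,
        library$fingerprint_config$n_bits
      )
      keep <- keep[order(match(keep, names(idx)))] # restore file order
      positions[[p]] <- keep
      pos_index[[p]] <- idx[keep]
    }
    rec <- reaction_record(rid, rxn$smarts, positions, parsed = rxn$parsed)
    rec$position_index <- pos_index
    reactions[[rid]] <- rec
  }
  out <- library
  out$reactions <- reactions
  out$total_products <- sum(vapply(reactions, count_products, numeric(1)))
  out
}

#' Hit rate below a score threshold
#'
#' Fraction of scores strictly below `x`.
#'
#' @param scores Non-empty numeric vector (a molecule score multiset).
#' @param x Score threshold.
#' @return Rate in `[0, 1]`.
#' @export
hit_rate <- function(scores, x) {
  if (length(scores) == 0L) stop("empty score set", call. = FALSE)
  mean(scores < x)
}

#' Enrichment factor of a method over a baseline
#'
#' Ratio of the two hit rates at threshold `x`. When the baseline has no
#' hits but the method does, the factor is infinite and flagged rather than
#' raised as an error (no finite enrichment can be reported).
#'
#' @param method_scores,baseline_scores Non-empty score vectors.
#' @param x Score threshold.
#' @return List with `ef`, `method_rate`, `baseline_rate`, `finite`.
#' @export
enrichment_factor <- function(method_scores, baseline_scores, x) {
  hr_m <- hit_rate(method_scores, x)
  hr_b <- hit_rate(baseline_scores, x)
  if (hr_b == 0) {
    ef <- if (hr_m > 0) Inf else NaN
    return(list(ef = ef, method_rate = hr_m, baseline_rate = hr_b,
                finite = FALSE))
  }
  list(ef = hr_m / hr_b, method_rate = hr_m, baseline_rate = hr_b,
       finite = TRUE)
}

#' Enrichment report over a threshold sweep
#'
#' @param method_scores,baseline_scores Score vectors.
#' @param thresholds Score thresholds (one row each).
#' @return data.frame with hit counts, rates, and the enrichment factor
#'   (`NA` ef with `finite = FALSE` marks a zero-hit baseline).
#' @export
enrichment_report <- function(method_scores, baseline_scores, thresholds) {
  rows <- lapply(thresholds, function(x) {
    e <- enrichment_factor(method_scores, baseline_scores, x)
    data.frame(
      threshold = x,
      method_hits = sum(method_scores < x),
      method_rate = e$method_rate,
      baseline_hits = sum(baseline_scores < x),
      baseline_rate = e$baseline_rate,
      ef = if (e$finite) e$ef else NA_real_,
      finite = e$finite
    )
  })
  do.call(rbind, rows)
}

# number of hits at a quantile: round half up
hit_count_at_quantile <- function(n_total, quantile) {
  floor(n_total * quantile + 0.5)
}

#' Build a pre-docked benchmark
#'
#' Reduces the library with the diversity selectors, enumerates every
#' product of the reduced space, scores each with the backend, and sets the
#' hit threshold at the best `hit_quantile` fraction of scores (round half
#' up; the threshold is the next score above the last hit, so strictly-less
#' comparison recovers exactly the hit set). Molecules that fail assembly
#' or scoring are excluded from the hit-eligible set with a warning.
#'
#' @param library A `combinatorial_library`.
#' @param backend A `fitness_backend` scoring raw energies.
#' @param n_reactions,n_fragments Reduced size (per reaction and position).
#' @param hit_quantile Top fraction labelled as virtual hits.
#' @return A `predocked_benchmark`: reduced library, `score_table`
#'   (canonical_smiles, raw_energy), `hit_threshold`, `hits` (keys),
#'   `n_products`.
#' @export
build_predocked_benchmark <- function(library, backend,
                                      n_reactions = 4L, n_fragments = 500L,
                                      hit_quantile = 0.001) {
  red <- reduce_library(library, n_reactions, n_fragments)
  genotypes <- unlist(lapply(red$reactions, enumerate_genotypes),
                      recursive = FALSE)
  prods <- assemble_products(red, genotypes)
  ok <- !vapply(prods, inherits, logical(1), "assembly_error")
  if (any(!ok)) {
    warning(sum(!ok), " products failed assembly and are excluded",
            call. = FALSE)
  }
  keys <- vapply(prods[ok], `[[`, character(1), "canonical_smiles")
  # duplicates can arise when different genotypes give the same molecule;
  # the score table covers each enumerable product (genotype) once
  mols <- prods[ok]
  uk <- !duplicated(keys)
  raw <- backend$evaluate(mols[uk])
  score_map <- stats::setNames(raw, keys[uk])
  score_table <- data.frame(
    genotype = vapply(genotypes[ok], genotype_key, character(1)),
    canonical_smiles = keys,
    raw_energy = unname(score_map[keys]),
    stringsAsFactors = FALSE
  )
  n_products <- nrow(score_table)
  n_hits <- hit_count_at_quantile(n_products, hit_quantile)
  s <- sort(score_table$raw_energy)
  threshold <- if (n_hits >= n_products) Inf else s[n_hits + 1L]
  ord <- order(score_table$raw_energy, score_table$canonical_smiles)
  hits <- unique(score_table$canonical_smiles[ord][seq_len(n_hits)])
  structure(
    list(
      library = red,
      score_table = score_table,
      hit_quantile = hit_quantile,
      n_products = n_products,
      n_hits = n_hits,
      hit_threshold = threshold,
      hits = hits
    ),
    class = "predocked_benchmark"
  )
}

#' @export
print.predocked_benchmark <- function(x, ...) {
  cat("<pre-docked benchmark: ", x$n_products, " products, ",
      x$n_hits, " hits below ", format(x$hit_threshold, digits = 4), ">\n",
      sep = "")
  invisible(x)
}

#' Random screening baseline
#'
#' `n` independent product-count-weighted random genotypes (duplicates
#' allowed), assembled and scored — the baseline sampler of the enrichment
#' factor.
#'
#' @param library A `combinatorial_library`.
#' @param n Sample size.
#' @param backend A `fitness_backend`.
#' @param cache Optional [new_score_cache()] shared with other evaluations.
#' @return data.frame with `molecule_key` and `raw_energy` (one row per
#'   draw).
#' @export
random_baseline <- function(library, n, backend, cache = new_score_cache()) {
  stopifnot(n >= 1L)
  genotypes <- sample_random_genotypes(library, n)
  prods <- assemble_products(library, genotypes)
  ok <- !vapply(prods, inherits, logical(1), "assembly_error")
  if (any(!ok)) warning(sum(!ok), " baseline draws failed assembly",
                        call. = FALSE)
  keys <- vapply(prods[ok], `[[`, character(1), "canonical_smiles")
  uk <- unique(keys)
  missing <- uk[!vapply(uk, function(k) !is.null(cache$scores[[k]]),
                        logical(1))]
  if (length(missing) > 0L) {
    mols <- lapply(missing, function(k) library$cache$molecules[[k]])
    vals <- backend$evaluate(mols)
    for (j in seq_along(missing)) cache$scores[[missing[j]]] <- vals[j]
    cache$backend_calls <- cache$backend_calls + length(missing)
  }
  data.frame(
    molecule_key = keys,
    raw_energy = vapply(keys, function(k) cache$scores[[k]], numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
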