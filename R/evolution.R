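# Selectors, offspring factories, and the generation loop.
#
# All selection acts on the effective score fitness + penalty (lower is
# better); ties are broken by molecule key so runs are replayable from the
# seed alone.

#' Selector specification
#'
#' @param kind `"elitist"`, `"tournament"` or `"roulette"`.
#' @param k Number of individuals to select.
#' @param remove_selected Drop selections from the pool afterwards.
#' @param tournament_size,accept_chance Tournament parameters.
#' @return A `selector_spec`.
#' @export
selector_spec <- function(kind = c("elitist", "tournament", "roulette"),
                          k, remove_selected = FALSE,
                          tournament_size = NULL, accept_chance = NULL) {
  kind <- match.arg(kind)
  stopifnot(k >= 1L)
  if (kind == "tournament") {
    stopifnot(!is.null(tournament_size), tournament_size >= 1L,
              !is.null(accept_chance), accept_chance > 0, accept_chance <= 1)
  }
  structure(
    list(kind = kind, k = as.integer(k), remove_selected = remove_selected,
         tournament_size = tournament_size, accept_chance = accept_chance),
    class = "selector_spec"
  )
}

effective_score <- function(pop) pop$fitness + pop$penalty

#' Elitist selection
#'
#' The `k` individuals with the lowest effective score (fitness + penalty),
#' ties broken by molecule key.
#'
#' @param pop Evaluated individuals data.frame.
#' @param k Number to select.
#' @param remove_selected Also return the pool without the selection.
#' @return List with `selected` and `remaining` data.frames.
#' @export
elitist_select <- function(pop, k, remove_selected = FALSE) {
  if (nrow(pop) < k) {
    stop("cannot select ", k, " from a population of ", nrow(pop),
         call. = FALSE)
  }
  ord <- order(effective_score(pop), pop$molecule_key)
  sel <- ord[seq_len(k)]
  list(
    selected = pop[sel, , drop = FALSE],
    remaining = if (remove_selected) pop[-sel, , drop = FALSE] else pop
  )
}

# linear roulette weights: distance from an anchor (the pool's worst
# effective score by default) plus a small floor, so weights stay
# nonnegative for docking-style negative scores and a molecule scoring
# twice as far below the anchor gets twice the selection chance
roulette_weights <- function(scores, eps = 0.01, anchor = NULL) {
  if (is.null(anchor)) anchor <- max(scores)
  rng <- anchor - min(scores)
  if (rng <= 0) return(rep(1, length(scores)))
  pmax(anchor - scores, 0) + eps * rng
}

#' Roulette (fitness-proportional) selection
#'
#' Weighted sampling without replacement within one call; weights are
#' linear in the score difference from the pool's worst individual (see
#' `vignette("synthevolve-methods")` for why raw score ratios are not
#' usable with negative docking scores).
#'
#' @inheritParams elitist_select
#' @param eps Weight floor as a fraction of the score range.
#' @param anchor Optional explicit worst-score anchor; defaults to the
#'   pool's worst effective score.
#' @return List with `selected` and `remaining`.
#' @export
roulette_select <- function(pop, k, remove_selected = FALSE, eps = 0.01,
                            anchor = NULL) {
  if (nrow(pop) < k) {
    stop("cannot select ", k, " from a population of ", nrow(pop),
         call. = FALSE)
  }
  w <- roulette_weights(effective_score(pop), eps, anchor)
  sel <- sample.int(nrow(pop), k, replace = FALSE, prob = w)
  list(
    selected = pop[sel, , drop = FALSE],
    remaining = if (remove_selected) pop[-sel, , drop = FALSE] else pop
  )
}

#' Tournament selection
#'
#' Each of the `k` selections draws `tournament_size` contestants uniformly
#' without replacement, sorts them by effective score, and walks the
#' ranking giving each contestant an `accept_chance` chance to accept; if
#' every contestant declines, the tournament's best is taken. Individuals
#' already selected within the call are excluded from later tournaments.
#'
#' @inheritParams elitist_select
#' @param tournament_size Contestants per tournament.
#' @param accept_chance Acceptance probability per rank.
#' @return List with `selected` and `remaining`.
#' @export
tournament_select <- function(pop, k, tournament_size, accept_chance,
                              remove_selected = FALSE) {
  if (tournament_size > nrow(pop)) {
    stop("tournament size ", tournament_size, " exceeds population ",
         nrow(pop), call. = FALSE)
  }
  if (nrow(pop) - k + 1L < tournament_size) {
    stop("cannot run ", k, " tournaments of size ", tournament_size,
         " on a population of ", nrow(pop), call. = FALSE)
  }
  eff <- effective_score(pop)
  avail <- seq_len(nrow(pop))
  sel <- integer(0)
  for (draw in seq_len(k)) {
    cand <- avail[sample.int(length(avail), tournament_size)]
    cand <- cand[order(eff[cand], pop$molecule_key[cand])]
    accepted <- which(stats::runif(tournament_size) < accept_chance)
    pick <- if (length(accepted) > 0L) cand[accepted[1]] else cand[1]
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  list(
    selected = pop[sel, , drop = FALSE],
    remaining = if (remove_selected) pop[-sel, , drop = FALSE] else pop
  )
}

apply_selector <- function(pop, spec) {
  switch(spec$kind,
    elitist = elitist_select(pop, spec$k, spec$remove_selected),
    roulette = roulette_select(pop, spec$k, spec$remove_selected),
    tournament = tournament_select(pop, spec$k, spec$tournament_size,
                                   spec$accept_chance, spec$remove_selected)
  )
}

# --- mutation / crossover ----------------------------------------------------

# lazily built per-position synthon-synthon similarity matrices
position_sims <- function(library, reaction_id, position) {
  key <- paste0(reaction_id, "#", position)
  hit <- library$cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- library$reactions[[reaction_id]]$position_index[[position]]
  s <- tanimoto_cross(library$synthon_fps[idx], library$synthon_fps[idx],
                      library$fingerprint_config$n_bits)
  dimnames(s) <- list(names(idx), names(idx))
  library$cache[[key]] <- s
  s
}

#' Fragment mutation
#'
#' Replaces the synthon at one uniformly chosen position with another
#' synthon from the same position list, sampled with Tanimoto similarity to
#' the current synthon as weight, restricted to the
#' `[min_similarity, max_similarity]` window. An empty window is widened by
#' dropping the upper bound, then the lower; a position with no
#' alternative at all yields the genotype unchanged.
#'
#' @param genotype A `ligand_genotype`.
#' @param library The library.
#' @param min_similarity,max_similarity Similarity window.
#' @return A mutated `ligand_genotype` (closure guaranteed).
#' @export
mutate_fragment <- function(genotype, library, min_similarity = 0,
                            max_similarity = 1) {
  rxn <- library$reactions[[genotype$reaction_id]]
  p <- sample.int(rxn$arity, 1L)
  ids <- rxn$positions[[p]]
  cur <- genotype$synthon_ids[p]
  others <- ids[ids != cur]
  if (length(others) == 0L) {
    message("fragment mutation no-op: position ", p, " of ",
            genotype$reaction_id, " has a single synthon")
    return(genotype)
  }
  sims <- position_sims(library, genotype$reaction_id, p)[cur, others]
  window <- others[sims >= min_similarity & sims <= max_similarity]
  if (length(window) == 0L) window <- others[sims >= min_similarity]
  if (length(window) == 0L) window <- others
  w <- sims[match(window, others)]
  if (sum(w) <= 0) w <- rep(1, length(window))
  new_id <- window[sample.int(length(window), 1L, prob = w)]
  g <- genotype
  g$synthon_ids[p] <- new_id
  g
}

# most similar synthon of reaction/position to a set of reference
# fingerprints (max over references); ties broken by synthon id order
best_matching_synthon <- function(library, reaction_id, position, ref_fps) {
  idx <- library$reactions[[reaction_id]]$position_index[[position]]
  sims <- tanimoto_cross(library$synthon_fps[idx], ref_fps,
                         library$fingerprint_config$n_bits)
  score <- apply(sims, 1L, max)
  ord <- order(-score, names(idx))
  names(idx)[ord[1]]
}

genotype_fps <- function(library, genotype) {
  rxn <- library$reactions[[genotype$reaction_id]]
  lapply(seq_along(genotype$synthon_ids), function(p) {
    library$synthon_fps[[rxn$position_index[[p]][genotype$synthon_ids[p]]]]
  })
}

#' Reaction mutation
#'
#' Switches to a different reaction (uniformly chosen) and fills each new
#' position with the synthon most similar to the old genotype's fragments:
#' position `p` targets the old fragment at position `p` where one exists,
#' surplus positions target all old fragments.
#'
#' @inheritParams mutate_fragment
#' @return A `ligand_genotype` on the new reaction.
#' @export
mutate_reaction <- function(genotype, library) {
  others <- setdiff(names(library$reactions), genotype$reaction_id)
  if (length(others) == 0L) {
    warning("single-reaction library: reaction mutation is a no-op",
            call. = FALSE)
    return(genotype)
  }
  new_rid <- others[sample.int(length(others), 1L)]
  map_fragments_to_reaction(library, new_rid, genotype)
}

# pick, for every position of reaction new_rid, the synthon most similar to
# the corresponding old fragment (index-aligned; surplus positions match
# against all old fragments)
map_fragments_to_reaction <- function(library, new_rid, old_genotype) {
  old_fps <- genotype_fps(library, old_genotype)
  arity <- library$reactions[[new_rid]]$arity
  syn <- character(arity)
  for (p in seq_len(arity)) {
    refs <- if (p <= length(old_fps)) old_fps[p] else old_fps
    syn[p] <- best_matching_synthon(library, new_rid, p, refs)
  }
  ligand_genotype(new_rid, syn)
}

#' Crossover
#'
#' One parent (uniformly chosen) donates the reaction; the positions are
#' partitioned randomly between the parents with each parent contributing
#' at least one fragment. Fragments contributed by a parent on a different
#' reaction are mapped into the donor reaction's position lists by maximal
#' Tanimoto similarity, exactly as in reaction mutation.
#'
#' @param parent_a,parent_b `ligand_genotype` parents.
#' @param library The library.
#' @return An offspring `ligand_genotype` (closure guaranteed).
#' @export
crossover <- function(parent_a, parent_b, library) {
  parents <- list(parent_a, parent_b)
  donor <- sample.int(2L, 1L)
  other <- 3L - donor
  rid <- parents[[donor]]$reaction_id
  arity <- library$reactions[[rid]]$arity
  repeat {
    src <- sample.int(2L, arity, replace = TRUE)
    if (length(unique(src)) == 2L) break
  }
  other_fps <- genotype_fps(library, parents[[other]])
  syn <- character(arity)
  for (p in seq_len(arity)) {
    if (src[p] == donor) {
      syn[p] <- parents[[donor]]$synthon_ids[p]
    } else if (parents[[other]]$reaction_id == rid) {
      syn[p] <- parents[[other]]$synthon_ids[p]
    } else {
      refs <- if (p <= length(other_fps)) other_fps[p] else other_fps
      syn[p] <- best_matching_synthon(library, rid, p, refs)
    }
  }
  ligand_genotype(rid, syn)
}

# --- protocol ----------------------------------------------------------------

#' Protocol step
#'
#' A (selector, offspring factory) pair with its options.
#'
#' @param selector A [selector_spec()].
#' @param factory `"identity"`, `"mutator"` or `"crossover"`.
#' @param n_offspring Offspring produced by the step (identity steps copy
#'   their selection and ignore this).
#' @param fragment_prob Probability a mutation acts on a fragment rather
#'   than the reaction (the stated 2:1 ratio = 2/3).
#' @param min_similarity,max_similarity Fragment-mutation window.
#' @param fragment_only,reaction_only Restrict the mutation kind.
#' @return A `protocol_step`.
#' @export
protocol_step <- function(selector, factory = c("identity", "mutator", "crossover"),
                          n_offspring = NULL, fragment_prob = 2 / 3,
                          min_similarity = 0, max_similarity = 1,
                          fragment_only = FALSE, reaction_only = FALSE) {
  factory <- match.arg(factory)
  if (factory != "identity") stopifnot(n_offspring >= 1L)
  stopifnot(min_similarity >= 0, max_similarity <= 1,
            min_similarity <= max_similarity)
  structure(
    list(selector = selector, factory = factory,
         n_offspring = if (is.null(n_offspring)) NULL else as.integer(n_offspring),
         fragment_prob = fragment_prob,
         min_similarity = min_similarity, max_similarity = max_similarity,
         fragment_only = fragment_only, reaction_only = reaction_only),
    class = "protocol_step"
  )
}

#' The default seven-step reproduction protocol
#'
#' 1. moderate mutations: roulette 15, 30 offspring, fragment:reaction 2:1,
#'    minimum similarity 0.6, parents kept;
#' 2. excessive crossover: roulette 15, 60 offspring, parents kept;
#' 3. drastic mutations: as 1 but fragment-only with maximum similarity 0.25;
#' 4. reaction mutation: as 1 but reaction-only;
#' 5. identity: elitist 15 copied unchanged and removed from the pool;
#' 6. as 1 on the depleted pool;
#' 7. as 2 on the depleted pool.
#'
#' @return List of seven [protocol_step()]s.
#' @export
default_protocol <- function() {
  rw15 <- function() selector_spec("roulette", k = 15L)
  list(
    protocol_step(rw15(), "mutator", 30L, min_similarity = 0.6),
    protocol_step(rw15(), "crossover", 60L),
    protocol_step(rw15(), "mutator", 30L, fragment_only = TRUE,
                  max_similarity = 0.25),
    protocol_step(rw15(), "mutator", 30L, reaction_only = TRUE),
    protocol_step(selector_spec("elitist", k = 15L, remove_selected = TRUE),
                  "identity"),
    protocol_step(rw15(), "mutator", 30L, min_similarity = 0.6),
    protocol_step(rw15(), "crossover", 60L)
  )
}

#' Evolution run configuration
#'
#' Defaults reproduce the published protocol: 200 random starting
#' individuals, 50 survivors per generation, 30 generations, tournament
#' main selector (size 15, acceptance 0.75), and the seven-step
#' reproduction protocol of [default_protocol()].
#'
#' @param initial_population Random genotypes in generation 0.
#' @param survivors Individuals passed between generations.
#' @param generations Number of reproduction cycles.
#' @param main_selector Selector reducing each new population.
#' @param steps Ordered list of [protocol_step()]s.
#' @param seed RNG seed (mandatory: runs are replayable by seed).
#' @param lid_n Root order of the ligand-efficiency normalization.
#' @param penalty_threshold,penalty_step Similarity-penalty parameters.
#' @return An `evolution_config`.
#' @export
evolution_config <- function(initial_population = 200L, survivors = 50L,
                             generations = 30L, main_selector = NULL,
                             steps = default_protocol(), seed = 1L,
                             lid_n = 2L, penalty_threshold = 0.95,
                             penalty_step = 0.5) {
  if (is.null(main_selector)) {
    main_selector <- selector_spec("tournament", k = survivors,
                                   remove_selected = TRUE,
                                   tournament_size = 15L,
                                   accept_chance = 0.75)
  }
  stopifnot(initial_population >= survivors, generations >= 0L)
  structure(
    list(initial_population = as.integer(initial_population),
         survivors = as.integer(survivors),
         generations = as.integer(generations),
         main_selector = main_selector, steps = steps,
         seed = as.integer(seed), lid_n = as.integer(lid_n),
         penalty_threshold = penalty_threshold, penalty_step = penalty_step),
    class = "evolution_config"
  )
}

step_offspring <- function(step, parents_df, library) {
  parents <- pop_genotypes(parents_df)
  np <- length(parents)
  if (step$factory == "identity") {
    out <- parents_df
    out$factory <- "identity"
    out$evaluated <- FALSE
    out$parent1 <- parents_df$id
    out$parent2 <- NA_integer_
    return(out)
  }
  n <- step$n_offspring
  if (step$factory == "mutator") {
    # round-robin: every parent is used the same number of times when
    # n_offspring is a multiple of the parent count (15 -> 30: twice each)
    assign <- rep(seq_len(np), length.out = n)
    genos <- vector("list", n)
    for (j in seq_len(n)) {
      g <- parents[[assign[j]]]
      do_fragment <- if (step$fragment_only) TRUE
        else if (step$reaction_only) FALSE
        else stats::runif(1) < step$fragment_prob
      genos[[j]] <- if (do_fragment) {
        mutate_fragment(g, library, step$min_similarity, step$max_similarity)
      } else {
        mutate_reaction(g, library)
      }
    }
    out <- make_individuals(genos, factory = "mutator")
    out$parent1 <- parents_df$id[assign]
    return(out)
  }
  # crossover: random pair per offspring
  genos <- vector("list", n)
  p1 <- integer(n); p2 <- integer(n)
  for (j in seq_len(n)) {
    pr <- sample.int(np, 2L)
    genos[[j]] <- crossover(parents[[pr[1]]], parents[[pr[2]]], library)
    p1[j] <- parents_df$id[pr[1]]
    p2[j] <- parents_df$id[pr[2]]
  }
  out <- make_individuals(genos, factory = "crossover")
  out$parent1 <- p1
  out$parent2 <- p2
  out
}

#' Run the evolutionary optimization
#'
#' Generation 0 draws `initial_population` random genotypes
#' (product-count-weighted reactions, uniform synthons), evaluates them and
#' reduces to `survivors` with the main selector. Each later generation
#' applies the reproduction steps in order against the survivor pool,
#' evaluates all non-identity offspring, merges them with the identity
#' copies and applies the main selector again. Every individual ever
#' created is logged with its lineage.
#'
#' @param config An [evolution_config()].
#' @param library A `combinatorial_library`.
#' @param backend A `fitness_backend`.
#' @return An `evolution_run`: list with `individuals` (all rows),
#'   `generations` (per-generation best/10th/100th/median fitness),
#'   `n_evaluated`, `n_distinct_molecules`, `backend_calls`, `config`.
#' @export
run_evolution <- function(config, library, backend) {
  stopifnot(inherits(config, "evolution_config"))
  set.seed(config$seed)
  cache <- new_score_cache()
  eval_pop <- function(pop) {
    evaluate_population(pop, library, backend, cache,
                        lid_n = config$lid_n,
                        penalty_threshold = config$penalty_threshold,
                        penalty_step = config$penalty_step)
  }
  next_id <- 1L
  assign_ids <- function(df) {
    df$id <- seq.int(next_id, length.out = nrow(df))
    next_id <<- next_id + nrow(df)
    df
  }

  pop0 <- make_individuals(sample_random_genotypes(library,
                                                   config$initial_population))
  pop0 <- assign_ids(eval_pop(pop0))
  log_rows <- list(pop0)
  gen_stats <- list()
  all_fitness <- pop0$fitness

  stat_row <- function(gen) {
    s <- sort(all_fitness)
    data.frame(
      generation = gen,
      n_evaluated = length(s),
      best = s[1],
      rank10 = if (length(s) >= 10L) s[10] else NA_real_,
      rank100 = if (length(s) >= 100L) s[100] else NA_real_,
      median = stats::median(s)
    )
  }
  gen_stats[[1]] <- stat_row(0L)

  survivors <- apply_selector(pop0, config$main_selector)$selected

  if (config$generations > 0L) {
    for (gen in seq_len(config$generations)) {
      pool <- survivors
      identity_rows <- NULL
      offspring <- list()
      for (step in config$steps) {
        sel <- apply_selector(pool, step$selector)
        pool <- sel$remaining
        produced <- step_offspring(step, sel$selected, library)
        if (step$factory == "identity") {
          identity_rows <- rbind(identity_rows, produced)
        } else {
          produced$generation <- gen
          offspring[[length(offspring) + 1L]] <- produced
        }
      }
      new_pop <- do.call(rbind, offspring)
      new_pop <- assign_ids(eval_pop(new_pop))
      all_fitness <- c(all_fitness, new_pop$fitness)
      if (!is.null(identity_rows)) {
        identity_rows <- assign_ids(identity_rows)
        identity_rows$generation <- gen
        merged <- rbind(identity_rows, new_pop)
      } else {
        merged <- new_pop
      }
      # penalties are contextual: recompute over the merged population
      merged$penalty <- apply_similarity_penalty(
        merged$fitness,
        population_fps(library, merged),
        merged$molecule_key,
        threshold = config$penalty_threshold, step = config$penalty_step,
        n_bits = library$fingerprint_config$n_bits
      )
      log_rows[[length(log_rows) + 1L]] <- merged
      gen_stats[[gen + 1L]] <- stat_row(gen)
      survivors <- apply_selector(merged, config$main_selector)$selected
    }
  }

  individuals <- do.call(rbind, log_rows)
  rownames(individuals) <- NULL
  evaluated <- individuals[individuals$evaluated, , drop = FALSE]
  structure(
    list(
      individuals = individuals,
      generations = do.call(rbind, gen_stats),
      final_population = survivors,
      n_evaluated = nrow(evaluated),
      n_distinct_molecules = length(unique(evaluated$molecule_key)),
      backend_calls = cache$backend_calls,
      config = config
    ),
    class = "evolution_run"
  )
}

# fingerprints of the products of an evaluated population (cache-backed)
population_fps <- function(library, pop) {
  lapply(seq_len(nrow(pop)), function(i) {
    pm <- library$cache$molecules[[pop$molecule_key[i]]]
    if (is.null(pm)) integer(0) else pm$fingerprint
  })
}

#' @export
print.evolution_run <- function(x, ...) {
  cat("<evolution run: ", x$n_evaluated, " individuals evaluated, ",
      x$n_distinct_molecules, " distinct molecules, best fitness ",
      format(min(x$individuals$fitness, na.rm = TRUE), digits = 4), ">\n",
      sep = "")
  invisible(x)
}
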