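# Selectors, reproduction operators, and the generation loop.

# a hand-built evaluated population with controllable scores
score_pop <- function(fitness, penalty = 0, keys = NULL) {
  n <- length(fitness)
  if (is.null(keys)) keys <- sprintf("mol%02d", seq_len(n))
  df <- make_individuals(replicate(n, ligand_genotype("amide", c("a", "b")),
                                   simplify = FALSE))
  df$id <- seq_len(n)
  df$molecule_key <- keys
  df$fitness <- fitness
  df$penalty <- rep(penalty, length.out = n)
  df
}

test_that("elitist selection returns the k best with stable tie-breaks", {
  pop <- score_pop(c(-3, -5, -1, -5, -2), keys = c("e", "d", "c", "b", "a"))
  all_sel <- elitist_select(pop, 5L)
  expect_identical(nrow(all_sel$selected), 5L)
  best <- elitist_select(pop, 1L)$selected
  expect_identical(best$molecule_key, "b") # tie at -5 broken by key
  # tie at the cut: k = 2 must take both -5 rows in key order, matching a
  # plain sort oracle
  two <- elitist_select(pop, 2L)$selected
  oracle <- pop[order(pop$fitness + pop$penalty, pop$molecule_key), ][1:2, ]
  expect_identical(two$molecule_key, oracle$molecule_key)
  # removal depletes the pool of its best
  rem <- elitist_select(pop, 2L, remove_selected = TRUE)$remaining
  expect_gt(min(rem$fitness), -5)
  expect_error(elitist_select(pop, 6L), "cannot select")
})

test_that("roulette selection realizes the linear two-to-one ratio", {
  # scores -4 and -2 with an explicit anchor at 0: selection chances 2:1
  pop <- score_pop(c(-4, -2))
  set.seed(31)
  picks <- vapply(1:20000, function(i) {
    roulette_select(pop, 1L, anchor = 0)$selected$molecule_key
  }, character(1))
  n1 <- sum(picks == "mol01")
  # weights (4 + eps*4, 2 + eps*4): expected share of mol01
  p1 <- 4.04 / (4.04 + 2.04)
  ci <- stats::qbinom(c(0.005, 0.995), 20000L, p1)
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])
})

test_that("roulette selection is uniform for all-equal scores", {
  pop <- score_pop(rep(-3, 5))
  set.seed(32)
  picks <- vapply(1:20000, function(i) {
    roulette_select(pop, 1L)$selected$molecule_key
  }, character(1))
  p <- stats::chisq.test(table(picks))$p.value
  expect_gt(p, 0.001)
})

test_that("roulette frequencies match the closed-form weights", {
  fitness <- c(-6, -4.5, -4, -2.5, -1)
  pop <- score_pop(fitness)
  # the weight contract: distance from the pool's worst score plus a 1%
  # floor of the range
  w <- (max(fitness) - fitness) + 0.01 * (max(fitness) - min(fitness))
  set.seed(33)
  picks <- vapply(1:20000, function(i) {
    roulette_select(pop, 1L)$selected$molecule_key
  }, character(1))
  counts <- table(factor(picks, levels = pop$molecule_key))
  p <- stats::chisq.test(counts, p = w / sum(w))$p.value
  expect_gt(p, 0.001)
})

test_that("tournament with certain acceptance always returns the best", {
  pop <- score_pop(c(-9, -7, -5, -3, -1))
  set.seed(34)
  for (i in 1:25) {
    sel <- tournament_select(pop, 1L, tournament_size = 5L,
                             accept_chance = 1.0)$selected
    expect_identical(sel$molecule_key, "mol01")
  }
})

test_that("tournament rank frequencies follow the acceptance cascade", {
  # pool size == tournament size: the ranking is fixed, so selection
  # probabilities are p(r) = 0.75 * 0.25^(r-1), with the all-decline mass
  # 0.25^3 falling back to the best
  pop <- score_pop(c(-9, -5, -1))
  probs <- c(0.75 + 0.25^3, 0.25 * 0.75, 0.25^2 * 0.75)
  set.seed(35)
  picks <- vapply(1:50000, function(i) {
    tournament_select(pop, 1L, tournament_size = 3L,
                      accept_chance = 0.75)$selected$molecule_key
  }, character(1))
  counts <- table(factor(picks, levels = pop$molecule_key))
  p <- stats::chisq.test(counts, p = probs)$p.value
  expect_gt(p, 0.001)
  # size-2 path enumeration: P(best) = 0.75 + 0.25^2
  pop2 <- score_pop(c(-9, -1))
  set.seed(36)
  best2 <- mean(vapply(1:20000, function(i) {
    tournament_select(pop2, 1L, tournament_size = 2L,
                      accept_chance = 0.75)$selected$molecule_key == "mol01"
  }, logical(1)))
  ci <- stats::qbinom(c(0.005, 0.995), 20000L, 0.75 + 0.25^2) / 20000
  expect_gte(best2, ci[1])
  expect_lte(best2, ci[2])
  expect_error(tournament_select(pop2, 1L, tournament_size = 5L,
                                 accept_chance = 0.5), "exceeds")
})

test_that("fragment mutation picks the only in-window alternative", {
  dir <- tempfile()
  paths <- generate_fixture_library(dir, n_reactions = 2L,
                                    n_per_position = 2L, seed = 13L)
  lib <- load_library(paths$reactions, paths$reagents)
  rxn <- lib$reactions[[1]]
  g <- ligand_genotype(rxn$reaction_id,
                       vapply(rxn$positions, `[`, character(1), 1L))
  set.seed(37)
  for (i in 1:20) {
    m <- mutate_fragment(g, lib)
    changed <- which(m$synthon_ids != g$synthon_ids)
    expect_length(changed, 1L)
    expect_identical(m$synthon_ids[changed],
                     rxn$positions[[changed]][2])
  }
})

test_that("mutation offspring always stay inside the library", {
  lib <- test_library()
  set.seed(38)
  genos <- sample_random_genotypes(lib, 250L)
  for (g in genos) {
    m1 <- mutate_fragment(g, lib, 0.6, 1)
    m2 <- mutate_fragment(g, lib, 0, 0.25)
    m3 <- mutate_reaction(g, lib)
    expect_silent(ligand_genotype(m1$reaction_id, m1$synthon_ids, lib))
    expect_silent(ligand_genotype(m2$reaction_id, m2$synthon_ids, lib))
    expect_silent(ligand_genotype(m3$reaction_id, m3$synthon_ids, lib))
    # fragment mutation changes exactly one position
    expect_identical(sum(m1$synthon_ids != g$synthon_ids), 1L)
  }
})

test_that("fragment mutation samples proportionally to similarity", {
  lib <- test_library()
  rxn <- lib$reactions[[1]]
  g <- ligand_genotype(rxn$reaction_id,
                       c(rxn$positions[[1]][1], rxn$positions[[2]][1]))
  sims1 <- sv("position_sims")(lib, rxn$reaction_id, 1L)
  cand <- rxn$positions[[1]][-1]
  w <- sims1[rxn$positions[[1]][1], cand]
  set.seed(39)
  draws <- character(0)
  while (length(draws) < 20000) {
    m <- mutate_fragment(g, lib)
    if (m$synthon_ids[1] != g$synthon_ids[1]) { # position 1 was mutated
      draws <- c(draws, m$synthon_ids[1])
    }
  }
  counts <- table(factor(draws, levels = cand))
  p <- stats::chisq.test(counts, p = w / sum(w))$p.value
  expect_gt(p, 0.001)
})

test_that("reaction mutation maps fragments by maximal similarity", {
  dir <- tempfile()
  paths <- generate_fixture_library(dir, n_reactions = 2L,
                                    n_per_position = 12L, seed = 17L)
  lib <- load_library(paths$reactions, paths$reagents)
  rids <- names(lib$reactions)
  g <- ligand_genotype(rids[1], vapply(lib$reactions[[1]]$positions, `[`,
                                       character(1), 3L))
  set.seed(40)
  m <- mutate_reaction(g, lib)
  expect_identical(m$reaction_id, rids[2]) # two-reaction library
  # brute-force argmax oracle over the target position lists
  old_fps <- sv("genotype_fps")(lib, g)
  for (p in 1:2) {
    idx <- lib$reactions[[rids[2]]]$position_index[[p]]
    sims <- vapply(seq_along(idx), function(j) {
      tanimoto(structure(lib$synthon_fps[[idx[j]]], n_bits = 2048L),
               structure(old_fps[[p]], n_bits = 2048L))
    }, numeric(1))
    best <- names(idx)[order(-sims, names(idx))][1]
    expect_identical(m$synthon_ids[p], best)
  }
})

test_that("crossover mixes parents and respects closure", {
  lib <- test_library()
  rxn <- lib$reactions[[1]]
  pa <- ligand_genotype(rxn$reaction_id, c(rxn$positions[[1]][1],
                                           rxn$positions[[2]][1]))
  pb <- ligand_genotype(rxn$reaction_id, c(rxn$positions[[1]][2],
                                           rxn$positions[[2]][2]))
  mixed <- c(
    paste(pa$synthon_ids[1], pb$synthon_ids[2]),
    paste(pb$synthon_ids[1], pa$synthon_ids[2])
  )
  set.seed(41)
  for (i in 1:100) {
    off <- crossover(pa, pb, lib)
    expect_identical(off$reaction_id, rxn$reaction_id)
    expect_true(paste(off$synthon_ids, collapse = " ") %in% mixed)
  }
  # identical parents reproduce themselves
  off <- crossover(pa, pa, lib)
  expect_identical(off$synthon_ids, pa$synthon_ids)
  # cross-reaction crossover: closure plus similarity-mapped fragments
  rxn2 <- lib$reactions[[2]]
  pc <- ligand_genotype(rxn2$reaction_id, c(rxn2$positions[[1]][5],
                                            rxn2$positions[[2]][5]))
  for (i in 1:50) {
    off <- crossover(pa, pc, lib)
    expect_silent(ligand_genotype(off$reaction_id, off$synthon_ids, lib))
    expect_true(off$reaction_id %in% c(rxn$reaction_id, rxn2$reaction_id))
  }
})

test_that("the run accounting follows the protocol arithmetic", {
  lib <- test_library()
  be <- surrogate_backend(seed = 3L)
  run0 <- run_evolution(evolution_config(generations = 0L, seed = 51L),
                        lib, be)
  expect_identical(run0$n_evaluated, 200L)
  run2 <- run_evolution(evolution_config(generations = 2L, seed = 51L),
                        lib, be)
  expect_identical(run2$n_evaluated, 200L + 2L * 240L)
  # identity copies are logged but not evaluated
  ids <- run2$individuals[run2$individuals$factory == "identity", ]
  expect_identical(nrow(ids), 2L * 15L)
  expect_true(all(!ids$evaluated))
  # identity preserves scores bit-exactly
  parents <- run2$individuals[match(ids$parent1, run2$individuals$id), ]
  expect_identical(ids$fitness, parents$fitness)
  expect_identical(ids$raw_energy, parents$raw_energy)
})

test_that("equal seeds reproduce a run exactly", {
  lib <- test_library()
  be <- surrogate_backend(seed = 3L)
  cfg <- evolution_config(generations = 3L, seed = 77L)
  r1 <- run_evolution(cfg, lib, be)
  r2 <- run_evolution(cfg, lib, be)
  expect_identical(r1$individuals, r2$individuals)
  expect_identical(r1$generations, r2$generations)
  r3 <- run_evolution(evolution_config(generations = 3L, seed = 78L), lib, be)
  expect_false(identical(r1$individuals$molecule_key,
                         r3$individuals$molecule_key))
})

test_that("the identity step depletes the pool of its best molecules", {
  lib <- test_library()
  pop <- evaluated_population(lib, 50L, seed = 52L)
  pop$id <- seq_len(nrow(pop))
  sel <- elitist_select(pop, 15L, remove_selected = TRUE)
  best_before <- min(pop$fitness + pop$penalty)
  best_after <- min(sel$remaining$fitness + sel$remaining$penalty)
  expect_gte(best_after, best_before)
  expect_identical(nrow(sel$remaining), 35L)
  # the removed 15 are exactly the 15 best
  expect_lte(max(sel$selected$fitness + sel$selected$penalty), best_after)
})
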