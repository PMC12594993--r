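# Score normalization, similarity penalty, duplicate caching, backends.

test_that("ligand-efficiency normalization matches its closed form", {
  expect_equal(lid_rootn(-25, 25, 2), -5)
  expect_equal(lid_rootn(-30, 30, 1), -1)
  expect_equal(lid_rootn(-8, 16, 4), -4)
  expect_error(lid_rootn(-5, 0, 2), ">= 1")
  expect_error(lid_rootn(-5, 10, 5), "n must be")
  # strictly increasing in raw energy; for negative energies, increasing
  # (toward zero) in size - the anti-size-bias direction
  expect_true(all(diff(lid_rootn(seq(-40, -1, by = 1), 20, 2)) > 0))
  expect_true(all(diff(lid_rootn(-30, 10:60, 2)) > 0))
})

test_that("identical copies are penalized 0, 0.5, 1.0 in score order", {
  fp <- structure(c(3L, 17L, 900L), n_bits = 2048L)
  pen <- apply_similarity_penalty(
    fitness = c(-5, -5, -5),
    fingerprints = list(fp, fp, fp),
    molecule_keys = rep("CCO", 3)
  )
  expect_identical(sort(pen), c(0, 0.5, 1.0))
})

test_that("similarity exactly at the threshold carries no penalty", {
  a <- structure(1:20, n_bits = 2048L)
  b <- structure(1:19, n_bits = 2048L) # tanimoto 19/20 = 0.95 exactly
  expect_equal(tanimoto(a, b), 0.95)
  pen <- apply_similarity_penalty(c(-4, -3), list(a, b), c("a", "b"))
  expect_identical(pen, c(0, 0))
  # strictly above the threshold does
  b2 <- structure(1:20, n_bits = 2048L)
  expect_identical(apply_similarity_penalty(c(-4, -3), list(a, b2),
                                            c("a", "b")), c(0, 0.5))
})

test_that("dissimilar populations receive no penalty", {
  lib <- test_library()
  pop <- evaluated_population(lib, 30L, seed = 8L)
  dup <- duplicated(pop$molecule_key)
  expect_true(all(pop$penalty[!dup & pop$penalty > 0] >= 0)) # sanity
  distinct <- pop[!duplicated(pop$molecule_key), ]
  fps <- sv("population_fps")(lib, distinct)
  sims <- sv("tanimoto_cross")(fps, fps, 2048L)
  if (max(sims[upper.tri(sims)]) <= 0.95) {
    expect_true(all(distinct$penalty == 0))
  }
})

test_that("total penalty mass matches a brute-force pair count", {
  lib <- test_library()
  set.seed(21)
  base <- sample_random_genotypes(lib, 25L)
  genos <- c(base, base[1:8]) # force duplicates
  pop <- make_individuals(genos)
  pop <- evaluate_population(pop, lib, surrogate_backend(seed = 9L))
  fps <- sv("population_fps")(lib, pop)
  # O(N^2) oracle: walk individuals best-first, count stored fingerprints
  # with similarity strictly above 0.95
  ord <- order(pop$fitness, pop$molecule_key)
  expected <- numeric(nrow(pop))
  for (r in seq_along(ord)) {
    i <- ord[r]
    if (r > 1L) {
      expected[i] <- 0.5 * sum(vapply(ord[seq_len(r - 1L)], function(j) {
        tanimoto(structure(fps[[i]], n_bits = 2048L),
                 structure(fps[[j]], n_bits = 2048L)) > 0.95
      }, logical(1)))
    }
  }
  expect_equal(pop$penalty, expected)
  expect_equal(sum(pop$penalty), sum(expected))
})

test_that("the backend runs exactly once per distinct uncached molecule", {
  lib <- toy2_library()
  set.seed(4)
  base <- sample_random_genotypes(lib, 6L)
  keys6 <- unique(vapply(lapply(base, assemble_product, library = lib),
                         `[[`, character(1), "canonical_smiles"))
  # make sure the 6 draws really are 6 distinct molecules
  expect_length(keys6, 6L)
  genos <- c(base, base[c(1, 2, 3, 1)]) # 10 individuals, 6 molecules
  cache <- new_score_cache()
  counting <- surrogate_backend(seed = 2L)
  pop <- evaluate_population(make_individuals(genos), lib, counting, cache)
  expect_identical(cache$backend_calls, 6L)
  # same population again: all cached
  pop2 <- evaluate_population(make_individuals(genos), lib, counting, cache)
  expect_identical(cache$backend_calls, 6L)
  expect_identical(pop2$raw_energy, pop$raw_energy)
  # identical copies share the raw score and cascade penalties
  copies <- which(pop$molecule_key == pop$molecule_key[1])
  expect_true(length(copies) >= 2L)
  expect_identical(length(unique(pop$raw_energy[copies])), 1L)
  expect_identical(sort(pop$penalty[copies])[1:2], c(0, 0.5))
})

test_that("the surrogate backend is deterministic and finite", {
  lib <- toy2_library()
  be1 <- surrogate_backend(seed = 7L)
  be2 <- surrogate_backend(seed = 7L)
  genos <- unlist(lapply(lib$reactions, enumerate_genotypes),
                  recursive = FALSE)
  prods <- sv("assemble_products")(lib, genos)
  ok <- !vapply(prods, inherits, logical(1), "assembly_error")
  expect_true(all(ok))
  v1 <- be1$evaluate(prods)
  v2 <- be2$evaluate(prods)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  # a different landscape seed gives different scores
  expect_false(identical(be1$evaluate(prods[1:5]),
                         surrogate_backend(seed = 8L)$evaluate(prods[1:5])))
})

test_that("the enumerated toy space has a unique surrogate minimum", {
  lib <- test_library() # 4 x 20 x 20
  be <- surrogate_backend(seed = 42L)
  genos <- unlist(lapply(lib$reactions, enumerate_genotypes),
                  recursive = FALSE)
  prods <- sv("assemble_products")(lib, genos)
  keys <- vapply(prods, `[[`, character(1), "canonical_smiles")
  uk <- !duplicated(keys)
  raw <- be$evaluate(prods[uk])
  expect_identical(sum(raw == min(raw)), 1L)
})

test_that("the lookup backend serves stored scores and rejects unknowns", {
  tab <- data.frame(canonical_smiles = c("CCO", "CCN"),
                    raw_energy = c(-12.5, -8.25))
  be <- lookup_backend(tab)
  mkmol <- function(s) structure(list(canonical_smiles = s, heavy_atoms = 3L,
                                      fingerprint = integer(0)),
                                 class = "product_molecule")
  expect_identical(be$evaluate(list(mkmol("CCO"), mkmol("CCN"))),
                   c(-12.5, -8.25))
  expect_error(be$evaluate(list(mkmol("CCC"))), "no score for molecule")
  # table round-trips bit-identically through the CSV dialect
  path <- tempfile(fileext = ".csv")
  write_score_table(tab, path)
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(rt$canonical_smiles, tab$canonical_smiles)
  expect_identical(rt$raw_energy, tab$raw_energy)
})

test_that("assembly failures get the worst-score sentinel and the run continues", {
  lib <- toy2_library()
  set.seed(6)
  pop <- make_individuals(sample_random_genotypes(lib, 5L))
  # an in-library genotype whose synthons cannot react: amine x amine would
  # not load, so force a failing backend instead for one molecule
  failing <- structure(list(
    id = "failing",
    evaluate = function(mols) {
      vapply(mols, function(m) {
        if (m$heavy_atoms %% 2 == 0) stop("boom") else -10
      }, numeric(1))
    }
  ), class = "fitness_backend")
  expect_warning(
    out <- evaluate_population(pop, lib, failing),
    "sentinel"
  )
  bad <- is.na(out$raw_energy)
  expect_true(any(bad))
  expect_true(all(out$fitness[bad] > max(out$fitness[!bad])))
})
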