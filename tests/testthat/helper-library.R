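# Shared fixture libraries, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

# the standard toy space: 4 two-component reactions x 20 synthons/position
test_library <- function() {
  if (is.null(.fixture_env$lib)) {
    dir <- tempfile("fixlib")
    paths <- generate_fixture_library(dir, n_reactions = 4L,
                                      n_per_position = 20L, seed = 7L)
    .fixture_env$lib <- load_library(paths$reactions, paths$reagents)
    .fixture_env$paths <- paths
  }
  .fixture_env$lib
}

test_library_paths <- function() {
  test_library()
  .fixture_env$paths
}

# a small 2-reaction x 10-synthon library ("toy2")
toy2_library <- function() {
  if (is.null(.fixture_env$toy2)) {
    dir <- tempfile("toy2")
    paths <- generate_fixture_library(dir, n_reactions = 2L,
                                      n_per_position = 10L, seed = 11L)
    .fixture_env$toy2 <- load_library(paths$reactions, paths$reagents)
  }
  .fixture_env$toy2
}

# evaluated population of n random genotypes under the surrogate
evaluated_population <- function(library, n, seed = 1L, backend_seed = 5L) {
  set.seed(seed)
  pop <- make_individuals(sample_random_genotypes(library, n))
  evaluate_population(pop, library, surrogate_backend(seed = backend_seed))
}

# internal helpers reached through the namespace (tests run against the
# installed package)
sv <- function(name) get(name, envir = asNamespace("synthevolve"))

# the 4 x 20 x 20 pre-docked benchmark under a fixed surrogate landscape,
# built once (enumeration + scoring of 1600 products)
shared_benchmark <- function() {
  if (is.null(.fixture_env$bench)) {
    set.seed(4242)
    .fixture_env$bench <- build_predocked_benchmark(
      test_library(), surrogate_backend(seed = 42L),
      n_reactions = 4L, n_fragments = 20L, hit_quantile = 0.001
    )
  }
  .fixture_env$bench
}
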