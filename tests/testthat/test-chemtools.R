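# Chemistry primitives: SMILES round trips, SMARTS matching, reaction
# application, fingerprints, similarity, heavy atoms, scaffolds.

test_that("SMILES parse/write round-trips preserve the molecule", {
  cases <- c(
    "CC(=O)O", "NCCc1ccccc1", "O=S(=O)(Cl)c1ccc(C)cc1",
    "c1ccc2[nH]ccc2c1", "C1CCCCC1", "[O-]C(=O)C[N+](C)(C)C",
    "Cc1ccc(-c2ccccc2)cc1", "BrCCOc1ccc(F)cc1", "c1ccncc1",
    "CC(C)(C)OC(=O)N1CCNCC1"
  )
  for (s in cases) {
    mol <- parse_smiles(s)
    rewritten <- mol_to_smiles(mol)
    expect_identical(canonical_smiles(rewritten), canonical_smiles(s),
                     info = s)
  }
})

test_that("implicit hydrogen counts follow standard valences", {
  expect_identical(parse_smiles("CCO")$hcount, c(3L, 2L, 1L))
  expect_identical(parse_smiles("O")$hcount, 2L)
  # sulfonyl sulfur uses the expanded valence, no implicit H
  expect_identical(parse_smiles("CS(=O)(=O)C")$hcount[2], 0L)
  # aromatic ring carbons carry one H at two ring neighbours
  expect_identical(parse_smiles("c1ccccc1")$hcount, rep(1L, 6))
  # pyridine-type nitrogen carries none; pyrrole must be bracketed
  expect_identical(parse_smiles("c1ccncc1")$hcount[4], 0L)
  expect_identical(parse_smiles("c1cc[nH]c1")$hcount[4], 1L)
  expect_identical(parse_smiles("[O-]C")$hcount[1], 0L)
})

test_that("malformed SMILES are rejected", {
  expect_error(parse_smiles("CC(=O"), "unbalanced")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C$C"), "unexpected character")
})

test_that("SMARTS templates match reaction handles and only those", {
  acid_t <- "[CX3:1](=[O:2])[OX2H1]"
  amine_t <- "[NX3;!H0:3]"
  acid <- parse_smiles("CC(=O)O")
  amine <- parse_smiles("NCCc1ccccc1")
  expect_length(smarts_matches(acid, acid_t), 1L)
  expect_length(smarts_matches(amine, amine_t), 1L)
  # cross matches must fail
  expect_length(smarts_matches(acid, amine_t), 0L)
  expect_length(smarts_matches(amine, acid_t), 0L)
  # tertiary amine has no N-H
  expect_length(smarts_matches(parse_smiles("CN(C)C"), amine_t), 0L)
  # predicates: aromaticity, ring membership, H count, OR lists
  tol <- parse_smiles("Cc1ccccc1")
  expect_length(smarts_matches(tol, "c"), 6L)
  expect_length(smarts_matches(tol, "[CH3]"), 1L)
  expect_length(smarts_matches(tol, "[c;R]"), 6L)
  expect_length(smarts_matches(tol, "[C;!R]"), 1L)
  expect_length(smarts_matches(parse_smiles("FCCl"), "[F,Cl,Br]"), 2L)
})

test_that("unsupported SMARTS constructs raise clear errors", {
  expect_error(parse_smarts("[$(NC=O)]"), "recursive")
  expect_error(parse_smarts("c1ccccc1"), "ring-closure")
})

test_that("reaction application reproduces independently computed products", {
  # expected canonical SMILES frozen from an independent cheminformatics
  # run of the same reaction SMARTS on the same reagents
  cases <- list(
    list(smarts = "[CX3:1](=[O:2])[OX2H1].[NX3;!H0:3]>>[C:1](=[O:2])[N:3]",
         reagents = c("CC(=O)O", "NCCc1ccccc1"),
         expected = "CC(=O)NCCc1ccccc1"),
    list(smarts = "[SX4:1](=[O:2])(=[O:3])[Cl].[NX3;!H0:4]>>[S:1](=[O:2])(=[O:3])[N:4]",
         reagents = c("O=S(=O)(Cl)c1ccc(C)cc1", "NCCOC"),
         expected = "COCCNS(=O)(=O)c1ccc(C)cc1"),
    list(smarts = "[CX3:1](=[O:2])[OX2H1].[OX2H1:3]>>[C:1](=[O:2])[O:3]",
         reagents = c("OC(=O)c1ccccc1", "OCCC"),
         expected = "CCCOC(=O)c1ccccc1"),
    list(smarts = "[CX4:1][Br].[OX2H1:2]>>[C:1][O:2]",
         reagents = c("BrCCc1ccccc1", "OCC(C)C"),
         expected = "CC(C)COCCc1ccccc1")
  )
  for (cs in cases) {
    rxn <- parse_reaction_smarts(cs$smarts)
    prods <- apply_reaction(rxn, lapply(cs$reagents, parse_smiles))
    got <- unique(canonical_smiles(vapply(prods, mol_to_smiles, character(1))))
    expect_identical(got, canonical_smiles(cs$expected),
                     info = cs$smarts)
  }
})

test_that("assembly is deterministic and failures are signalled, not crashes", {
  lib <- toy2_library()
  set.seed(3)
  g <- sample_random_genotype(lib)
  p1 <- assemble_product(g, lib)
  p2 <- assemble_product(g, lib)
  expect_identical(p1$canonical_smiles, p2$canonical_smiles)
  # non-reacting partners: two amines under the amide coupling
  rxn <- parse_reaction_smarts(
    "[CX3:1](=[O:2])[OX2H1].[NX3;!H0:3]>>[C:1](=[O:2])[N:3]"
  )
  expect_error(
    apply_reaction(rxn, list(parse_smiles("NCC"), parse_smiles("NCCC"))),
    class = "assembly_error"
  )
})

test_that("a 2x2 toy reaction yields 4 distinct products", {
  dir <- tempfile()
  paths <- generate_fixture_library(dir, n_reactions = 2L,
                                    n_per_position = 2L, seed = 3L)
  lib <- load_library(paths$reactions, paths$reagents)
  rxn <- lib$reactions[[1]]
  genos <- enumerate_genotypes(rxn)
  expect_length(genos, 4L)
  prods <- vapply(genos, function(g) {
    assemble_product(g, lib)$canonical_smiles
  }, character(1))
  expect_length(unique(prods), 4L)
})

test_that("tanimoto similarity obeys its definition and conventions", {
  fp <- function(bits) structure(bits, n_bits = 2048L)
  expect_equal(tanimoto(fp(c(1L, 5L, 9L)), fp(c(1L, 5L, 9L))), 1.0)
  expect_equal(tanimoto(fp(1:3), fp(4:6)), 0.0)
  expect_equal(tanimoto(fp(1:3), fp(2:4)), 0.5)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 1.0)
  expect_error(tanimoto(fp(1:3), structure(1:3, n_bits = 1024L)), "differ")
  # symmetry over random pairs
  set.seed(42)
  for (i in 1:20) {
    a <- fp(sort(sample.int(2048L, 40)))
    b <- fp(sort(sample.int(2048L, 40)))
    expect_identical(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("fingerprints are invariant to atom ordering", {
  pairs <- list(
    c("CC(=O)NCCc1ccccc1", "c1ccccc1CCNC(C)=O"),
    c("COc1ccc(CCN)cc1", "NCCc1ccc(OC)cc1")
  )
  for (p in pairs) {
    expect_identical(ecfp_bits(p[1]), ecfp_bits(p[2]))
  }
  # and to canonical re-parse
  s <- "O=S(=O)(NCC)c1ccc(C)cc1"
  expect_identical(ecfp_bits(s), ecfp_bits(canonical_smiles(s)))
})

test_that("heavy atom counts exclude hydrogens", {
  expect_identical(heavy_atom_count("c1ccccc1"), 6L)
  expect_identical(heavy_atom_count("O"), 1L)
  expect_identical(heavy_atom_count("CCO"), 3L)
  expect_identical(heavy_atom_count("[NH4+]"), 1L)
})

test_that("Bemis-Murcko scaffolds keep rings and linkers only", {
  benzene <- canonical_smiles("c1ccccc1")
  expect_identical(murcko_scaffold("Cc1ccccc1"), benzene)
  expect_identical(murcko_scaffold("CCCCCC"), "")
  # independently computed scaffold: methyl-biphenyl -> biphenyl
  expect_identical(murcko_scaffold("Cc1ccc(-c2ccccc2)cc1"),
                   canonical_smiles("c1ccc(-c2ccccc2)cc1"))
  # exocyclic double bond on a linker is retained
  expect_identical(murcko_scaffold("O=C(c1ccccc1)c1ccccc1"),
                   canonical_smiles("O=C(c1ccccc1)c1ccccc1"))
  # but a plain side chain is not
  expect_identical(murcko_scaffold("CC(=O)c1ccccc1"), benzene)
})
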