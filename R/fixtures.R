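# Synthetic toy libraries.
#
# Emits reaction/reagent files for up to four robust two-component
# couplings (amide, sulfonamide, ester, Williamson ether), with reagent
# SMILES decorated procedurally from a safe substituent alphabet: bodies
# never contain a second reaction handle (no free OH/NH/COOH/halide outside
# the handle), so every written reagent matches its reactant template and
# loads with zero drops.

FIXTURE_REACTIONS <- list(
  amide = list(
    smarts = "[CX3:1](=[O:2])[OX2H1].[NX3;!H0:3]>>[C:1](=[O:2])[N:3]",
    handles = c("OC(=O)", "N")
  ),
  sulfonamide = list(
    smarts = "[SX4:1](=[O:2])(=[O:3])[Cl].[NX3;!H0:4]>>[S:1](=[O:2])(=[O:3])[N:4]",
    handles = c("ClS(=O)(=O)", "N")
  ),
  ester = list(
    smarts = "[CX3:1](=[O:2])[OX2H1].[OX2H1:3]>>[C:1](=[O:2])[O:3]",
    handles = c("OC(=O)", "OC")
  ),
  ether = list(
    smarts = "[CX4:1][Br].[OX2H1:2]>>[C:1][O:2]",
    handles = c("BrC", "OC")
  )
)

# deterministic universe of body strings (appended after a handle prefix)
fixture_bodies <- function() {
  chains <- c("C", "CC", "CCC", "CC(C)", "CCCC", "CC(C)C", "CCOC",
              "CC(C)(C)", "CCCOC", "CCN(C)C", "CCCC(C)", "CCOCC")
  ring_term <- c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1",
                 "c1ccc(OC)cc1", "C1CCCCC1", "c1ccc(C(F)(F)F)cc1",
                 "c1cccc(F)c1")
  ring_link_open <- c("c1ccc(", "c1cc(F)cc(", "C1CCC(", "c1ccc(OC)c(")
  ring_link_close <- c(")cc1", ")c1", ")CC1", ")c1")
  bodies <- chains
  for (ch in chains) for (rt in ring_term) {
    bodies <- c(bodies, paste0(ch, rt))
  }
  for (ch in chains) for (rl in seq_along(ring_link_open)) for (c2 in chains) {
    bodies <- c(bodies,
                paste0(ch, ring_link_open[rl], c2, ring_link_close[rl]))
  }
  unique(bodies)
}

# run code with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy combinatorial library on disk
#'
#' Writes `reactions.tsv` and `reagents.tsv` in the documented tabular
#' dialect. Deterministic for a given seed (byte-identical files).
#'
#' @param dir Output directory (created if missing).
#' @param n_reactions Number of reactions, 2--4.
#' @param n_per_position Reagents per position (each position gets an
#'   independent random subset of the body universe).
#' @param seed Integer seed controlling reagent selection.
#' @return Invisible list with `reactions` and `reagents` file paths.
#' @export
generate_fixture_library <- function(dir, n_reactions = 4L,
                                     n_per_position = 20L, seed = 7L) {
  stopifnot(n_reactions >= 2L, n_reactions <= length(FIXTURE_REACTIONS),
            n_per_position >= 1L)
  bodies <- fixture_bodies()
  if (n_per_position > length(bodies)) {
    stop("at most ", length(bodies), " reagents per position are available",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rxn_names <- names(FIXTURE_REACTIONS)[seq_len(n_reactions)]

  rx_rows <- list()
  rg_rows <- list()
  with_local_seed(seed, {
    for (rn in rxn_names) {
      def <- FIXTURE_REACTIONS[[rn]]
      rx_rows[[rn]] <- data.frame(
        reaction_id = rn, smarts = def$smarts, n_positions = 2L,
        stringsAsFactors = FALSE
      )
      for (p in 1:2) {
        pick <- sort(sample.int(length(bodies), n_per_position))
        rg_rows[[paste(rn, p)]] <- data.frame(
          smiles = paste0(def$handles[p], bodies[pick]),
          synthon_id = sprintf("%s_p%d_%03d", rn, p - 1L,
                               seq_len(n_per_position)),
          reaction_id = rn,
          position = p - 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  reactions_path <- file.path(dir, "reactions.tsv")
  reagents_path <- file.path(dir, "reagents.tsv")
  utils::write.table(do.call(rbind, rx_rows), reactions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, rg_rows), reagents_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(reactions = reactions_path, reagents = reagents_path))
}
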