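# Extended-connectivity (circular) fingerprints.
#
# Classic ECFP construction: every atom starts from a hashed invariant of
# (atomic number, heavy degree, H count, charge, aromaticity); each
# iteration rehashes the atom identifier together with the sorted
# (bond order, neighbour identifier) pairs, out to the configured radius.
# All identifiers from all iterations are folded modulo the bit length.
# Identifiers are 32-bit FNV-1a hashes computed in exact double arithmetic,
# so fingerprints are reproducible across platforms.

FNV_OFFSET <- 2166136261
FNV_PRIME <- 16777619
TWO32 <- 2^32

# (a * b) mod 2^32 without losing precision (a, b < 2^32)
mul32 <- function(a, b) {
  alo <- a %% 65536
  ahi <- (a - alo) / 65536
  (((ahi * b) %% 65536) * 65536 + alo * b) %% TWO32
}

xor32 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(as.integer(ahi), as.integer(bhi)) * 65536 +
    bitwXor(as.integer(alo), as.integer(blo))
}

# murmur3-style finalizer: full avalanche so short inputs still spread
# over all 32 bits
fmix32 <- function(h) {
  h <- xor32(h, floor(h / 65536))
  h <- mul32(h, 2246822507) # 0x85ebca6b
  h <- xor32(h, floor(h / 8192))
  h <- mul32(h, 3266489909) # 0xc2b2ae35
  xor32(h, floor(h / 65536))
}

# FNV-1a over a vector of non-negative integers (< 2^32), finalized
hash32 <- function(ints) {
  h <- FNV_OFFSET
  for (x in ints) {
    h <- xor32(h, x %% TWO32)
    h <- mul32(h, FNV_PRIME)
  }
  fmix32(h)
}

# deterministic uniform in [0, 1) from integers
hash01 <- function(ints) hash32(ints) / TWO32

#' Fingerprint configuration
#'
#' @param radius Neighbourhood radius of the circular fingerprint.
#' @param n_bits Folded bit length.
#' @return A `fingerprint_config` list.
#' @export
fingerprint_config <- function(radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0L, n_bits >= 8L)
  structure(list(kind = "ecfp", radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "fingerprint_config")
}

#' Circular fingerprint of a molecule
#'
#' @param mol A `sev_mol` graph or SMILES string.
#' @param config A [fingerprint_config()].
#' @return Sorted integer vector of on-bit positions (1-based, in
#'   `1..n_bits`) with attribute `n_bits`.
#' @export
ecfp_bits <- function(mol, config = fingerprint_config()) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  n <- n_atoms(mol)
  adj <- vector("list", n)
  aord <- vector("list", n)
  for (i in seq_along(mol$bond_a)) {
    a <- mol$bond_a[i]; b <- mol$bond_b[i]
    o <- as.integer(mol$bond_order[i] * 2) # 2,3,4,6: integer bond code
    adj[[a]] <- c(adj[[a]], b); aord[[a]] <- c(aord[[a]], o)
    adj[[b]] <- c(adj[[b]], a); aord[[b]] <- c(aord[[b]], o)
  }
  deg <- heavy_degree(mol)
  ids <- vapply(seq_len(n), function(i) {
    hash32(c(
      unname(ELEMENT_NUMBERS[mol$elem[i]]), deg[i], mol$hcount[i],
      mol$charge[i] + 16L, as.integer(mol$arom[i])
    ))
  }, numeric(1))
  all_ids <- ids
  if (config$radius > 0L) {
    for (r in seq_len(config$radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        if (deg[i] == 0L) return(hash32(c(r, ids[i])))
        nb <- order(aord[[i]] * TWO32 + ids[adj[[i]]])
        pairs <- as.numeric(rbind(aord[[i]][nb], ids[adj[[i]][nb]]))
        hash32(c(r, ids[i], pairs))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- sort(unique(as.integer(all_ids %% config$n_bits) + 1L))
  attr(bits, "n_bits") <- config$n_bits
  bits
}

#' Tanimoto similarity of two fingerprints
#'
#' Defined as the ratio of intersection to union of on-bits; by convention
#' two all-zero fingerprints have similarity 1.
#'
#' @param fp_a,fp_b On-bit integer vectors (as from [ecfp_bits()]) with
#'   matching `n_bits`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  na <- attr(fp_a, "n_bits"); nb <- attr(fp_b, "n_bits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("fingerprint bit lengths differ (", na, " vs ", nb, ")",
         call. = FALSE)
  }
  u <- length(union(fp_a, fp_b))
  if (u == 0L) return(1.0)
  length(intersect(fp_a, fp_b)) / u
}

# dense 0/1 matrix (rows = fingerprints) from a list of on-bit vectors;
# used for vectorized pairwise Tanimoto via tcrossprod
fp_matrix <- function(fps, n_bits) {
  m <- matrix(0, nrow = length(fps), ncol = n_bits)
  for (i in seq_along(fps)) m[i, fps[[i]]] <- 1
  m
}

# pairwise Tanimoto between rows of two on-bit lists
tanimoto_cross <- function(fps_a, fps_b, n_bits) {
  ma <- fp_matrix(fps_a, n_bits)
  mb <- fp_matrix(fps_b, n_bits)
  inter <- tcrossprod(ma, mb)
  ca <- rowSums(ma); cb <- rowSums(mb)
  un <- outer(ca, cb, "+") - inter
  s <- inter / un
  s[un == 0] <- 1.0
  s
}
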