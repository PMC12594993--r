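---
title: "Evolutionary screening of make-on-demand libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary screening of make-on-demand libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthevolve)
```

## The problem

Make-on-demand compound collections (Enamine REAL and its peers) are not
enumerated databases: they are defined implicitly by a few hundred reactions
and per-reaction reagent lists, and their product spaces run into the
billions. Screening them exhaustively with a flexible docking protocol is
computationally out of reach. `synthevolve` searches such a space with an
evolutionary algorithm whose genotype is the *recipe* of a molecule — a
reaction identifier plus one synthon identifier per reactant position —
rather than a free-form structure. Because every operator (mutation,
crossover, random sampling) only ever exchanges entries of the library's own
reagent lists, every candidate the search visits is synthesizable by
construction. That closure property is the core claim the test suite
verifies most aggressively.

## The model

**Genotype and library.** A `combinatorial_library` holds reactions (reaction
SMARTS with $k \ge 2$ reactant templates) and per-position synthon lists.
Every synthon SMILES is parsed once at load, validated against the reactant
template of its position, and fingerprinted. A `ligand_genotype` is
`(reaction_id, synthon_ids)`; the product molecule is obtained by applying
the reaction SMARTS to the synthons and canonicalizing the result.

**Fitness.** A pluggable backend maps an assembled product to a raw
interface-energy-like score, lower is better. Raw energies are normalized by
molecular size before selection:

$$\mathrm{fitness}_n(x) = \frac{\mathrm{energy}(x)}{\sqrt[n]{\mathrm{heavyatoms}(x)}}$$

with $n = 2$ by default (the geometric mean of the raw score and classic
ligand efficiency, `lid_rootn()`). Without this, docking-style scores drift
toward ever-larger molecules; $n = 1$ over-corrects toward tiny ones.

**Duplicate handling.** Identical genotypes and identical molecules recur
constantly in an evolutionary run. A score cache guarantees the backend is
invoked exactly once per distinct canonical SMILES across the whole run. To
keep one good molecule from taking over a population, a similarity penalty
is applied within each evaluated population: molecules are processed
best-first, each is compared against all already-stored fingerprints, and
every stored fingerprint with Tanimoto similarity strictly above 0.95 adds
+0.5 to the molecule's selection score. Three identical copies therefore
score +0, +0.5, +1.0 — a few copies of a strong molecule stay competitive,
many do not.

**Selection.** Three selectors operate on the penalized score:

* *elitist* — the deterministic top *k*, ties broken by canonical SMILES;
* *tournament* — draw `tournament_size` contestants uniformly, walk the
  sorted ranking accepting each with probability `accept_chance`; if all
  decline, the tournament's best is taken (the fallback is our choice — the
  alternative, redrawing the tournament, changes no ranking probabilities
  materially but can loop);
* *roulette* — weighted sampling without replacement with weights linear in
  score. Raw score *ratios* are meaningless for negative docking scores (a
  molecule at −4 is not "twice as good" as one at −2 in any scale-free
  sense), so weights are distances from an anchor — by default the pool's
  worst score — plus a floor of 1% of the score range so the worst
  individual keeps a nonzero chance. Relative to an explicit anchor this
  preserves the intended property that a molecule twice as far below the
  anchor is selected twice as often. This deviates from a naive reading of
  fitness-proportional selection and is deliberate.

**Reproduction.**

* *Fragment mutation* replaces the synthon at one uniformly chosen position
  with another synthon from the same list, sampled with Tanimoto similarity
  to the current synthon as the weight, inside a `[min, max]` similarity
  window. An empty window is widened (upper bound dropped first, then the
  lower); a position with a single synthon is a logged no-op. Widening
  rather than erroring keeps the protocol total on small or homogeneous
  reagent lists.
* *Reaction mutation* switches to a different reaction (uniform) and fills
  each new position with the synthon most similar to the old fragment at
  the same index; positions beyond the old arity match against all old
  fragments. Index pairing is our choice — reagent files carry no semantic
  position labels, and index alignment is the only stable convention.
* *Crossover* lets one parent (uniform) donate the reaction; positions are
  partitioned randomly with each parent contributing at least one fragment.
  Fragments from a parent on a different reaction are similarity-mapped
  into the donor's lists exactly as in reaction mutation.

**The generation loop.** Generation 0 draws `initial_population` (default
200) random genotypes — reaction weighted by its product count, synthons
uniform — evaluates them, and reduces to `survivors` (default 50) with the
main selector (tournament, size 15, acceptance 0.75). Each of the
`generations` (default 30) cycles applies seven steps: moderate mutation
(roulette 15 → 30 offspring, fragment:reaction 2:1, minimum similarity 0.6),
crossover (roulette 15 → 60), drastic fragment-only mutation (maximum
similarity 0.25, 30), reaction-only mutation (30), an elitist identity step
(15 copied unchanged and removed from the pool), then the mutation and
crossover steps once more against the depleted pool (30 + 60). The 240
non-identity offspring are evaluated, merged with the 15 identity copies,
penalties are recomputed over the merged population (penalties are
contextual, raw scores and fitness are carried over bit-exactly), and the
main selector reduces to 50. The arithmetic is fixed by the defaults:
$200 + 30 \times 240 = 7400$ evaluated individuals per run, regardless of
library size. Two readings of "reduce the new population" are possible; we
apply the main selector to identity copies plus offspring only, so elites
persist across generations exclusively through the identity step, which is
what gives that step its purpose.

In the mutation steps each selected parent is used the same number of times
(15 parents → 30 offspring means exactly twice each); crossover draws a
fresh random pair per offspring. Selection inside every step uses the
penalty-adjusted score — the penalty exists precisely to damp takeover
during selection, so exempting any step from it would defeat it.

## Chemistry engine

No installed R package applies reaction SMARTS to reagents, so the package
carries a compact engine of its own: a SMILES reader/writer over a minimal
molecular graph, a SMARTS matcher, and a reaction applicator with the usual
transform semantics (mapped atoms persist with their untouched substituents,
matched-but-unmapped atoms leave as leaving groups, product-side bonds are
formed or retyped, hydrogen counts adjust with the heavy-bond order change).
Canonicalization is delegated to OpenBabel via ChemmineOB, which is also the
cross-check used in the tests: every product the engine builds is verified
against canonical SMILES frozen from an independent cheminformatics run of
the same reaction SMARTS.

The supported SMARTS subset is deliberate: tree-shaped patterns (no
ring-closure digits, no recursive SMARTS), element/aromaticity primitives,
`H`/`X`/`D` counts, ring membership `R`, charges, negation, and `,`/`;`/`&`
logic. Reactant templates in synthon libraries describe the local
environment of a reaction handle — an acid, an amine, a sulfonyl chloride —
and that is exactly what the subset covers. Multi-match templates (e.g. the
two symmetric sulfonyl oxygens) produce several product candidates; the
lexicographically smallest canonical SMILES is kept, making assembly
deterministic. Product templates must be fully atom-mapped; atom additions
on the product side are not supported.

Fingerprints are extended-connectivity (circular) fingerprints computed
in-package: radius 2, folded to 2048 bits, atom invariants from element,
degree, hydrogen count, charge and aromaticity, identifiers hashed with a
32-bit FNV-1a/murmur-finalized hash implemented in exact double arithmetic
so fingerprints are platform-stable. Fingerprints are invariant to atom
order (and therefore to canonical re-parse), but not to aromatic-form
changes: a Kekulé-written input is perceived as non-aromatic by design, so
callers should fingerprint canonical (aromatic-form) SMILES, which is what
every internal path does.

## The synthetic library and the surrogate landscape

Real synthon files are distributed under NDA, so the package generates toy
libraries emulating their structure: up to four robust two-component
couplings (amide, sulfonamide, ester, Williamson ether) whose reagents are a
reaction handle plus a procedurally composed body from a safe substituent
alphabet (alkyl chains, (hetero-free) aryl rings, halogen and ether
decorations — never a second reaction handle). Every generated reagent
matches its template, so fixture libraries load with zero drops, and files
are byte-identical for a given seed. The default study space is 4 reactions
× 20 synthons per position (1600 products) — large enough that a 7400-
evaluation run cannot trivially enumerate it genotype-by-genotype, small
enough to enumerate for ground truth in tests.

The surrogate fitness backend stands in for docking: each fingerprint bit
carries a fixed pseudo-random weight in $[-1, 1]$ derived from the bit index
and a landscape seed, and a molecule's energy is the weighted sum over its
on-bits plus a mild size term, scaled into a docking-like range (roughly −45
to 0). Because similar molecules share substructure bits, the landscape is
correlated and approximately additive over synthons — navigable by local
moves, which is the property an evolutionary search needs and which real
affinity landscapes are assumed to have. What the surrogate does *not*
emulate: score noise between docking replicates, activity cliffs sharper
than fingerprint overlap, protonation/stereochemistry effects, or any
protein-specific structure. A passing benchmark therefore demonstrates that
the optimizer exploits a correlated landscape restricted to the library —
not that it would reproduce any particular docking campaign.

## Benchmark and evaluation

The pre-docked benchmark reduces a library with two greedy diversity
selectors (seeded random start, then repeatedly the candidate with the
lowest mean Tanimoto similarity to the current selection — first per
position, then across reactions), enumerates every product of the reduced
space, scores it, and labels the best 0.1% as virtual hits (round half up;
at the reference size of 4 reactions × 500 × 500 that is exactly 1000 of
one million). The hit threshold is set to the score just above the last
hit, so the strict-less-than hit rate

$$\mathrm{HitRate}(x) = \frac{|\{m : \mathrm{score}(m) < x\}|}{|M|}$$

recovers exactly the hit set; with ties at the boundary the strict
comparison is authoritative and the hit count may deviate from the nominal
quantile. Enrichment is the ratio of the method's hit rate to that of a
product-count-weighted random sample of equal size (duplicates allowed,
mirroring the sampler's independent-draw definition). A zero-hit baseline
with a scoring method is reported as an explicit non-finite flag, never
clamped.

At desk scale the acceptance suite runs the full default protocol twenty
times against twenty surrogate landscapes on the 1600-product space and
requires enrichment above 1 at the top-0.1% threshold in every repeat, and
the optimizer's best score to match an equal-budget random sample's best in
at least 18 of 20 — on a space this small an equal random budget almost
surely contains the global optimum, so this asserts the optimizer finds it
too, which it did in 20 of 20 during development.

## Numerical choices and degenerate inputs

* Ties are broken lexicographically by canonical SMILES (selection order,
  hit sets, argmax similarity mapping), making every code path replayable
  from the seed.
* A single global seeded RNG stream is consumed in protocol order; the same
  seed reproduces a run's individuals table exactly.
* Similarity exactly at the 0.95 penalty threshold carries no penalty
  (strict inequality, read literally).
* Two all-zero fingerprints have Tanimoto similarity 1 by convention.
* Assembly or backend failures score at a sentinel 10 units above the worst
  fitness observed so far, with a warning; the run continues. The sentinel
  keeps failures strictly dominated without distorting roulette weights the
  way an infinite score would.
* Empty mutation windows widen rather than error; single-reaction libraries
  make reaction mutation a warning no-op.
* Per-position synthon similarity matrices are computed lazily and cached
  on the library, since mutation touches them constantly.

## Problem sizes used by the tests

The test and acceptance workloads were sized for a laptop-class single
core: the 4 × 20 × 20 fixture space (1600 products) for end-to-end runs and
benchmark construction, 2 × 10 × 10 for unit tests, full 7400-individual
accounting runs, selector frequency checks at 20,000–50,000 draws, and the
million-product benchmark checked at its true size through position-list
arithmetic and a synthetic score vector (assembling a million products is
deliberately out of scope for the default suite).

## Known limitations

* The SMARTS subset excludes ring-closure and recursive patterns; templates
  needing them must be rewritten or pre-filtered upstream.
* Aromatic perception is taken from the input SMILES (lowercase notation),
  not re-derived; Kekulé-written aromatic inputs are treated as drawn.
* Stereochemistry and protonation states are ignored throughout, matching
  the scoring model's stated behaviour.
* The multi-node distribution of docking is out of scope; evaluation is
  serial with the same semantics a process pool would provide, and the
  backend contract (one call per distinct molecule) is the parallelism
  seam.
* Enrichment values on the toy space are not comparable to campaign-scale
  numbers; they demonstrate the mechanism, not the magnitude.
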