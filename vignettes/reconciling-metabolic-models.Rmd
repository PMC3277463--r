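---
title: "Reconciling, balancing and comparing metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling, balancing and comparing metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metreconcile)
```

This vignette is the package's account of its methods: what is assumed,
what is tunable and why, what the synthetic corpus generator does and does
not emulate, and where the design was genuinely open.

## Identity is structural, with names as evidence

The package's central assumption is that cross-source metabolite identity
can only be *asserted* on structure and only *suggested* on names. Every
entry with a SMILES descriptor gets two canonical keys from the chemistry
backend (ChemmineOB/OpenBabel): a stereo-level key (isomeric SMILES) and a
connectivity-level key with stereo marks stripped. Connectivity is the
default join level because many published models omit stereo-specificity;
stereo keys then sub-partition each connectivity group rather than blocking
the merge. Canonical SMILES are toolkit-specific, so keys carry a
backend+version tag and comparisons across tags are an error, never a
silent mismatch.

Name evidence enters at three strengths:

* **Exact normalized equality** assigns. Normalization case-folds, spells
  out Greek letters, rewrites every `<stem>ic acid` to `<stem>ate` (before
  stopword removal, so "acid" never survives as a token), removes stereo
  descriptors (`cis`, `trans`, `L-`, `D-`, `alpha`, ...), locants, bare
  numerals, single-letter tokens and a configurable non-chemistry stopword
  list, and splits compound tokens led by known substituent prefixes so
  that locant-order variants of one name give equal token multisets. Token
  comparison is multiset-based, not order-based, because real synonym pairs
  differ in token order alone. None of these transformations can change
  which molecule a name denotes, which is why equality after them is
  treated as assignment-strength evidence.
* **Reaction context** assigns when unique. A reaction with exactly one
  unresolved participant is matched against every fully resolved reaction
  on the remaining participant multiset — direction suppressed, free
  protons excluded, coefficients compared up to one global scale factor. A
  unique candidate structure fills the slot; multiple distinct candidates
  produce ranked suggestions only, because a wrong automatic merge is far
  more expensive downstream than a deferred one.
* **Phonetic similarity** only ever suggests. The encoder is a
  metaphone-style consonant-class code (the right family for Latinate
  chemical vocabulary; Soundex-class codes collapse too much). Suggestions
  are scored by the fraction of tokens with matching codes, floored at 0.5
  and capped at 5 by default. Both values are honest configuration, not
  calibration: no printed data pins them, so they are exposed as arguments.

Resolution passes repeat to a fixed point, with all assignments of a pass
computed against the state at the start of that pass. This makes a
dependency chain resolve one link per pass — the pass count in the log is
then a meaningful measure of how deep the corpus's unknowns were nested —
and makes the resolved set grow monotonically, which bounds the number of
passes by the number of unresolved entries.

Entries with *partial* atomistic detail (a `*` wildcard atom, an `R`/`X`
side chain, an `(X)n` repeat) are never auto-resolved and never join
comparisons; they surface in suggestion lists and exclusion tallies. A
structure/formula disagreement on one entry is classed as partial too: the
package flags the conflict for curation instead of deciding which field
wins, because no principled tie-break exists without consulting the source.

## Balancing: a deliberately small repair vocabulary

The repair model assumes that formulas and integer charges describe the
major microspecies at the source's reference pH; the package does not
compute protonation states (a pKa engine is a different tool), it consumes
them. Fractional charges are rejected rather than rounded — silent rounding
would manufacture balance errors of exactly the kind the audit is meant to
find.

With the vocabulary fixed to {H⁺, H₂O}, the charge equation pins the proton
delta and the oxygen equation pins the water delta, so feasibility is a
check, not a search, and the minimal repair is unique. This smallness is a
feature: a richer vocabulary (rewriting arbitrary coefficients, adding
electrons) could "fix" reactions by changing their chemistry. Anything
outside the vocabulary is reported `infeasible` and routed to curation,
including the degenerate case where a reaction consists of repair species
only and the repair would cancel every participant. One-sided reactions
(exchange/demand pseudo-fluxes) are unbalanced by construction and get
their own `boundary` status so they are never "repaired" into nonsense.

Compositions for balancing come from formula+charge when present, falling
back to structure-derived element counts; entries with partial detail never
contribute. A missing charge defaults to the structure's net charge, then
to zero — the common convention for neutral species in published tables.
All stoichiometric arithmetic is exact: coefficients are reduced integer
rationals, and sums are computed over a cleared common denominator, so a
repair decision never hinges on floating-point noise.

The closed form is the primary route; an LP route (a small built-in
two-phase simplex with Bland's rule) sits behind the same interface and is
cross-checked against the closed form in the tests. The simplex also powers
FBA, where rationals stay in the model and floats appear only inside the
solver; mass balance at the optimum is verified to 1e-6. Infinite user
bounds are boxed at 1e9 internally and a solution pressing against that box
is reported `unbounded` — deterministic, and honest about what the solver
can distinguish.

## Reaction keys and comparisons

A reaction key is the sorted multiset of (connectivity key, |coefficient|,
side) with direction suppressed, per-side strings sorted so that a
direction flip or participant permutation cannot change the key, and
compartments simplified to internal vs transport. Free protons are excluded
from keys — sources genuinely disagree on explicit protonation, and the
balancing module (not the identity module) is where protons are accounted —
but water is retained, because a water difference changes the chemistry and
must stay visible. Coefficients are normalized by their global rational
gcd, so a uniformly doubled reaction matches its original. `family` mode
additionally collapses configured cofactor pairs (NAD(H), NADP(H), F420 by
default, extensible) to a class token; strict mode is the default for
comparisons since nothing in a source marks which cofactor usage is
"incidental".

Source comparisons count connectivity keys (metabolite level) or strict
reaction keys (reaction level) per Venn region, with partial/unresolved
entries excluded and tallied separately — an identity claim about an
R-group entry would be a guess, and a count built on guesses is worse than
a smaller honest count.

## The synthetic corpus: what it emulates, what it does not

`make_synthetic_corpus()` builds a balanced true network — polyol backbones
of increasing chain length transformed by kinase, two dehydrogenase,
phosphatase and transport templates — against a small cofactor set whose
phosphoryl and redox relations are chemically exact (the triphosphate and
diphosphate esters differ by PO₃ and one charge; the pyridinium and
dihydropyridine pair differ by one hydride). The cofactor molecules
themselves are synthetic stand-ins, not the real cofactors, and are labeled
as such wherever they appear; every balancing identity the templates rely
on holds exactly for them.

Derived views inject the classic error classes independently per entry or
reaction: `name-variant`, `case-variant` and `stereo-prefix` replace the
name *and drop the structure* (they emulate name-only sources — with the
structure retained, recovery would be trivial and the test would show
nothing); `id-style-swap` re-keys an entry but keeps its structure;
`duplicate-entry` adds a second id for the same structure;
`r-group-masking` wildcards the structure and drops the formula;
`missing-proton` deletes one proton from a proton-producing reaction; and
`wrong-water-coeff` doubles a water coefficient. View 1 is a clean,
structure-rich reference: resolving name-only views against a curated
source is the workflow the package exists for, and without any resolved
anchor, independent corruption across all views would leave a fraction of
molecules structure-free everywhere — unrecoverable by any method, which
would measure the generator, not the reconciler. Cofactors are never
corrupted; their naming is effectively universal in practice.

The generator is a deterministic function of its seed. It does **not**
emulate: realistic name distributions (its variants are exactly the
normalizable kinds, so name recovery on this corpus is an upper bound),
content overlap statistics of real databases, gene–protein–reaction
annotation noise, or compartmentalization beyond a cytosol/external pair.
Passing recovery tests on this corpus therefore demonstrates mechanism
correctness, not expected field performance on arbitrary models.

Default study conditions used across the test suite: 50 reactions, 3
views, naming-error rates 0.5 (or 0.25+0.25 for the case/stereo-only
condition), seeds fixed per test. Property suites run 200 random repair
reactions against an exhaustive ±10 search, 100 random graphs (≤ 12
reactions) against an independent igraph simple-path oracle, and SBML round
trips on generated models — sizes chosen so the whole suite stays well
under a minute of solver work while still exercising every branch.

## Pathway prospecting

The metabolite–reaction graph is bipartite: substrate→reaction and
reaction→product arcs, a mirrored orientation-node pair for reversible
reactions, and *no* arcs for currency metabolites (default `h`, `h2o`,
`atp`, `adp`, `pi`, `nad(h)`, `nadp(h)`, `co2` — explicit and overridable,
because the exclusion list changes path counts and silent defaults would
make results irreproducible). Enumeration returns *all* paths within
`slack` of the minimum reaction count, forbidding reaction reuse (either
orientation) and metabolite revisits, ordered by length then lexicographic
reaction sequence, truncated at a cap with an explicit flag. Paths are
graph-connective only — no stoichiometric feasibility is imposed. That is
the standard trade-off of graph methods: exhaustiveness and scaling in
exchange for admitting routes a flux model might reject, so prospecting
output is a candidate list for constraint-based follow-up, not a
prediction.

## SBML

Export writes Level 3 Version 1 with the fbc extension (species per
metabolite–compartment pair, charge and formula on species, flux bounds as
parameters, one active maximization objective). Exact rationals, original
ids, synonyms, SMILES and backward-direction flags do not fit core SBML
attributes and travel as foreign-namespace attributes, which SBML permits
and other toolchains ignore; the test suite includes a cross-read of our
export by an independent SBML implementation (cobrapy). Import restores
them when present and falls back to core attributes otherwise. Id
sanitization to valid SIds is deterministic, and a sanitization collision
is an error rather than a silent merge.

## Known limitations

* Protonation states are inputs; models whose formulas reflect different
  reference pH values will show spurious (real, but uninteresting) proton
  imbalances that the repair will duly "fix".
* Name normalization is tuned to English-language biochemical nomenclature;
  the substituent-prefix list and stopword list are configurable but not
  comprehensive.
* The built-in simplex is dense and suitable for desk-scale models
  (hundreds of reactions); corpus-scale FBA would want a sparse LP backend
  behind the same interface.
* Reaction-family grouping depends on the configured cofactor classes;
  unconfigured cofactor families are simply kept distinct.
* Path enumeration is exponential in `slack` on dense graphs; the cap
  exists for exactly that reason and truncation is always flagged.
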