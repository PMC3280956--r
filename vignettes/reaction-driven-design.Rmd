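---
title: "Reaction-driven de novo design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-driven de novo design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxndesign)
```

## The method in one paragraph

`rxndesign` grows candidate ligands the way a medicinal chemist would plan a
synthesis: starting from a purchasable building block, it repeatedly applies
named chemical reactions from a template library, always coupling in another
purchasable block, and keeps the intermediates that most resemble a known
active reference ligand. Resemblance is measured by an iterative
optimal-assignment graph kernel on either the pharmacophore-typed molecular
graph or a reduced feature graph. Because every bond the program forms
corresponds to a literature reaction applied to cataloged reactants, each
designed molecule comes with an explicit synthesis route (block identifiers,
reaction names, protocol citations). The whole construction is deterministic:
two runs with identical inputs produce byte-identical output.

## Molecular model

Molecules are hydrogen-suppressed, **kekulized** graphs; aromaticity is a
derived flag computed by the package (SSSR perception followed by a
simplified Hückel count), never a bond order. This choice keeps implicit
hydrogen counts well defined after arbitrary graph edits, which the reaction
engine relies on: after a transform, hydrogens are refilled from standard
valences and aromaticity is re-perceived. Parsing, kekulization and canonical
SMILES writing are delegated to Open Babel (via ChemmineR/ChemmineOB); all
determinism guarantees are stated relative to Open Babel's canonical SMILES.

The aromaticity rules are deliberately simple: a SSSR ring is aromatic when
every atom is C/N/O/S/Se, sp2-compatible (no triple bond, at most three
connections), contributes either one π electron (any double bond into a ring
system) or two (lone pair of a heteroatom without a double bond), and the
total satisfies 4n+2. This reproduces the aromatic systems the reaction
library can form (benzenes, pyridines, pyrroles, furans, thiophenes,
(benz)imidazoles, triazoles, pyrazoles, thiazoles); exotic cases (azulenes,
mesoionics) are out of scope and simply stay non-aromatic.

## Pharmacophore typing

Each heavy atom receives exactly one of eight types — A (acceptor), D
(donor), E (donor and acceptor), P (positive), N (negative), R (aromatic), L
(lipophilic), 0 (untyped). The package defines the types by a fixed
priority cascade

P ≻ N ≻ E ≻ D ≻ A ≻ R ≻ L ≻ 0

with documented predicates of its own: P is a formal positive charge or a protonatable
aliphatic amine (sp3 N bonded only to non-aromatic carbons with no adjacent
carbonyl/thiocarbonyl/sulfonyl, no N–N or N–O); N is a formal negative
charge; donors are N/O/S with at least one hydrogen; acceptors are
non-aromatic O, pyridine-type aromatic N, and sp3 N that is not an amide
nitrogen; L is carbon whose neighbors are only carbon/halogen, plus
halogens. The cascade makes typing single-valued and idempotent, with the intended
reference behaviors (aromatic carbons are R,
pyridine N is A and feeds the acceptor bit of its ring's reduced vertex,
protonated amines are P). Aromatic heteroatoms keep their heteroatom
character rather than falling through to R — this is what makes benzene and
pyridine distinguishable at the reduced-graph level. Thiophene sulfur ends
up R (neither donor nor acceptor) — a documented convention; substructure
classes not covered by the predicates fall through to R, L or 0.

## Reduced graph

Every SSSR ring collapses to one vertex; fused systems containing an atom in
more than two SSSR rings collapse to a single "amalgamated" vertex (the
criterion is applied literally, so bridged polycyclics amalgamate only when
some atom lies in three or more SSSR rings). Maximal connected clusters of
acyclic L/0 atoms form one vertex; every other acyclic atom is its own
vertex. An atom shared by exactly two rings is assigned to the
earlier-ranked ring (rings ordered by size, then sorted atom indices) so the
vertices partition the molecule and atom counts sum to the heavy-atom count;
edge orders still use the full ring atom sets, so fused rings connect with
an order-2 edge and merely bonded rings with order 1.

Vertices carry a 10-bit label (8 types + ring + amalgamated) and an atom
count `ac`. Vertex similarity is

f_vc(A, B) = sdFactor(|ac_A − ac_B|) × Ti(bv_A, bv_B),

with Ti the bit-vector Tanimoto index c/(a+b−c). The penalty is constrained to be 1 at equal counts, 0 once the difference
exceeds five, and strictly between 0 and 1 in between; the package uses the
simplest curve satisfying all three,
`sdFactor(Δ) = max(0, 1 − Δ/6)`, isolated behind one function so a different
decay can be substituted.

Reduced graphs with a vertex of more than six neighbors are flagged invalid
and discarded by every caller (the kernel's neighbor matching is defined for
degree ≤ 6).

## The similarity kernel

Vertex-pair similarities iterate

s(u, v) ← (1 − α) · base(u, v) + α · neighbor(u, v)

to a fixed point (synchronous updates from the all-base initialization;
α < 1 makes the map a contraction). `base` is type equality on molecular
graphs and `f_vc` on reduced graphs. `neighbor` is the value of a
maximum-weight one-to-one matching of the two neighbor lists — pair weight =
edge-label compatibility × current similarity, where bond labels are
1/2/3/aromatic on molecular graphs and 1/2 on reduced graphs — normalized by
the larger neighbor count. The final score assigns each vertex of the
smaller graph to one vertex of the larger graph to maximize the summed
similarities (Hungarian algorithm) and divides by the larger vertex count,
so self-similarity is exactly 1 and size mismatch is penalized. Optimal-assignment kernels differ between implementations in their
normalization and neighbor-matching constants; the choices above are this
package's documented convention, and the structural contracts hold (symmetry, boundedness, the α = 0 label-only limit,
and exact agreement of the assignment stage with exhaustive enumeration).

Defaults: α = 0.875 for molecular graphs, α = 0.4 for reduced graphs,
tolerance 1e-6, 100-iteration cap (non-convergence is reported, never
silently accepted). The iteration and the assignment run in C++ (Rcpp): the
neighbor matching by exhaustive injective enumeration (degree ≤ 6), the
final assignment by an O(n³) Hungarian algorithm, both tested against a
brute-force permutation oracle.

## Reaction templates

Templates couple one or two reactants into exactly one product. The reactant
side is a reaction center written in the package's SMARTS subset (elements,
`#n`, `a`/`A`, `*`, charge, `Hn`, `Xn`, `Dn`, `R`/`R0`, `!`, `,`/`;` logic,
atom maps; recursive SMARTS deliberately excluded). Environment exclusions —
"this nitrogen must not be an amide nitrogen" — are expressed as `forbid`
patterns anchored at the component's first matched atom, which keeps the
matcher simple and the exclusions explicit in the library file. The product
side is a kekulized mapped pattern interpreted as graph edits: matched but
unmapped reactant atoms leave (the leaving group), bonds between two matched
atoms exist in the product only if drawn there (explicit `-`/`=`/`#`
override; a default bond keeps an existing bond's order or creates a single
bond), unmapped product atoms are new atoms. Hydrogens are refilled and
aromaticity re-perceived afterwards, so ring formations (Paal-Knorr,
Huisgen, Hantzsch, Knorr, benzimidazole closure) come out aromatic without
aromatic bond primitives on the product side.

A reactant participates only when its reaction center matches **exactly
once** (on symmetry-reduced matches, after forbid filtering): multiple
copies of the same functional group disqualify the block, which avoids
regio-ambiguous products and protecting-group gymnastics. No reactivity
ranking between competing groups is attempted. Each template declares its
minimal dummy fragments (smallest molecules satisfying each component) and a
leaving-group formula with its mass; at load time every template is
round-tripped on its own dummies — match exactly once, react, one connected
sanitized product, mass balance — so a broken library fails fast with the
template id.

The shipped library is a curated, extensible starting set: 24 coupling templates (amide, ester, sulfonamide,
Suzuki, Buchwald, N-alkylation, Williamson, Sonogashira, reductive
aminations, urea, carbamate, Knoevenagel, and 8 ring formations including a
regioisomer-split azide-alkyne pair and a regioisomer-split pyrazole pair)
plus 5 one-component FGA/FGI preprocessing templates (nitro→amine,
nitrile→amine, methyl-ester→acid, aryl-halide→boronic acid,
alcohol→bromide). The YAML schema is documented in the library file itself
so users can grow the set toward the hundreds of couplings a production
catalog would warrant.

## Building-block preparation

Standardization keeps the largest fragment, deprotonates carboxylic acids
and protonates basic aliphatic amines (the same predicate as type P), then
filtering applies, in order: mass in [30, 300] Da; at most 4 SSSR rings;
elements within C, N, O, S, P, F, Cl, Br, I, B, Si, Se; at most 3 fluorines;
valid valences; no structural alert; no duplicate canonical SMILES.
Duplicate removal runs after charge standardization so protomers collapse.
The alert list is a curated set of classic reactive-group filters
(acyl halides except chloroformates, isocyanates, epoxides, aziridines,
peroxides, diazonium, nitroso, anhydrides, enal Michael acceptors,
non-activated alkyl halides with benzylic/allylic/α-carbonyl exceptions),
shipped as an editable YAML taken per run from `--alerts` so a project can
tighten or relax it. Azides and
sulfonyl chlorides are deliberately not alerted: they are coupling handles
of the shipped library.

FGA/FGI preprocessing applies every matching one-component template once per
block, keeps the original, sends the converted block back through filtering
and duplicate removal, and never recurses. Annotation then records, for
every block, the (reaction, component) pairs whose center matches exactly
once; blocks with no annotation are stored but flagged unusable. The store
is a deterministic TSV keyed by id and canonical SMILES plus a JSON report
of per-rule rejection and per-reaction annotation counts — an embedded flat
file rather than a database server, which is deployment detail, not method.

## Construction algorithm

Start fragments are the annotated blocks ranked by kernel similarity to the
reference (ties: canonical SMILES, then id). Each design cycle has two
steps. Step 1 asks which reaction to apply: every applicable
(reaction, component) on the growing molecule Z is scored through its
*dummy product* — Z coupled with the complementary minimal dummy fragment,
or the actual product for one-component reactions, which compete in the same
ranking — and the top-scoring reaction(s), ties included, proceed. Step 2
enumerates every catalog block annotated for the complementary component,
forms and scores all real products, and carries the top-tied products
forward, never more than `beam_width` (default 10) states per round.

Stopping is controlled by the reference mass window (70%–130% by default)
and the score: below the lower bound every extension is accepted even if the
score drops; from the first intermediate at or above the lower bound
onwards, an extension must strictly improve the score and may never push the
mass over the upper bound, otherwise the previous intermediate is finalized.
The step that crosses the lower bound is itself accepted unconditionally —
the improvement test starts after the crossing. "Improved" is read as
strictly greater, which prevents infinite plateaus. A step cap (default 4)
finalizes unconditionally; products finalized by the cap or by a dead end
(no applicable reaction, no surviving product) are kept but flagged
`below_mass_window` when light, since the last valid reaction step defines
the product. A start that dies without completing a single step yields no
route and the next-ranked block takes its place until `n_starts` productive
starts are reached or the catalog is exhausted.

Every route records the ordered (reaction, partner block) steps with
provenance (catalog ids, FGA/FGI parentage, protocol citations); replaying
the steps through the reaction engine reproduces the final canonical SMILES
exactly, and the test suite checks this on 100% of emitted routes. Scoring
is cached by canonical SMILES, which keeps catalog-scale runs in seconds.

## The synthetic catalog generator

Real vendor catalogs (tens of thousands of purchasable blocks) are not
redistributable, so the package ships a deterministic generator
(`generate_catalog()`) that enumerates scaffold × functional-group
combinations (phenyl, tolyl, pyridyl, cyclohexyl, propyl, methoxyethyl ×
acid, amine, secondary amine, alcohol, boronic acid, aryl/benzyl halide,
sulfonyl chloride, 1,3-/1,4-diketone, azide, alkyne, aldehyde, ketone,
thioamide, hydrazine, α-bromoketone, chloroformate, arylene-diamine, nitro,
nitrile, methyl ester), each block carrying exactly one reactive group so
the exactly-once rule is exercised from both sides; a planted diacid tests
the rejecting side. Nine planted violations cover the filter rules
one-by-one, and a manifest records the expected outcome and expected
annotations of every record *by construction* — the preparation pipeline is
tested against the manifest, not the other way around. The seed only
shuffles record order (and keeps violations after their duplicate targets).

What the fixture does **not** emulate: realistic property distributions of
vendor catalogs (mass, ring counts, heteroatom density), multi-functional
blocks, salts and stereochemistry, or catalog scale. Passing tests therefore
demonstrate the correctness of the machinery — filtering, annotation,
reaction application, scoring, search control — not the pharmacological
quality of designs on real catalogs, which additionally depends on the
breadth of the reaction library and block inventory.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run the full pipeline at
fixture scale: a 63-record catalog (56 accepted blocks after preparation),
24+5 templates, design runs with 4 productive starts, beam 10, 4 steps, both
graph representations — sizes chosen so a complete run takes seconds while
still exercising pathway branching, dead starts and both stop rules.
Score ties are compared with an absolute tolerance of 1e-9 (scores are
deterministic doubles; genuine ties arise from symmetry, not rounding);
kernel convergence uses tol = 1e-6. The default `n_starts = 200` is sized
for catalog-scale runs; fixture-scale runs simply pass a smaller value.

## Known limitations

- Typing rules, aromaticity perception and the sdFactor curve are
  documented package conventions, each isolated behind a single function
  so alternatives can be substituted.
- The SMARTS subset has no recursive environments; exclusions must be
  expressible as anchored forbid patterns.
- 2D only: stereocenters pass through I/O untouched and are invisible to
  the score; no 3D pharmacophores, no docking.
- No drug-likeness/logP/synthesizability post-filters; such descriptors
  belong to external property-calculation software and are out of scope.
- Absolute kernel scores are implementation-specific; only the contracts
  and the induced rankings are meaningful across implementations.
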