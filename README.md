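# rxndesign

Reaction-driven de novo design of ligand candidates, in R.

## The problem

Most de novo design programs propose molecules nobody can make. `rxndesign`
takes the opposite route: it only ever grows a candidate by *virtually
executing a named chemical reaction* between the current intermediate and a
purchasable building block, so every designed molecule is born with a
synthesis plan — catalog identifiers of the reactants, reaction names, and
protocol citations for each step. Candidates are steered toward a known
active reference ligand by a graph-kernel similarity score, making the
package a tool for ligand-based scaffold hopping and bioisosteric
replacement when little more than one active compound is known.

## The method

Three components interlock:

1. **Scoring.** An iterative optimal-assignment graph kernel. Vertex-pair
   similarities obey the fixed point
   `s(u,v) = (1-α)·base(u,v) + α·match(neighbors(u), neighbors(v))`,
   where `match` is a maximum-weight one-to-one matching of the neighbor
   lists (edge-label compatible pairs weighted by current similarity,
   normalized by the larger degree). The molecule score is the value of a
   maximum-weight assignment of the smaller graph's vertices onto the larger
   graph, divided by the larger vertex count — so self-similarity is exactly
   1. Two representations: the pharmacophore-typed molecular graph
   (8 atom types A/D/E/P/N/R/L/0, default α = 0.875) and a reduced feature
   graph in which rings and lipophilic clusters collapse to labeled
   vertices with 10-bit labels and atom counts, compared by
   `f_vc = sdFactor(Δac) · Tanimoto(bv_A, bv_B)` (default α = 0.4).
2. **Chemistry.** A YAML library of reaction templates (24 couplings
   including 8 ring formations, plus 5 functional-group interconversions
   for catalog preprocessing). Reactant sides are atom-mapped reaction
   centers in a documented SMARTS subset; a center must match a reactant
   **exactly once** to qualify. Products are formed by explicit graph
   edits, sanitized, and re-perceived.
3. **Search.** A deterministic greedy/beam construction: the top-`n`
   catalog blocks most similar to the reference each seed a pathway; every
   cycle first picks the most promising reaction via *minimal dummy
   fragments*, then enumerates all annotated partner blocks, carrying at
   most 10 intermediates forward. Growth below 70% of the reference mass is
   unconditional; above it each step must strictly improve the score and
   stay under 130%, otherwise the previous intermediate becomes a final
   product. At most 4 steps per route.

## Worked example

The package ships a deterministic synthetic catalog generator, so the whole
pipeline runs without downloads:

```r
library(rxndesign)

# 1. synthetic building-block catalog (63 records incl. planted violations)
generate_catalog(fixture_spec(seed = 7), "catalog.smi", "manifest.json")

# 2. standardize, filter, preprocess (FGA/FGI), annotate
coupling <- load_reaction_library(system.file("extdata", "coupling_reactions.yaml",
                                              package = "rxndesign"))
fga    <- load_reaction_library(system.file("extdata", "preprocessing_reactions.yaml",
                                            package = "rxndesign"))
alerts <- load_alerts(system.file("extdata", "alerts.yaml", package = "rxndesign"))
catalog <- build_catalog("catalog.smi", coupling, fga, alerts)
catalog
#> <building-block catalog: 56 blocks (52 usable), 15 rejected>

# 3. design against a reference ligand
ref <- assign_pharmacophore_types(parse_smiles("O=C(Nc1ccc(C)cc1)c1ccccc1", "ref"))
designs <- run_design(catalog, ref, coupling,
                      design_config(n_starts = 4, representation = "molgraph"))
head(designs$summary[, c("smiles", "score", "mass", "n_steps", "start_block")])
#>                                      smiles     score    mass n_steps   start_block
#> 1         Cc1ccc(cc1)C(=O)Nc1ccccc1 0.8662424 211.264       1   BB_acid_tol
#> 2                Cc1ccc(o1)c1ccccc1 0.5557775 158.200       1 BB_dione14_ph
#> 3                Cc1ccc(s1)c1ccccc1 0.5557775 174.266       1 BB_dione14_ph
#> 4      Cc1cc(n(n1)c1ccccc1)c1ccccc1 0.5138699 234.302       1 BB_dione13_ph
#> 5       c1ccc(cc1)c1scc(n1)c1ccccc1 0.5060958 237.325       1 BB_bromoketone_ph
```

The top design is N-phenyl-p-toluamide (kernel score 0.866 against the
reference N-(4-methylphenyl)benzamide — the same scaffold with the amide
flipped), built in one amide coupling from the 4-methylbenzoic acid block;
the runners-up are ring-formation products (furan, thiophene, pyrazole,
thiazole) that replace the amide linker with heteroaromatic bioisosteres.
Every route replays exactly:

```r
r <- designs$products[[1]]$routes[[1]]
r$steps[[1]]$reaction_name
#> [1] "Amide coupling (primary amine)"
replay_route(r, catalog, coupling) == r$final_smiles
#> [1] TRUE
```

A command-line front end wraps the same functions
(`inst/cli/rxndesign.R`, subcommands `fixtures`, `prep`, `score`, `design`,
`report`).

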