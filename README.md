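# gemevidence

Genome-scale metabolic models that carry their own curation record.

A genome-scale metabolic model (GEM) distills the biochemistry of an
organism — typically assembled from hundreds of publications — into a
simulatable reaction network. Normally the model file records only the
network; the experimental record that justified every gene–reaction link
is lost. `gemevidence` keeps both in one SBML file and makes the record
executable:

- **evidence items**: referenced assertions (gene catalyzes reaction,
  reaction/metabolite present or absent, gene localizes to compartment),
  each graded with an Evidence and Conclusion Ontology (ECO) code;
- **test cases**: stored phenotype experiments — medium settings, deleted
  genes, and flux-threshold outcomes — that are re-simulated against the
  model like a software test suite;
- **FBA / parsimonious FBA**: linear optimization of the flux vector
  `v` under steady state `S v = 0` and bounds `l ≤ v ≤ u`, maximizing an
  objective `cᵀv`; pFBA then fixes the optimum `Z` and minimizes total
  absolute flux `Σ|v|`;
- **quality control**: elemental/charge mass balance, dead-end
  metabolites, census statistics, evidence-support classes, and
  presence/absence conflict reports;
- **strain translation**: reciprocal-best-hit ortholog mapping from
  tabular alignment hits, rewriting the gene layer (GPRs, evidence, test
  deletions) losslessly;
- **expression contextualization**: per-pathway log2-change profiles and
  candidate-gene co-expression screens over the model's pathways.

The package is aimed at curators and modelers who maintain fungal (or
any microbial) GEMs and want continuous, automated validation of every
edit against the accumulated experimental knowledge.

## Worked example

```r
library(gemevidence)

# a toy network with two alternative routes from A to B, plus its
# evidence set and an engineered 3-pass/1-fail phenotype suite
m <- fixture_model("redundant_routes", ub = 10)
m$evidence <- fixture_evidence(m)
m$tests <- fixture_suite(m, n_pass = 3, n_fail = 1)
m
#> gem_model <fixture_redundant_routes>: 1 compartments, 5 metabolites, 7 reactions, 5 genes
#>   evidence items: 7, test cases: 4
#>   objective: EX_B (1)

sol <- optimize_model(m, method = "pfba")
sol
#> flux_solution: optimal, objective = 10, total |v| = 40
round(sol$fluxes, 4)
#> EX_A  RS1  RS2  RL1  RL2  RL3 EX_B
#>  -10   10   10    0    0    0   10
```

The FBA optimum (10) is set by the uptake capacity; parsimonious FBA
routes all flux through the 2-step pathway (`RS1`, `RS2`), leaving the
3-step route idle — total absolute flux 40 instead of 50.

```r
run_suite(m)
#> suite: 4 run, 3 passed, 1 failed, 0 errored

model_statistics(m, suite = run_suite(m))
#> reactions: total 7, transport 0, boundary 2, unbalanced 0, annotated 0, no_genes 2, evidence_for_presence 1, known_gene 1
#> metabolites: total 5, annotated 0, dead_end 0
#> genes: total 5, known_function 1, verified_location 0, predicted_location 1
#> evidence: total 7, gene_reaction 2, reaction_presence 2, metabolite_presence 2, localization 1
#> tests: total 4, passing 3, failing 1
```

The three passing tests are the growth and no-growth phenotypes the
network actually satisfies; the failing one expects growth on a closed
medium, which steady-state mass conservation forbids — exactly the kind
of discrepancy the suite exists to surface. Models round-trip through
SBML with the whole record attached (`write_sbml()` / `read_sbml()`).

## Command line

A thin wrapper script ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","gem-cli.R",package="gemevidence"))')" \
    validate model.xml --format json
```

Subcommands: `validate` (exit code 1 if any test fails — CI-friendly),
`stats`, `balance`, `deadends`, `translate`, `expr`, `fixtures`.

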