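---
title: "Evidence-annotated genome-scale metabolic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-annotated genome-scale metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemevidence)
```

## The problem this package addresses

A genome-scale metabolic model (GEM) condenses hundreds of publications'
worth of biochemistry — which reactions an organism carries, which genes
encode the enzymes, where the proteins live — into a single simulatable
network. The curation knowledge behind such a model is usually lost: the
model file records the network, not the experiments that justified each
link. `gemevidence` keeps both together. It stores structured *evidence
items* (referenced assertions about genes, reactions, metabolites and
localizations, each graded with an Evidence and Conclusion Ontology code)
and *test cases* (simulatable phenotype observations: a growth medium, a
set of deleted genes, and flux-threshold outcomes) inside the SBML model
file itself, and re-runs the whole test suite against any edited model.
A model maintained this way can be changed freely and re-validated
against its entire experimental record in minutes, the same workflow that
unit tests provide for software.

## Constraint-based simulation

The simulatable content of a model is the steady-state flux cone. With
stoichiometric matrix $S$ (rows: non-boundary metabolites, columns:
reactions), flux vector $v$, bounds $l \le v \le u$ (mmol gDW$^{-1}$
h$^{-1}$) and objective weights $c$, flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; l \le v \le u .$$

Parsimonious FBA (pFBA) follows with a second stage: the objective is
held at its optimum $Z$ and total absolute flux $\sum_j |v_j|$ is
minimized, which removes futile cycles and spreads no flux over routes
longer than necessary. Both stages are linear programs after each flux is
split into non-negative forward and backward parts $v_j = f_j - b_j$ with
capacities $f_j \le \max(u_j, 0)$ and $b_j \le \max(-l_j, 0)$; at a
pFBA optimum no reaction carries flux in both directions, so the linear
total $\sum_j (f_j + b_j)$ equals $\sum_j |v_j|$ exactly.

Only objective values are contractual. FBA flux vectors are famously
non-unique, so the returned vector is one optimum among possibly many and
downstream code must not rely on its identity — this is why test-case
outcomes are defined on optimized objective values, never on individual
fluxes of a fixed solution.

### The LP backend

`solve_lp()` is a dense two-phase primal simplex written for this
package, using Bland's anti-cycling rule for both the entering and the
leaving variable. Degeneracy is the normal state of affairs in flux LPs —
closing the uptake exchanges of a medium produces many equality rows that
force variables to zero — and the general-purpose simplex available in
the R ecosystem does not survive these inputs reliably, so correctness
took precedence over speed: the backend is validated in the test suite
against an independent brute-force vertex-enumeration oracle (every basic
point of the polytope is enumerated and checked) and against a second
simplex implementation on non-degenerate cases. The solver sits behind a
minimal contract (equalities, inequalities, objective in; status,
optimum, primal out), so a faster backend can be substituted without
touching the flux code. Zero-capacity split variables (e.g. the backward
part of an irreversible reaction) are eliminated before the solver runs.

Numerical choices: pivot/feasibility tolerance $10^{-9}$; pFBA fixes the
first-stage objective within a relative slack of $10^{-6}$
($c^\top v \ge Z - 10^{-6}\max(1, |Z|)$ for maximization — the
symmetric form is used for minimization, and the $\max(1,\cdot)$ guard
keeps the slack meaningful for optima below 1). Bounds must be finite;
the conventional $\pm 1000$ plays the role of infinity, as is standard
in this field's model files. Infeasible and unbounded statuses are
surfaced as such — never silently reported as zero flux.

## Test-case semantics

A test case is evaluated with the following protocol, chosen so that the
settings list alone defines the medium:

1. every boundary reaction *not* named in the test's settings is
   restricted to the direction that excretes its metabolite (uptake
   closed, secretion open); direction is read off the stoichiometry, so
   both `A ->` and `-> A` encodings behave identically;
2. the settings' bound overrides are applied verbatim;
3. deleted genes are propagated through the GPR rules: a reaction whose
   boolean rule evaluates false gets bounds $(0, 0)$; a reaction with no
   rule is never disabled (gene-less reactions must stay simulatable);
4. each outcome's own reaction is optimized in the direction of its
   comparator — maximized for `greater`, minimized for `less` — and the
   optimum is compared with the stored threshold;
5. the test passes iff every outcome holds.

Optimizing the outcome reaction itself (rather than a fixed biomass
objective) makes `less` outcomes certificates of impossibility, which is
what a no-growth phenotype asserts. Tests whose references do not resolve
or whose LP fails are tallied as *errored*, not failed — including the
genuinely open case of mixed-direction outcomes on an infeasible model —
so suite totals always partition as passed + failed + errored = run. The
runner defaults to FBA; pFBA can be selected per run (the optimum, and
hence every verdict, is identical — only reported flux vectors differ).
The canonical growth/no-growth threshold used when *generating* tests is
$10^{-6}$; stored thresholds are compared exactly as stored.

## The evidence record in SBML

Models are read and written as SBML Level 3 Version 1 with the
flux-balance-constraints (fbc v2) extension: bounds as fbc parameters,
the objective as an fbc objective, GPRs as gene-product associations, and
ChEBI/database cross-references as MIRIAM-style identifier URIs in RDF
annotations. The evidence record lives in a dedicated XML namespace
(`http://gemevidence.org/annotation/version1`) inside the model-level
`<annotation>` element, which the SBML specification explicitly reserves
for tool-specific content — embedding the curation record does not break
the format, and files remain loadable by any standards-compliant tool.

Element names: `ev:evidenceData` holds `ev:listOfEvidences` (each
`ev:evidence` carries `id`, `assertion`, `subject`, `target`, `ecoCode`
attributes, an optional `ev:description` child and `ev:reference`
children) and `ev:listOfTestCases` (each `ev:testCase` holds
`ev:setting`, `ev:deletion`, `ev:outcome` and `ev:reference` elements).
Numbers are serialized with 15 significant digits, which makes
write–read–write cycles byte-identical. SBML identifiers are restricted
to `[A-Za-z_][A-Za-z0-9_]*`, but model-internal ids are opaque strings —
JGI transcript ids are purely numeric — so ids are prefixed (`M_`, `R_`,
`G_`, `C_`) and sanitized on writing, with the verbatim id preserved in
`fbc:label` for genes and an `ev:originalId` attribute otherwise.
Translation between strains therefore never mangles an identifier.

Three deliberate conservatisms: absence assertions (`reaction_absent`,
`metabolite_absent`, `gene_not_catalyzes_reaction`) are stored but never
auto-applied to the network — they only feed the conflict report, since
a negative growth result can coexist with a positive assay under partial
genetic redundancy, and resolving that requires a curator. Malformed or
unrecognized evidence blocks are skipped with a warning count (unknown
assertion kinds are preserved as opaque records), never aborting a model
read. And every literature-backed item must carry at least one reference;
only prediction-rank ECO codes may stand alone.

## Quality control and census statistics

`check_mass_balance()` computes per-element imbalances (product side
minus substrate side); reactions touching a participant without a
formula, with an unparseable formula, or with a wildcard R-group are
*undetermined*, never guessed. Formulas follow Hill notation with integer
counts; the undissociated (protonated) convention is assumed, i.e.
formulas carry their protons, so proton bookkeeping is part of the
element balance rather than a separate term. `find_dead_ends()` uses the
connectivity definition — a metabolite that, given reaction
reversibilities, can only be produced or only consumed — rather than
LP-based blocked-reaction analysis; the connectivity notion is the
standard census meaning, is exact, and needs no solver. Dead ends are
deliberately reported, not removed: they mark curation frontiers.

`classify_support()` assigns each reaction the strongest of five classes
(characterized enzyme > measured but unknown enzyme > strong similarity
> other > no evidence) from its presence evidence and its genes' link
evidence. ECO accessions map to coarse ranks (experimental, similarity,
prediction, other) through a packaged, editable table
(`inst/extdata/eco_ranks.tsv`); the published category-level figures this
classification mirrors do not pin down a unique code-level mapping, so
the table is data, not code, and unknown codes fall to `other` with a
warning. Census counts that depend on this table (known-function genes,
verified vs predicted localization) inherit its choices.

## Strain translation

Ortholog pairs come from reciprocal best hits over two directed
12-column tabular alignment hit tables: best means maximal bitscore,
ties broken by minimal e-value, then by lexicographically smallest
subject id (a deterministic, auditable rule). An optional e-value or
identity pre-filter is available but off by default — whether the
original mapping filtered first is unknowable from the published
artifacts, and an unfiltered RBH is the more reproducible baseline.
`translate_model()` rewrites GPR leaves through the bijection. An
unmapped `or` arm narrows alternatives silently; an unmapped `and`
member would silently weaken a subunit requirement and therefore flags
the reaction as *degraded* in the transfer report. A fully emptied rule
leaves the reaction in place as gene-less. Only the gene layer changes:
reaction and metabolite counts are invariant under translation.

## Expression contextualization

Pathway labels group reactions, and through their GPR leaves, genes.
`pathway_change_profile()` reports per-gene log2 changes against a
user-chosen reference condition — the input matrix is assumed
pre-normalized log2 (microarray/RNA-seq preprocessing is out of scope),
and the reference is a required argument because no baseline can be
defaulted responsibly. Genes absent from the matrix are listed as
missing, never imputed as zero. `coexpression_score()` computes Pearson
correlations of a candidate gene against pathway members across
conditions (at least three required; zero-variance profiles yield `NA`),
the screen by which an unassigned transporter can be tied to a
co-regulated biosynthetic cluster.

## What the fixtures emulate — and what they do not

The fixture generators (`fixture_model()`, `fixture_suite()`,
`fixture_evidence()`, `fixture_hits()`, `fixture_expression()`) produce
networks whose optima, dead ends, balance verdicts and suite outcomes
are known in closed form: linear chains (optimum = uptake capacity), a
2:1-yield condensation (optimum = capacity/2), a two-compartment
transport chain, engineered dead-end sets, and a redundant-route network
on which parsimonious FBA must choose the 2-step over the 3-step route
(total flux $4u$ vs $5u$). Seeds are explicit parameters everywhere and
the global RNG state is restored after use; identical spec + seed gives
byte-identical serialization.

These toys exercise every contract — steady-state mass conservation,
GPR logic, boundary closure, serialization, pairing, profiling — at
sizes where independent oracles (vertex enumeration, truth tables,
double argmax) are exhaustive: networks of ≤ 10 reactions, GPR rules of
≤ 10 genes, 20 × 20 score matrices, all well inside a few minutes of
CPU. What passing them does *not* show: behavior on genome-scale
numerics (thousands of reactions, poorly scaled coefficients), curation
pathologies of real files (vendor-specific annotation dialects, partial
fbc usage), or biological realism of any kind. In particular, the
published strain models this framework descends from are distributed as
journal supplements and are not bundled here; the acceptance test that
would recompute their censuses (1325 genes, 2320 reactions, 3482
evidence items, 471 tests, 373/98 pass/fail) runs only when the file is
placed under `inst/extdata/published/`, and is reported as failing
otherwise rather than silently skipped.

## Known limitations

- The simplex backend is dense and unoptimized; genome-scale models will
  solve, but slowly. The solve contract exists precisely so a sparse
  backend can replace it.
- Only the annotation dialect documented above is parsed. Evidence
  embedded by other editors in their own namespaces is surfaced through
  the unparsed-block warning count, not translated: reverse-engineering a
  third-party dialect without its reference files would be guesswork.
- FVA, MOMA, thermodynamic constraints, gap-filling and automatic repair
  of failing tests are out of scope; failing tests are curation targets,
  and the package's job is to keep them visible.
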