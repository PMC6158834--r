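## Deterministic toy networks with analytically known behavior. Every
## generator attaches its ground truth (optimal objective, dead-end set,
## key reaction ids) as the "ground_truth" attribute, which doubles as the
## cross-module integration oracle.

#' Generate a toy metabolic model
#'
#' Topologies:
#' \describe{
#'   \item{chain}{linear pathway `M1 -> ... -> Mn` fed by an uptake
#'     exchange with capacity `ub`; optimum equals `ub`.}
#'   \item{branch}{`A -> B` and `A -> C` from one uptake; optimizing the
#'     B drain gives `ub`.}
#'   \item{yield_half}{`2 A -> B`: two units of substrate per product,
#'     so the optimum is `ub / 2`.}
#'   \item{compartmented}{extracellular/cytosolic compartments joined by
#'     two transport reactions around a conversion step; optimum `ub`,
#'     transport count 2.}
#'   \item{dead_end_k}{a chain plus `k` terminal metabolites that are
#'     produced but never consumed; the ground-truth dead-end set has
#'     exactly those `k` ids.}
#'   \item{redundant_routes}{two alternative routes from A to B, one of
#'     2 steps and one of 3; FBA optimum `ub` either way, and the
#'     parsimonious solution uses only the short route with total
#'     absolute flux `4 * ub` (long-route-only solutions carry `5 * ub`).}
#' }
#' All internal metabolites share one formula, so every non-boundary
#' reaction is elementally balanced; every uptake/drain is a one-sided
#' boundary reaction. Each enzymatic reaction has a single dedicated gene
#' `g_<reaction>` and a subsystem label usable by the pathway profiling.
#'
#' @param topology one of `chain`, `branch`, `yield_half`,
#'   `compartmented`, `dead_end_k`, `redundant_routes`.
#' @param n chain length (chain topologies), `>= 2`.
#' @param ub uptake capacity (mmol/gDW/h).
#' @param k number of engineered dead ends.
#' @return a [gem_model()] with a `ground_truth` attribute: a list with
#'   `optimum`, `objective_reaction`, `uptake_reaction`, `uptake_bound`,
#'   `dead_ends`, `n_transport`.
#' @export
fixture_model <- function(topology = c("chain", "branch", "yield_half",
                                       "compartmented", "dead_end_k",
                                       "redundant_routes"),
                          n = 3, ub = 10, k = 3) {
  topology <- match.arg(topology)
  b <- .model_builder(paste0("fixture_", topology))
  gt <- list(uptake_bound = ub, dead_ends = character(), n_transport = 0L)
  switch(topology,
    chain = {
      stopifnot(n >= 2)
      ids <- paste0("M", seq_len(n))
      for (m in ids) b$met(m)
      b$exchange("EX_M1", "M1", lb = -ub, ub = 0)
      for (i in seq_len(n - 1)) {
        b$rxn(paste0("R", i), stats::setNames(c(-1, 1), ids[c(i, i + 1)]),
              gene = paste0("g", i), subsystem = "core")
      }
      b$exchange(paste0("EX_M", n), ids[n], lb = 0, ub = 1000)
      b$objective(paste0("EX_M", n))
      gt$optimum <- ub
      gt$objective_reaction <- paste0("EX_M", n)
      gt$uptake_reaction <- "EX_M1"
    },
    branch = {
      for (m in c("A", "B", "C")) b$met(m)
      b$exchange("EX_A", "A", lb = -ub, ub = 0)
      b$rxn("R_AB", c(A = -1, B = 1), gene = "g1", subsystem = "branch_b")
      b$rxn("R_AC", c(A = -1, C = 1), gene = "g2", subsystem = "branch_c")
      b$exchange("EX_B", "B"); b$exchange("EX_C", "C")
      b$objective("EX_B")
      gt$optimum <- ub
      gt$objective_reaction <- "EX_B"; gt$uptake_reaction <- "EX_A"
    },
    yield_half = {
      b$met("A")
      b$exchange("EX_A", "A", lb = -ub, ub = 0)
      ## condensation: two substrate units per product; product formula
      ## is doubled so the reaction stays elementally balanced
      b$met("B2", formula = "C12H24O12")
      b$rxn("R1", c(A = -2, B2 = 1), gene = "g1", subsystem = "core")
      b$exchange("EX_B2", "B2")
      b$objective("EX_B2")
      gt$optimum <- ub / 2
      gt$objective_reaction <- "EX_B2"; gt$uptake_reaction <- "EX_A"
    },
    compartmented = {
      b$comp("e", "extracellular")
      b$met("A_e", comp = "e"); b$met("B_e", comp = "e")
      b$met("A_c"); b$met("B_c")
      b$exchange("EX_A", "A_e", lb = -ub, ub = 0)
      b$rxn("T_A", c(A_e = -1, A_c = 1), gene = "gT1", subsystem = "transport",
            lb = -1000)
      b$rxn("R1", c(A_c = -1, B_c = 1), gene = "g1", subsystem = "core")
      b$rxn("T_B", c(B_c = -1, B_e = 1), gene = "gT2", subsystem = "transport")
      b$exchange("EX_B", "B_e")
      b$objective("EX_B")
      gt$optimum <- ub; gt$n_transport <- 2L
      gt$objective_reaction <- "EX_B"; gt$uptake_reaction <- "EX_A"
    },
    dead_end_k = {
      stopifnot(k >= 1)
      for (m in c("M1", "M2", "M3")) b$met(m)
      b$exchange("EX_M1", "M1", lb = -ub, ub = 0)
      b$rxn("R1", c(M1 = -1, M2 = 1), gene = "g1", subsystem = "core")
      b$rxn("R2", c(M2 = -1, M3 = 1), gene = "g2", subsystem = "core")
      b$exchange("EX_M3", "M3")
      dead <- paste0("D", seq_len(k))
      for (j in seq_len(k)) {
        b$met(dead[j])
        b$rxn(paste0("RD", j), stats::setNames(c(-1, 1), c("M1", dead[j])),
              gene = paste0("gd", j), subsystem = "side")
      }
      b$objective("EX_M3")
      gt$optimum <- ub
      gt$dead_ends <- sort(dead)
      gt$objective_reaction <- "EX_M3"; gt$uptake_reaction <- "EX_M1"
    },
    redundant_routes = {
      for (m in c("A", "X", "Y1", "Y2", "B")) b$met(m)
      b$exchange("EX_A", "A", lb = -ub, ub = 0)
      b$rxn("RS1", c(A = -1, X = 1), gene = "gs1", subsystem = "short_route")
      b$rxn("RS2", c(X = -1, B = 1), gene = "gs2", subsystem = "short_route")
      b$rxn("RL1", c(A = -1, Y1 = 1), gene = "gl1", subsystem = "long_route")
      b$rxn("RL2", c(Y1 = -1, Y2 = 1), gene = "gl2", subsystem = "long_route")
      b$rxn("RL3", c(Y2 = -1, B = 1), gene = "gl3", subsystem = "long_route")
      b$exchange("EX_B", "B")
      b$objective("EX_B")
      gt$optimum <- ub
      gt$pfba_total_flux <- 4 * ub
      gt$short_route <- c("RS1", "RS2"); gt$long_route <- c("RL1", "RL2", "RL3")
      gt$objective_reaction <- "EX_B"; gt$uptake_reaction <- "EX_A"
    })
  model <- b$build()
  attr(model, "ground_truth") <- gt
  model
}

## tiny internal builder so fixture definitions read declaratively
.model_builder <- function(id) {
  env <- new.env(parent = emptyenv())
  env$comps <- data.frame(id = "c", name = "cytosol", stringsAsFactors = FALSE)
  env$mets <- list(); env$rxns <- list(); env$stoich <- list()
  env$genes <- character(); env$obj <- numeric()
  list(
    comp = function(cid, name = cid) {
      env$comps <- rbind(env$comps, data.frame(id = cid, name = name,
                                               stringsAsFactors = FALSE))
    },
    met = function(mid, comp = "c", formula = "C6H12O6", charge = 0L,
                   chebi = NA_character_) {
      env$mets[[mid]] <- data.frame(id = mid, name = mid, compartment = comp,
        formula = formula, charge = charge, chebi = chebi, boundary = FALSE,
        stringsAsFactors = FALSE)
    },
    rxn = function(rid, st, gene = NA_character_, subsystem = NA_character_,
                   lb = 0, ub = 1000) {
      env$rxns[[rid]] <- data.frame(id = rid, name = rid, lower_bound = lb,
        upper_bound = ub, subsystem = subsystem,
        gpr = if (is.na(gene)) "" else gene, xrefs = "", stringsAsFactors = FALSE)
      env$stoich[[rid]] <- st
      if (!is.na(gene)) env$genes <- union(env$genes, gene)
    },
    exchange = function(rid, mid, lb = 0, ub = 1000) {
      env$rxns[[rid]] <- data.frame(id = rid, name = rid, lower_bound = lb,
        upper_bound = ub, subsystem = "exchange", gpr = "", xrefs = "",
        stringsAsFactors = FALSE)
      env$stoich[[rid]] <- stats::setNames(-1, mid)
    },
    objective = function(rid, w = 1) env$obj <- stats::setNames(w, rid),
    build = function() {
      gem_model(id = id,
        compartments = env$comps,
        metabolites = do.call(rbind, env$mets),
        reactions = do.call(rbind, env$rxns),
        stoichiometry = env$stoich,
        genes = data.frame(id = env$genes, name = env$genes,
                           stringsAsFactors = FALSE),
        objective = env$obj)
    })
}

#' Generate a test suite with known pass/fail composition
#'
#' Builds `n_pass + n_fail` test cases for a fixture model whose ground
#' truth is known. Passing tests alternate between growth tests (medium
#' open, objective must exceed the growth threshold) and no-growth tests
#' (medium closed, objective must stay below it); failing tests expect
#' growth on a closed medium, which steady-state mass balance forbids.
#' With a seed, test ids are shuffled deterministically so serialization
#' order is exercised; composition is unaffected.
#'
#' @param model a [fixture_model()] result.
#' @param n_pass,n_fail number of passing/failing tests to engineer.
#' @param threshold growth threshold.
#' @param seed optional integer seed for the deterministic shuffle.
#' @return list of [test_case()] objects.
#' @export
fixture_suite <- function(model, n_pass = 3, n_fail = 1, threshold = 1e-6,
                          seed = NULL) {
  gt <- attr(model, "ground_truth")
  if (is.null(gt)) stop("model carries no ground truth; use fixture_model()")
  medium <- data.frame(reaction = gt$uptake_reaction,
                       lower_bound = -gt$uptake_bound, upper_bound = 0,
                       stringsAsFactors = FALSE)
  tests <- list()
  for (i in seq_len(n_pass)) {
    tests[[length(tests) + 1L]] <- if (i %% 2 == 1) {
      test_case(id = sprintf("pass_growth_%02d", i),
                name = "growth on open medium",
                settings = medium,
                outcomes = data.frame(reaction = gt$objective_reaction,
                                      cmp = "greater", value = threshold))
    } else {
      test_case(id = sprintf("pass_nogrowth_%02d", i),
                name = "no growth on closed medium",
                outcomes = data.frame(reaction = gt$objective_reaction,
                                      cmp = "less", value = threshold))
    }
  }
  for (i in seq_len(n_fail)) {
    tests[[length(tests) + 1L]] <- test_case(
      id = sprintf("fail_growth_%02d", i),
      name = "growth expected on closed medium (engineered failure)",
      outcomes = data.frame(reaction = gt$objective_reaction,
                            cmp = "greater", value = threshold))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    tests <- tests[sample(seq_along(tests))]
  }
  tests
}

#' Generate one evidence item per assertion kind
#'
#' Builds a seven-item evidence set referencing components of the given
#' fixture model, covering every assertion kind once — the canonical
#' round-trip and census fixture.
#'
#' @param model a [fixture_model()] result with at least one gene-bearing
#'   reaction.
#' @return list of seven [evidence_item()] objects.
#' @export
fixture_evidence <- function(model) {
  rid <- model$reactions$id[nzchar(model$reactions$gpr)][1]
  gid <- gpr_genes(model$reactions$gpr[model$reactions$id == rid])[1]
  mid <- model$metabolites$id[1]
  cid <- model$compartments$id[1]
  ref <- list(reference("pubmed", "12345678", "toy assay"))
  list(
    evidence_item("ev1", "gene_catalyzes_reaction", gid, rid,
                  eco_code = "ECO:0000314", description = "direct assay",
                  references = ref),
    evidence_item("ev2", "gene_not_catalyzes_reaction", gid, rid,
                  eco_code = "ECO:0000315", description = "mutant keeps activity",
                  references = ref),
    evidence_item("ev3", "reaction_present", rid,
                  eco_code = "ECO:0000269", description = "activity measured",
                  references = ref),
    evidence_item("ev4", "reaction_absent", rid,
                  eco_code = "ECO:0000269", references = ref),
    evidence_item("ev5", "metabolite_present", mid,
                  eco_code = "ECO:0000269", description = "compound detected",
                  references = ref),
    evidence_item("ev6", "metabolite_absent", mid,
                  eco_code = "ECO:0000269", references = ref),
    evidence_item("ev7", "gene_localizes_to_compartment", gid, cid,
                  eco_code = "ECO:0000255", description = "targeting signal predicted"))
}

#' Seeded random hit tables with a known reciprocal-best-hit answer
#'
#' Draws a dense score matrix between `n` strain-A and `n` strain-B
#' genes and emits both directed hit tables (every pair appears in each
#' direction with a shared bitscore). The exhaustive double-argmax over
#' the matrix is then the reference answer for RBH pairing.
#'
#' @param n genes per strain.
#' @param seed integer seed.
#' @return list: `hits_ab`, `hits_ba` (12-column hit tables), `scores`
#'   (the underlying matrix, rows = A genes, cols = B genes).
#' @export
fixture_hits <- function(n = 20, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  a <- sprintf("a%02d", seq_len(n)); b <- sprintf("b%02d", seq_len(n))
  scores <- matrix(round(stats::runif(n * n, 30, 300), 1), n, n,
                   dimnames = list(a, b))
  mk <- function(q, s, sc) data.frame(
    query = q, subject = s, pident = round(pmin(100, sc / 3), 1),
    length = 300L, mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 300L,
    sstart = 1L, send = 300L, evalue = signif(10^(-sc / 30), 3), bitscore = sc,
    stringsAsFactors = FALSE)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  list(hits_ab = mk(a[grid$i], b[grid$j], scores[cbind(grid$i, grid$j)]),
       hits_ba = mk(b[grid$j], a[grid$i], scores[cbind(grid$i, grid$j)]),
       scores = scores)
}

#' Seeded expression matrix for a fixture model
#'
#' Log2 expression for every model gene across `n_cond` conditions, with
#' the genes of one pathway shifted by `shift` in all non-reference
#' conditions — a known differential signal for profile tests.
#'
#' @param model a [fixture_model()] result.
#' @param n_cond number of conditions (first is the reference).
#' @param shift log2 shift applied to `pathway` member genes.
#' @param pathway subsystem label to shift.
#' @param seed integer seed.
#' @return matrix, genes x conditions; reference condition is `cond1`.
#' @export
fixture_expression <- function(model, n_cond = 4, shift = 2,
                               pathway = NULL, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  genes <- model$genes$id
  m <- matrix(round(stats::rnorm(length(genes) * n_cond, mean = 8, sd = 0.5), 3),
              nrow = length(genes),
              dimnames = list(genes, paste0("cond", seq_len(n_cond))))
  if (!is.null(pathway)) {
    mem <- intersect(pathway_members(model, pathway), genes)
    m[mem, -1] <- m[mem, -1] + shift
  }
  m
}
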