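make_balance_model <- function() {
  gem_model("bal",
    compartments = data.frame(id = "c", name = "cytosol"),
    metabolites = data.frame(
      id = c("A", "B", "C", "D", "E"),
      name = NA_character_, compartment = "c",
      formula = c("CH4", "O2", "CH4O2", "CH3", NA),
      charge = c(0L, 0L, 0L, 0L, NA),
      chebi = NA_character_, boundary = FALSE),
    reactions = data.frame(
      id = c("Rok", "Rbad", "Rmiss"),
      lower_bound = 0, upper_bound = 1000),
    stoichiometry = list(Rok = c(A = -1, B = -1, C = 1),
                         Rbad = c(A = -1, D = 1),
                         Rmiss = c(A = -1, E = 1)))
}

test_that("mass balance detects balanced, unbalanced and undetermined reactions", {
  m <- make_balance_model()
  expect_identical(check_mass_balance(m, "Rok")$verdict, "balanced")
  bad <- check_mass_balance(m, "Rbad")
  expect_identical(bad$verdict, "unbalanced")
  expect_equal(bad$elements[["H"]], -1)  # one H short on the product side
  miss <- check_mass_balance(m, "Rmiss")
  expect_identical(miss$verdict, "undetermined")
  expect_match(miss$note, "missing formula")
  # wildcard R-group participants are undetermined, not guessed
  m$metabolites$formula[m$metabolites$id == "E"] <- "C2H5R"
  expect_identical(check_mass_balance(m, "Rmiss")$verdict, "undetermined")
  # charge imbalance flags an otherwise element-balanced reaction
  m2 <- m
  m2$metabolites$charge[m2$metabolites$id == "C"] <- -1L
  expect_identical(check_mass_balance(m2, "Rok")$verdict, "unbalanced")
})

test_that("a reaction and its exact reverse get the same balance verdict", {
  m <- make_balance_model()
  for (rid in c("Rok", "Rbad")) {
    m2 <- m
    m2$stoichiometry[[rid]] <- -m2$stoichiometry[[rid]]
    expect_identical(check_mass_balance(m2, rid)$verdict,
                     check_mass_balance(m, rid)$verdict, info = rid)
  }
})

test_that("Hill formulas parse to element counts with wildcard flags", {
  f <- parse_formula("C6H12O6")
  expect_equal(f$counts[c("C", "H", "O")], c(C = 6L, H = 12L, O = 6L))
  expect_false(f$wildcard)
  expect_true(parse_formula("C2H5R")$wildcard)
  expect_false(parse_formula("XeF4")$wildcard)  # Xe is an element, X alone is not
  expect_true(parse_formula("CHX")$wildcard)
  expect_null(parse_formula(NA))
  expect_error(parse_formula("C6H12O6!"), "unparseable")
})

test_that("engineered dead ends are recovered exactly", {
  m <- fixture_model("dead_end_k", k = 3)
  expect_identical(find_dead_ends(m), attr(m, "ground_truth")$dead_ends)
  # a metabolite inside a reversible chain interior is not a dead end
  mc <- fixture_model("compartmented")
  expect_length(find_dead_ends(mc), 0)
  # exhaustive check on the small network: every metabolite's verdict
  # matches direct inspection of producer/consumer sets
  dead <- find_dead_ends(m)
  for (mid in m$metabolites$id) {
    prod <- cons <- FALSE
    for (rid in m$reactions$id) {
      st <- m$stoichiometry[[rid]]
      if (!mid %in% names(st)) next
      co <- st[[mid]]
      ub <- m$reactions$upper_bound[m$reactions$id == rid]
      lb <- m$reactions$lower_bound[m$reactions$id == rid]
      if ((co > 0 && ub > 0) || (co < 0 && lb < 0)) prod <- TRUE
      if ((co < 0 && ub > 0) || (co > 0 && lb < 0)) cons <- TRUE
    }
    expect_identical(mid %in% dead, !(prod && cons), info = mid)
  }
})

test_that("dead-end detection is invariant under reordering and relabeling", {
  m <- fixture_model("dead_end_k", k = 3)
  ref <- find_dead_ends(m)
  # reverse reaction order
  m2 <- m
  m2$reactions <- m2$reactions[rev(seq_len(nrow(m2$reactions))), ]
  m2$stoichiometry <- m2$stoichiometry[rev(names(m2$stoichiometry))]
  expect_identical(find_dead_ends(m2), ref)
  # relabel metabolites bijectively
  relab <- stats::setNames(paste0("met_", m$metabolites$id), m$metabolites$id)
  m3 <- m
  m3$metabolites$id <- unname(relab[m3$metabolites$id])
  m3$stoichiometry <- lapply(m3$stoichiometry, function(st) {
    stats::setNames(as.numeric(st), unname(relab[names(st)]))
  })
  expect_identical(find_dead_ends(m3), sort(unname(relab[ref])))
})

test_that("model statistics match hand counts on an engineered fixture", {
  m <- fixture_model("compartmented")
  m$metabolites$chebi[1:2] <- c("CHEBI:1", "CHEBI:2")
  m$reactions$xrefs[m$reactions$id == "R1"] <- "rhea:100"
  m$evidence <- fixture_evidence(m)
  m$tests <- fixture_suite(m, 2, 1)
  suite <- run_suite(m)
  st <- model_statistics(m, suite = suite)
  expect_equal(st$reactions$total, 5)
  expect_equal(st$reactions$transport, 2)
  expect_equal(st$reactions$boundary, 2)
  expect_equal(st$reactions$no_genes, 2)  # the two exchanges
  expect_equal(st$reactions$annotated, 1)
  expect_equal(st$metabolites$total, 4)
  expect_equal(st$metabolites$annotated, 2)
  expect_equal(st$metabolites$dead_end, 0)
  expect_equal(st$genes$total, 3)
  expect_equal(st$evidence$total, 7)
  expect_equal(st$tests$passing, 2)
  expect_equal(st$tests$failing, 1)
  # subcategories never exceed totals
  expect_true(all(unlist(st$reactions) <= st$reactions$total))
  expect_true(all(unlist(st$metabolites) <= st$metabolites$total))
})

test_that("reaction support classification follows the documented ranking", {
  m <- fixture_model("redundant_routes")
  ref <- list(reference("pubmed", "1"))
  ev <- list(
    evidence_item("s1", "gene_catalyzes_reaction", "gs1", "RS1",
                  eco_code = "ECO:0000314", references = ref),       # characterized
    evidence_item("s2", "reaction_present", "RS2",
                  eco_code = "ECO:0000269", references = ref),       # measured
    evidence_item("s3", "gene_catalyzes_reaction", "gl1", "RL1",
                  eco_code = "ECO:0000250", references = ref),       # similarity
    evidence_item("s4", "gene_catalyzes_reaction", "gl2", "RL2",
                  eco_code = "ECO:0000501", references = ref))       # prediction -> other
  cls <- classify_support(m, ev)
  got <- stats::setNames(cls$classes$class, cls$classes$reaction)
  expect_identical(got[["RS1"]], "characterized_enzyme")
  expect_identical(got[["RS2"]], "measured_unknown_enzyme")
  expect_identical(got[["RL1"]], "strong_similarity")
  expect_identical(got[["RL2"]], "other")
  expect_identical(got[["RL3"]], "no_evidence")
  expect_identical(got[["EX_A"]], "no_evidence")  # gene-less, no evidence
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-12)
  # characterized beats similarity when both exist for one reaction
  ev2 <- c(ev, list(evidence_item("s5", "gene_catalyzes_reaction", "gs2", "RL1",
                                  eco_code = "ECO:0000314", references = ref)))
  cls2 <- classify_support(m, ev2)
  expect_identical(cls2$classes$class[cls2$classes$reaction == "RL1"],
                   "characterized_enzyme")
  # unknown ECO codes rank as 'other', with a warning
  ev3 <- list(evidence_item("s6", "gene_catalyzes_reaction", "gs1", "RS1",
                            eco_code = "ECO:9999999", references = ref))
  expect_warning(cls3 <- classify_support(m, ev3), "rank table")
  expect_identical(cls3$classes$class[cls3$classes$reaction == "RS1"], "other")
})

test_that("metabolite support fraction counts experimental presence items", {
  m <- fixture_model("chain", n = 4)
  ref <- list(reference("pubmed", "1"))
  ev <- list(evidence_item("m1", "metabolite_present", "M1",
                           eco_code = "ECO:0000269", references = ref))
  expect_equal(metabolite_support_fraction(m, ev), 0.25)
  expect_equal(metabolite_support_fraction(m, list()), 0)
})

test_that("presence/absence contradictions are listed, never resolved", {
  m <- fixture_model("chain")
  ref <- list(reference("pubmed", "1"))
  ev <- list(
    evidence_item("p1", "reaction_present", "R1", eco_code = "ECO:0000269",
                  references = ref),
    evidence_item("n1", "reaction_absent", "R1", eco_code = "ECO:0000269",
                  references = ref),
    evidence_item("p2", "gene_catalyzes_reaction", "g1", "R1",
                  eco_code = "ECO:0000314", references = ref),
    evidence_item("n2", "gene_not_catalyzes_reaction", "g1", "R1",
                  eco_code = "ECO:0000315", references = ref),
    evidence_item("p3", "metabolite_present", "M2", eco_code = "ECO:0000269",
                  references = ref))
  conf <- conflict_report(ev)
  expect_equal(nrow(conf), 2)
  expect_setequal(conf$kind, c("reaction", "gene_reaction"))
  expect_equal(nrow(conflict_report(ev[c(1, 5)])), 0)
  expect_equal(nrow(conflict_report(list())), 0)
})
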