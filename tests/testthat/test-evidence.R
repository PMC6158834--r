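test_that("all seven assertion kinds construct, serialize and re-parse", {
  m <- fixture_model("compartmented")
  m$evidence <- fixture_evidence(m)
  expect_setequal(vapply(m$evidence, `[[`, "", "assertion"), evidence_assertions())
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(evidence_to_table(m2$evidence), evidence_to_table(m$evidence))
  expect_length(parse_evidence(m2), 7)
})

test_that("test cases round-trip with settings, deletions and outcomes", {
  m <- fixture_model("chain")
  growth <- test_case("t_growth", "growth on M1",
    settings = data.frame(reaction = "EX_M1", lower_bound = -10, upper_bound = 0),
    outcomes = data.frame(reaction = "EX_M3", cmp = "greater", value = 1e-6),
    references = list(reference("pubmed", "999", "plate assay")))
  ko <- test_case("t_ko", "knockout abolishes growth",
    settings = data.frame(reaction = "EX_M1", lower_bound = -10, upper_bound = 0),
    deleted_genes = "g1",
    outcomes = data.frame(reaction = "EX_M3", cmp = "less", value = 1e-6))
  m$tests <- list(growth, ko)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  tests <- parse_test_cases(read_sbml(path))
  expect_length(tests, 2)
  byid <- tests[order(vapply(tests, `[[`, "", "id"))]
  expect_identical(byid[[1]]$settings$reaction, "EX_M1")
  expect_identical(byid[[2]]$deleted_genes, "g1")
  expect_identical(byid[[2]]$outcomes$cmp, "less")
  expect_identical(byid[[1]]$references[[1]]$value, "999")
})

test_that("evidence serialization round-trips for random seeded item sets", {
  m <- fixture_model("redundant_routes")
  set.seed(7)
  kinds <- evidence_assertions()
  items <- lapply(1:25, function(i) {
    kind <- sample(kinds, 1)
    subj <- switch(sub("_.*", "", kind),
      gene = sample(m$genes$id, 1),
      reaction = sample(m$reactions$id, 1),
      metabolite = sample(m$metabolites$id, 1))
    targ <- switch(kind,
      gene_catalyzes_reaction = ,
      gene_not_catalyzes_reaction = sample(m$reactions$id, 1),
      gene_localizes_to_compartment = sample(m$compartments$id, 1),
      "")
    evidence_item(sprintf("ev%03d", i), kind, subj, targ,
      eco_code = sprintf("ECO:%07d", sample(c(269, 314, 250, 501), 1)),
      description = paste("experiment", i),
      references = list(reference(sample(c("pubmed", "doi", "patent"), 1),
                                  paste0("ref-", i))))
  })
  m$evidence <- items
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  expect_identical(evidence_to_table(read_sbml(path)$evidence),
                   evidence_to_table(items))
})

test_that("malformed and unknown evidence blocks are skipped, counted, never fatal", {
  m <- fixture_model("chain")
  m$evidence <- fixture_evidence(m)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  txt <- readLines(path)
  bad <- paste0('<ev:evidence id="broken1" subject="x"/>',
                '<ev:evidence id="odd1" assertion="reaction_maybe_present" ',
                'subject="R1" ecoCode="ECO:0000269"/>')
  txt <- sub("<ev:listOfEvidences>", paste0("<ev:listOfEvidences>", bad), txt)
  writeLines(txt, path)
  expect_warning(m2 <- read_sbml(path), "skipped")
  expect_equal(attr(m2, "annotation_warnings"), 2L)
  # the unknown kind is preserved as an opaque record; the broken one dropped
  expect_length(m2$evidence, 8)
  opaque <- Filter(function(e) inherits(e, "gem_evidence_opaque"), m2$evidence)
  expect_length(opaque, 1)
  expect_identical(opaque[[1]]$assertion, "reaction_maybe_present")
})

test_that("evidence census partitions by family and sums to the total", {
  expect_equal(evidence_census(list())$total, 0)
  m <- fixture_model("compartmented")
  ev <- fixture_evidence(m)
  cen <- evidence_census(ev)
  expect_equal(cen$total, 7)
  expect_equal(cen$gene_reaction, 2)
  expect_equal(cen$reaction_presence, 2)
  expect_equal(cen$metabolite_presence, 2)
  expect_equal(cen$localization, 1)
  # engineered 3+2+1 composition
  rid <- m$reactions$id[nzchar(m$reactions$gpr)][1]
  gid <- gpr_genes(m$reactions$gpr[m$reactions$id == rid])[1]
  items <- c(
    lapply(1:3, function(i) evidence_item(paste0("a", i), "gene_catalyzes_reaction",
                                          gid, rid, eco_code = "ECO:0000314",
                                          references = list(reference("pubmed", "1")))),
    lapply(1:2, function(i) evidence_item(paste0("b", i), "reaction_present", rid,
                                          eco_code = "ECO:0000269",
                                          references = list(reference("pubmed", "1")))),
    list(evidence_item("c1", "metabolite_present", m$metabolites$id[1],
                       eco_code = "ECO:0000269",
                       references = list(reference("pubmed", "1")))))
  cen2 <- evidence_census(items)
  expect_equal(unlist(cen2[c("gene_reaction", "reaction_presence",
                             "metabolite_presence", "localization")]),
               c(gene_reaction = 3, reaction_presence = 2,
                 metabolite_presence = 1, localization = 0))
  # property: partition always sums to total for random mixes
  set.seed(11)
  for (i in 1:5) {
    sub <- sample(items, sample(seq_along(items), 1))
    cen3 <- evidence_census(sub)
    expect_equal(cen3$gene_reaction + cen3$reaction_presence +
                 cen3$metabolite_presence + cen3$localization, cen3$total)
  }
})

test_that("evidence items validate their subject and target types", {
  m <- fixture_model("chain")
  good <- evidence_item("e1", "gene_catalyzes_reaction", "g1", "R1",
                        eco_code = "ECO:0000314",
                        references = list(reference("pubmed", "1")))
  expect_length(evidence_validate(m, list(good)), 0)
  bad <- evidence_item("e2", "gene_catalyzes_reaction", "gX", "R1",
                       eco_code = "ECO:0000314",
                       references = list(reference("pubmed", "1")))
  expect_match(evidence_validate(m, list(bad)), "unknown gene", all = FALSE)
  expect_error(evidence_item("e3", "gene_catalyzes_reaction", "g1", "",
                             eco_code = "ECO:0000314"), "target")
  expect_error(evidence_item("e4", "reaction_present", "R1", eco_code = "ECO:99"),
               "ECO")
})
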