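mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r[[1]], subject = r[[2]], pident = 90, length = 300,
               mismatch = 5, gapopen = 0, qstart = 1, qend = 300, sstart = 1,
               send = 300,
               evalue = if (length(r) >= 4) as.numeric(r[[4]]) else 1e-50,
               bitscore = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

test_that("mutual best hits are paired; one-sided bests are not", {
  ab <- mk_hits(list("a1", "b1", 100))
  ba <- mk_hits(list("b1", "a1", 95))
  map <- reciprocal_best_hits(ab, ba)
  expect_identical(map$pairs, data.frame(a = "a1", b = "b1"))
  # a1's best is b1 but b1 prefers a2: a1 stays unmapped
  ab2 <- mk_hits(list("a1", "b1", 100), list("a2", "b1", 90))
  ba2 <- mk_hits(list("b1", "a2", 99), list("b1", "a1", 80))
  map2 <- reciprocal_best_hits(ab2, ba2)
  expect_identical(map2$pairs, data.frame(a = "a2", b = "b1"))
  expect_identical(map2$unmapped_a, "a1")
})

test_that("ties break by e-value then lexicographic subject id", {
  ab <- mk_hits(list("a1", "b2", 100, 1e-40), list("a1", "b1", 100, 1e-50))
  ba <- mk_hits(list("b1", "a1", 100), list("b2", "a1", 100))
  expect_identical(reciprocal_best_hits(ab, ba)$pairs$b, "b1")  # lower e-value
  ab2 <- mk_hits(list("a1", "b2", 100, 1e-50), list("a1", "b1", 100, 1e-50))
  expect_identical(reciprocal_best_hits(ab2, ba)$pairs$b, "b1")  # lexicographic
})

test_that("duplicate hit rows keep the best-scoring copy with a warning", {
  ab <- mk_hits(list("a1", "b1", 80), list("a1", "b1", 100))
  ba <- mk_hits(list("b1", "a1", 90))
  expect_warning(map <- reciprocal_best_hits(ab, ba), "duplicate")
  expect_equal(nrow(map$pairs), 1)
})

test_that("RBH equals the exhaustive double-argmax oracle on seeded matrices", {
  for (seed in c(1, 7, 42)) {
    fx <- fixture_hits(n = 20, seed = seed)
    map <- reciprocal_best_hits(fx$hits_ab, fx$hits_ba)
    want <- oracle_rbh(fx$scores)
    expect_identical(map$pairs$a, want$a, info = paste("seed", seed))
    expect_identical(map$pairs$b, want$b, info = paste("seed", seed))
    # bijectivity and disjointness invariants
    expect_false(anyDuplicated(map$pairs$a) > 0)
    expect_false(anyDuplicated(map$pairs$b) > 0)
    expect_length(intersect(map$unmapped_a, map$pairs$a), 0)
  }
})

test_that("swapping the hit tables transposes the map exactly", {
  fx <- fixture_hits(n = 15, seed = 3)
  fwd <- reciprocal_best_hits(fx$hits_ab, fx$hits_ba)
  rev <- reciprocal_best_hits(fx$hits_ba, fx$hits_ab)
  expect_identical(fwd$pairs$a, rev$pairs[order(rev$pairs$b), ]$b)
  expect_identical(fwd$pairs$b, rev$pairs[order(rev$pairs$b), ]$a)
})

test_that("hit tables read from disk in 12-column tabular format", {
  fx <- fixture_hits(n = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fx$hits_ab, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  back <- read_hits(path)
  expect_identical(names(back)[c(1, 2, 11, 12)],
                   c("query", "subject", "evalue", "bitscore"))
  expect_equal(nrow(back), nrow(fx$hits_ab))
  writeLines("a\tb\t1", path)
  expect_error(read_hits(path), "12")
})

test_that("model translation rewrites GPRs and reports unmapped genes", {
  m <- fixture_model("redundant_routes")
  m$reactions$gpr[m$reactions$id == "RS1"] <- "gs1 or gs2"
  m$reactions$gpr[m$reactions$id == "RS2"] <- "gs1 and gs2"
  m$evidence <- list(
    evidence_item("e1", "gene_catalyzes_reaction", "gs1", "RS1",
                  eco_code = "ECO:0000314",
                  references = list(reference("pubmed", "1"))),
    evidence_item("e2", "gene_catalyzes_reaction", "gl3", "RL3",
                  eco_code = "ECO:0000314",
                  references = list(reference("pubmed", "2"))))
  map <- list(pairs = data.frame(
    a = c("gs1", "gl1", "gl2"), b = c("B_s1", "B_l1", "B_l2"),
    stringsAsFactors = FALSE), unmapped_a = character(), unmapped_b = character())
  class(map) <- "ortholog_map"
  out <- translate_model(m, map, "ab")
  tr <- out$model
  expect_identical(tr$reactions$gpr[tr$reactions$id == "RS1"], "B_s1")
  expect_identical(tr$reactions$gpr[tr$reactions$id == "RS2"], "B_s1")
  expect_identical(out$report$degraded_reactions, "RS2")
  expect_true(all(c("gs2", "gl3") %in% out$report$unmapped_genes))
  # gene layer swapped; reaction/metabolite layers untouched
  expect_setequal(tr$genes$id, c("B_s1", "B_l1", "B_l2"))
  expect_identical(tr$reactions$id, m$reactions$id)
  expect_identical(tr$metabolites$id, m$metabolites$id)
  # fully emptied GPR leaves the reaction in place, gene-less
  expect_identical(tr$reactions$gpr[tr$reactions$id == "RL3"], "")
  # gene-subject evidence rewritten or dropped with a log
  expect_identical(out$report$dropped_evidence, "e2")
  expect_identical(tr$evidence[[1]]$subject, "B_s1")
})

test_that("translation round-trips over a complete bijection", {
  m <- fixture_model("chain", n = 4)
  map <- list(pairs = data.frame(a = m$genes$id,
                                 b = paste0("B_", m$genes$id),
                                 stringsAsFactors = FALSE),
              unmapped_a = character(), unmapped_b = character())
  class(map) <- "ortholog_map"
  there <- translate_model(m, map, "ab")$model
  back <- translate_model(there, map, "ba")$model
  expect_identical(back$reactions$gpr, m$reactions$gpr)
  expect_setequal(back$genes$id, m$genes$id)
})
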