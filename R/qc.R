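## Structural quality control: mass balance, dead-end metabolites, census
## statistics, and the evidence-support classification of reactions.

#' Check a reaction's elemental and charge balance
#'
#' The imbalance of element `e` is the product-side total minus the
#' substrate-side total, `sum coeff * count(e)` over participants. A
#' reaction is balanced when every element's imbalance is zero and, when
#' all participants carry a charge, the charge imbalance is zero too.
#' When any participant lacks a formula, carries a wildcard element
#' (R-group), or has an unparseable formula, the verdict is
#' `undetermined` with a diagnostic; boundary reactions are intrinsically
#' one-sided and also report `undetermined`.
#'
#' @param model a [gem_model()].
#' @param reaction reaction id.
#' @return object of class `gem_balance_report`: `reaction`, `verdict`
#'   (`balanced`/`unbalanced`/`undetermined`), `elements` (named
#'   imbalance vector), `charge` (imbalance or `NA`), `note`.
#' @export
check_mass_balance <- function(model, reaction) {
  if (!reaction %in% model$reactions$id) stop("unknown reaction: ", reaction)
  st <- model$stoichiometry[[reaction]]
  rep <- structure(list(reaction = reaction, verdict = "undetermined",
                        elements = numeric(), charge = NA_real_, note = ""),
                   class = "gem_balance_report")
  if (isTRUE(is_boundary_reaction(model)[[reaction]])) {
    rep$note <- "boundary reaction (one-sided by construction)"
    return(rep)
  }
  mets <- model$metabolites[match(names(st), model$metabolites$id), ]
  elements <- list()
  for (i in seq_along(st)) {
    f <- tryCatch(parse_formula(mets$formula[i]), error = function(e) e)
    if (inherits(f, "error")) {
      rep$note <- paste0("unparseable formula for ", mets$id[i], ": ",
                         conditionMessage(f))
      return(rep)
    }
    if (is.null(f)) {
      rep$note <- paste0("missing formula for ", mets$id[i])
      return(rep)
    }
    if (f$wildcard) {
      rep$note <- paste0("wildcard element in formula of ", mets$id[i])
      return(rep)
    }
    elements[[i]] <- f$counts
  }
  all_el <- unique(unlist(lapply(elements, names)))
  imb <- stats::setNames(numeric(length(all_el)), all_el)
  for (i in seq_along(st)) {
    cnt <- elements[[i]]
    imb[names(cnt)] <- imb[names(cnt)] + st[[i]] * cnt
  }
  rep$elements <- imb
  charged <- !is.na(mets$charge)
  if (all(charged)) rep$charge <- sum(st * mets$charge)
  ok <- all(abs(imb) < 1e-9) && (is.na(rep$charge) || abs(rep$charge) < 1e-9)
  rep$verdict <- if (ok) "balanced" else "unbalanced"
  rep
}

#' @export
print.gem_balance_report <- function(x, ...) {
  cat(sprintf("reaction %s: %s", x$reaction, x$verdict))
  bad <- x$elements[abs(x$elements) > 1e-9]
  if (length(bad)) {
    cat(" (", paste(sprintf("%s %+g", names(bad), bad), collapse = ", "), ")", sep = "")
  }
  if (nzchar(x$note)) cat(" -", x$note)
  cat("\n")
  invisible(x)
}

#' Balance-check every reaction
#'
#' @param model a [gem_model()].
#' @return data.frame: reaction, verdict, note.
#' @export
mass_balance_table <- function(model) {
  do.call(rbind, lapply(model$reactions$id, function(rid) {
    r <- check_mass_balance(model, rid)
    data.frame(reaction = rid, verdict = r$verdict, note = r$note,
               stringsAsFactors = FALSE)
  }))
}

#' Find dead-end metabolites
#'
#' Connectivity-based definition: a non-boundary metabolite is a dead end
#' when, accounting for reaction reversibility, it can only ever be
#' produced or only ever be consumed (or touches no reaction at all).
#' Reactions associated with such metabolites are guaranteed to carry no
#' flux at steady state. Boundary species are excluded.
#'
#' @param model a [gem_model()].
#' @return sorted character vector of dead-end metabolite ids.
#' @export
find_dead_ends <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  producible <- stats::setNames(logical(length(mets)), mets)
  consumable <- stats::setNames(logical(length(mets)), mets)
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    lb <- model$reactions$lower_bound[i]
    ub <- model$reactions$upper_bound[i]
    st <- model$stoichiometry[[rid]]
    st <- st[names(st) %in% mets]
    for (mid in names(st)) {
      coef <- st[[mid]]
      fwd_prod <- coef > 0; fwd_cons <- coef < 0
      if (ub > 0) {
        producible[mid] <- producible[mid] || fwd_prod
        consumable[mid] <- consumable[mid] || fwd_cons
      }
      if (lb < 0) {
        producible[mid] <- producible[mid] || fwd_cons
        consumable[mid] <- consumable[mid] || fwd_prod
      }
    }
  }
  sort(mets[!(producible & consumable)])
}

#' Census statistics of a model
#'
#' The model statistics table: reaction counts (total, transport,
#' boundary, unbalanced, annotated, gene-less, with presence evidence,
#' with an evidence-backed gene link), metabolite counts (total,
#' ChEBI-annotated, dead-end), gene counts (total, known function,
#' verified/predicted location), the evidence census by family, and test
#' totals when a suite report is supplied.
#'
#' Definitions: a transport reaction is a non-boundary reaction touching
#' at least two compartments; an annotated reaction carries at least one
#' database cross-reference; `no_genes` counts empty GPRs; a gene has
#' known function when an experimental-rank gene-reaction link exists,
#' verified location when an experimental-rank localization item exists,
#' predicted location when its only localization support is a prediction.
#'
#' @param model a [gem_model()].
#' @param evidence evidence list (defaults to the model's own).
#' @param tests test list (defaults to the model's own).
#' @param suite optional [run_suite()] report for the test totals.
#' @param eco_ranks ECO rank table, see [eco_rank_table()].
#' @return nested list of class `gem_stats_report`.
#' @export
model_statistics <- function(model, evidence = model$evidence,
                             tests = model$tests, suite = NULL,
                             eco_ranks = eco_rank_table()) {
  bnd <- is_boundary_reaction(model)
  comp_of <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  transport <- vapply(model$reactions$id, function(rid) {
    if (bnd[[rid]]) return(FALSE)
    length(unique(stats::na.omit(comp_of[names(model$stoichiometry[[rid]])]))) >= 2
  }, logical(1))
  bal <- mass_balance_table(model)
  kinds <- vapply(evidence, function(e) e$assertion %||% "", character(1))
  subj <- vapply(evidence, function(e) e$subject %||% "", character(1))
  targ <- vapply(evidence, function(e) e$target %||% "", character(1))
  rank_of <- function(e) .eco_rank(e$eco_code, eco_ranks)

  pres_rxn <- unique(subj[kinds == "reaction_present"])
  link_rxn <- unique(targ[kinds == "gene_catalyzes_reaction"])
  known_fun_genes <- unique(subj[kinds == "gene_catalyzes_reaction" &
    vapply(evidence, function(e) rank_of(e) == "experimental", logical(1))])
  loc_items <- kinds == "gene_localizes_to_compartment"
  loc_exp <- unique(subj[loc_items &
    vapply(evidence, function(e) rank_of(e) == "experimental", logical(1))])
  loc_any <- unique(subj[loc_items])

  dead <- find_dead_ends(model)
  rep <- list(
    reactions = list(
      total = nrow(model$reactions),
      transport = sum(transport),
      boundary = sum(bnd),
      unbalanced = sum(bal$verdict == "unbalanced"),
      annotated = sum(nzchar(model$reactions$xrefs)),
      no_genes = sum(!nzchar(model$reactions$gpr)),
      evidence_for_presence = sum(model$reactions$id %in% pres_rxn),
      known_gene = sum(model$reactions$id %in% link_rxn)),
    metabolites = list(
      total = nrow(model$metabolites),
      annotated = sum(!is.na(model$metabolites$chebi)),
      dead_end = length(dead)),
    genes = list(
      total = nrow(model$genes),
      known_function = sum(model$genes$id %in% known_fun_genes),
      verified_location = sum(model$genes$id %in% loc_exp),
      predicted_location = sum(model$genes$id %in% setdiff(loc_any, loc_exp))),
    evidence = evidence_census(evidence),
    tests = list(total = length(tests),
                 passing = if (is.null(suite)) NA_integer_ else suite$passed,
                 failing = if (is.null(suite)) NA_integer_ else suite$failed))
  class(rep) <- "gem_stats_report"
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gem_stats_report <- function(x, ...) {
  p <- function(lbl, l) {
    cat(lbl, ": ", paste(sprintf("%s %s", names(l), unlist(l)), collapse = ", "),
        "\n", sep = "")
  }
  p("reactions", x$reactions); p("metabolites", x$metabolites)
  p("genes", x$genes); p("evidence", x$evidence); p("tests", x$tests)
  invisible(x)
}

#' Default ECO support-rank table
#'
#' Maps Evidence and Conclusion Ontology accessions to a coarse support
#' rank used by the census and the reaction support classification:
#' `experimental` (direct assays, mutant phenotypes, expert-curated
#' experimental statements), `similarity` (sequence similarity /
#' orthology inference), `prediction` (computational predictions,
#' automatic assertions), `other`. The packaged defaults live in
#' `inst/extdata/eco_ranks.tsv` and can be replaced by any two-column
#' (`eco`, `rank`) table.
#'
#' @param path optional path to a custom table.
#' @return data.frame with columns `eco`, `rank`.
#' @export
.eco_cache <- new.env(parent = emptyenv())

eco_rank_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.eco_cache$default)) {
      .eco_cache$default <- utils::read.delim(
        system.file("extdata", "eco_ranks.tsv", package = "gemevidence"),
        stringsAsFactors = FALSE, comment.char = "#")
    }
    return(.eco_cache$default)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

.eco_rank <- function(eco, eco_ranks) {
  i <- match(eco, eco_ranks$eco)
  if (is.na(i)) "other" else eco_ranks$rank[i]
}

#' Classify the experimental support of each reaction
#'
#' Each reaction receives the strongest class supported by its own
#' presence evidence and its genes' link evidence, in decreasing order of
#' support: `characterized_enzyme` (an experimental-rank gene-reaction
#' link), `measured_unknown_enzyme` (experimental-rank evidence that the
#' reaction occurs, but no characterized gene), `strong_similarity` (a
#' gene link inferred by sequence similarity), `other` (any remaining
#' evidence, or links with unknown ECO codes, which are counted with a
#' warning), and `no_evidence`.
#'
#' @param model a [gem_model()].
#' @param evidence evidence list (defaults to the model's own).
#' @param eco_ranks ECO rank table, see [eco_rank_table()].
#' @return list with `classes` (data.frame reaction/class) and
#'   `fractions` (named numeric summing to 1 over the five classes).
#' @export
classify_support <- function(model, evidence = model$evidence,
                             eco_ranks = eco_rank_table()) {
  lv <- c("characterized_enzyme", "measured_unknown_enzyme",
          "strong_similarity", "other", "no_evidence")
  score <- stats::setNames(rep(5L, nrow(model$reactions)), model$reactions$id)
  unknown_eco <- 0L
  for (e in evidence) {
    kind <- e$assertion
    rid <- if (kind %in% c("gene_catalyzes_reaction")) e$target
           else if (kind == "reaction_present") e$subject
           else next
    if (!rid %in% names(score)) next
    rk <- .eco_rank(e$eco_code, eco_ranks)
    if (!e$eco_code %in% eco_ranks$eco) unknown_eco <- unknown_eco + 1L
    cls <- if (kind == "gene_catalyzes_reaction") {
      switch(rk, experimental = 1L, similarity = 3L, 4L)
    } else {
      switch(rk, experimental = 2L, 4L)
    }
    score[rid] <- min(score[rid], cls)
  }
  if (unknown_eco > 0L) {
    warning(sprintf("%d evidence item(s) with ECO codes missing from the rank table; classed as 'other'",
                    unknown_eco))
  }
  classes <- data.frame(reaction = names(score), class = lv[score],
                        stringsAsFactors = FALSE)
  fr <- table(factor(classes$class, levels = lv)) / max(1L, nrow(classes))
  list(classes = classes, fractions = stats::setNames(as.numeric(fr), lv))
}

#' Fraction of metabolites with experimental support
#'
#' @param model a [gem_model()].
#' @param evidence evidence list.
#' @param eco_ranks ECO rank table.
#' @return fraction in `[0, 1]` of metabolites with an
#'   experimental-rank presence item.
#' @export
metabolite_support_fraction <- function(model, evidence = model$evidence,
                                        eco_ranks = eco_rank_table()) {
  if (nrow(model$metabolites) == 0) return(0)
  measured <- unique(vapply(
    Filter(function(e) e$assertion == "metabolite_present" &&
             .eco_rank(e$eco_code, eco_ranks) == "experimental", evidence),
    `[[`, "", "subject"))
  mean(model$metabolites$id %in% measured)
}

#' Report contradictory evidence pairs
#'
#' Lists pairs of items asserting both presence and absence of the same
#' entity or link. Conflicts are reported for curation, never
#' auto-resolved: a negative growth result can coexist with a positive
#' enzyme assay (partial redundancy), so resolution needs a curator.
#'
#' @param evidence list of [evidence_item()] objects.
#' @return data.frame: `kind` (entity family), `key` (the contested
#'   subject/link), `positive_id`, `negative_id`.
#' @export
conflict_report <- function(evidence) {
  out <- data.frame(kind = character(), key = character(),
                    positive_id = character(), negative_id = character(),
                    stringsAsFactors = FALSE)
  pairs <- list(
    c("reaction_present", "reaction_absent", "reaction"),
    c("metabolite_present", "metabolite_absent", "metabolite"),
    c("gene_catalyzes_reaction", "gene_not_catalyzes_reaction", "gene_reaction"))
  key_of <- function(e) if (nzchar(e$target)) paste0(e$subject, "->", e$target) else e$subject
  for (p in pairs) {
    pos <- Filter(function(e) e$assertion == p[1], evidence)
    neg <- Filter(function(e) e$assertion == p[2], evidence)
    for (ep in pos) for (en in neg) {
      if (key_of(ep) == key_of(en)) {
        out <- rbind(out, data.frame(kind = p[3], key = key_of(ep),
                                     positive_id = ep$id, negative_id = en$id,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}
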