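#' Literature evidence attached to a model component
#'
#' An evidence item is one referenced assertion about the network: a
#' gene-reaction link (positive or negative), presence or absence of a
#' reaction or metabolite, or the subcellular localization of a gene
#' product. Each item carries an Evidence and Conclusion Ontology (ECO)
#' accession grading the support, a short description of the underlying
#' experiment, and literature references.
#'
#' Absence assertions (`reaction_absent`, `metabolite_absent`,
#' `gene_not_catalyzes_reaction`) are stored as negative results only: they
#' are never auto-applied to the network and feed the QC
#' [conflict_report()] instead.
#'
#' @param id item identifier.
#' @param assertion one of `gene_catalyzes_reaction`,
#'   `gene_not_catalyzes_reaction`, `reaction_present`, `reaction_absent`,
#'   `metabolite_present`, `metabolite_absent`,
#'   `gene_localizes_to_compartment`.
#' @param subject gene, reaction, or metabolite id (the entity the
#'   assertion is about).
#' @param target reaction or compartment id for link/localization
#'   assertions; `""` otherwise.
#' @param eco_code ECO accession (`ECO:nnnnnnn`).
#' @param description short free-text experiment summary.
#' @param references list of [reference()] objects.
#' @return object of class `gem_evidence`.
#' @export
evidence_item <- function(id, assertion, subject, target = "",
                          eco_code = "ECO:0000000", description = "",
                          references = list()) {
  assertion <- match.arg(assertion, evidence_assertions())
  if (!grepl("^ECO:[0-9]{7}$", eco_code)) {
    stop("eco_code must match ECO:nnnnnnn, got: ", eco_code)
  }
  needs_target <- assertion %in% c("gene_catalyzes_reaction",
                                   "gene_not_catalyzes_reaction",
                                   "gene_localizes_to_compartment")
  if (needs_target && !nzchar(target)) {
    stop("assertion ", assertion, " requires a target id")
  }
  ## a literature-backed item needs a reference; purely computational
  ## items (prediction-rank ECO codes) may stand alone
  if (length(references) == 0 &&
      !identical(.eco_rank(eco_code, eco_rank_table()), "prediction")) {
    stop("evidence item ", id,
         " needs at least one reference or a prediction-type ECO code")
  }
  structure(list(id = as.character(id), assertion = assertion,
                 subject = as.character(subject), target = as.character(target),
                 eco_code = eco_code, description = as.character(description),
                 references = references),
            class = "gem_evidence")
}

#' The recognized assertion kinds
#' @return character vector of the seven assertion kinds.
#' @export
evidence_assertions <- function() {
  c("gene_catalyzes_reaction", "gene_not_catalyzes_reaction",
    "reaction_present", "reaction_absent",
    "metabolite_present", "metabolite_absent",
    "gene_localizes_to_compartment")
}

#' A literature reference
#'
#' @param kind one of `pubmed`, `doi`, `pmc`, `patent`, `url`.
#' @param value accession string (PMID, DOI, ...).
#' @param description optional short free text.
#' @return object of class `gem_reference`.
#' @export
reference <- function(kind, value, description = "") {
  kind <- match.arg(kind, c("pubmed", "doi", "pmc", "patent", "url"))
  if (!nzchar(value)) stop("reference value must be non-empty")
  structure(list(kind = kind, value = as.character(value),
                 description = as.character(description)),
            class = "gem_reference")
}

#' A phenotype test case
#'
#' A test case stores one simulatable phenotype observation: the medium
#' (boundary-bound overrides), the deleted genes, and flux-threshold
#' outcomes the solution must satisfy. When a test is run, every boundary
#' reaction not named in `settings` is restricted to only excreting its
#' metabolite, so `settings` fully defines the available medium.
#'
#' @param id,name identifiers.
#' @param settings data.frame with columns `reaction`, `lower_bound`,
#'   `upper_bound` (bound overrides defining the simulation condition).
#' @param deleted_genes character vector of inactivated gene ids.
#' @param outcomes data.frame with columns `reaction`, `cmp`
#'   (`"greater"`/`"less"`) and `value` (flux threshold); at least one row.
#' @param references list of [reference()] objects.
#' @return object of class `gem_test`.
#' @export
test_case <- function(id, name = id, settings = NULL, deleted_genes = character(),
                      outcomes, references = list()) {
  if (is.null(settings)) {
    settings <- data.frame(reaction = character(), lower_bound = numeric(),
                           upper_bound = numeric(), stringsAsFactors = FALSE)
  }
  settings <- as.data.frame(settings, stringsAsFactors = FALSE)
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  if (nrow(outcomes) == 0) stop("a test case needs at least one outcome")
  if (!all(outcomes$cmp %in% c("greater", "less"))) {
    stop("outcome cmp must be 'greater' or 'less'")
  }
  structure(list(id = as.character(id), name = as.character(name),
                 settings = settings,
                 deleted_genes = as.character(deleted_genes),
                 outcomes = outcomes, references = references),
            class = "gem_test")
}

#' Flatten evidence items into a table
#'
#' One row per item; references are collapsed into a `|`-separated token
#' column (`kind:value`). This is the delimited export form of the
#' model's evidence record.
#'
#' @param items list of [evidence_item()] objects.
#' @return data.frame sorted by item id.
#' @export
evidence_to_table <- function(items) {
  if (length(items) == 0) {
    return(data.frame(id = character(), assertion = character(),
                      subject = character(), target = character(),
                      eco_code = character(), description = character(),
                      references = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(items, function(e) {
    refs <- paste(vapply(e$references, function(r) paste0(r$kind, ":", r$value),
                         character(1)), collapse = "|")
    data.frame(id = e$id, assertion = e$assertion, subject = e$subject,
               target = e$target, eco_code = e$eco_code,
               description = e$description, references = refs,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Census of evidence items by assertion family
#'
#' Partitions items into the families used by the model statistics table:
#' gene-reaction links (positive and negative), reaction presence/absence,
#' metabolite presence/absence, and gene-compartment localization. Family
#' counts always sum to the total.
#'
#' @param items list of [evidence_item()] objects.
#' @return named list: `total`, `gene_reaction`, `reaction_presence`,
#'   `metabolite_presence`, `localization`.
#' @export
evidence_census <- function(items) {
  kinds <- vapply(items, `[[`, "", "assertion")
  fam <- function(kk) sum(kinds %in% kk)
  out <- list(
    total = length(items),
    gene_reaction = fam(c("gene_catalyzes_reaction", "gene_not_catalyzes_reaction")),
    reaction_presence = fam(c("reaction_present", "reaction_absent")),
    metabolite_presence = fam(c("metabolite_present", "metabolite_absent")),
    localization = fam("gene_localizes_to_compartment")
  )
  stopifnot(out$gene_reaction + out$reaction_presence +
            out$metabolite_presence + out$localization == out$total)
  out
}

#' Extract the evidence items carried by a model
#'
#' @param model a [gem_model()] read with [read_sbml()] or built in code.
#' @return list of [evidence_item()] objects.
#' @export
parse_evidence <- function(model) model$evidence

#' Extract the test cases carried by a model
#'
#' @param model a [gem_model()].
#' @return list of [test_case()] objects.
#' @export
parse_test_cases <- function(model) model$tests

#' Check evidence items against a model's component ids
#'
#' @param model a [gem_model()].
#' @param items evidence list (defaults to the model's own).
#' @return character vector of problems (unknown subjects/targets).
#' @export
evidence_validate <- function(model, items = model$evidence) {
  probs <- character()
  ids <- list(gene = model$genes$id, reaction = model$reactions$id,
              metabolite = model$metabolites$id, compartment = model$compartments$id)
  subject_type <- c(gene_catalyzes_reaction = "gene",
                    gene_not_catalyzes_reaction = "gene",
                    reaction_present = "reaction", reaction_absent = "reaction",
                    metabolite_present = "metabolite", metabolite_absent = "metabolite",
                    gene_localizes_to_compartment = "gene")
  target_type <- c(gene_catalyzes_reaction = "reaction",
                   gene_not_catalyzes_reaction = "reaction",
                   gene_localizes_to_compartment = "compartment")
  for (e in items) {
    stype <- subject_type[[e$assertion]]
    if (!(e$subject %in% ids[[stype]])) {
      probs <- c(probs, sprintf("evidence %s: unknown %s '%s'", e$id, stype, e$subject))
    }
    if (e$assertion %in% names(target_type)) {
      ttype <- target_type[[e$assertion]]
      if (!(e$target %in% ids[[ttype]])) {
        probs <- c(probs, sprintf("evidence %s: unknown %s '%s'", e$id, ttype, e$target))
      }
    }
  }
  probs
}
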