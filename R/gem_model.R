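#' Construct a genome-scale metabolic model
#'
#' A `gem_model` is the in-memory form of a constraint-based metabolic
#' network: compartments, metabolites, reactions with flux bounds and
#' gene-protein-reaction (GPR) rules, genes, and a linear objective.
#' Evidence items and test cases attached to the model (see
#' [evidence_item()] and [test_case()]) travel with it through SBML
#' serialization.
#'
#' Flux bounds follow the usual mmol/gDW/h convention. Stoichiometric
#' coefficients are signed: negative for substrates, positive for products.
#' A reaction is a boundary (exchange/drain) reaction when exactly one
#' non-boundary metabolite participates in it; models that instead mark
#' external species with `boundary = TRUE` are handled equivalently, since
#' boundary species are excluded from the steady-state constraint.
#'
#' @param id model identifier.
#' @param name human-readable name.
#' @param compartments data.frame with columns `id`, `name`.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (Hill notation or `NA`), `charge` (integer or `NA`),
#'   `chebi` (ChEBI accession or `NA`), `boundary` (logical; `TRUE` marks a
#'   species outside the mass balance).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem` (pathway label or `NA`), `gpr` (boolean
#'   rule string over gene ids, `""`/`NA` for gene-less reactions), and
#'   optionally `xrefs` (semicolon-separated `db:accession` tokens).
#' @param stoichiometry named list: reaction id -> named numeric vector of
#'   metabolite coefficients.
#' @param genes data.frame with columns `id`, `name`.
#' @param objective named numeric vector of reaction weights (typically a
#'   single biomass reaction with weight 1).
#' @param evidence list of [evidence_item()] objects.
#' @param tests list of [test_case()] objects.
#' @param notes free-text notes stored in the SBML file.
#'
#' @return an object of class `gem_model`.
#' @seealso [read_sbml()], [write_sbml()], [gem_validate()]
#' @export
gem_model <- function(id, name = id,
                      compartments = data.frame(id = character(), name = character()),
                      metabolites = data.frame(),
                      reactions = data.frame(),
                      stoichiometry = list(),
                      genes = data.frame(id = character(), name = character()),
                      objective = numeric(),
                      evidence = list(),
                      tests = list(),
                      notes = "") {
  metabolites <- .complete_met_table(metabolites)
  reactions <- .complete_rxn_table(reactions)
  genes <- .complete_gene_table(genes)
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  m <- structure(list(
    id = as.character(id), name = as.character(name),
    compartments = compartments,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry,
    genes = genes,
    objective = objective,
    evidence = evidence,
    tests = tests,
    notes = as.character(notes)
  ), class = "gem_model")
  m
}

.complete_met_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- data.frame(id = character(), stringsAsFactors = FALSE)
  }
  defaults <- list(name = NA_character_, compartment = NA_character_,
                   formula = NA_character_, charge = NA_integer_,
                   chebi = NA_character_, boundary = FALSE)
  for (col in names(defaults)) {
    if (is.null(df[[col]])) df[[col]] <- rep(defaults[[col]], nrow(df))
  }
  df$boundary <- isTRUE_vec(df$boundary)
  df
}

.complete_rxn_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- data.frame(id = character(), stringsAsFactors = FALSE)
  }
  defaults <- list(name = NA_character_, lower_bound = 0, upper_bound = 1000,
                   subsystem = NA_character_, gpr = "", xrefs = "")
  for (col in names(defaults)) {
    if (is.null(df[[col]])) df[[col]] <- rep(defaults[[col]], nrow(df))
  }
  df$gpr[is.na(df$gpr)] <- ""
  df$xrefs[is.na(df$xrefs)] <- ""
  df
}

.complete_gene_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- data.frame(id = character(), stringsAsFactors = FALSE)
  }
  if (is.null(df$name)) df$name <- rep(NA_character_, nrow(df))
  df
}

isTRUE_vec <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  x
}

#' @export
print.gem_model <- function(x, ...) {
  cat(sprintf("gem_model <%s>: %d compartments, %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$compartments), nrow(x$metabolites),
              nrow(x$reactions), nrow(x$genes)))
  cat(sprintf("  evidence items: %d, test cases: %d\n",
              length(x$evidence), length(x$tests)))
  if (length(x$objective)) {
    cat("  objective:", paste(sprintf("%s (%g)", names(x$objective), x$objective),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a model's internal cross-references and invariants
#'
#' Checks that all ids are unique and non-empty, every metabolite's
#' compartment exists, every stoichiometry entry and objective weight
#' references a known reaction/metabolite, every GPR leaf references a
#' declared gene, bounds are ordered, and no reaction has an empty
#' stoichiometry.
#'
#' @param model a [gem_model()].
#' @return character vector of problems; `character(0)` when the model is
#'   valid.
#' @export
gem_validate <- function(model) {
  probs <- character()
  chk_unique <- function(ids, what) {
    if (anyDuplicated(ids)) {
      probs <<- c(probs, sprintf("duplicate %s id(s): %s", what,
                                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    if (any(!nzchar(ids) | is.na(ids))) {
      probs <<- c(probs, sprintf("empty %s id present", what))
    }
  }
  chk_unique(model$compartments$id, "compartment")
  chk_unique(model$metabolites$id, "metabolite")
  chk_unique(model$reactions$id, "reaction")
  chk_unique(model$genes$id, "gene")

  bad_comp <- setdiff(stats::na.omit(model$metabolites$compartment), model$compartments$id)
  if (length(bad_comp)) {
    probs <- c(probs, sprintf("unknown compartment(s): %s", paste(bad_comp, collapse = ", ")))
  }
  miss_st <- setdiff(model$reactions$id, names(model$stoichiometry))
  if (length(miss_st)) {
    probs <- c(probs, sprintf("reaction(s) without stoichiometry: %s",
                              paste(miss_st, collapse = ", ")))
  }
  for (rid in intersect(model$reactions$id, names(model$stoichiometry))) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0) {
      probs <- c(probs, sprintf("reaction %s has empty stoichiometry", rid))
    }
    unk <- setdiff(names(st), model$metabolites$id)
    if (length(unk)) {
      probs <- c(probs, sprintf("reaction %s references unknown metabolite(s): %s",
                                rid, paste(unk, collapse = ", ")))
    }
  }
  if (nrow(model$reactions)) {
    bad <- model$reactions$lower_bound > model$reactions$upper_bound
    if (any(bad)) {
      probs <- c(probs, sprintf("lower_bound > upper_bound for: %s",
                                paste(model$reactions$id[bad], collapse = ", ")))
    }
    for (i in seq_len(nrow(model$reactions))) {
      g <- model$reactions$gpr[i]
      if (nzchar(g)) {
        leaves <- gpr_genes(gpr_parse(g))
        unk <- setdiff(leaves, model$genes$id)
        if (length(unk)) {
          probs <- c(probs, sprintf("reaction %s GPR references undeclared gene(s): %s",
                                    model$reactions$id[i], paste(unk, collapse = ", ")))
        }
      }
    }
  }
  unk_obj <- setdiff(names(model$objective), model$reactions$id)
  if (length(unk_obj)) {
    probs <- c(probs, sprintf("objective references unknown reaction(s): %s",
                              paste(unk_obj, collapse = ", ")))
  }
  probs
}

#' Classify boundary reactions
#'
#' A reaction is a boundary (exchange) reaction when exactly one
#' non-boundary metabolite participates: the one-sided drain/source form
#' `A ->` or `-> A`, or the explicit-external-species form `A -> A_ext`
#' with `A_ext` flagged as a boundary species.
#'
#' @param model a [gem_model()].
#' @return named logical vector over reaction ids.
#' @export
is_boundary_reaction <- function(model) {
  bnd_species <- model$metabolites$id[model$metabolites$boundary]
  out <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    sum(!(names(st) %in% bnd_species)) == 1L
  }, logical(1))
  names(out) <- model$reactions$id
  out
}

#' @rdname is_boundary_reaction
#' @details `boundary_metabolite()` returns, for each boundary reaction,
#'   the id of its single non-boundary metabolite (`NA` for internal
#'   reactions).
#' @export
boundary_metabolite <- function(model) {
  bnd_species <- model$metabolites$id[model$metabolites$boundary]
  out <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    inside <- names(st)[!(names(st) %in% bnd_species)]
    if (length(inside) == 1L) inside else NA_character_
  }, character(1))
  names(out) <- model$reactions$id
  out
}

#' Compare two models field by field
#'
#' Structural equality used by the round-trip guarantees: ids, names,
#' stoichiometry, bounds, GPR trees, annotations, objective, evidence and
#' test cases must all agree. Row/element order within tables is not
#' significant.
#'
#' @param a,b models to compare.
#' @param tol numeric tolerance for bounds/coefficients.
#' @return `TRUE`, or a character vector describing the first differences.
#' @export
gem_equal <- function(a, b, tol = 1e-9) {
  diffs <- character()
  cmp_tab <- function(ta, tb, what) {
    ta <- ta[order(ta$id), , drop = FALSE]
    tb <- tb[order(tb$id), , drop = FALSE]
    if (!identical(ta$id, tb$id)) {
      diffs <<- c(diffs, sprintf("%s ids differ", what)); return(invisible())
    }
    for (col in intersect(names(ta), names(tb))) {
      va <- ta[[col]]; vb <- tb[[col]]
      same <- if (is.numeric(va)) {
        (is.na(va) & is.na(vb)) | (!is.na(va) & !is.na(vb) & abs(va - vb) <= tol)
      } else {
        (is.na(va) & is.na(vb)) | (!is.na(va) & !is.na(vb) & va == vb)
      }
      if (!all(same)) {
        diffs <<- c(diffs, sprintf("%s column %s differs for: %s", what, col,
                                   paste(ta$id[!same], collapse = ", ")))
      }
    }
  }
  cmp_tab(a$compartments, b$compartments, "compartment")
  cmp_tab(a$metabolites, b$metabolites, "metabolite")
  ra <- a$reactions; rb <- b$reactions
  # GPR strings compare as trees, not as text
  ra$gpr <- vapply(ra$gpr, function(g) gpr_format(gpr_parse(g)), character(1))
  rb$gpr <- vapply(rb$gpr, function(g) gpr_format(gpr_parse(g)), character(1))
  cmp_tab(ra, rb, "reaction")
  cmp_tab(a$genes, b$genes, "gene")
  for (rid in intersect(names(a$stoichiometry), names(b$stoichiometry))) {
    sa <- a$stoichiometry[[rid]]; sb <- b$stoichiometry[[rid]]
    sa <- sa[order(names(sa))]; sb <- sb[order(names(sb))]
    if (!identical(names(sa), names(sb)) || any(abs(sa - sb) > tol)) {
      diffs <- c(diffs, sprintf("stoichiometry differs for %s", rid))
    }
  }
  oa <- a$objective[order(names(a$objective))]
  ob <- b$objective[order(names(b$objective))]
  if (!identical(names(oa), names(ob)) || (length(oa) && any(abs(oa - ob) > tol))) {
    diffs <- c(diffs, "objective differs")
  }
  if (!identical(evidence_to_table(a$evidence), evidence_to_table(b$evidence))) {
    diffs <- c(diffs, "evidence differs")
  }
  if (length(a$tests) != length(b$tests)) {
    diffs <- c(diffs, "test case count differs")
  } else if (length(a$tests)) {
    ta <- a$tests[order(vapply(a$tests, `[[`, "", "id"))]
    tb <- b$tests[order(vapply(b$tests, `[[`, "", "id"))]
    for (i in seq_along(ta)) {
      if (!isTRUE(all.equal(ta[[i]], tb[[i]], tolerance = tol))) {
        diffs <- c(diffs, sprintf("test case %s differs", ta[[i]]$id))
      }
    }
  }
  if (length(diffs)) diffs else TRUE
}
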