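## SBML Level 3 Version 1 + fbc version 2 I/O.
## The evidence/test-case record lives in a dedicated annotation namespace
## on the <model> element; its element and attribute names are documented
## in the package vignette and round-trip bit-exactly.

.ns_core <- "http://www.sbml.org/sbml/level3/version1/core"
.ns_fbc  <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.ns_ev   <- "http://gemevidence.org/annotation/version1"
.ns_rdf  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.ns_bq   <- "http://biomodels.net/biology-qualifiers/"

.sbml_ns <- function() {
  c(s = .ns_core, fbc = .ns_fbc, ev = .ns_ev, rdf = .ns_rdf, bq = .ns_bq)
}

.fmt_num <- function(x) sprintf("%.15g", x)

## SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; model-internal ids are
## opaque strings (JGI transcript ids are purely numeric), so every id is
## prefixed and non-SId characters are mapped. The verbatim id is kept in
## fbc:label (genes) or an originalId attribute in the annotation
## namespace, so translation between strains stays lossless.
.sid <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", id))

.sid_needs_tag <- function(prefix, id) !identical(.sid(prefix, id), paste0(prefix, id))

#' Write a model to SBML Level 3 (fbc)
#'
#' Emits SBML Level 3 Version 1 with the flux-balance-constraints (fbc v2)
#' extension: flux bounds as fbc bound parameters, the objective as an fbc
#' objective, GPR rules as fbc gene-product associations, and ChEBI /
#' database cross-references as MIRIAM-style identifier URIs. Evidence
#' items and test cases are embedded in the model annotation under the
#' package's annotation namespace; the written file re-reads to a model
#' equal to the input (see [gem_equal()]).
#'
#' @param model a valid [gem_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  probs <- gem_validate(model)
  if (length(probs)) {
    stop("refusing to write invalid model:\n  ", paste(probs, collapse = "\n  "))
  }
  doc <- xml2::xml_new_root("sbml",
    xmlns = .ns_core, "xmlns:fbc" = .ns_fbc, "xmlns:ev" = .ns_ev,
    "xmlns:rdf" = .ns_rdf, "xmlns:bqbiol" = .ns_bq,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model",
    id = .sid("", model$id), name = model$name, "fbc:strict" = "false")
  if (nzchar(model$notes)) {
    notes <- xml2::xml_add_child(mnode, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", model$notes)
  }
  if (length(model$evidence) || length(model$tests)) {
    ann <- xml2::xml_add_child(mnode, "annotation")
    .write_evidence_annotation(ann, model$evidence, model$tests)
  }

  if (nrow(model$compartments)) {
    lst <- xml2::xml_add_child(mnode, "listOfCompartments")
    for (i in seq_len(nrow(model$compartments))) {
      cid <- model$compartments$id[i]
      nd <- xml2::xml_add_child(lst, "compartment", id = .sid("C_", cid),
                                constant = "true")
      if (!is.na(model$compartments$name[i])) {
        xml2::xml_set_attr(nd, "name", model$compartments$name[i])
      }
      if (.sid_needs_tag("C_", cid)) xml2::xml_set_attr(nd, "ev:originalId", cid)
    }
  }

  if (nrow(model$metabolites)) {
    lst <- xml2::xml_add_child(mnode, "listOfSpecies")
    for (i in seq_len(nrow(model$metabolites))) {
      mt <- model$metabolites[i, ]
      sid <- .sid("M_", mt$id)
      nd <- xml2::xml_add_child(lst, "species", id = sid,
        compartment = .sid("C_", mt$compartment),
        hasOnlySubstanceUnits = "false",
        boundaryCondition = if (mt$boundary) "true" else "false",
        constant = "false")
      if (!is.na(mt$name)) xml2::xml_set_attr(nd, "name", mt$name)
      if (!is.na(mt$formula)) xml2::xml_set_attr(nd, "fbc:chemicalFormula", mt$formula)
      if (!is.na(mt$charge)) xml2::xml_set_attr(nd, "fbc:charge", as.character(mt$charge))
      if (.sid_needs_tag("M_", mt$id)) xml2::xml_set_attr(nd, "ev:originalId", mt$id)
      if (!is.na(mt$chebi)) {
        .write_miriam(nd, sid, paste0("https://identifiers.org/chebi/", mt$chebi))
      }
    }
  }

  ## fbc flux bounds are parameters; one shared parameter per distinct value
  vals <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  if (length(vals)) {
    pids <- stats::setNames(sprintf("fb_%d", seq_along(vals)), .fmt_num(vals))
    lst <- xml2::xml_add_child(mnode, "listOfParameters")
    for (v in vals) {
      xml2::xml_add_child(lst, "parameter", id = pids[[.fmt_num(v)]],
                          value = .fmt_num(v), constant = "true")
    }
  }

  if (nrow(model$reactions)) {
    lst <- xml2::xml_add_child(mnode, "listOfReactions")
    for (i in seq_len(nrow(model$reactions))) {
      rx <- model$reactions[i, ]
      sid <- .sid("R_", rx$id)
      nd <- xml2::xml_add_child(lst, "reaction", id = sid,
        reversible = if (rx$lower_bound < 0) "true" else "false",
        fast = "false",
        "fbc:lowerFluxBound" = pids[[.fmt_num(rx$lower_bound)]],
        "fbc:upperFluxBound" = pids[[.fmt_num(rx$upper_bound)]])
      if (!is.na(rx$name)) xml2::xml_set_attr(nd, "name", rx$name)
      if (!is.na(rx$subsystem)) xml2::xml_set_attr(nd, "ev:subsystem", rx$subsystem)
      if (.sid_needs_tag("R_", rx$id)) xml2::xml_set_attr(nd, "ev:originalId", rx$id)
      if (nzchar(rx$xrefs)) {
        uris <- vapply(strsplit(rx$xrefs, ";")[[1]], function(tok) {
          parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
          paste0("https://identifiers.org/", parts[1], "/",
                 paste(parts[-1], collapse = ":"))
        }, character(1))
        .write_miriam(nd, sid, uris)
      }
      st <- model$stoichiometry[[rx$id]]
      subs <- st[st < 0]; prods <- st[st > 0]
      if (length(subs)) {
        ln <- xml2::xml_add_child(nd, "listOfReactants")
        for (mid in names(subs)) {
          xml2::xml_add_child(ln, "speciesReference", species = .sid("M_", mid),
                              stoichiometry = .fmt_num(-subs[[mid]]), constant = "true")
        }
      }
      if (length(prods)) {
        ln <- xml2::xml_add_child(nd, "listOfProducts")
        for (mid in names(prods)) {
          xml2::xml_add_child(ln, "speciesReference", species = .sid("M_", mid),
                              stoichiometry = .fmt_num(prods[[mid]]), constant = "true")
        }
      }
      tree <- gpr_parse(rx$gpr)
      if (!is.null(tree)) {
        gpa <- xml2::xml_add_child(nd, "fbc:geneProductAssociation")
        .write_gpa(gpa, tree)
      }
    }
  }

  if (length(model$objective)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = .sid("R_", rid),
                          "fbc:coefficient" = .fmt_num(model$objective[[rid]]))
    }
  }

  if (nrow(model$genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(model$genes))) {
      g <- model$genes[i, ]
      nd <- xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = .sid("G_", g$id),
                                "fbc:label" = g$id)
      if (!is.na(g$name)) xml2::xml_set_attr(nd, "fbc:name", g$name)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

.write_miriam <- function(node, sid, uris) {
  xml2::xml_set_attr(node, "metaid", paste0("meta_", sid))
  ann <- xml2::xml_add_child(node, "annotation")
  rdf <- xml2::xml_add_child(ann, "rdf:RDF")
  dsc <- xml2::xml_add_child(rdf, "rdf:Description",
                             "rdf:about" = paste0("#meta_", sid))
  isq <- xml2::xml_add_child(dsc, "bqbiol:is")
  bag <- xml2::xml_add_child(isq, "rdf:Bag")
  for (u in uris) xml2::xml_add_child(bag, "rdf:li", "rdf:resource" = u)
}

.write_gpa <- function(parent, tree) {
  if (tree$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = .sid("G_", tree$gene))
    return(invisible())
  }
  nd <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
  for (a in tree$args) .write_gpa(nd, a)
}

.write_evidence_annotation <- function(ann, evidence, tests) {
  root <- xml2::xml_add_child(ann, "ev:evidenceData", "xmlns:ev" = .ns_ev)
  if (length(evidence)) {
    le <- xml2::xml_add_child(root, "ev:listOfEvidences")
    for (e in evidence) {
      nd <- xml2::xml_add_child(le, "ev:evidence", id = e$id,
        assertion = e$assertion, subject = e$subject, ecoCode = e$eco_code)
      if (nzchar(e$target)) xml2::xml_set_attr(nd, "target", e$target)
      if (nzchar(e$description)) {
        xml2::xml_add_child(nd, "ev:description", e$description)
      }
      for (r in e$references) .write_reference(nd, r)
    }
  }
  if (length(tests)) {
    lt <- xml2::xml_add_child(root, "ev:listOfTestCases")
    for (tc in tests) {
      nd <- xml2::xml_add_child(lt, "ev:testCase", id = tc$id, name = tc$name)
      if (nrow(tc$settings)) {
        ls <- xml2::xml_add_child(nd, "ev:listOfSettings")
        for (j in seq_len(nrow(tc$settings))) {
          xml2::xml_add_child(ls, "ev:setting",
            reaction = tc$settings$reaction[j],
            lowerBound = .fmt_num(tc$settings$lower_bound[j]),
            upperBound = .fmt_num(tc$settings$upper_bound[j]))
        }
      }
      if (length(tc$deleted_genes)) {
        ld <- xml2::xml_add_child(nd, "ev:listOfDeletions")
        for (g in tc$deleted_genes) xml2::xml_add_child(ld, "ev:deletion", gene = g)
      }
      lo <- xml2::xml_add_child(nd, "ev:listOfOutcomes")
      for (j in seq_len(nrow(tc$outcomes))) {
        xml2::xml_add_child(lo, "ev:outcome",
          reaction = tc$outcomes$reaction[j],
          cmp = tc$outcomes$cmp[j],
          value = .fmt_num(tc$outcomes$value[j]))
      }
      for (r in tc$references) .write_reference(nd, r)
    }
  }
}

.write_reference <- function(node, r) {
  nd <- xml2::xml_add_child(node, "ev:reference", kind = r$kind, value = r$value)
  if (nzchar(r$description)) xml2::xml_set_attr(nd, "description", r$description)
}

#' Read an SBML Level 3 (fbc) model
#'
#' Parses an SBML Level 3 Version 1 file with the fbc extension into a
#' [gem_model()], preserving bounds, objective, GPR trees, formulas,
#' charges, ChEBI/database cross-references, and any embedded evidence
#' items and test cases. Both boundary-reaction encodings are accepted:
#' one-sided stoichiometry (`A ->`) and explicit external species flagged
#' `boundaryCondition="true"`; the encoding seen is recorded in the
#' `boundary_encoding` attribute of the returned model.
#'
#' Malformed evidence/test-case annotation blocks are skipped with a
#' warning (counts in the `annotation_warnings` attribute); they never
#' abort the model read. Cross-reference problems in the model itself do
#' abort, listing the offending ids.
#'
#' @param path SBML file path.
#' @return a [gem_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in ", path, ": ", conditionMessage(e))
  })
  ns <- .sbml_ns()
  mnode <- xml2::xml_find_first(doc, "/s:sbml/s:model", ns)
  if (inherits(mnode, "xml_missing")) stop("no <model> element in ", path)

  orig_id <- function(node, prefix) {
    o <- xml2::xml_attr(node, "ev:originalId", ns)
    if (!is.na(o)) return(o)
    sub(paste0("^", prefix), "", xml2::xml_attr(node, "id"))
  }

  comps <- xml2::xml_find_all(mnode, "./s:listOfCompartments/s:compartment", ns)
  compartments <- data.frame(
    id = vapply(comps, orig_id, "", prefix = "C_"),
    name = vapply(comps, xml2::xml_attr, "", attr = "name"),
    stringsAsFactors = FALSE)

  sps <- xml2::xml_find_all(mnode, "./s:listOfSpecies/s:species", ns)
  sid2met <- character()
  metabolites <- .complete_met_table(data.frame(id = character()))
  if (length(sps)) {
    met_id <- vapply(sps, orig_id, "", prefix = "M_")
    sid2met <- stats::setNames(met_id, vapply(sps, xml2::xml_attr, "", attr = "id"))
    chebi <- vapply(sps, function(nd) {
      uris <- xml2::xml_attr(xml2::xml_find_all(
        nd, ".//rdf:li[contains(@rdf:resource, 'chebi')]", ns), "rdf:resource", ns)
      if (length(uris)) sub("^.*/(CHEBI:[0-9]+)$", "\\1", uris[[1]]) else NA_character_
    }, character(1))
    metabolites <- data.frame(
      id = met_id,
      name = vapply(sps, xml2::xml_attr, "", attr = "name"),
      compartment = sub("^C_", "", vapply(sps, xml2::xml_attr, "", attr = "compartment")),
      formula = vapply(sps, xml2::xml_attr, "", attr = "fbc:chemicalFormula", ns = ns),
      charge = as.integer(vapply(sps, xml2::xml_attr, "", attr = "fbc:charge", ns = ns)),
      chebi = chebi,
      boundary = vapply(sps, xml2::xml_attr, "", attr = "boundaryCondition") == "true",
      stringsAsFactors = FALSE)
    ## compartment attr may carry a sanitized id; map back through originalId
    comp_orig <- stats::setNames(compartments$id,
                                 vapply(comps, xml2::xml_attr, "", attr = "id"))
    raw_comp <- vapply(sps, xml2::xml_attr, "", attr = "compartment")
    hit <- raw_comp %in% names(comp_orig)
    metabolites$compartment[hit] <- comp_orig[raw_comp[hit]]
  }

  pars <- xml2::xml_find_all(mnode, "./s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(
    as.numeric(vapply(pars, xml2::xml_attr, "", attr = "value")),
    vapply(pars, xml2::xml_attr, "", attr = "id"))

  gps <- xml2::xml_find_all(mnode, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gid_label <- stats::setNames(
    vapply(gps, xml2::xml_attr, "", attr = "fbc:label", ns = ns),
    vapply(gps, xml2::xml_attr, "", attr = "fbc:id", ns = ns))
  genes <- data.frame(
    id = unname(gid_label),
    name = vapply(gps, xml2::xml_attr, "", attr = "fbc:name", ns = ns),
    stringsAsFactors = FALSE)

  rxs <- xml2::xml_find_all(mnode, "./s:listOfReactions/s:reaction", ns)
  stoich <- list()
  reactions <- .complete_rxn_table(data.frame(id = character()))
  if (length(rxs)) {
    rx_id <- vapply(rxs, orig_id, "", prefix = "R_")
    getb <- function(nd, which) {
      pid <- xml2::xml_attr(nd, paste0("fbc:", which), ns)
      if (is.na(pid)) stop("reaction ", xml2::xml_attr(nd, "id"),
                           " lacks fbc:", which)
      if (!pid %in% names(parval)) stop("unresolved flux bound parameter: ", pid)
      parval[[pid]]
    }
    xrefs <- vapply(rxs, function(nd) {
      uris <- xml2::xml_attr(xml2::xml_find_all(
        nd, "./s:annotation//rdf:li", ns), "rdf:resource", ns)
      if (!length(uris)) return("")
      paste(vapply(uris, function(u) {
        parts <- strsplit(sub("^https?://identifiers\\.org/", "", u), "/")[[1]]
        paste0(parts[1], ":", paste(parts[-1], collapse = "/"))
      }, character(1)), collapse = ";")
    }, character(1))
    reactions <- data.frame(
      id = rx_id,
      name = vapply(rxs, xml2::xml_attr, "", attr = "name"),
      lower_bound = vapply(rxs, getb, 0, which = "lowerFluxBound"),
      upper_bound = vapply(rxs, getb, 0, which = "upperFluxBound"),
      subsystem = vapply(rxs, xml2::xml_attr, "", attr = "ev:subsystem", ns = ns),
      gpr = vapply(rxs, function(nd) {
        gpa <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation/*", ns)
        if (inherits(gpa, "xml_missing")) return("")
        gpr_format(.read_gpa(gpa, gid_label, ns))
      }, character(1)),
      xrefs = xrefs,
      stringsAsFactors = FALSE)
    unresolved <- character()
    for (i in seq_along(rxs)) {
      refs <- xml2::xml_find_all(rxs[[i]],
        "./s:listOfReactants/s:speciesReference | ./s:listOfProducts/s:speciesReference", ns)
      sgn <- ifelse(xml2::xml_name(xml2::xml_parent(refs)) == "listOfReactants", -1, 1)
      spc <- vapply(refs, xml2::xml_attr, "", attr = "species")
      bad <- !(spc %in% names(sid2met))
      if (any(bad)) unresolved <- c(unresolved, spc[bad])
      coef <- sgn * as.numeric(vapply(refs, xml2::xml_attr, "", attr = "stoichiometry"))
      st <- stats::setNames(coef[!bad], unname(sid2met[spc[!bad]]))
      st <- tapply(st, names(st), sum)
      stoich[[rx_id[i]]] <- stats::setNames(as.numeric(st), names(st))
    }
    if (length(unresolved)) {
      stop("unresolved species reference(s): ", paste(unique(unresolved), collapse = ", "))
    }
  }

  objective <- numeric()
  fo <- xml2::xml_find_all(mnode,
    "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (length(fo)) {
    sid2rx <- stats::setNames(reactions$id,
                              vapply(rxs, xml2::xml_attr, "", attr = "id"))
    objective <- stats::setNames(
      as.numeric(vapply(fo, xml2::xml_attr, "", attr = "fbc:coefficient", ns = ns)),
      unname(sid2rx[vapply(fo, xml2::xml_attr, "", attr = "fbc:reaction", ns = ns)]))
  }

  notes <- ""
  np <- xml2::xml_find_first(mnode, "./s:notes//*[local-name()='p']", ns)
  if (!inherits(np, "xml_missing")) notes <- xml2::xml_text(np)

  parsed <- .read_evidence_annotation(mnode, ns)

  model <- gem_model(
    id = sub("^", "", xml2::xml_attr(mnode, "id")),
    name = xml2::xml_attr(mnode, "name"),
    compartments = compartments, metabolites = metabolites,
    reactions = reactions, stoichiometry = stoich, genes = genes,
    objective = objective, evidence = parsed$evidence, tests = parsed$tests,
    notes = notes)
  probs <- gem_validate(model)
  if (length(probs)) {
    stop("model in ", path, " failed validation:\n  ", paste(probs, collapse = "\n  "))
  }
  enc <- if (any(model$metabolites$boundary)) "explicit_species"
         else if (any(is_boundary_reaction(model))) "one_sided"
         else "none"
  attr(model, "boundary_encoding") <- enc
  attr(model, "annotation_warnings") <- parsed$warnings
  model
}

.read_gpa <- function(node, gid_label, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "fbc:geneProduct", ns)
    lab <- if (gid %in% names(gid_label)) gid_label[[gid]] else sub("^G_", "", gid)
    return(list(op = "gene", gene = lab))
  }
  if (!nm %in% c("and", "or")) stop("unexpected gene association element: ", nm)
  kids <- xml2::xml_children(node)
  list(op = nm, args = lapply(kids, .read_gpa, gid_label = gid_label, ns = ns))
}

.read_evidence_annotation <- function(mnode, ns) {
  warnings <- 0L
  evidence <- list()
  tests <- list()
  evs <- xml2::xml_find_all(mnode,
    "./s:annotation/ev:evidenceData/ev:listOfEvidences/ev:evidence", ns)
  for (nd in evs) {
    e <- tryCatch({
      refs <- lapply(xml2::xml_find_all(nd, "./ev:reference", ns), .read_reference)
      desc <- xml2::xml_find_first(nd, "./ev:description", ns)
      assertion <- xml2::xml_attr(nd, "assertion")
      args <- list(id = xml2::xml_attr(nd, "id"),
                   subject = xml2::xml_attr(nd, "subject"),
                   target = if (is.na(xml2::xml_attr(nd, "target"))) ""
                            else xml2::xml_attr(nd, "target"),
                   eco_code = xml2::xml_attr(nd, "ecoCode"),
                   description = if (inherits(desc, "xml_missing")) ""
                                 else xml2::xml_text(desc),
                   references = refs)
      if (is.na(args$id) || is.na(assertion) || is.na(args$subject) ||
          is.na(args$eco_code)) stop("missing required evidence attribute")
      if (assertion %in% evidence_assertions()) {
        do.call(evidence_item, c(args, list(assertion = assertion)))
      } else {
        ## unknown assertion kind: preserved as an opaque record
        warnings <- warnings + 1L
        structure(c(args[c("id", "subject", "target", "eco_code", "description",
                           "references")], list(assertion = assertion)),
                  class = c("gem_evidence_opaque", "gem_evidence"))
      }
    }, error = function(err) {
      warnings <<- warnings + 1L
      NULL
    })
    if (!is.null(e)) evidence <- c(evidence, list(e))
  }
  tcs <- xml2::xml_find_all(mnode,
    "./s:annotation/ev:evidenceData/ev:listOfTestCases/ev:testCase", ns)
  for (nd in tcs) {
    tc <- tryCatch({
      sets <- xml2::xml_find_all(nd, "./ev:listOfSettings/ev:setting", ns)
      settings <- data.frame(
        reaction = vapply(sets, xml2::xml_attr, "", attr = "reaction"),
        lower_bound = as.numeric(vapply(sets, xml2::xml_attr, "", attr = "lowerBound")),
        upper_bound = as.numeric(vapply(sets, xml2::xml_attr, "", attr = "upperBound")),
        stringsAsFactors = FALSE)
      dels <- xml2::xml_find_all(nd, "./ev:listOfDeletions/ev:deletion", ns)
      outs <- xml2::xml_find_all(nd, "./ev:listOfOutcomes/ev:outcome", ns)
      outcomes <- data.frame(
        reaction = vapply(outs, xml2::xml_attr, "", attr = "reaction"),
        cmp = vapply(outs, xml2::xml_attr, "", attr = "cmp"),
        value = as.numeric(vapply(outs, xml2::xml_attr, "", attr = "value")),
        stringsAsFactors = FALSE)
      refs <- lapply(xml2::xml_find_all(nd, "./ev:reference", ns), .read_reference)
      test_case(id = xml2::xml_attr(nd, "id"), name = xml2::xml_attr(nd, "name"),
                settings = settings,
                deleted_genes = vapply(dels, xml2::xml_attr, "", attr = "gene"),
                outcomes = outcomes, references = refs)
    }, error = function(err) {
      warnings <<- warnings + 1L
      NULL
    })
    if (!is.null(tc)) tests <- c(tests, list(tc))
  }
  if (warnings > 0L) {
    warning(sprintf("%d malformed or unknown annotation block(s) skipped", warnings))
  }
  list(evidence = evidence, tests = tests, warnings = warnings)
}

.read_reference <- function(nd) {
  d <- xml2::xml_attr(nd, "description")
  reference(kind = xml2::xml_attr(nd, "kind"), value = xml2::xml_attr(nd, "value"),
            description = if (is.na(d)) "" else d)
}
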