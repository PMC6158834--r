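## Strain translation: reciprocal-best-hit ortholog mapping from pairwise
## sequence-hit tables, and gene-layer rewriting of a model.

#' Read a 12-column tabular sequence-hit file
#'
#' The standard tabular alignment format: query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path TSV file path (no header).
#' @return data.frame with those column names.
#' @export
read_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12) stop("expected 12 tab-separated columns, got ", ncol(df))
  names(df) <- cols
  df
}

## best subject per query: max bitscore, ties by min e-value, then by
## lexicographically smallest subject id
.best_hits <- function(hits) {
  if (anyDuplicated(hits[c("query", "subject")])) {
    keep <- order(hits$query, hits$subject, -hits$bitscore, hits$evalue)
    hits <- hits[keep, , drop = FALSE]
    dup <- duplicated(hits[c("query", "subject")])
    if (any(dup)) {
      warning(sprintf("%d duplicate (query,subject) row(s); keeping best-scoring", sum(dup)))
      hits <- hits[!dup, , drop = FALSE]
    }
  }
  hits <- hits[order(hits$query, -hits$bitscore, hits$evalue, hits$subject), ,
               drop = FALSE]
  hits[!duplicated(hits$query), c("query", "subject"), drop = FALSE]
}

#' Reciprocal best hits between two strains
#'
#' Pairs gene `a` of strain A with gene `b` of strain B when `b` is the
#' best hit of `a` in the A-vs-B table and `a` is the best hit of `b` in
#' the B-vs-A table. "Best" means maximal bitscore, with ties broken by
#' minimal e-value and then by the lexicographically smallest subject id.
#' Optional pre-filters restrict the hits considered.
#'
#' @param hits_ab,hits_ba hit tables as from [read_hits()].
#' @param max_evalue optional e-value cutoff applied before pairing.
#' @param min_pident optional percent-identity cutoff.
#' @return object of class `ortholog_map`: `pairs` (data.frame `a`, `b`;
#'   a bijection), `unmapped_a`, `unmapped_b` (query ids that found no
#'   reciprocal partner).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = NULL,
                                 min_pident = NULL) {
  filt <- function(h) {
    if (!is.null(max_evalue)) h <- h[h$evalue <= max_evalue, , drop = FALSE]
    if (!is.null(min_pident)) h <- h[h$pident >= min_pident, , drop = FALSE]
    h
  }
  hits_ab <- filt(hits_ab); hits_ba <- filt(hits_ba)
  best_ab <- .best_hits(hits_ab)
  best_ba <- .best_hits(hits_ba)
  back <- stats::setNames(best_ba$subject, best_ba$query)
  hit <- best_ab$subject %in% names(back) &
         back[best_ab$subject] == best_ab$query
  pairs <- data.frame(a = best_ab$query[hit], b = best_ab$subject[hit],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    unmapped_a = sort(setdiff(unique(hits_ab$query), pairs$a)),
    unmapped_b = sort(setdiff(unique(hits_ba$query), pairs$b))),
    class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d pairs, %d unmapped (A), %d unmapped (B)\n",
              nrow(x$pairs), length(x$unmapped_a), length(x$unmapped_b)))
  invisible(x)
}

#' Translate a model's gene layer to another strain
#'
#' Rewrites every GPR leaf through the ortholog map. Leaves without a
#' mapping are removed: a removed `or` arm narrows the alternatives, and
#' a removed `and` member weakens the subunit requirement, so the
#' affected reaction is flagged as degraded (silently requiring fewer
#' subunits changes knockout semantics). A fully emptied rule leaves the
#' reaction in place, gene-less. Evidence items whose subject or target
#' is a gene are rewritten where possible and dropped (with a log)
#' otherwise. Reaction and metabolite layers are untouched.
#'
#' @param model a [gem_model()].
#' @param map an [reciprocal_best_hits()] result.
#' @param direction `"ab"` (map gene ids from column `a` to `b`) or
#'   `"ba"`.
#' @return list: `model` (translated), `report` (list with
#'   `unmapped_genes`, `degraded_reactions`, `dropped_evidence`).
#' @export
translate_model <- function(model, map, direction = c("ab", "ba")) {
  direction <- match.arg(direction)
  mapping <- if (direction == "ab") {
    stats::setNames(map$pairs$b, map$pairs$a)
  } else {
    stats::setNames(map$pairs$a, map$pairs$b)
  }
  unmapped <- character(); degraded <- character()
  for (i in seq_len(nrow(model$reactions))) {
    tr <- gpr_translate(gpr_parse(model$reactions$gpr[i]), mapping)
    model$reactions$gpr[i] <- gpr_format(tr$tree)
    unmapped <- union(unmapped, tr$dropped)
    if (tr$degraded) degraded <- c(degraded, model$reactions$id[i])
  }
  old_genes <- model$genes
  keep <- old_genes$id %in% names(mapping)
  model$genes <- data.frame(id = unname(mapping[old_genes$id[keep]]),
                            name = old_genes$name[keep],
                            stringsAsFactors = FALSE)
  unmapped <- union(unmapped, old_genes$id[!keep])
  dropped_ev <- character()
  gene_subject <- c("gene_catalyzes_reaction", "gene_not_catalyzes_reaction",
                    "gene_localizes_to_compartment")
  new_ev <- list()
  for (e in model$evidence) {
    if (e$assertion %in% gene_subject) {
      if (e$subject %in% names(mapping)) {
        e$subject <- unname(mapping[[e$subject]])
        new_ev <- c(new_ev, list(e))
      } else {
        dropped_ev <- c(dropped_ev, e$id)
      }
    } else {
      new_ev <- c(new_ev, list(e))
    }
  }
  model$evidence <- new_ev
  ## test-case deletions reference genes too
  for (i in seq_along(model$tests)) {
    dg <- model$tests[[i]]$deleted_genes
    model$tests[[i]]$deleted_genes <- unname(mapping[dg[dg %in% names(mapping)]])
  }
  list(model = model,
       report = list(unmapped_genes = sort(unmapped),
                     degraded_reactions = sort(unique(degraded)),
                     dropped_evidence = sort(dropped_ev)))
}
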