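#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and`/`or`
#' connectives (case-insensitive) and parentheses, e.g.
#' `"(g1 and g2) or g3"`. The parse result is a tree of nested lists:
#' `list(op = "gene", gene = <id>)` at the leaves and
#' `list(op = "and"|"or", args = list(...))` at internal nodes. An empty
#' rule parses to `NULL`.
#'
#' Gene identifiers may be any run of characters other than whitespace and
#' parentheses, so strain transcript ids (including purely numeric JGI ids)
#' pass through verbatim.
#'
#' @param text GPR rule string (`""` or `NA` for no rule).
#' @return parse tree, or `NULL` for an empty rule.
#' @export
gpr_parse <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(NULL)
  }
  toks <- .gpr_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gpr_or(st)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error: unexpected token '%s' in rule: %s",
                 st$toks[st$pos], text))
  }
  tree
}

.gpr_tokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.gpr_or <- function(st) {
  args <- list(.gpr_and(st))
  while (!is.na(.gpr_peek(st)) && tolower(.gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gpr_and <- function(st) {
  args <- list(.gpr_atom(st))
  while (!is.na(.gpr_peek(st)) && tolower(.gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(.gpr_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gpr_atom <- function(st) {
  tok <- .gpr_peek(st)
  if (is.na(tok)) stop("GPR parse error: unexpected end of rule")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_or(st)
    if (is.na(.gpr_peek(st)) || .gpr_peek(st) != ")") {
      stop("GPR parse error: missing closing parenthesis")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok %in% c(")",  "and", "or", "AND", "OR")) {
    stop(sprintf("GPR parse error: unexpected token '%s'", tok))
  }
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tok)
}

#' Serialize a GPR parse tree back to rule text
#'
#' Produces a canonical fully parenthesized-where-needed form that
#' [gpr_parse()] round-trips to a structurally identical tree.
#'
#' @param tree a tree from [gpr_parse()], or `NULL`.
#' @return rule string (`""` for `NULL`).
#' @export
gpr_format <- function(tree) {
  if (is.null(tree)) return("")
  .fmt <- function(node, parent_op) {
    if (node$op == "gene") return(node$gene)
    inner <- vapply(node$args, .fmt, character(1), parent_op = node$op)
    s <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (!is.na(parent_op) && node$op != parent_op) paste0("(", s, ")") else s
  }
  .fmt(tree, NA_character_)
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A leaf evaluates to `TRUE` when its gene is not deleted; `and` is
#' conjunction, `or` disjunction. The empty rule (no gene requirement)
#' always evaluates active, so gene-less reactions are never disabled by
#' deletions.
#'
#' @param gpr a parse tree from [gpr_parse()] or a rule string.
#' @param deleted character vector of deleted gene ids.
#' @return logical: is the reaction still catalyzable?
#' @export
gpr_eval <- function(gpr, deleted = character()) {
  if (is.character(gpr)) gpr <- gpr_parse(gpr)
  if (is.null(gpr)) return(TRUE)
  .ev <- function(node) {
    switch(node$op,
      gene = !(node$gene %in% deleted),
      and = all(vapply(node$args, .ev, logical(1))),
      or = any(vapply(node$args, .ev, logical(1))),
      stop("bad GPR node op: ", node$op))
  }
  .ev(gpr)
}

#' List the gene ids appearing in a GPR
#'
#' @param gpr parse tree or rule string.
#' @return character vector of unique gene ids (empty for no rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- gpr_parse(gpr)
  if (is.null(gpr)) return(character())
  .collect <- function(node) {
    if (node$op == "gene") return(node$gene)
    unlist(lapply(node$args, .collect))
  }
  unique(.collect(gpr))
}

#' Rewrite GPR leaves through a gene id mapping
#'
#' Used by strain translation: each leaf is replaced by its mapped id;
#' unmapped leaves are dropped. Dropping an `or` arm narrows alternatives;
#' dropping an `and` member weakens the requirement, which the caller must
#' flag (see [translate_model()]). A node whose children all vanish
#' vanishes itself; a fully emptied rule becomes `NULL`.
#'
#' @param tree GPR parse tree.
#' @param mapping named character vector old id -> new id.
#' @return list with `tree` (possibly `NULL`), `dropped` (unmapped leaf
#'   ids), and `degraded` (`TRUE` when an `and` member was dropped).
#' @export
gpr_translate <- function(tree, mapping) {
  dropped <- character()
  degraded <- FALSE
  .tr <- function(node) {
    if (node$op == "gene") {
      if (node$gene %in% names(mapping)) {
        return(list(op = "gene", gene = unname(mapping[[node$gene]])))
      }
      dropped <<- c(dropped, node$gene)
      return(NULL)
    }
    kids <- lapply(node$args, .tr)
    lost <- vapply(kids, is.null, logical(1))
    if (node$op == "and" && any(lost) && !all(lost)) degraded <<- TRUE
    kids <- kids[!lost]
    if (length(kids) == 0) return(NULL)
    if (length(kids) == 1) return(kids[[1]])
    list(op = node$op, args = kids)
  }
  out <- if (is.null(tree)) NULL else .tr(tree)
  list(tree = out, dropped = unique(dropped), degraded = degraded)
}
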