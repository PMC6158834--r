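## Expression contextualization: map a log2 expression matrix onto the
## model's pathways and score candidate-gene co-expression.

#' Read a delimited expression matrix
#'
#' Genes in rows (first column), condition labels in the header. Values
#' are assumed to be pre-normalized log2 expression; no normalization is
#' performed here.
#'
#' @param path TSV file path.
#' @return numeric matrix, gene ids as rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in expression matrix")
  storage.mode(m) <- "double"
  m
}

#' Genes assigned to a pathway
#'
#' The union of GPR leaves over all reactions labelled with the given
#' subsystem. Gene-less pathways yield an empty set; a gene shared by
#' reactions of several pathways belongs to each.
#'
#' @param model a [gem_model()].
#' @param pathway subsystem label.
#' @return character vector of gene ids.
#' @export
pathway_members <- function(model, pathway) {
  hit <- !is.na(model$reactions$subsystem) & model$reactions$subsystem == pathway
  if (!any(hit)) stop("unknown pathway label: ", pathway)
  sort(unique(unlist(lapply(model$reactions$gpr[hit], gpr_genes))))
}

#' Pathway labels present in a model
#' @param model a [gem_model()].
#' @return sorted unique subsystem labels.
#' @export
pathway_labels <- function(model) {
  sort(unique(stats::na.omit(model$reactions$subsystem)))
}

#' Per-gene expression change of a pathway under a condition
#'
#' For each member gene with data, the change is
#' `expr[gene, condition] - expr[gene, reference]` on the log2 scale
#' (i.e. the log2 fold change vs the reference condition). Member genes
#' absent from the matrix are reported as missing, never imputed as zero.
#' The reference condition is a required input: the appropriate baseline
#' depends on the experiment and is never defaulted.
#'
#' @param model a [gem_model()].
#' @param expr matrix from [read_expression()].
#' @param pathway subsystem label.
#' @param condition condition (column) label.
#' @param reference reference condition label.
#' @return list of class `pathway_profile`: `pathway`, `condition`,
#'   `reference`, `changes` (data.frame gene/change), `missing` (gene
#'   ids without data).
#' @export
pathway_change_profile <- function(model, expr, pathway, condition, reference) {
  if (!condition %in% colnames(expr)) stop("unknown condition: ", condition)
  if (!reference %in% colnames(expr)) stop("unknown reference condition: ", reference)
  members <- pathway_members(model, pathway)
  have <- members %in% rownames(expr)
  changes <- data.frame(
    gene = members[have],
    change = expr[members[have], condition] - expr[members[have], reference],
    stringsAsFactors = FALSE)
  rownames(changes) <- NULL
  structure(list(pathway = pathway, condition = condition,
                 reference = reference, changes = changes,
                 missing = members[!have]),
            class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("pathway '%s', %s vs %s: %d genes (median change %.3g), %d missing\n",
              x$pathway, x$condition, x$reference, nrow(x$changes),
              stats::median(x$changes$change), length(x$missing)))
  invisible(x)
}

#' Change profiles for all pathways, as a tidy table
#'
#' @param model a [gem_model()].
#' @param expr expression matrix.
#' @param condition,reference condition labels.
#' @return data.frame: pathway, gene, change.
#' @export
pathway_profile_table <- function(model, expr, condition, reference) {
  out <- lapply(pathway_labels(model), function(p) {
    pr <- pathway_change_profile(model, expr, p, condition, reference)
    if (nrow(pr$changes) == 0) return(NULL)
    cbind(pathway = p, pr$changes, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Co-expression of a candidate gene with pathway members
#'
#' Pearson correlation of the candidate's expression profile against each
#' member gene's profile across all conditions, plus the mean over
#' members with a defined correlation. Zero-variance profiles yield `NA`
#' (correlation undefined), reported as such. This is the screen used to
#' tie an unassigned gene (e.g. a transporter) to a co-regulated cluster.
#'
#' @param expr expression matrix (log2).
#' @param candidate candidate gene id (row of `expr`).
#' @param members character vector of member gene ids.
#' @return list: `correlations` (data.frame gene/r), `mean_r`, `missing`
#'   (members without data).
#' @export
coexpression_score <- function(expr, candidate, members) {
  if (!candidate %in% rownames(expr)) stop("candidate not in matrix: ", candidate)
  if (ncol(expr) < 3) stop("need at least 3 conditions for correlation")
  members <- setdiff(members, candidate)
  have <- members %in% rownames(expr)
  x <- expr[candidate, ]
  r <- vapply(members[have], function(g) {
    y <- expr[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  list(correlations = data.frame(gene = members[have], r = unname(r),
                                 stringsAsFactors = FALSE),
       mean_r = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE),
       missing = members[!have])
}
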