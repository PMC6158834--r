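# Independent oracles used to check the package's optimizers and
# combinatorial routines. These deliberately share no code with the
# implementation: brute force, enumeration, or direct formulas only.

# LP oracle by vertex enumeration: the optimum of a bounded feasible LP
# over {v : S v = 0, lb <= v <= ub} is attained at a basic point where
# n - rank(S) components sit at a bound. Enumerate all such supports and
# bound patterns, solve the square system, keep feasible points.
oracle_fba_optimum <- function(model, objective, sense = "max") {
  mets <- model$metabolites$id[!model$metabolites$boundary]
  rids <- model$reactions$id
  n <- length(rids)
  S <- matrix(0, length(mets), n, dimnames = list(mets, rids))
  for (rid in rids) {
    st <- model$stoichiometry[[rid]]
    st <- st[names(st) %in% mets]
    if (length(st)) S[names(st), rid] <- st
  }
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cc <- numeric(n); names(cc) <- rids
  cc[names(objective)] <- objective
  r <- qr(S)$rank
  k <- n - r
  best <- NULL
  feas <- function(v) all(v >= lb - 1e-7 & v <= ub + 1e-7) &&
    max(abs(S %*% v)) < 1e-7
  supports <- if (k == 0) list(integer()) else
    asplit(utils::combn(n, k), 2)
  for (idx in supports) {
    idx <- as.integer(idx)
    patterns <- if (length(idx) == 0) list(numeric()) else {
      g <- expand.grid(rep(list(c(FALSE, TRUE)), length(idx)))
      lapply(seq_len(nrow(g)), function(i) ifelse(unlist(g[i, ]), ub[idx], lb[idx]))
    }
    for (vals in patterns) {
      E <- matrix(0, length(idx), n)
      if (length(idx)) E[cbind(seq_along(idx), idx)] <- 1
      A <- rbind(S, E)
      bb <- c(rep(0, nrow(S)), vals)
      sol <- tryCatch(qr.solve(A, bb, tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - bb)) > 1e-7) next
      if (!feas(sol)) next
      z <- sum(cc * sol)
      if (is.null(best) || (sense == "max" && z > best) ||
          (sense == "min" && z < best)) best <- z
    }
  }
  best
}

# GPR oracle: translate the rule to an R logical expression and eval it.
oracle_gpr_eval <- function(rule, genes, deleted) {
  expr <- rule
  for (g in genes) {
    expr <- gsub(paste0("\\b", g, "\\b"), if (g %in% deleted) "FALSE" else "TRUE", expr)
  }
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  eval(parse(text = expr))
}

# RBH oracle: exhaustive double argmax over a full score matrix with the
# documented tie-breaks (max score, then lexicographically smallest id;
# in the fixture tables the e-value is a monotone transform of the score,
# so score ties are e-value ties).
oracle_rbh <- function(scores) {
  argbest <- function(x) names(x)[order(-x, names(x))][1]
  best_a <- apply(scores, 1, argbest)
  best_b <- apply(scores, 2, function(col) argbest(col))
  pairs <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  for (a in rownames(scores)) {
    b <- best_a[[a]]
    if (best_b[[b]] == a) pairs <- rbind(pairs, data.frame(a = a, b = b))
  }
  pairs[order(pairs$a), , drop = FALSE]
}

# Random GPR tree generator for property tests (rule text, gene pool).
random_gpr <- function(n_genes, depth = 3) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.4) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    kids <- vapply(seq_len(k), function(i) build(d - 1), character(1))
    paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
  }
  list(rule = build(depth), genes = genes)
}

fixture_medium <- function(model) {
  gt <- attr(model, "ground_truth")
  data.frame(reaction = gt$uptake_reaction, lower_bound = -gt$uptake_bound,
             upper_bound = 0, stringsAsFactors = FALSE)
}
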