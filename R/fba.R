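## Constraint-based simulation: FBA and parsimonious FBA.
##
## Each flux v_j is split into non-negative forward/backward parts
## f_j - b_j with explicit caps, so both FBA and the pFBA total-flux
## minimization are plain LPs over non-negative variables and can be
## handed to any solver honouring the minimal solve contract below.

#' Solve a linear program over non-negative variables
#'
#' Minimal solve contract used by the flux analysis code: optimize
#' `obj . x` subject to `A_eq x = b_eq`, `A_ub x <= b_ub`, `x >= 0`.
#'
#' The backend is a dense two-phase primal simplex using Bland's
#' anti-cycling rule throughout, so degenerate problems (ubiquitous in
#' steady-state flux LPs with closed exchanges) terminate correctly.
#' Any solver honouring this contract can be substituted.
#'
#' @param obj objective coefficient vector.
#' @param A_eq,b_eq equality constraints (may have zero rows).
#' @param A_ub,b_ub inequality (`<=`) constraints (may have zero rows).
#' @param maximize logical.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`/`"infeasible"`/`"unbounded"`/
#'   `"failed"`), `objective`, and `x` (primal solution, `NULL` unless
#'   optimal).
#' @export
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric() }
  if (is.null(A_ub)) { A_ub <- matrix(0, 0, n); b_ub <- numeric() }
  m1 <- nrow(A_ub); m2 <- nrow(A_eq)
  m <- m1 + m2
  ## assemble equality-form rows with nonnegative rhs:
  ##   ineq rows get a +1 slack (rhs >= 0) or, after negation, a -1 surplus
  A <- rbind(A_ub, A_eq)
  b <- c(b_ub, b_eq)
  slack_sign <- c(rep(1, m1), rep(0, m2))
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  slack_sign[flip] <- -slack_sign[flip]
  b[flip] <- -b[flip]
  n_slack <- m1
  ## artificials for every row without a natural +1 basic slack
  need_art <- which(slack_sign <= 0)
  n_art <- length(need_art)
  N <- n + n_slack + n_art
  M <- matrix(0, m, N)
  M[, seq_len(n)] <- A
  for (i in seq_len(m1)) M[i, n + i] <- slack_sign[i]
  basis <- integer(m)
  basis[setdiff(seq_len(m), need_art)] <- n + setdiff(seq_len(m1), need_art)
  for (k in seq_along(need_art)) {
    M[need_art[k], n + n_slack + k] <- 1
    basis[need_art[k]] <- n + n_slack + k
  }
  art_cols <- if (n_art) n + n_slack + seq_len(n_art) else integer()

  run <- function(M, b, basis, cost, allowed) {
    repeat {
      cB <- cost[basis]
      red <- cost - as.numeric(crossprod(M, cB))  # reduced costs (canonical tableau)
      red[basis] <- 0
      enter <- allowed[which(red[allowed] < -tol)]
      if (!length(enter)) return(list(M = M, b = b, basis = basis, status = "optimal"))
      j <- min(enter)                              # Bland: smallest index
      col <- M[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(M = M, b = b, basis = basis, status = "unbounded"))
      ratio <- b[pos] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      i <- cand[which.min(basis[cand])]            # Bland on the leaving variable
      piv <- M[i, j]
      M[i, ] <- M[i, ] / piv; b[i] <- b[i] / piv
      for (r in seq_len(nrow(M))) {
        if (r != i && abs(M[r, j]) > 0) {
          b[r] <- b[r] - M[r, j] * b[i]
          M[r, ] <- M[r, ] - M[r, j] * M[i, ]
        }
      }
      basis[i] <- j
    }
  }

  if (m == 0) {
    ## no constraints: optimum at 0 unless improving direction exists
    dir <- if (maximize) obj > tol else obj < -tol
    if (any(dir)) return(list(status = "unbounded", objective = NA_real_, x = NULL))
    return(list(status = "optimal", objective = 0, x = numeric(n)))
  }

  if (n_art) {
    c1 <- numeric(N); c1[art_cols] <- 1
    ph1 <- run(M, b, basis, c1, seq_len(N))
    if (ph1$status != "optimal") return(list(status = "failed", objective = NA_real_, x = NULL))
    if (sum(ph1$b[ph1$basis %in% art_cols]) > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    M <- ph1$M; b <- ph1$b; basis <- ph1$basis
    ## pivot remaining (zero-valued) artificials out of the basis; a row
    ## with no eligible pivot is redundant and dropped
    drop_rows <- integer()
    for (i in which(basis %in% art_cols)) {
      elig <- which(abs(M[i, seq_len(n + n_slack)]) > tol)
      if (length(elig)) {
        j <- min(elig)
        piv <- M[i, j]
        M[i, ] <- M[i, ] / piv; b[i] <- b[i] / piv
        for (r in seq_len(nrow(M))) {
          if (r != i && abs(M[r, j]) > 0) {
            b[r] <- b[r] - M[r, j] * b[i]
            M[r, ] <- M[r, ] - M[r, j] * M[i, ]
          }
        }
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
    if (length(drop_rows)) {
      M <- M[-drop_rows, , drop = FALSE]
      b <- b[-drop_rows]
      basis <- basis[-drop_rows]
    }
  }

  c2 <- numeric(N)
  c2[seq_len(n)] <- if (maximize) -obj else obj
  ph2 <- run(M, b, basis, c2, seq_len(n + n_slack))
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  x <- numeric(N)
  x[ph2$basis] <- ph2$b
  x <- x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}

#' Build the flux LP from a model
#'
#' Assembles the steady-state problem: one column per reaction, one row
#' per non-boundary metabolite, `S v = 0`, bounds from the reaction table,
#' objective from the model (or an override). Boundary species are
#' excluded from the mass balance, which is what makes one-sided drains
#' and explicit-external-species encodings equivalent.
#'
#' @param model a [gem_model()] with at least one reaction.
#' @param objective optional named numeric vector overriding the model
#'   objective.
#' @param sense `"max"` or `"min"`.
#' @return object of class `flux_problem`: list with `S` (dense matrix,
#'   metabolite rows x reaction columns), `lb`, `ub`, `c`, `sense`,
#'   `reactions`, `metabolites`.
#' @export
build_problem <- function(model, objective = NULL, sense = "max") {
  if (nrow(model$reactions) == 0) stop("model has no reactions")
  if (is.null(objective)) objective <- model$objective
  mets <- model$metabolites$id[!model$metabolites$boundary]
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (rid in rids) {
    st <- model$stoichiometry[[rid]]
    st <- st[names(st) %in% mets]
    if (length(st)) S[names(st), rid] <- st
  }
  cc <- stats::setNames(numeric(length(rids)), rids)
  if (length(objective)) {
    unk <- setdiff(names(objective), rids)
    if (length(unk)) stop("objective references unknown reaction(s): ",
                          paste(unk, collapse = ", "))
    cc[names(objective)] <- objective
  }
  structure(list(S = S,
                 lb = stats::setNames(model$reactions$lower_bound, rids),
                 ub = stats::setNames(model$reactions$upper_bound, rids),
                 c = cc, sense = match.arg(sense, c("max", "min")),
                 reactions = rids, metabolites = mets),
            class = "flux_problem")
}

## Shared constraint blocks for the split formulation v = f - b with
## f, b >= 0. Split variables with zero capacity (e.g. backward parts of
## irreversible reactions) are eliminated up front: they can only be 0,
## and keeping degenerate zero-capacity columns needlessly enlarges the
## problem and trips simplex degeneracy. `fcols`/`bcols` record which
## reaction each retained column belongs to.
.split_constraints <- function(prob) {
  n <- ncol(prob$S)
  if (any(!is.finite(prob$lb)) || any(!is.finite(prob$ub))) {
    stop("flux bounds must be finite")
  }
  fcap <- pmax(prob$ub, 0)
  bcap <- pmax(-prob$lb, 0)
  fcols <- which(fcap > 0)
  bcols <- which(bcap > 0)
  nv <- length(fcols) + length(bcols)
  A_eq <- cbind(prob$S[, fcols, drop = FALSE], -prob$S[, bcols, drop = FALSE])
  keep <- rowSums(abs(A_eq)) > 0
  A_eq <- A_eq[keep, , drop = FALSE]
  b_eq <- numeric(sum(keep))
  A_ub <- diag(nv)
  b_ub <- c(fcap[fcols], bcap[bcols])
  vrow <- function(j) {
    r <- numeric(nv)
    kf <- match(j, fcols); kb <- match(j, bcols)
    if (!is.na(kf)) r[kf] <- 1
    if (!is.na(kb)) r[length(fcols) + kb] <- -1
    r
  }
  for (j in which(prob$lb > 0)) {        # -(f - b) <= -lb, forced forward flux
    A_ub <- rbind(A_ub, -vrow(j)); b_ub <- c(b_ub, -prob$lb[j])
  }
  for (j in which(prob$ub < 0)) {        # f - b <= ub < 0, forced backward flux
    A_ub <- rbind(A_ub, vrow(j)); b_ub <- c(b_ub, prob$ub[j])
  }
  list(A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
       n = n, fcols = fcols, bcols = bcols)
}

.split_objective <- function(prob, sc) {
  c(prob$c[sc$fcols], -prob$c[sc$bcols])
}

.split_fluxes <- function(x, sc) {
  v <- numeric(sc$n)
  v[sc$fcols] <- x[seq_along(sc$fcols)]
  v[sc$bcols] <- v[sc$bcols] - x[length(sc$fcols) + seq_along(sc$bcols)]
  v
}

.flux_solution <- function(status, objective = NA_real_, fluxes = NULL, prob = NULL) {
  structure(list(status = status, objective = objective, fluxes = fluxes),
            class = "flux_solution")
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the linear objective over the steady-state
#' flux polytope. The objective value is deterministic; the flux vector is
#' one of possibly many alternate optima and carries no uniqueness
#' guarantee.
#'
#' @param prob a [build_problem()] result.
#' @return `flux_solution`: `status` (`"optimal"`, `"infeasible"`,
#'   `"failed"`), `objective`, `fluxes` (named over reaction ids).
#' @export
fba <- function(prob) {
  sc <- .split_constraints(prob)
  if (ncol(sc$A_ub) == 0) {  # every flux fixed at zero
    return(.flux_solution("optimal", 0, stats::setNames(numeric(sc$n), prob$reactions)))
  }
  res <- solve_lp(.split_objective(prob, sc), sc$A_eq, sc$b_eq, sc$A_ub, sc$b_ub,
                  maximize = prob$sense == "max")
  if (res$status != "optimal") return(.flux_solution(res$status))
  v <- .split_fluxes(res$x, sc)
  .flux_solution("optimal", res$objective, stats::setNames(v, prob$reactions))
}

#' Parsimonious FBA
#'
#' Two-stage optimization: first the FBA optimum Z is computed, then the
#' objective is held at Z (within a relative tolerance) while the total
#' absolute flux `sum |v|` is minimized. The forward/backward split makes
#' the second stage linear; at its optimum no reaction carries flux in
#' both directions, so the reported total equals `sum |v|` exactly.
#'
#' @param prob a [build_problem()] result.
#' @param tol relative slack on the objective-fixing constraint.
#' @return `flux_solution` with the FBA `objective` and the
#'   minimal-total-flux vector; `total_flux` holds `sum |v|`.
#' @export
pfba <- function(prob, tol = 1e-6) {
  first <- fba(prob)
  if (first$status != "optimal") return(first)
  Z <- first$objective
  sc <- .split_constraints(prob)
  cvec <- .split_objective(prob, sc)
  slack <- tol * max(1, abs(Z))
  if (prob$sense == "max") {
    A_ub <- rbind(sc$A_ub, -cvec)  # c.v >= Z - slack
    b_ub <- c(sc$b_ub, -(Z - slack))
  } else {
    A_ub <- rbind(sc$A_ub, cvec)   # c.v <= Z + slack
    b_ub <- c(sc$b_ub, Z + slack)
  }
  res <- solve_lp(rep(1, ncol(sc$A_ub)), sc$A_eq, sc$b_eq, A_ub, b_ub,
                  maximize = FALSE)
  if (res$status != "optimal") return(.flux_solution(res$status))
  v <- .split_fluxes(res$x, sc)
  out <- .flux_solution("optimal", Z, stats::setNames(v, prob$reactions))
  out$total_flux <- res$objective
  out
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: %s", x$status))
  if (x$status == "optimal") cat(sprintf(", objective = %g", x$objective))
  if (!is.null(x$total_flux)) cat(sprintf(", total |v| = %g", x$total_flux))
  cat("\n")
  invisible(x)
}

#' Apply gene deletions to a model
#'
#' Evaluates every reaction's GPR with the given genes removed; reactions
#' whose rule goes inactive get bounds (0, 0). Reactions with no GPR are
#' never affected. Unknown gene ids are an error, not a silent no-op.
#'
#' @param model a [gem_model()].
#' @param genes character vector of gene ids to delete.
#' @return the modified model (a value copy).
#' @export
apply_deletions <- function(model, genes) {
  if (length(genes) == 0) return(model)
  unknown <- setdiff(genes, model$genes$id)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  for (i in seq_len(nrow(model$reactions))) {
    g <- model$reactions$gpr[i]
    if (nzchar(g) && !gpr_eval(gpr_parse(g), genes)) {
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  }
  model
}

#' Optimize a model in one call
#'
#' Convenience wrapper: builds the problem and runs [fba()] or [pfba()].
#'
#' @param model a [gem_model()].
#' @param objective optional objective override (named weights).
#' @param sense `"max"` or `"min"`.
#' @param method `"fba"` or `"pfba"`.
#' @return a `flux_solution`.
#' @export
optimize_model <- function(model, objective = NULL, sense = "max", method = "fba") {
  prob <- build_problem(model, objective = objective, sense = sense)
  switch(match.arg(method, c("fba", "pfba")), fba = fba(prob), pfba = pfba(prob))
}
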