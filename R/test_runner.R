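## Automated validation: run embedded phenotype test cases against a model.

#' Run one test case
#'
#' Simulation protocol: (1) work on a copy of the model's bounds; (2)
#' every boundary reaction not named in the test's settings is restricted
#' to only excreting its metabolite — uptake closed, secretion open — so
#' the settings list alone defines the medium; (3) the settings'
#' bound overrides are applied; (4) deleted genes are propagated through
#' the GPRs; (5) each outcome's own reaction is optimized in the
#' direction of its comparator (maximize for `greater`, minimize for
#' `less`) and the optimum is compared against the threshold; (6) the test
#' passes iff every outcome holds.
#'
#' Optimizing the outcome reaction itself (rather than a fixed biomass
#' objective) makes `less` outcomes certificates of impossibility: a
#' no-growth phenotype passes only when the model cannot grow at all
#' under the test's medium and deletions.
#'
#' Boundary direction is normalized from the stoichiometry: positive flux
#' means the metabolite leaves the system when its coefficient is
#' negative, and enters when positive; the uptake side is the one closed.
#'
#' @param model a [gem_model()].
#' @param test a [test_case()].
#' @param method `"fba"` or `"pfba"` (the optimum value is identical; the
#'   choice matters only for the reported flux vectors).
#' @return object of class `gem_test_result`: `id`, `passed`, `status`
#'   (`"ok"` or `"error"`), `note`, and `outcomes` data.frame with
#'   achieved flux, threshold, comparator and per-outcome verdict.
#' @export
run_test <- function(model, test, method = "fba") {
  res <- list(id = test$id, passed = FALSE, status = "ok", note = "",
              outcomes = NULL)
  class(res) <- "gem_test_result"
  bad <- c(setdiff(test$settings$reaction, model$reactions$id),
           setdiff(test$outcomes$reaction, model$reactions$id))
  if (length(bad)) {
    res$status <- "error"
    res$note <- paste("unknown reaction(s):", paste(unique(bad), collapse = ", "))
    return(res)
  }
  if (length(setdiff(test$deleted_genes, model$genes$id))) {
    res$status <- "error"
    res$note <- paste("unknown gene(s):",
                      paste(setdiff(test$deleted_genes, model$genes$id), collapse = ", "))
    return(res)
  }
  m <- .close_uptakes(model, keep_open = test$settings$reaction)
  idx <- match(test$settings$reaction, m$reactions$id)
  m$reactions$lower_bound[idx] <- test$settings$lower_bound
  m$reactions$upper_bound[idx] <- test$settings$upper_bound
  if (length(test$deleted_genes)) m <- apply_deletions(m, test$deleted_genes)

  out <- test$outcomes
  out$achieved <- NA_real_
  out$verdict <- NA
  for (j in seq_len(nrow(out))) {
    sense <- if (out$cmp[j] == "greater") "max" else "min"
    sol <- optimize_model(m, objective = stats::setNames(1, out$reaction[j]),
                          sense = sense, method = method)
    if (sol$status != "optimal") {
      res$status <- "error"
      res$note <- paste0("solver status '", sol$status, "' for outcome reaction ",
                         out$reaction[j])
      res$outcomes <- out
      return(res)
    }
    out$achieved[j] <- sol$objective
    out$verdict[j] <- if (out$cmp[j] == "greater") sol$objective > out$value[j]
                      else sol$objective < out$value[j]
  }
  res$outcomes <- out
  res$passed <- all(out$verdict)
  res
}

## Restrict every boundary reaction not in keep_open to the
## metabolite-excreting direction (canonical "drain only").
.close_uptakes <- function(model, keep_open = character()) {
  bnd <- is_boundary_reaction(model)
  bmet <- boundary_metabolite(model)
  for (rid in model$reactions$id[bnd]) {
    if (rid %in% keep_open) next
    i <- match(rid, model$reactions$id)
    coef <- model$stoichiometry[[rid]][[bmet[[rid]]]]
    if (coef < 0) {
      ## A -> : positive flux excretes; close negative (uptake) side
      model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
    } else {
      ## -> A : positive flux imports; close positive side
      model$reactions$upper_bound[i] <- min(model$reactions$upper_bound[i], 0)
    }
  }
  model
}

#' @export
print.gem_test_result <- function(x, ...) {
  cat(sprintf("test %s: %s\n", x$id,
              if (x$status == "error") paste("ERROR -", x$note)
              else if (x$passed) "passed" else "failed"))
  invisible(x)
}

#' Run a suite of test cases
#'
#' Executes the tests in deterministic order (by test id) and aggregates
#' totals. Tests that cannot be evaluated (unknown references, solver
#' failure) are tallied as errored, not failed, so
#' `passed + failed + errored == run` always holds.
#'
#' @param model a [gem_model()].
#' @param tests list of [test_case()] objects (defaults to the model's
#'   embedded suite).
#' @param method `"fba"` or `"pfba"`.
#' @return object of class `gem_suite_report`: `run`, `passed`, `failed`,
#'   `errored`, and `results` (list of `gem_test_result`).
#' @export
run_suite <- function(model, tests = model$tests, method = "fba") {
  ord <- order(vapply(tests, `[[`, "", "id"))
  tests <- tests[ord]
  results <- lapply(tests, function(tc) run_test(model, tc, method = method))
  ok <- vapply(results, function(r) r$status == "ok", logical(1))
  passed <- vapply(results, function(r) isTRUE(r$passed) && r$status == "ok", logical(1))
  rep <- list(run = length(results),
              passed = sum(passed),
              failed = sum(ok & !passed),
              errored = sum(!ok),
              results = results)
  class(rep) <- "gem_suite_report"
  rep
}

#' @export
print.gem_suite_report <- function(x, ...) {
  cat(sprintf("suite: %d run, %d passed, %d failed, %d errored\n",
              x$run, x$passed, x$failed, x$errored))
  invisible(x)
}

#' Turn a suite report into a table
#'
#' @param report a [run_suite()] result.
#' @return data.frame with one row per test: id, passed, status, note.
#' @export
suite_to_table <- function(report) {
  do.call(rbind, lapply(report$results, function(r) {
    data.frame(id = r$id, passed = r$passed, status = r$status, note = r$note,
               stringsAsFactors = FALSE)
  }))
}

#' Generate and run whole-system sanity checks
#'
#' Three families of generated checks, mirroring routine model QC:
#' producibility of each biomass precursor (a temporary drain is added and
#' must reach positive flux on the given medium), essentiality of medium
#' components (removing a named component must abolish growth), and named
#' flux-capability checks (a reaction that must be able to carry positive
#' flux, e.g. a peroxisomal oxidation step).
#'
#' @param model a [gem_model()].
#' @param biomass id of the growth/objective reaction.
#' @param precursors character vector of metabolite ids that biomass
#'   requires.
#' @param medium data.frame of settings (`reaction`, `lower_bound`,
#'   `upper_bound`) describing the reference medium.
#' @param essential character vector of medium reaction ids whose closure
#'   must abolish growth.
#' @param capabilities character vector of reaction ids that must support
#'   positive flux on the medium.
#' @param threshold growth/no-growth flux threshold.
#' @return list of `gem_test_result` objects.
#' @export
system_checks <- function(model, biomass, precursors = character(),
                          medium = NULL, essential = character(),
                          capabilities = character(), threshold = 1e-6) {
  if (!biomass %in% model$reactions$id) stop("unknown biomass reaction: ", biomass)
  if (is.null(medium)) {
    medium <- data.frame(reaction = character(), lower_bound = numeric(),
                         upper_bound = numeric(), stringsAsFactors = FALSE)
  }
  out <- list()
  for (p in precursors) {
    if (!p %in% model$metabolites$id) {
      r <- list(id = paste0("sys_precursor_", p), passed = FALSE,
                status = "error", note = paste("unknown metabolite:", p),
                outcomes = NULL)
      class(r) <- "gem_test_result"
      out <- c(out, list(r))
      next
    }
    m2 <- model
    drain <- paste0("SYSDRAIN_", p)
    m2$reactions <- rbind(m2$reactions, .complete_rxn_table(
      data.frame(id = drain, lower_bound = 0, upper_bound = 1000,
                 stringsAsFactors = FALSE)))
    m2$stoichiometry[[drain]] <- stats::setNames(-1, p)
    tc <- test_case(id = paste0("sys_precursor_", p),
                    name = paste("precursor producible:", p),
                    settings = medium,
                    outcomes = data.frame(reaction = drain, cmp = "greater",
                                          value = threshold))
    out <- c(out, list(run_test(m2, tc)))
  }
  for (ex in essential) {
    med2 <- medium[medium$reaction != ex, , drop = FALSE]
    tc <- test_case(id = paste0("sys_essential_", ex),
                    name = paste("no growth without", ex),
                    settings = med2,
                    outcomes = data.frame(reaction = biomass, cmp = "less",
                                          value = threshold))
    out <- c(out, list(run_test(model, tc)))
  }
  for (rid in capabilities) {
    tc <- test_case(id = paste0("sys_capability_", rid),
                    name = paste("flux capability:", rid),
                    settings = medium,
                    outcomes = data.frame(reaction = rid, cmp = "greater",
                                          value = threshold))
    out <- c(out, list(run_test(model, tc)))
  }
  out
}
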