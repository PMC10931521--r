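#' Flux balance analysis
#'
#' Solves the linear program `max obj' v` subject to steady-state mass
#' balance `S v = 0` and the model's reaction bounds.
#'
#' @param model A [MetabolicModel-class] with a non-empty objective.
#' @return A [FluxDistribution-class]. Status is `"infeasible"` when no
#'   flux vector satisfies the constraints and `"unbounded"` when the
#'   objective is unbounded (a symptom of missing bounds).
#' @examples
#' m <- makeToyModel()$model
#' fba(m)
#' @export
fba <- function(model) {
  if (!length(model@objective)) stop("model has an empty objective")
  obj <- objectiveVector(model)
  sol <- solveLP(obj, model@stoichiometry,
                 model@reactions$lower_bound, model@reactions$upper_bound,
                 maximize = TRUE)
  asFluxDistribution(model, sol)
}

objectiveVector <- function(model) {
  obj <- stats::setNames(rep(0, nrow(model@reactions)), model@reactions$id)
  obj[names(model@objective)] <- model@objective
  unname(obj)
}

asFluxDistribution <- function(model, sol) {
  fluxes <- stats::setNames(sol$v, model@reactions$id)
  if (sol$status == "optimal") {
    resid <- max(abs(as.vector(model@stoichiometry %*% sol$v)))
    if (resid > 1e-6) {
      stop("solver returned a flux vector violating steady state (residual ",
           format(resid), ")")
    }
  }
  new("FluxDistribution", fluxes = fluxes,
      objective_value = if (sol$status == "optimal") sol$value else NA_real_,
      status = sol$status)
}

#' Parsimonious FBA
#'
#' Minimizes total absolute flux subject to retaining at least
#' `objective_fraction` of the FBA optimum. With `objective_fraction = 0.9`
#' this reproduces the pruning constraint of a 90% minimum objective
#' fraction.
#'
#' @param model A [MetabolicModel-class] with a non-empty objective.
#' @param objective_fraction Fraction in (0, 1] of the FBA optimum that the
#'   solution must retain (default 1).
#' @return A [FluxDistribution-class] whose `objective_value` is the
#'   original objective evaluated at the parsimonious solution.
#' @export
pfba <- function(model, objective_fraction = 1.0) {
  stopifnot(objective_fraction > 0, objective_fraction <= 1)
  parent <- fba(model)
  if (parent@status != "optimal") return(parent)
  obj <- objectiveVector(model)
  sol <- solveWeightedAbsFluxLP(
    cost = rep(1, nrow(model@reactions)),
    S = model@stoichiometry,
    lb = model@reactions$lower_bound,
    ub = model@reactions$upper_bound,
    ineq = list(A = matrix(obj, 1), rhs = objective_fraction * parent@objective_value))
  if (sol$status != "optimal") {
    stop("parsimonious step unexpectedly ", sol$status)
  }
  fluxes <- stats::setNames(sol$v, model@reactions$id)
  resid <- max(abs(as.vector(model@stoichiometry %*% sol$v)))
  if (resid > 1e-6) stop("parsimonious solution violates steady state")
  new("FluxDistribution", fluxes = fluxes,
      objective_value = sum(obj * sol$v), status = "optimal")
}

#' Test whether a model can perform a metabolic task
#'
#' All exchange reactions not mentioned by the task are closed; the task's
#' uptake and secretion ranges are imposed on the exchanges of the named
#' extracellular metabolites (uptake = negative exchange flux), together
#' with any reaction-bound overrides. The task is feasible iff the
#' resulting polytope is non-empty. For feasible tasks the active reaction
#' set is taken from a minimal-total-flux (parsimonious) solution of the
#' task LP.
#'
#' @param model A [MetabolicModel-class].
#' @param task A [MetabolicTask-class]. Metabolites without an existing
#'   exchange get a temporary boundary exchange; a task metabolite with no
#'   extracellular counterpart is an error.
#' @return List with `feasible` (logical) and `active_reactions`
#'   (character vector of reactions with |flux| > 1e-9 in the parsimonious
#'   task solution; excludes temporary exchanges).
#' @export
checkTask <- function(model, task) {
  prep <- applyTaskEnvironment(model, task)
  work <- prep$model
  feas <- solveLP(rep(0, nrow(work@reactions)), work@stoichiometry,
                  work@reactions$lower_bound, work@reactions$upper_bound,
                  maximize = TRUE)
  if (feas$status != "optimal") {
    return(list(feasible = FALSE, active_reactions = character(0)))
  }
  sol <- solveWeightedAbsFluxLP(
    cost = rep(1, nrow(work@reactions)),
    S = work@stoichiometry,
    lb = work@reactions$lower_bound,
    ub = work@reactions$upper_bound)
  if (sol$status != "optimal") {
    return(list(feasible = FALSE, active_reactions = character(0)))
  }
  active <- work@reactions$id[abs(sol$v) > 1e-9]
  list(feasible = TRUE,
       active_reactions = setdiff(active, prep$temporary_exchanges))
}

# Build the task environment: close all exchanges, open/require the task's
# metabolite ranges, apply bound overrides. Returns the working model and
# the ids of exchanges added temporarily.
applyTaskEnvironment <- function(model, task) {
  work <- model
  exch <- isExchange(work)
  work@reactions$lower_bound[exch] <- 0
  work@reactions$upper_bound[exch] <- 0

  tmp_added <- character(0)
  ensureExchange <- function(met) {
    # returns the exchange reaction id for extracellular metabolite `met`
    row <- match(met, work@metabolites$id)
    if (is.na(row)) {
      stop("task '", task@id, "' references unknown metabolite: ", met)
    }
    if (work@metabolites$compartment[row] != work@extracellular) {
      # look for an extracellular counterpart by shared base name
      base <- sub(paste0("_", work@metabolites$compartment[row], "$"), "",
                  met)
      cand <- work@metabolites$id[
        work@metabolites$compartment == work@extracellular &
          sub(paste0("_", work@extracellular, "$"), "",
              work@metabolites$id) == base]
      if (length(cand) != 1) {
        stop("task '", task@id, "' metabolite '", met,
             "' has no extracellular counterpart")
      }
      met <- cand
      row <- match(met, work@metabolites$id)
    }
    S <- work@stoichiometry
    col_hits <- which(S[row, ] != 0 & exchFlags(work))
    if (length(col_hits)) return(work@reactions$id[col_hits[1]])
    ex_id <- paste0("EX_", met, "_task")
    work <<- addReaction(work, ex_id,
                         stats::setNames(-1, met), 0, 0)
    tmp_added <<- c(tmp_added, ex_id)
    ex_id
  }
  exchFlags <- function(m) isExchange(m)

  if (nrow(task@inputs)) {
    for (i in seq_len(nrow(task@inputs))) {
      ex <- ensureExchange(task@inputs$metabolite[i])
      # uptake range (min, max) -> exchange flux in [-max, -min]
      work <- setReactionBounds(work, ex, -task@inputs$max[i],
                                -task@inputs$min[i])
    }
  }
  if (nrow(task@outputs)) {
    for (i in seq_len(nrow(task@outputs))) {
      ex <- ensureExchange(task@outputs$metabolite[i])
      work <- setReactionBounds(work, ex, task@outputs$min[i],
                                task@outputs$max[i])
    }
  }
  if (nrow(task@bounds)) {
    for (i in seq_len(nrow(task@bounds))) {
      work <- setReactionBounds(work, task@bounds$reaction[i],
                                task@bounds$lower_bound[i],
                                task@bounds$upper_bound[i])
    }
  }
  list(model = work, temporary_exchanges = tmp_added)
}
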