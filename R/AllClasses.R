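#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Genome-scale metabolic network model
#'
#' Container for a constraint-based metabolic model: metabolites with
#' compartments and optional KEGG compound identifiers, reactions with
#' bounds and gene-protein-reaction (GPR) rules, a sparse stoichiometric
#' matrix (metabolites in rows, reactions in columns), and a linear
#' objective. The model's gene set is always derived from the GPR leaves.
#'
#' @slot id Model identifier.
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `kegg_id`, `formula` (the last two may be `NA`).
#' @slot reactions `data.frame` with columns `id`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule string, `""` if absent), `subsystem`.
#' @slot stoichiometry Sparse `dgCMatrix`, metabolites x reactions, with
#'   dimnames matching the metabolite and reaction ids.
#' @slot gprs List of parsed `GPRExpression` trees (or `NULL`), named by
#'   reaction id, parallel to `reactions`.
#' @slot objective Named numeric vector of objective coefficients over a
#'   subset of reaction ids (may be empty).
#' @slot compartments Named character vector mapping compartment id to a
#'   display name.
#' @slot extracellular Compartment id of the extracellular space.
#' @slot notes List of free-form annotations (e.g. infeasibility reports).
#' @seealso [metabolicModel()], [fba()], [pfba()], [checkTask()],
#'   [fluxSample()]
#' @export
setClass("MetabolicModel", slots = c(
  id = "character",
  metabolites = "data.frame",
  reactions = "data.frame",
  stoichiometry = "Matrix",
  gprs = "list",
  objective = "numeric",
  compartments = "character",
  extracellular = "character",
  notes = "list"
))

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment", "kegg_id", "formula")
  need_rxn <- c("id", "lower_bound", "upper_bound", "gpr", "subsystem")
  if (!all(need_met %in% names(met))) {
    msg <- c(msg, "metabolites must have columns id, name, compartment, kegg_id, formula")
  }
  if (!all(need_rxn %in% names(rxn))) {
    msg <- c(msg, "reactions must have columns id, lower_bound, upper_bound, gpr, subsystem")
  }
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (!identical(rownames(S), met$id)) {
    msg <- c(msg, "stoichiometry rownames must equal metabolite ids")
  }
  if (!identical(colnames(S), rxn$id)) {
    msg <- c(msg, "stoichiometry colnames must equal reaction ids")
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    msg <- c(msg, paste0("lower_bound > upper_bound for: ",
                         paste(bad, collapse = ", ")))
  }
  if (nrow(rxn) > 0 && any(Matrix::colSums(S != 0) == 0)) {
    bad <- rxn$id[Matrix::colSums(S != 0) == 0]
    msg <- c(msg, paste0("reactions with empty stoichiometry: ",
                         paste(bad, collapse = ", ")))
  }
  if (!all(met$compartment %in% names(object@compartments))) {
    bad <- unique(met$compartment[!met$compartment %in% names(object@compartments)])
    msg <- c(msg, paste0("undeclared compartments: ", paste(bad, collapse = ", ")))
  }
  if (length(object@extracellular) != 1L ||
      !object@extracellular %in% names(object@compartments)) {
    msg <- c(msg, "extracellular must name one declared compartment")
  }
  if (!identical(names(object@gprs), rxn$id)) {
    msg <- c(msg, "gprs must be named by (and parallel to) reaction ids")
  }
  if (length(object@objective) &&
      !all(names(object@objective) %in% rxn$id)) {
    msg <- c(msg, "objective keys must be reaction ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicModel
#'
#' @param id Model identifier.
#' @param metabolites `data.frame` with at least columns `id` and
#'   `compartment`; `name`, `kegg_id` and `formula` are filled with defaults
#'   when absent.
#' @param reactions `data.frame` with at least columns `id`, `lower_bound`,
#'   `upper_bound`; `gpr` (rule string) and `subsystem` optional.
#' @param stoichiometry Either a metabolites x reactions matrix, or a list
#'   (named by reaction id) of named coefficient vectors
#'   (metabolite id -> signed coefficient).
#' @param objective Named numeric vector of objective coefficients.
#' @param compartments Named character vector (id -> name); inferred from
#'   the metabolites when missing.
#' @param extracellular Compartment id of the extracellular space
#'   (default `"e"`).
#' @return A validated [MetabolicModel-class].
#' @export
metabolicModel <- function(id, metabolites, reactions, stoichiometry,
                           objective = numeric(0), compartments = NULL,
                           extracellular = "e") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$kegg_id)) metabolites$kegg_id <- NA_character_
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  metabolites <- metabolites[, c("id", "name", "compartment", "kegg_id", "formula")]
  reactions <- reactions[, c("id", "lower_bound", "upper_bound", "gpr", "subsystem")]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
    S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      unknown <- setdiff(names(coefs), metabolites$id)
      if (length(unknown)) {
        stop("reaction '", rid, "' references undeclared metabolites: ",
             paste(unknown, collapse = ", "))
      }
      if (!rid %in% reactions$id) stop("stoichiometry for unknown reaction: ", rid)
      S[names(coefs), rid] <- coefs
    }
  } else {
    S <- Matrix::Matrix(as.matrix(stoichiometry), sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }
  if (is.null(compartments)) {
    ids <- unique(metabolites$compartment)
    compartments <- stats::setNames(ids, ids)
  }
  gprs <- lapply(reactions$gpr, parseGPR)
  names(gprs) <- reactions$id
  new("MetabolicModel", id = id, metabolites = metabolites,
      reactions = reactions, stoichiometry = methods::as(S, "CsparseMatrix"),
      gprs = gprs, objective = objective, compartments = compartments,
      extracellular = extracellular, notes = list())
}

#' Metabolic task: a required metabolic capability
#'
#' A task states ranges of allowed uptakes (`inputs`) and required
#' secretions (`outputs`) of extracellular metabolites, plus optional
#' reaction-bound overrides (e.g. to force a minimum flux through a demand
#' reaction). Task feasibility is checked with all exchange reactions not
#' mentioned by the task closed.
#'
#' @slot id,description Identifiers.
#' @slot inputs `data.frame(metabolite, min, max)` of uptake ranges.
#' @slot outputs `data.frame(metabolite, min, max)` of secretion ranges.
#' @slot bounds `data.frame(reaction, lower_bound, upper_bound)` overrides.
#' @slot curated_reactions Optional curated reaction list used by
#'   [taskReactionSet()] instead of the parsimonious active set.
#' @export
setClass("MetabolicTask", slots = c(
  id = "character",
  description = "character",
  inputs = "data.frame",
  outputs = "data.frame",
  bounds = "data.frame",
  curated_reactions = "characterOrNULL"
))

setValidity("MetabolicTask", function(object) {
  msg <- character(0)
  for (nm in c("inputs", "outputs")) {
    df <- slot(object, nm)
    if (!all(c("metabolite", "min", "max") %in% names(df))) {
      msg <- c(msg, paste0(nm, " needs columns metabolite, min, max"))
    } else if (nrow(df) && any(df$min > df$max)) {
      msg <- c(msg, paste0(nm, ": min > max"))
    }
  }
  if (nrow(object@bounds) &&
      !all(c("reaction", "lower_bound", "upper_bound") %in% names(object@bounds))) {
    msg <- c(msg, "bounds needs columns reaction, lower_bound, upper_bound")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicTask
#'
#' @param id,description Identifiers.
#' @param inputs,outputs Either `data.frame(metabolite, min, max)` or a
#'   named list `metabolite = c(min, max)`.
#' @param bounds Optional `data.frame(reaction, lower_bound, upper_bound)`.
#' @param curated_reactions Optional character vector of reaction ids.
#' @return A [MetabolicTask-class].
#' @export
metabolicTask <- function(id, description = id, inputs = list(),
                          outputs = list(), bounds = NULL,
                          curated_reactions = NULL) {
  as_range_df <- function(x) {
    if (is.data.frame(x)) return(x)
    if (length(x) == 0) {
      return(data.frame(metabolite = character(0), min = numeric(0),
                        max = numeric(0)))
    }
    data.frame(metabolite = names(x),
               min = vapply(x, function(v) v[1], numeric(1)),
               max = vapply(x, function(v) v[2], numeric(1)),
               row.names = NULL)
  }
  if (is.null(bounds)) {
    bounds <- data.frame(reaction = character(0), lower_bound = numeric(0),
                         upper_bound = numeric(0))
  }
  new("MetabolicTask", id = id, description = description,
      inputs = as_range_df(inputs), outputs = as_range_df(outputs),
      bounds = bounds, curated_reactions = curated_reactions)
}

#' Single flux distribution from an LP solve
#'
#' @slot fluxes Named numeric vector over reaction ids.
#' @slot objective_value Objective at the solution (`NA` if not optimal).
#' @slot status One of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @export
setClass("FluxDistribution", slots = c(
  fluxes = "numeric",
  objective_value = "numeric",
  status = "character"
))

#' Set of sampled flux distributions for one condition
#'
#' @slot condition Condition label.
#' @slot reaction_ids Ordered reaction ids (columns of `samples`).
#' @slot samples Numeric matrix, one sampled flux vector per row.
#' @slot seed Integer seed used for sampling.
#' @export
setClass("FluxSampleSet", slots = c(
  condition = "character",
  reaction_ids = "character",
  samples = "matrix",
  seed = "integer"
))

setValidity("FluxSampleSet", function(object) {
  if (!identical(colnames(object@samples), object@reaction_ids)) {
    return("sample columns must match reaction_ids")
  }
  TRUE
})

#' Per-gene signed weight table
#'
#' Maps model genes to signed weights (the log2 fold change of genes below
#' the FDR threshold, 0 otherwise) for GPR propagation and task scoring.
#'
#' @slot weights Named numeric vector over gene ids.
#' @slot provenance One of `"de_derived"`, `"shuffled"`, `"synthetic"`.
#' @slot n_unmapped Number of differential-expression rows dropped because
#'   the gene is not in the model.
#' @export
setClass("GeneWeightTable", slots = c(
  weights = "numeric",
  provenance = "character",
  n_unmapped = "integer"
))

setValidity("GeneWeightTable", function(object) {
  if (length(object@weights) && is.null(names(object@weights))) {
    return("weights must be named by gene id")
  }
  if (any(!is.finite(object@weights))) return("weights must be finite")
  if (!object@provenance %in% c("de_derived", "shuffled", "synthetic")) {
    return("provenance must be de_derived, shuffled or synthetic")
  }
  TRUE
})

#' @describeIn GeneWeightTable-class Constructor.
#' @param weights Named numeric vector of per-gene signed weights.
#' @param provenance Provenance tag.
#' @param n_unmapped Count of dropped non-model genes.
#' @export
geneWeightTable <- function(weights, provenance = "synthetic",
                            n_unmapped = 0L) {
  new("GeneWeightTable", weights = weights, provenance = provenance,
      n_unmapped = as.integer(n_unmapped))
}

#' Condition-specific constraint recipe
#'
#' The constraint recipe applied before transcript-guided model extraction:
#' exchanges of consumed metabolites opened to a fixed uptake bound
#' (theoretical overabundance), an ATP-hydrolysis objective with a finite
#' upper bound, fixed DNA and RNA maintenance demands, and a uniform upper
#' bound on internal reactions.
#'
#' @slot consumed_metabolites Extracellular metabolite ids measured as
#'   consumed.
#' @slot uptake_bound Lower bound applied to their exchanges (default -10).
#' @slot objective_reaction Reaction id of the ATP-hydrolysis demand.
#' @slot objective_upper_bound Upper bound on the objective flux
#'   (default 100).
#' @slot maintenance Named numeric vector of demand-reaction ids -> fixed
#'   flux (default 1 unit each for the DNA and RNA demands).
#' @slot internal_upper_bound Upper bound applied to all non-exchange
#'   reactions (default 1e6).
#' @export
setClass("ConditionConstraints", slots = c(
  consumed_metabolites = "character",
  uptake_bound = "numeric",
  objective_reaction = "character",
  objective_upper_bound = "numeric",
  maintenance = "numeric",
  internal_upper_bound = "numeric"
))

setValidity("ConditionConstraints", function(object) {
  msg <- character(0)
  if (object@uptake_bound >= 0) msg <- c(msg, "uptake_bound must be < 0")
  vals <- c(object@uptake_bound, object@objective_upper_bound,
            object@maintenance, object@internal_upper_bound)
  if (any(!is.finite(vals))) msg <- c(msg, "all bounds must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConditionConstraints-class Constructor with the default
#'   recipe values.
#' @param consumed_metabolites,uptake_bound,objective_reaction See slots.
#' @param objective_upper_bound,maintenance,internal_upper_bound See slots.
#' @export
conditionConstraints <- function(consumed_metabolites,
                                 objective_reaction,
                                 maintenance,
                                 uptake_bound = -10,
                                 objective_upper_bound = 100,
                                 internal_upper_bound = 1e6) {
  new("ConditionConstraints",
      consumed_metabolites = consumed_metabolites,
      uptake_bound = uptake_bound,
      objective_reaction = objective_reaction,
      objective_upper_bound = objective_upper_bound,
      maintenance = maintenance,
      internal_upper_bound = internal_upper_bound)
}
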