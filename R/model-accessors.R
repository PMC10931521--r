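## Accessors and editing helpers for MetabolicModel and friends.

#' @rdname modelAccessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname modelAccessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname modelAccessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @rdname modelAccessors
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))
#' @rdname modelAccessors
#' @export
setGeneric("reactionBounds", function(object) standardGeneric("reactionBounds"))
#' @rdname modelAccessors
#' @export
setGeneric("objectiveCoefficients",
           function(object) standardGeneric("objectiveCoefficients"))
#' @rdname modelAccessors
#' @export
setGeneric("objectiveCoefficients<-",
           function(object, value) standardGeneric("objectiveCoefficients<-"))
#' @rdname modelAccessors
#' @export
setGeneric("isExchange", function(object) standardGeneric("isExchange"))
#' @rdname modelAccessors
#' @export
setGeneric("gprOf", function(object, reaction) standardGeneric("gprOf"))

#' Model accessors
#'
#' @param object A [MetabolicModel-class].
#' @param reaction A reaction id.
#' @param value Replacement value.
#' @name modelAccessors
NULL

#' @rdname modelAccessors
setMethod("reactionIds", "MetabolicModel", function(object) {
  object@reactions$id
})

#' @rdname modelAccessors
setMethod("metaboliteIds", "MetabolicModel", function(object) {
  object@metabolites$id
})

#' @rdname modelAccessors
setMethod("modelGenes", "MetabolicModel", function(object) {
  sort(unique(unlist(lapply(object@gprs, gprGenes))))
})

#' @rdname modelAccessors
setMethod("stoichMatrix", "MetabolicModel", function(object) {
  object@stoichiometry
})

#' @rdname modelAccessors
setMethod("reactionBounds", "MetabolicModel", function(object) {
  data.frame(id = object@reactions$id,
             lower_bound = object@reactions$lower_bound,
             upper_bound = object@reactions$upper_bound)
})

#' @rdname modelAccessors
setMethod("objectiveCoefficients", "MetabolicModel", function(object) {
  object@objective
})

#' @rdname modelAccessors
setMethod("objectiveCoefficients<-", "MetabolicModel", function(object, value) {
  object@objective <- value
  validObject(object)
  object
})

#' @rdname modelAccessors
setMethod("isExchange", "MetabolicModel", function(object) {
  S <- object@stoichiometry
  n_mets <- Matrix::colSums(S != 0)
  extracellular_met <- object@metabolites$compartment == object@extracellular
  touches_only_extra <- Matrix::colSums(S[!extracellular_met, , drop = FALSE] != 0) == 0
  ans <- n_mets == 1 & touches_only_extra
  stats::setNames(as.logical(ans), object@reactions$id)
})

#' @rdname modelAccessors
setMethod("gprOf", "MetabolicModel", function(object, reaction) {
  object@gprs[[reaction]]
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@id, "'\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions (",
      sum(isExchange(object)), " exchanges), ",
      length(modelGenes(object)), " genes\n", sep = "")
  cat("  compartments: ",
      paste(names(object@compartments), collapse = ", "),
      " (extracellular: ", object@extracellular, ")\n", sep = "")
  if (length(object@objective)) {
    cat("  objective:",
        paste(sprintf("%g*%s", object@objective, names(object@objective)),
              collapse = " + "), "\n")
  }
})

setMethod("show", "MetabolicTask", function(object) {
  cat("MetabolicTask '", object@id, "': ", object@description, "\n", sep = "")
  cat("  inputs: ", nrow(object@inputs), ", outputs: ", nrow(object@outputs),
      ", bound overrides: ", nrow(object@bounds), "\n", sep = "")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, ")", sep = "")
  if (object@status == "optimal") {
    cat(": objective ", format(object@objective_value), ", ",
        sum(abs(object@fluxes) > 1e-9), "/", length(object@fluxes),
        " active reactions", sep = "")
  }
  cat("\n")
})

setMethod("show", "FluxSampleSet", function(object) {
  cat("FluxSampleSet '", object@condition, "': ", nrow(object@samples),
      " samples x ", length(object@reaction_ids), " reactions (seed ",
      object@seed, ")\n", sep = "")
})

setMethod("show", "GeneWeightTable", function(object) {
  w <- object@weights
  cat("GeneWeightTable (", object@provenance, "): ", length(w), " genes, ",
      sum(w != 0), " nonzero", sep = "")
  if (object@n_unmapped > 0) cat(", ", object@n_unmapped, " unmapped dropped")
  cat("\n")
})

#' @describeIn GeneWeightTable-class Extract the named weight vector.
#' @param object A `GeneWeightTable`.
#' @export
geneWeights <- function(object) object@weights

#' Sampled flux matrix
#'
#' @param object A [FluxSampleSet-class].
#' @return Numeric matrix, samples in rows, reactions in columns.
#' @export
sampleMatrix <- function(object) object@samples

## ---- editing helpers ----------------------------------------------------

#' Modify reaction bounds
#'
#' @param model A [MetabolicModel-class].
#' @param reaction Character vector of reaction ids.
#' @param lower_bound,upper_bound Replacement bounds (recycled); `NA` leaves
#'   the existing bound unchanged.
#' @return The modified model.
#' @export
setReactionBounds <- function(model, reaction, lower_bound = NA,
                              upper_bound = NA) {
  idx <- match(reaction, model@reactions$id)
  if (anyNA(idx)) {
    stop("unknown reactions: ", paste(reaction[is.na(idx)], collapse = ", "))
  }
  lb <- rep_len(lower_bound, length(idx))
  ub <- rep_len(upper_bound, length(idx))
  keep_lb <- is.na(lb)
  keep_ub <- is.na(ub)
  model@reactions$lower_bound[idx[!keep_lb]] <- lb[!keep_lb]
  model@reactions$upper_bound[idx[!keep_ub]] <- ub[!keep_ub]
  validObject(model)
  model
}

#' Add a reaction to a model
#'
#' @param model A [MetabolicModel-class].
#' @param id New reaction id.
#' @param stoichiometry Named numeric vector (metabolite id -> coefficient);
#'   all metabolites must already exist in the model.
#' @param lower_bound,upper_bound Flux bounds.
#' @param gpr Optional GPR rule string.
#' @param subsystem Optional subsystem label.
#' @return The extended model.
#' @export
addReaction <- function(model, id, stoichiometry, lower_bound = 0,
                        upper_bound = 1000, gpr = "", subsystem = NA_character_) {
  if (id %in% model@reactions$id) stop("reaction already present: ", id)
  unknown <- setdiff(names(stoichiometry), model@metabolites$id)
  if (length(unknown)) {
    stop("reaction '", id, "' references undeclared metabolites: ",
         paste(unknown, collapse = ", "))
  }
  model@reactions <- rbind(model@reactions, data.frame(
    id = id, lower_bound = lower_bound, upper_bound = upper_bound,
    gpr = gpr, subsystem = subsystem))
  newcol <- Matrix::Matrix(0, nrow(model@metabolites), 1, sparse = TRUE,
                           dimnames = list(model@metabolites$id, id))
  newcol[names(stoichiometry), 1] <- stoichiometry
  model@stoichiometry <- methods::as(cbind(model@stoichiometry, newcol),
                                     "CsparseMatrix")
  model@gprs <- c(model@gprs, stats::setNames(list(parseGPR(gpr)), id))
  validObject(model)
  model
}

#' Drop reactions (and resulting orphan metabolites) from a model
#'
#' @param model A [MetabolicModel-class].
#' @param reactions Reaction ids to remove.
#' @param drop_orphans Remove metabolites left in no reaction
#'   (default TRUE).
#' @return The reduced model.
#' @export
removeReactions <- function(model, reactions, drop_orphans = TRUE) {
  idx <- match(reactions, model@reactions$id)
  if (anyNA(idx)) {
    stop("unknown reactions: ", paste(reactions[is.na(idx)], collapse = ", "))
  }
  keep <- setdiff(seq_len(nrow(model@reactions)), idx)
  model@reactions <- model@reactions[keep, , drop = FALSE]
  rownames(model@reactions) <- NULL
  model@stoichiometry <- model@stoichiometry[, keep, drop = FALSE]
  model@gprs <- model@gprs[keep]
  model@objective <- model@objective[names(model@objective) %in% model@reactions$id]
  if (drop_orphans) {
    used <- Matrix::rowSums(model@stoichiometry != 0) > 0
    model@metabolites <- model@metabolites[used, , drop = FALSE]
    rownames(model@metabolites) <- NULL
    model@stoichiometry <- model@stoichiometry[used, , drop = FALSE]
  }
  validObject(model)
  model
}

#' Restrict a model to a reaction subset
#'
#' Keeps the given reactions and the metabolites they use; the objective is
#' restricted to surviving reactions.
#'
#' @param model A [MetabolicModel-class].
#' @param reactions Reaction ids to keep.
#' @return The sub-model.
#' @export
subModel <- function(model, reactions) {
  removeReactions(model, setdiff(model@reactions$id, reactions))
}
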