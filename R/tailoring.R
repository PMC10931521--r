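## Tissue/condition model tailoring with an auditable curation ledger.

emptyLedger <- function() {
  data.frame(reaction_id = character(0), action = character(0),
             reason = character(0), source = character(0))
}

ledgerEntry <- function(reaction_id, action, reason, source) {
  data.frame(reaction_id = reaction_id, action = action, reason = reason,
             source = source)
}

#' Build a tissue model by mapping reference reactions from a general model
#'
#' Extracts the subnetwork of a general (species-level) model spanned by a
#' reference tissue reaction list plus user-curated species-specific
#' additions, by shared reaction identifiers. Metabolites left in no
#' reaction are excluded. Reference ids absent from the general model are
#' reported in the ledger (`action = "unmappable"`), never silently
#' dropped; unknown species-specific additions are an error.
#'
#' @param general_model A [MetabolicModel-class].
#' @param reference_reaction_ids Reaction ids defining the tissue model.
#' @param extra_reactions Additional (species-specific) reaction ids
#'   (default none).
#' @return List with `model` (the tissue [MetabolicModel-class]) and
#'   `ledger` (a curation `data.frame`: reaction_id, action, reason,
#'   source).
#' @export
mapReferenceReactions <- function(general_model, reference_reaction_ids,
                                  extra_reactions = character(0)) {
  all_ids <- reactionIds(general_model)
  unknown_extra <- setdiff(extra_reactions, all_ids)
  if (length(unknown_extra)) {
    stop("species-specific additions not in the general model: ",
         paste(unknown_extra, collapse = ", "))
  }
  unmappable <- setdiff(reference_reaction_ids, all_ids)
  mapped <- intersect(reference_reaction_ids, all_ids)
  keep <- union(mapped, extra_reactions)
  model <- subModel(general_model, keep)

  ledger <- rbind(
    if (length(mapped)) ledgerEntry(mapped, "mapped",
                                    "shared reaction identifier",
                                    "reference_model"),
    if (length(setdiff(extra_reactions, mapped)))
      ledgerEntry(setdiff(extra_reactions, mapped), "added_species_specific",
                  "curated species-specific addition", "general_model"),
    if (length(unmappable)) ledgerEntry(unmappable, "unmappable",
                                        "not present in general model",
                                        "reference_model"))
  list(model = model, ledger = ledger)
}

#' Add exchange reactions for measured metabolites
#'
#' For every measured metabolite (by KEGG compound id) with a significant
#' produced-or-consumed call versus blank media, whose exchange reaction
#' exists in the general model but not in the tissue model, that exchange
#' is copied over. When the extracellular species itself is disconnected in
#' the tissue model, the lexicographically first transport reaction linking
#' it to the rest of the tissue model is co-added from the general model
#' (an exchange without its transporter is dead); each co-addition gets its
#' own ledger entry. The operation is idempotent.
#'
#' @param model Tissue [MetabolicModel-class].
#' @param general_model General [MetabolicModel-class] (superset).
#' @param measured Character vector of measured KEGG compound ids.
#' @param change_calls Classification output of [classifyMetabolites()]
#'   (its `classes` component, or the list itself), or `NULL` to treat all
#'   measured metabolites as changed.
#' @param kegg_map Optional `data.frame(kegg_id, metabolite)` mapping
#'   measured compound ids to rownames of the abundance data (defaults to
#'   treating measured ids as KEGG ids present on the models).
#' @return List with `model`, `ledger`, and `counts`
#'   (`matched`, `with_exchange`, `added`).
#' @export
addExchangesForMeasured <- function(model, general_model, measured,
                                    change_calls = NULL, kegg_map = NULL) {
  changed_kegg <- measured
  if (!is.null(change_calls)) {
    classes <- if (is.list(change_calls) && !is.data.frame(change_calls)) {
      change_calls$classes
    } else {
      change_calls
    }
    keep_class <- c("consumed_only", "produced_or_consumed")
    changed <- classes$metabolite[classes$class %in% keep_class]
    if (!is.null(kegg_map)) {
      changed <- kegg_map$kegg_id[kegg_map$metabolite %in% changed]
    }
    changed_kegg <- intersect(measured, changed)
  }

  gmet <- general_model@metabolites
  extra_comp <- general_model@extracellular
  ledger <- emptyLedger()
  n_matched <- 0L
  n_with_exchange <- 0L
  n_added <- 0L
  out <- model

  for (kegg in changed_kegg) {
    hits <- gmet$id[!is.na(gmet$kegg_id) & gmet$kegg_id == kegg &
                      gmet$compartment == extra_comp]
    if (length(hits) > 1) {
      stop("measured compound ", kegg, " maps to multiple extracellular ",
           "metabolites: ", paste(hits, collapse = ", "))
    }
    if (!length(hits)) next
    n_matched <- n_matched + 1L
    met <- hits
    ex_general <- exchangeFor(general_model, met)
    if (is.na(ex_general)) next
    n_with_exchange <- n_with_exchange + 1L

    if (ex_general %in% reactionIds(out)) {
      ledger <- rbind(ledger, ledgerEntry(ex_general, "present",
                                          paste0("exchange for ", kegg,
                                                 " already in model"),
                                          "metabolomics"))
      next
    }
    out <- copyReactionFrom(out, general_model, ex_general)
    n_added <- n_added + 1L
    ledger <- rbind(ledger, ledgerEntry(
      ex_general, "added_exchange",
      paste0("measured compound ", kegg, " produced/consumed vs blank"),
      "metabolomics"))

    # transport-chain completion: the extracellular species must connect
    # to a non-exchange reaction of the tissue model
    transporters <- transportReactionsFor(general_model, met)
    present <- intersect(transporters, reactionIds(out))
    if (!length(present) && length(transporters)) {
      tr <- sort(transporters)[1]
      out <- copyReactionFrom(out, general_model, tr)
      ledger <- rbind(ledger, ledgerEntry(
        tr, "added_transport",
        paste0("transport chain completion for ", met), "general_model"))
    }
  }
  list(model = out, ledger = ledger,
       counts = c(matched = n_matched, with_exchange = n_with_exchange,
                  added = n_added))
}

exchangeFor <- function(model, met) {
  ex <- isExchange(model)
  row <- match(met, model@metabolites$id)
  hits <- which(model@stoichiometry[row, ] != 0 & ex)
  if (length(hits)) model@reactions$id[hits[1]] else NA_character_
}

transportReactionsFor <- function(model, met) {
  ex <- isExchange(model)
  row <- match(met, model@metabolites$id)
  hits <- which(model@stoichiometry[row, ] != 0 & !ex)
  model@reactions$id[hits]
}

copyReactionFrom <- function(model, source_model, rid) {
  i <- match(rid, source_model@reactions$id)
  col <- source_model@stoichiometry[, i]
  col <- col[col != 0]
  # bring along any missing metabolites
  missing_mets <- setdiff(names(col), model@metabolites$id)
  if (length(missing_mets)) {
    add <- source_model@metabolites[
      source_model@metabolites$id %in% missing_mets, , drop = FALSE]
    model@metabolites <- rbind(model@metabolites, add)
    rownames(model@metabolites) <- NULL
    pad <- Matrix::Matrix(0, nrow(add), ncol(model@stoichiometry),
                          sparse = TRUE,
                          dimnames = list(add$id, colnames(model@stoichiometry)))
    model@stoichiometry <- methods::as(rbind(model@stoichiometry, pad),
                                       "CsparseMatrix")
    new_comp <- setdiff(unique(add$compartment), names(model@compartments))
    if (length(new_comp)) {
      model@compartments <- c(model@compartments,
                              source_model@compartments[new_comp])
    }
  }
  addReaction(model, rid, col,
              lower_bound = source_model@reactions$lower_bound[i],
              upper_bound = source_model@reactions$upper_bound[i],
              gpr = source_model@reactions$gpr[i],
              subsystem = source_model@reactions$subsystem[i])
}

#' Apply the condition-specific constraint recipe
#'
#' Sets the exchanges of consumed metabolites to the uptake bound
#' (default lower bound -10, a theoretical overabundance), installs the
#' ATP-hydrolysis objective with its upper bound (default 100 flux units),
#' fixes the DNA and RNA maintenance demands (default 1 unit each), and
#' raises the upper bound of every internal (non-exchange) reaction to the
#' internal bound (default 1e6) so internal fluxes do not constrain the
#' solution space. If the constrained model is infeasible, each maintenance
#' demand is relaxed in turn to name the blocking demands in an
#' infeasibility report (stored in `model@notes$infeasibility`).
#'
#' @param model A [MetabolicModel-class].
#' @param cc A [ConditionConstraints-class].
#' @return The constrained model; feasibility (or the blocking demands) is
#'   recorded in `model@notes`.
#' @export
applyConditionConstraints <- function(model, cc) {
  missing_rxn <- setdiff(c(cc@objective_reaction, names(cc@maintenance)),
                         reactionIds(model))
  if (length(missing_rxn)) {
    stop("constraint recipe references missing reactions: ",
         paste(missing_rxn, collapse = ", "))
  }
  out <- model
  ex_flag <- isExchange(out)

  # consumed metabolite exchanges opened to the uptake bound
  for (met in cc@consumed_metabolites) {
    ex <- exchangeFor(out, met)
    if (is.na(ex)) stop("no exchange reaction for consumed metabolite: ", met)
    out <- setReactionBounds(out, ex, lower_bound = cc@uptake_bound)
  }

  # internal (non-exchange) upper bounds
  internal <- reactionIds(out)[!ex_flag]
  internal <- setdiff(internal, c(cc@objective_reaction, names(cc@maintenance)))
  out <- setReactionBounds(out, internal,
                           upper_bound = cc@internal_upper_bound)

  # objective: ATP hydrolysis, bounded above
  out <- setReactionBounds(out, cc@objective_reaction, lower_bound = 0,
                           upper_bound = cc@objective_upper_bound)
  out@objective <- stats::setNames(1, cc@objective_reaction)

  # maintenance demands fixed
  for (d in names(cc@maintenance)) {
    out <- setReactionBounds(out, d, lower_bound = cc@maintenance[[d]],
                             upper_bound = cc@maintenance[[d]])
  }

  sol <- fba(out)
  if (sol@status == "optimal") {
    out@notes$feasible <- TRUE
  } else {
    blocking <- character(0)
    for (d in names(cc@maintenance)) {
      relaxed <- setReactionBounds(out, d, lower_bound = 0, upper_bound = 0)
      if (fba(relaxed)@status == "optimal") blocking <- c(blocking, d)
    }
    out@notes$feasible <- FALSE
    out@notes$infeasibility <- list(
      blocking_demands = blocking,
      message = if (length(blocking)) {
        paste("infeasible; blocking maintenance demands:",
              paste(blocking, collapse = ", "))
      } else {
        "infeasible; no single maintenance demand explains it"
      })
    warning(out@notes$infeasibility$message)
  }
  out
}

#' Write a curation ledger as TSV
#'
#' @param ledger Ledger `data.frame`.
#' @param path Output path.
#' @export
writeLedger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
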