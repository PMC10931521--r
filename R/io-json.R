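## JSON model dialect.
##
## Schema (documented contract, stable across versions):
## {
##   "id": "model id",
##   "compartments": {"c": "cytosol", "e": "extracellular"},
##   "extracellular": "e",
##   "metabolites": [{"id","name","compartment","kegg_id","formula"}, ...],
##   "reactions":  [{"id","stoichiometry":{"met": coef, ...},
##                   "lower_bound","upper_bound","gpr","subsystem"}, ...],
##   "objective": {"reaction id": coefficient, ...}
## }
## kegg_id / formula / subsystem may be null; gpr is "" when absent.

#' Read a metabolic model
#'
#' @param path File path.
#' @param format `"json"` (the package's documented dialect) or `"sbml"`
#'   (SBML Level 3 with the FBC package); guessed from the file extension
#'   when omitted.
#' @return A [MetabolicModel-class].
#' @seealso [writeModel()]
#' @export
readModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = readModelJSON(path), sbml = readModelSBML(path))
}

#' Write a metabolic model
#'
#' @param model A [MetabolicModel-class].
#' @param path Output path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = writeModelJSON(model, path),
         sbml = writeModelSBML(model, path))
  invisible(path)
}

readModelJSON <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON model '", path,
                                           "': ", conditionMessage(e)))
  for (field in c("id", "compartments", "metabolites", "reactions")) {
    if (is.null(doc[[field]])) stop("JSON model missing field: ", field)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               kegg_id = m$kegg_id %||% NA_character_,
               formula = m$formula %||% NA_character_)
  }))
  known <- mets$id
  stoich <- list()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    coefs <- unlist(r$stoichiometry)
    unknown <- setdiff(names(coefs), known)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    stoich[[r$id]] <<- coefs
    data.frame(id = r$id, lower_bound = r$lower_bound,
               upper_bound = r$upper_bound, gpr = r$gpr %||% "",
               subsystem = r$subsystem %||% NA_character_)
  }))
  comp <- unlist(doc$compartments)
  bad <- setdiff(unique(mets$compartment), names(comp))
  if (length(bad)) {
    stop("metabolites use undeclared compartments: ",
         paste(bad, collapse = ", "))
  }
  objective <- unlist(doc$objective) %||% numeric(0)
  storage.mode(objective) <- "double"
  metabolicModel(id = doc$id, metabolites = mets, reactions = rxns,
                 stoichiometry = stoich,
                 objective = objective,
                 compartments = comp,
                 extracellular = doc$extracellular %||% "e")
}

writeModelJSON <- function(model, path) {
  rxn_list <- lapply(seq_len(nrow(model@reactions)), function(i) {
    rid <- model@reactions$id[i]
    col <- model@stoichiometry[, i]
    col <- col[col != 0]
    list(id = rid,
         stoichiometry = as.list(col),
         lower_bound = model@reactions$lower_bound[i],
         upper_bound = model@reactions$upper_bound[i],
         gpr = model@reactions$gpr[i],
         subsystem = model@reactions$subsystem[i])
  })
  met_list <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    as.list(model@metabolites[i, c("id", "name", "compartment", "kegg_id",
                                   "formula")])
  })
  doc <- list(id = model@id,
              compartments = as.list(model@compartments),
              extracellular = model@extracellular,
              metabolites = met_list,
              reactions = rxn_list,
              objective = as.list(model@objective))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write a flux sample set as TSV
#'
#' Reactions as columns (header row), one sampled flux vector per row,
#' preceded by the condition label column.
#'
#' @param x A [FluxSampleSet-class].
#' @param path Output path.
#' @export
writeFluxSamples <- function(x, path) {
  df <- data.frame(condition = x@condition, x@samples, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux sample set written by [writeFluxSamples()]
#'
#' @param path TSV path.
#' @param seed Seed to record on the object (not re-derivable from file).
#' @export
readFluxSamples <- function(path, seed = NA_integer_) {
  df <- utils::read.delim(path, check.names = FALSE)
  new("FluxSampleSet", condition = as.character(df$condition[1]),
      reaction_ids = setdiff(colnames(df), "condition"),
      samples = as.matrix(df[, setdiff(colnames(df), "condition"),
                             drop = FALSE]),
      seed = as.integer(seed))
}
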