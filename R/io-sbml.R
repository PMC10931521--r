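## SBML Level 3 (FBC version 2) interchange.
##
## Species/reaction/gene ids are namespaced with the conventional M_/R_/G_
## prefixes on write and stripped on read. KEGG compound ids travel in the
## species notes as "KEGG: Cxxxxx"; bounds become shared fbc parameters;
## GPRs are written as fbc:geneProductAssociation trees.

SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  xhtml = "http://www.w3.org/1999/xhtml"
)

writeModelSBML <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS[["sbml"]],
    "xmlns:fbc" = SBML_NS[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbmlId(model@id),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_along(model@compartments)) {
    xml2::xml_add_child(comps, "compartment",
                        id = names(model@compartments)[i],
                        name = model@compartments[[i]], constant = "true")
  }

  species <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    attrs <- list(id = paste0("M_", sbmlId(m$id)), name = m$name,
                  compartment = m$compartment,
                  hasOnlySubstanceUnits = "false",
                  boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula)) attrs[["fbc:chemicalFormula"]] <- m$formula
    sp <- do.call(xml2::xml_add_child, c(list(species, "species"), attrs))
    if (!is.na(m$kegg_id)) {
      notes <- xml2::xml_add_child(sp, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = SBML_NS[["xhtml"]])
      xml2::xml_add_child(body, "p", paste0("KEGG: ", m$kegg_id))
    }
  }

  # shared bound parameters
  bounds <- sort(unique(c(model@reactions$lower_bound,
                          model@reactions$upper_bound)))
  bound_id <- stats::setNames(
    sprintf("bnd_%d", seq_along(bounds) - 1L),
    vapply(bounds, format, character(1), digits = 17))
  params <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(params, "parameter", id = bound_id[[i]],
                        value = format(bounds[i], digits = 17),
                        constant = "true")
  }

  if (length(model@objective)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model@objective)) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective",
                          "fbc:reaction" = paste0("R_", sbmlId(rid)),
                          "fbc:coefficient" =
                            format(model@objective[[rid]], digits = 17))
    }
  }

  genes <- modelGenes(model)
  if (length(genes)) {
    lgp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lgp, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbmlId(g)),
                          "fbc:label" = g)
    }
  }

  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model@reactions))) {
    r <- model@reactions[i, ]
    rx <- xml2::xml_add_child(
      rxns, "reaction", id = paste0("R_", sbmlId(r$id)),
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bound_id[[format(r$lower_bound, digits = 17)]],
      "fbc:upperFluxBound" = bound_id[[format(r$upper_bound, digits = 17)]])
    col <- model@stoichiometry[, i]
    col <- col[col != 0]
    reactants <- col[col < 0]
    products <- col[col > 0]
    if (length(reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (met in names(reactants)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sbmlId(met)),
                            stoichiometry = format(-reactants[[met]],
                                                   digits = 17),
                            constant = "true")
      }
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (met in names(products)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sbmlId(met)),
                            stoichiometry = format(products[[met]],
                                                   digits = 17),
                            constant = "true")
      }
    }
    gpr <- model@gprs[[i]]
    if (!is.null(gpr)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      addGPANode(gpa, gpr)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

addGPANode <- function(parent, expr) {
  if (expr$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbmlId(expr$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", expr$kind))
    for (ch in expr$children) addGPANode(node, ch)
  }
}

fbcAttr <- function(node, name) {
  a <- xml2::xml_attr(node, paste0("fbc:", name))
  if (all(is.na(a))) a <- xml2::xml_attr(node, name)
  a
}

sbmlId <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

readModelSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- SBML_NS
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  comp_nodes <- xml2::xml_find_all(mdl, ".//sbml:listOfCompartments/sbml:compartment", ns)
  compartments <- stats::setNames(
    vapply(comp_nodes, function(n) {
      nm <- xml2::xml_attr(n, "name")
      if (is.na(nm)) xml2::xml_attr(n, "id") else nm
    }, character(1)),
    xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp_nodes, "id")),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  sub("^M_", "", xml2::xml_attr(sp_nodes, "id")),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    kegg_id = vapply(sp_nodes, function(n) {
      txt <- xml2::xml_text(xml2::xml_find_first(
        n, ".//xhtml:p[starts-with(text(), 'KEGG: ')]", ns))
      if (is.na(txt)) NA_character_ else sub("^KEGG: ", "", txt)
    }, character(1)),
    formula = fbcAttr(sp_nodes, "chemicalFormula"))
  bad <- setdiff(unique(mets$compartment), names(compartments))
  if (length(bad)) {
    stop("species use undeclared compartments: ", paste(bad, collapse = ", "))
  }

  par_nodes <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_label <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                                xml2::xml_attr(gp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction", ns)
  known <- mets$id
  stoich <- list()
  rxns <- do.call(rbind, lapply(rx_nodes, function(n) {
    rid <- sub("^R_", "", xml2::xml_attr(n, "id"))
    coefs <- numeric(0)
    for (ref in xml2::xml_find_all(n, ".//sbml:listOfReactants/sbml:speciesReference", ns)) {
      met <- sub("^M_", "", xml2::xml_attr(ref, "species"))
      coefs[met] <- (if (met %in% names(coefs)) coefs[met] else 0) -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(n, ".//sbml:listOfProducts/sbml:speciesReference", ns)) {
      met <- sub("^M_", "", xml2::xml_attr(ref, "species"))
      coefs[met] <- (if (met %in% names(coefs)) coefs[met] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    unknown <- setdiff(names(coefs), known)
    if (length(unknown)) {
      stop("reaction '", rid, "' references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    lb_ref <- fbcAttr(n, "lowerFluxBound")
    ub_ref <- fbcAttr(n, "upperFluxBound")
    gpa <- xml2::xml_find_first(n, ".//fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      renderGPR(parseGPANode(gpa, gene_label, ns))
    stoich[[rid]] <<- coefs
    data.frame(id = rid, lower_bound = par_val[[lb_ref]],
               upper_bound = par_val[[ub_ref]], gpr = gpr,
               subsystem = NA_character_)
  }))

  fo_nodes <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- stats::setNames(
    as.numeric(fbcAttr(fo_nodes, "coefficient")),
    sub("^R_", "", fbcAttr(fo_nodes, "reaction")))

  extracellular <- guessExtracellular(names(compartments), compartments)
  metabolicModel(id = sub("^M_", "", xml2::xml_attr(mdl, "id")),
                 metabolites = mets, reactions = rxns, stoichiometry = stoich,
                 objective = objective, compartments = compartments,
                 extracellular = extracellular)
}

parseGPANode <- function(node, gene_label, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- fbcAttr(node, "geneProduct")
    label <- gene_label[[ref]]
    gprLeaf(if (is.null(label) || is.na(label)) sub("^G_", "", ref) else label)
  } else if (nm %in% c("and", "or")) {
    gprNode(nm, lapply(xml2::xml_children(node), parseGPANode,
                       gene_label = gene_label, ns = ns))
  } else {
    stop("unsupported geneProductAssociation node: ", nm)
  }
}

guessExtracellular <- function(ids, named) {
  hit <- ids[tolower(named) %in% c("extracellular", "extracellular space") |
               ids %in% c("e", "e0", "ext")]
  if (length(hit)) hit[1] else ids[1]
}
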