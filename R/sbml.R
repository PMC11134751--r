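SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sid_encode <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", id))
sid_decode <- function(prefix, sid) sub(paste0("^", prefix), "", sid)

#' Write a model to SBML (Level 3, fbc version 2)
#'
#' Species carry `fbc:chemicalFormula`/`fbc:charge`, bounds are shared
#' `listOfParameters` entries referenced through `fbc:lowerFluxBound` /
#' `fbc:upperFluxBound`, GPRs become `fbc:geneProductAssociation` trees and
#' the objective an `fbc:listOfObjectives` entry.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x)
  }
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 17)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    "    <listOfCompartments>")
  for (cid in sort(unique(model$metabolites$compartment)))
    lines <- c(lines, sprintf(
      '      <compartment id="%s" name="%s" constant="true"/>',
      cid, model_compartments[[cid]]))
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', esc(m$formula)))
    if (!is.na(m$charge))
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"',
             ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false"%s/>'),
      sid_encode("M_", m$id), esc(m$name), m$compartment, extra))
  }
  lines <- c(lines, "    </listOfSpecies>")

  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- function(v) sid_encode("bnd_", gsub("-", "minus_", num(v)))
  lines <- c(lines, "    <listOfParameters>",
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     vapply(bounds, bid, character(1)),
                     vapply(bounds, num, character(1))),
             "    </listOfParameters>", "    <listOfReactions>")

  gpr_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    switch(node$op,
      gene = sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     pad, sid_encode("G_", node$gene)),
      and = c(sprintf("%s<fbc:and>", pad),
              unlist(lapply(node$args, gpr_xml, indent + 2)),
              sprintf("%s</fbc:and>", pad)),
      or = c(sprintf("%s<fbc:or>", pad),
             unlist(lapply(node$args, gpr_xml, indent + 2)),
             sprintf("%s</fbc:or>", pad)))
  }

  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sto <- model$stoichiometry[model$stoichiometry$reaction_id == r$id, ]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      sid_encode("R_", r$id), esc(r$name),
      tolower(r$lower_bound < 0), bid(r$lower_bound), bid(r$upper_bound)))
    reac <- sto[sto$coefficient < 0, ]
    prod <- sto[sto$coefficient > 0, ]
    if (nrow(reac)) lines <- c(lines, "        <listOfReactants>",
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              vapply(reac$metabolite_id, function(x) sid_encode("M_", x), character(1)),
              vapply(-reac$coefficient, num, character(1))),
      "        </listOfReactants>")
    if (nrow(prod)) lines <- c(lines, "        <listOfProducts>",
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              vapply(prod$metabolite_id, function(x) sid_encode("M_", x), character(1)),
              vapply(prod$coefficient, num, character(1))),
      "        </listOfProducts>")
    if (!is.na(r$gpr))
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpr_xml(parse_gpr(r$gpr), 10), "        </fbc:geneProductAssociation>")
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")

  if (!is.null(model$objective))
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>",
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              sid_encode("R_", model$objective)),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  if (length(model$genes))
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
              vapply(model$genes, function(g) sid_encode("G_", g), character(1)),
              vapply(model$genes, esc, character(1))),
      "    </fbc:listOfGeneProducts>")
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' Supports Level 3 with the fbc extension (bounds as flux-bound parameters,
#' GPRs as gene-product associations) and, as a fallback, Level 2 files with
#' kinetic-law `LOWER_BOUND`/`UPPER_BOUND` parameters and
#' `GENE_ASSOCIATION:` notes.
#'
#' @param path SBML file path.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path))
    stop("cannot read SBML file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[["d1"]], fbc = SBML_FBC_NS)
  level <- xml2::xml_attr(doc, "level")
  model_node <- xml2::xml_find_first(doc, "./s:model", ns)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  comp_map <- resolve_compartments(
    xml2::xml_attr(comp_nodes, "id"), xml2::xml_attr(comp_nodes, "name"))

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_attrs <- lapply(sp, xml2::xml_attrs)
  getattr <- function(attrs, key) if (key %in% names(attrs)) attrs[[key]] else NA_character_
  metabolites <- tibble::tibble(
    sid = vapply(sp_attrs, getattr, character(1), "id"),
    name = vapply(sp_attrs, getattr, character(1), "name"),
    compartment = unname(comp_map[vapply(sp_attrs, getattr, character(1), "compartment")]),
    formula = vapply(sp_attrs, getattr, character(1), "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(sp_attrs, getattr, character(1), "charge"))))
  metabolites$id <- sid_decode("M_", metabolites$sid)
  metabolites$name <- ifelse(is.na(metabolites$name), metabolites$id, metabolites$name)

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rx_nodes)
  rid <- character(n); rname <- character(n); lb <- numeric(n); ub <- numeric(n)
  gpr <- rep(NA_character_, n)
  sto_list <- vector("list", n)
  undeclared <- character()
  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    attrs <- xml2::xml_attrs(node)
    rid[i] <- sid_decode("R_", attrs[["id"]])
    rname[i] <- if ("name" %in% names(attrs)) attrs[["name"]] else rid[i]
    if ("lowerFluxBound" %in% names(attrs)) {
      lb[i] <- pvals[[attrs[["lowerFluxBound"]]]]
      ub[i] <- pvals[[attrs[["upperFluxBound"]]]]
    } else {
      kl <- xml2::xml_find_all(node, ".//s:kineticLaw//s:parameter", ns)
      kv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                            xml2::xml_attr(kl, "id"))
      rev <- !identical(attrs[["reversible"]], "false")
      lb[i] <- if ("LOWER_BOUND" %in% names(kv)) kv[["LOWER_BOUND"]]
               else if (rev) -1000 else 0
      ub[i] <- if ("UPPER_BOUND" %in% names(kv)) kv[["UPPER_BOUND"]] else 1000
    }
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    mids <- c(sid_decode("M_", xml2::xml_attr(reac, "species")),
              sid_decode("M_", xml2::xml_attr(prod, "species")))
    coefs <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
               as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    undeclared <- c(undeclared, setdiff(mids, metabolites$id))
    sto_list[[i]] <- tibble::tibble(reaction_id = rid[i], metabolite_id = mids,
                                    coefficient = coefs)
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(ga, "xml_missing")) {
      gpr[i] <- deparse_gpr(structure(read_fbc_gpr(ga, ns), class = "gpr"))
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(node, "./s:notes", ns))
      if (!is.na(notes) && grepl("GENE_ASSOCIATION", notes)) {
        rule <- sub(".*GENE_ASSOCIATION:\\s*([^\n<]*).*", "\\1", notes)
        rule <- trimws(rule)
        if (nzchar(rule)) gpr[i] <- rule
      }
    }
  }
  if (length(undeclared))
    stop("SBML reactions reference undeclared species: ",
         paste(unique(undeclared), collapse = ", "), call. = FALSE)

  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "label")
  if (!length(genes) || all(is.na(genes)))
    genes <- sid_decode("G_", xml2::xml_attr(gp, "id"))

  fo <- xml2::xml_find_first(doc, ".//fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- if (inherits(fo, "xml_missing")) NULL
               else sid_decode("R_", xml2::xml_attr(fo, "reaction"))

  metabolic_model(
    metabolites = metabolites[, c("id", "name", "compartment", "formula", "charge")],
    reactions = tibble::tibble(id = rid, name = rname, lower_bound = lb,
                               upper_bound = ub, gpr = gpr),
    stoichiometry = dplyr::bind_rows(sto_list),
    genes = if (length(genes)) genes else NULL,
    objective = objective, id = model_id)
}

read_fbc_gpr <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(list(op = "gene",
                gene = sid_decode("G_", xml2::xml_attr(node, "geneProduct"))))
  kids <- xml2::xml_find_all(node, "./*")
  list(op = nm, args = lapply(kids, read_fbc_gpr, ns = ns))
}

## Map arbitrary SBML compartment ids onto the package's four-compartment
## vocabulary, by id when already e/c/m/x, otherwise by name.
resolve_compartments <- function(ids, names) {
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    if (ids[i] %in% names(model_compartments)) {
      out[i] <- ids[i]
    } else {
      hit <- grep(substr(tolower(ifelse(is.na(names[i]), "", names[i])), 1, 6),
                  model_compartments, fixed = TRUE)
      if (length(hit) != 1L)
        stop("cannot map SBML compartment '", ids[i],
             "' onto {extracellular, cytosol, mitochondria, peroxisome}",
             call. = FALSE)
      out[i] <- names(model_compartments)[hit]
    }
  }
  stats::setNames(out, ids)
}
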