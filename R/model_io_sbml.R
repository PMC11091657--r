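## SBML Level 3 + FBC version 2 reader/writer.
##
## Covers the subset of SBML/FBC that constraint-based models actually use:
## species, reactions with stoichiometry, flux bounds through fbc parameters,
## the active FBC objective, and gene-product associations (and/or trees).
## Identifiers follow the usual SBML conventions (R_/M_/G_ prefixes), which
## are stripped on read and re-added on write so that JSON and SBML versions
## of the same model have identical ids.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

## fbc attributes may or may not be serialised with an explicit prefix
fbc_attr <- function(node, name, ns) {
  v <- xml2::xml_attr(node, paste0("fbc:", name), ns = ns)
  miss <- is.na(v)
  if (any(miss))
    v[miss] <- xml2::xml_attr(node, name)[miss]
  v
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("format error in SBML file ", path, ": ",
                         conditionMessage(e)))
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing"))
    stop("format error in ", path, ": no <model> element")

  params <- xml2::xml_find_all(mnode, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(mnode, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("format error in ", path, ": no species")
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = fbc_attr(sp, "chemicalFormula", ns),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  gp <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  gp_label <- stats::setNames(
    fbc_attr(gp, "label", ns),
    strip_prefix(fbc_attr(gp, "id", ns), "G_"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  obj_rxn <- NA_character_
  fo <- xml2::xml_find_first(
    mnode, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!inherits(fo, "xml_missing"))
    obj_rxn <- strip_prefix(fbc_attr(fo, "reaction", ns), "R_")

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- strip_prefix(fbc_attr(node, "geneProduct", ns), "G_")
      return(if (gid %in% names(gp_label)) gp_label[[gid]] else gid)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
  }

  rn <- xml2::xml_find_all(mnode, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rn)) stop("format error in ", path, ": no reactions")
  stoich <- list()
  rows <- lapply(rn, function(x) {
    rid <- strip_prefix(xml2::xml_attr(x, "id"), "R_")
    sref <- function(which, sign) {
      nodes <- xml2::xml_find_all(
        x, paste0("./s:", which, "/s:speciesReference"), ns)
      if (!length(nodes)) return(numeric())
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        strip_prefix(xml2::xml_attr(nodes, "species"), "M_"))
    }
    st <- c(sref("listOfReactants", -1), sref("listOfProducts", 1))
    st <- tapply(st, names(st), sum)  # merge duplicated species references
    stoich[[rid]] <<- stats::setNames(as.numeric(st), names(st))
    lb_id <- fbc_attr(x, "lowerFluxBound", ns)
    ub_id <- fbc_attr(x, "upperFluxBound", ns)
    if (is.na(lb_id) || is.na(ub_id) ||
        !(lb_id %in% names(par_val)) || !(ub_id %in% names(par_val)))
      stop("format error in ", path, ": reaction ", rid,
           " lacks resolvable fbc flux bounds")
    gpa <- xml2::xml_find_first(x, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else gpa_to_string(gpa)
    nm <- xml2::xml_attr(x, "name")
    data.frame(id = rid, name = if (is.na(nm)) rid else nm,
               lower_bound = par_val[[lb_id]],
               upper_bound = par_val[[ub_id]],
               gpr = gpr, stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rows)
  metabolic_model(id = xml2::xml_attr(mnode, "id"), metabolites = mets,
                  reactions = rxns, stoichiometry = stoich,
                  genes = if (length(gp_label)) unname(gp_label) else NULL,
                  objective = obj_rxn)
}

#' Write a metabolic model as SBML Level 3 with FBC
#'
#' @param model a \code{metabolic_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bnd_id <- stats::setNames(paste0("fb_", seq_along(bounds)), num(bounds))
  comps <- unique(stats::na.omit(model$metabolites$compartment))
  if (!length(comps)) comps <- "c"

  gpr_xml <- function(gpr) {
    node_xml <- function(node) {
      if (!is.null(node$gene))
        return(paste0('<fbc:geneProductRef fbc:geneProduct="G_',
                      esc(node$gene), '"/>'))
      inner <- paste(vapply(node$args, node_xml, character(1)),
                     collapse = "")
      paste0("<fbc:", node$op, ">", inner, "</fbc:", node$op, ">")
    }
    tree <- parse_gpr(gpr)
    if (gpr_is_empty(tree)) return("")
    paste0("<fbc:geneProductAssociation>", node_xml(tree),
           "</fbc:geneProductAssociation>")
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_CORE_NS, '" xmlns:fbc="', SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('<model id="', esc(model$id), '" fbc:strict="true">'),
    "<listOfCompartments>",
    paste0('<compartment id="', esc(comps), '" constant="true"/>'),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, paste0(
      '<species id="M_', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(if (is.na(m$compartment)) comps[1]
                             else m$compartment),
      '"', if (!is.na(m$formula))
        paste0(' fbc:chemicalFormula="', esc(m$formula), '"'),
      ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
      ' constant="false"/>'))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>",
             paste0('<parameter id="', bnd_id, '" value="', names(bnd_id),
                    '" constant="true"/>'),
             "</listOfParameters>")
  if (!is.na(model$objective))
    lines <- c(lines,
      '<fbc:listOfObjectives fbc:activeObjective="obj">',
      '<fbc:objective fbc:id="obj" fbc:type="maximize">',
      "<fbc:listOfFluxObjectives>",
      paste0('<fbc:fluxObjective fbc:reaction="R_', esc(model$objective),
             '" fbc:coefficient="1"/>'),
      "</fbc:listOfFluxObjectives>", "</fbc:objective>",
      "</fbc:listOfObjectives>")
  if (length(model$genes))
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               paste0('<fbc:geneProduct fbc:id="G_', esc(model$genes),
                      '" fbc:label="', esc(model$genes), '"/>'),
               "</fbc:listOfGeneProducts>")
  lines <- c(lines, "<listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    subs <- st[st < 0]; prods <- st[st > 0]
    sref <- function(v)
      paste0('<speciesReference species="M_', esc(names(v)),
             '" stoichiometry="', num(abs(unname(v))),
             '" constant="true"/>')
    lines <- c(lines, paste0(
      '<reaction id="R_', esc(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0), '" fast="false"',
      ' fbc:lowerFluxBound="', bnd_id[[num(r$lower_bound)]],
      '" fbc:upperFluxBound="', bnd_id[[num(r$upper_bound)]], '">'))
    if (length(subs))
      lines <- c(lines, "<listOfReactants>", sref(subs), "</listOfReactants>")
    if (length(prods))
      lines <- c(lines, "<listOfProducts>", sref(prods), "</listOfProducts>")
    g <- gpr_xml(r$gpr)
    if (nzchar(g)) lines <- c(lines, g)
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
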