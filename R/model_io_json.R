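#' Read a metabolic model from file
#'
#' Supports the BiGG-style JSON dialect (the primary format; what the BiGG
#' database distributes) and SBML Level 3 with the FBC package for bounds,
#' objectives and gene associations.
#'
#' @param path path to the model file.
#' @param format \code{"bigg-json"} or \code{"sbml"}; guessed from the file
#'   extension by default.
#' @param require_objective error when no objective reaction is declared
#'   (set \code{FALSE} to load and assign an objective afterwards).
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "bigg-json", "sbml"),
                       require_objective = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "bigg-json", xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from extension of ",
                          path))
  }
  model <- switch(format,
                  `bigg-json` = read_model_json(path),
                  sbml = read_model_sbml(path))
  if (require_objective && is.na(model$objective))
    stop("no objective: model '", model$id,
         "' declares no objective reaction (load with ",
         "require_objective = FALSE and set one)")
  validate_model(model)
  model
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("format error in BiGG JSON file ", path, ": ",
                         conditionMessage(e)))
  for (el in c("metabolites", "reactions"))
    if (is.null(doc[[el]]))
      stop("format error in ", path, ": missing element '", el, "'")
  chr1 <- function(x, default = NA_character_)
    if (is.null(x)) default else as.character(x)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("format error in ", path,
                            ": metabolite without an 'id'")
    data.frame(id = m$id, name = chr1(m$name, m$id),
               compartment = chr1(m$compartment),
               formula = chr1(m$formula), stringsAsFactors = FALSE)
  }))
  stoich <- list()
  objective <- NA_character_
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("format error in ", path,
                            ": reaction without an 'id'")
    st <- unlist(r$metabolites)
    stoich[[r$id]] <<- stats::setNames(as.numeric(st), names(st))
    oc <- if (is.null(r$objective_coefficient)) 0
          else as.numeric(r$objective_coefficient)
    if (oc != 0) objective <<- r$id
    data.frame(id = r$id, name = chr1(r$name, r$id),
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               gpr = chr1(r$gene_reaction_rule, ""),
               subsystem = chr1(r$subsystem),
               objective_coefficient = oc, stringsAsFactors = FALSE)
  }))
  genes <- vapply(doc$genes, function(g) as.character(g$id), character(1))
  metabolic_model(id = chr1(doc$id, basename(path)), metabolites = mets,
                  reactions = rxns, stoichiometry = stoich,
                  genes = if (length(genes)) genes else NULL,
                  objective = objective)
}

#' Write a metabolic model as BiGG-style JSON
#'
#' @param model a \code{metabolic_model}.
#' @param path output path.
#' @param pretty pretty-print the JSON.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path, pretty = TRUE) {
  null_na <- function(x) if (is.na(x)) NULL else x
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name,
                compartment = null_na(m$compartment))
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  oc <- model$reactions$objective_coefficient
  if (is.null(oc))
    oc <- as.numeric(model$reactions$id == model$objective &
                     !is.na(model$objective))
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(st),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr)
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    if (oc[i] != 0) out$objective_coefficient <- oc[i]
    out
  })
  doc <- list(id = model$id, metabolites = mets, reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g, name = g)),
              version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = pretty)
  invisible(path)
}
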