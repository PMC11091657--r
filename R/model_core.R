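#' Construct a stoichiometric metabolic model
#'
#' The central container of the package: a set of metabolites, a set of
#' bounded reactions with stoichiometry and optional GPR rules, the gene
#' list, and one objective reaction (normally the lumped biomass reaction,
#' whose flux is the specific growth rate in h^-1).  All fluxes are in
#' mmol/gDCW/h; exchange reactions follow the BiGG sign convention
#' (negative flux = uptake, positive = secretion).
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} and optionally \code{formula}.
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound} and optionally \code{gpr}
#'   (string), \code{subsystem}.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids.
#' @param genes character vector of gene ids; defaults to the union of all
#'   genes referenced by the GPR rules.
#' @param objective id of the objective reaction, or \code{NA} if unset.
#' @return validated object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = NULL, objective = NA_character_) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions,
                          stoichiometry = stoichiometry,
                          genes = as.character(genes),
                          objective = objective),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks: non-empty unique metabolite and reaction ids, finite ordered
#' bounds, every stoichiometric coefficient referring to a listed
#' metabolite, every GPR gene listed in \code{genes}, a resolvable
#' objective, and non-empty stoichiometry for non-boundary reactions.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  m <- model$metabolites; r <- model$reactions
  if (anyDuplicated(m$id) || any(!nzchar(m$id)))
    stop("metabolite ids must be non-empty and unique")
  if (anyDuplicated(r$id) || any(!nzchar(r$id)))
    stop("reaction ids must be non-empty and unique")
  if (any(r$lower_bound > r$upper_bound))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(r$id[r$lower_bound > r$upper_bound], collapse = ", "))
  if (!setequal(names(model$stoichiometry), r$id))
    stop("stoichiometry entries must match reaction ids exactly")
  bad_met <- setdiff(unique(unlist(lapply(model$stoichiometry, names))), m$id)
  if (length(bad_met))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(bad_met, collapse = ", "))
  empty <- vapply(model$stoichiometry[r$id], length, integer(1)) == 0L
  if (any(empty))
    stop("reaction(s) with empty stoichiometry: ",
         paste(r$id[empty], collapse = ", "))
  gpr_gene_ids <- unique(unlist(lapply(r$gpr, gpr_genes)))
  missing_genes <- setdiff(gpr_gene_ids, model$genes)
  if (length(missing_genes))
    stop("GPR rules reference gene(s) absent from the gene list: ",
         paste(missing_genes, collapse = ", "))
  if (!is.na(model$objective) && !(model$objective %in% r$id))
    stop("objective reaction '", model$objective, "' not in the model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", length(x$genes), "\n",
      "  objective: ", if (is.na(x$objective)) "<unset>" else x$objective,
      "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @param sparse return a \pkg{Matrix} sparse matrix (default) or base dense.
#' @return the matrix S with one row per metabolite and one column per
#'   reaction, dimnames set to the respective ids.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(rxns)) {
    st <- model$stoichiometry[[rxns[j]]]
    ii <- c(ii, match(names(st), mets))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  if (sparse) S else as.matrix(S)
}

#' Identify boundary (exchange/sink) reactions
#'
#' A reaction is a boundary reaction when it involves a single metabolite,
#' i.e. it transports mass across the system boundary.
#'
#' @param model a \code{metabolic_model}.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  n <- vapply(model$stoichiometry[model$reactions$id], length, integer(1))
  model$reactions$id[n == 1L]
}

#' Check elemental balance of every reaction
#'
#' Uses the metabolite \code{formula} fields to compute, per reaction, the
#' net elemental difference between products and substrates.  Boundary
#' reactions and reactions listed in \code{exempt} (typically the lumped
#' biomass) are skipped, as is any reaction touching a metabolite without a
#' formula.
#'
#' @param model a \code{metabolic_model}.
#' @param exempt reaction ids excluded from the check.
#' @param tol absolute tolerance on elemental counts.
#' @return data.frame with columns \code{reaction_id}, \code{element},
#'   \code{imbalance}, one row per violation (zero rows when balanced).
#' @export
check_mass_balance <- function(model, exempt = character(), tol = 1e-6) {
  skip <- union(exempt, exchange_reactions(model))
  formulas <- stats::setNames(model$metabolites$formula,
                              model$metabolites$id)
  out <- list()
  for (rid in setdiff(model$reactions$id, skip)) {
    st <- model$stoichiometry[[rid]]
    fs <- formulas[names(st)]
    if (anyNA(fs)) next
    counts <- Reduce(`+`, Map(function(f, coef) parse_formula(f) * coef,
                              fs, st))
    bad <- counts[abs(counts) > tol]
    if (length(bad))
      out[[rid]] <- data.frame(reaction_id = rid, element = names(bad),
                               imbalance = as.numeric(bad))
  }
  if (!length(out))
    return(data.frame(reaction_id = character(), element = character(),
                      imbalance = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## "C6H12O6" -> named vector over the full element alphabet of the model
parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
  parts <- regmatches(f, list(m))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  nn <- sub("^[A-Z][a-z]?", "", parts)
  nn[!nzchar(nn)] <- "1"
  base <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  v <- stats::setNames(as.numeric(nn), el)
  for (e in intersect(names(v), names(base))) base[e] <- base[e] + v[e]
  base
}
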