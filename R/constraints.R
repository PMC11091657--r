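#' Measured rates for one culture condition
#'
#' Holds the measured specific growth rate and the uptake/secretion rates of
#' the profiled metabolites for one batch culture condition, with sign
#' conventions made explicit: magnitudes are non-negative and each species
#' carries a direction tag.  In model sign convention an uptake of
#' magnitude q becomes an exchange flux of -q, a secretion +q.
#'
#' @param growth_rate specific growth rate (h^-1).
#' @param rates data.frame with columns \code{species}, \code{magnitude}
#'   (mmol/gDCW/h, >= 0) and \code{direction} (\code{"uptake"} or
#'   \code{"secretion"}).
#' @param provenance \code{"measured-table"} for rates transcribed from a
#'   printed table, \code{"estimated"} for rates fitted from a fermentation
#'   profile.
#' @param label free-text condition label.
#' @return object of class \code{condition_constraints}.
#' @export
condition_constraints <- function(growth_rate, rates,
                                  provenance = c("measured-table",
                                                 "estimated"),
                                  label = "") {
  provenance <- match.arg(provenance)
  rates <- as.data.frame(rates, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "magnitude", "direction") %in% names(rates)),
            all(rates$direction %in% c("uptake", "secretion")))
  if (any(rates$magnitude < 0))
    stop("rate magnitudes must be non-negative; use 'direction' for sign")
  if (!is.finite(growth_rate))
    stop("growth_rate must be a finite number")
  structure(list(growth_rate = as.numeric(growth_rate), rates = rates,
                 provenance = provenance, label = label),
            class = "condition_constraints")
}

#' Signed exchange rates of a condition (uptake negative)
#' @param constraints a [condition_constraints()].
#' @return named numeric vector over species.
#' @export
signed_rates <- function(constraints) {
  r <- constraints$rates
  stats::setNames(ifelse(r$direction == "uptake", -1, 1) * r$magnitude,
                  r$species)
}

#' Read a measured-rate table
#'
#' Reads a delimited table of per-condition exchange-rate magnitudes and
#' growth rates (one row per culture condition; the layout of the printed
#' rate tables this package works from).  Direction tags come from the
#' species-to-exchange mapping, see [read_exchange_map()].
#'
#' @param path delimited file with columns \code{condition},
#'   \code{growth_rate} and one column per species magnitude.
#' @param exchange_map data.frame from [read_exchange_map()] supplying
#'   \code{species} and \code{direction}.
#' @return named list of [condition_constraints()], one per row.
#' @export
read_rate_table <- function(path, exchange_map) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "growth_rate") %in% names(tab)))
  species <- setdiff(names(tab), c("condition", "growth_rate"))
  unmapped <- setdiff(species, exchange_map$species)
  if (length(unmapped))
    stop("species without an exchange mapping: ",
         paste(unmapped, collapse = ", "))
  dirs <- stats::setNames(exchange_map$direction, exchange_map$species)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    condition_constraints(
      growth_rate = tab$growth_rate[i],
      rates = data.frame(species = species,
                         magnitude = as.numeric(tab[i, species]),
                         direction = unname(dirs[species]),
                         stringsAsFactors = FALSE),
      provenance = "measured-table", label = tab$condition[i])
  })
  stats::setNames(out, tab$condition)
}

#' Read / write a species-to-exchange-reaction mapping
#'
#' The mapping file links profiled species names to model exchange-reaction
#' ids and fixes each species' physiological direction (glucose and
#' succinate are consumed; GABA, glutamate and acetate are secreted).
#'
#' @param path delimited file with columns \code{species},
#'   \code{reaction_id}, \code{direction}.
#' @return data.frame with those columns.
#' @export
read_exchange_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "reaction_id", "direction") %in% names(map)))
  map
}

#' @rdname read_exchange_map
#' @param map mapping data.frame.
#' @export
write_exchange_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Constrain model exchanges to measured rates
#'
#' In \code{"hard"} mode each mapped exchange reaction's bounds become
#' \code{[rate - tol, rate + tol]} in model sign convention; the growth
#' rate, when mapped (species \code{"growth"}), pins the objective reaction
#' the same way.  In \code{"reference-only"} mode bounds are left at their
#' physiological defaults and the signed rates are attached as
#' least-absolute-deviation references
#' (\code{attr(model, "lad_references")}).
#'
#' @param model a [metabolic_model()].
#' @param constraints a [condition_constraints()].
#' @param exchange_map data.frame from [read_exchange_map()].
#' @param mode \code{"hard"} or \code{"reference-only"}.
#' @param tol half-width of the hard bound interval (mmol/gDCW/h); the
#'   default 0 pins rates exactly.
#' @return a new \code{metabolic_model}.
#' @export
set_exchange_bounds <- function(model, constraints, exchange_map,
                                mode = c("hard", "reference-only"),
                                tol = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(constraints, "condition_constraints"))
  targets <- constraint_targets(model, constraints, exchange_map)
  if (mode == "hard") {
    idx <- match(targets$reaction_id, model$reactions$id)
    model$reactions$lower_bound[idx] <- targets$value - tol
    model$reactions$upper_bound[idx] <- targets$value + tol
    validate_model(model)
  } else {
    attr(model, "lad_references") <- data.frame(
      reaction_id = targets$reaction_id, value = targets$value, weight = 1)
  }
  model
}

## resolve a condition's species (plus growth) onto model reactions,
## in model sign convention
constraint_targets <- function(model, constraints, exchange_map) {
  sr <- signed_rates(constraints)
  map <- exchange_map
  rid <- stats::setNames(map$reaction_id, map$species)
  unmapped <- setdiff(names(sr), names(rid))
  if (length(unmapped))
    stop("no exchange mapping for species: ",
         paste(unmapped, collapse = ", "))
  growth_rxn <- if ("growth" %in% names(rid)) unname(rid[["growth"]])
                else model$objective
  ids <- c(unname(rid[names(sr)]), growth_rxn)
  vals <- c(unname(sr), constraints$growth_rate)
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing))
    stop("mapped reaction(s) absent from model: ",
         paste(missing, collapse = ", "))
  data.frame(reaction_id = ids, value = vals, stringsAsFactors = FALSE)
}
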