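#' Specify gene and/or reaction knockouts
#'
#' Gene knockouts act through the GPR rules: a reaction is disabled only
#' when its rule evaluates inactive under the knocked-out gene set (so an
#' isozyme-backed reaction survives a single-gene deletion).  Reaction
#' knockouts disable the listed reactions directly, which is how an
#' in-silico strain is usually pinned when the affected reactions are known
#' by name rather than by locus.
#'
#' @param genes character vector of gene ids to delete.
#' @param reactions character vector of reaction ids to force to zero flux.
#' @return object of class \code{knockout_spec}.
#' @export
knockout_spec <- function(genes = character(), reactions = character()) {
  structure(list(genes = unique(as.character(genes)),
                 reactions = unique(as.character(reactions))),
            class = "knockout_spec")
}

#' Apply a knockout specification to a model
#'
#' Every reaction whose GPR evaluates inactive under the deleted genes, and
#' every directly listed reaction, gets \code{lower_bound = upper_bound = 0}.
#' All other bounds are untouched and the input model is not modified.
#'
#' @param model a [metabolic_model()].
#' @param spec a [knockout_spec()] (a plain character vector is treated as
#'   reaction ids).
#' @return a new \code{metabolic_model} with the knocked reactions closed;
#'   the ids of the closed reactions are attached as
#'   \code{attr(, "knocked_reactions")}.
#' @export
apply_knockouts <- function(model, spec) {
  if (is.character(spec)) spec <- knockout_spec(reactions = spec)
  stopifnot(inherits(spec, "knockout_spec"))
  unknown_g <- setdiff(spec$genes, model$genes)
  if (length(unknown_g))
    stop("unknown gene id(s): ", paste(unknown_g, collapse = ", "))
  unknown_r <- setdiff(spec$reactions, model$reactions$id)
  if (length(unknown_r))
    stop("unknown reaction id(s): ", paste(unknown_r, collapse = ", "))

  off <- spec$reactions
  if (length(spec$genes)) {
    inactive <- vapply(model$reactions$gpr, function(g)
      !evaluate_gpr(g, knocked = spec$genes), logical(1), USE.NAMES = FALSE)
    off <- union(off, model$reactions$id[inactive])
  }
  idx <- model$reactions$id %in% off
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  attr(model, "knocked_reactions") <- sort(off)
  validate_model(model)
  model
}
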