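#' Classify the change of one reaction's flux between two conditions
#'
#' Pure function of the two fluxes, the relative-change threshold and the
#' zero tolerance.  With \eqn{\epsilon} = \code{zero_tol}:
#' \itemize{
#'   \item both \eqn{|v| < \epsilon}: \code{unchanged};
#'   \item \eqn{|a| < \epsilon \le |b|}: \code{de-novo} (flux appears);
#'   \item \eqn{|b| < \epsilon \le |a|}: \code{abolished} (flux vanishes);
#'   \item opposite signs, both \eqn{\ge \epsilon}: \code{inverted};
#'   \item otherwise the magnitudes are compared as a ratio:
#'     \code{induced} if \eqn{|b| > (1+T)\,|a|}, \code{suppressed} if
#'     \eqn{|b| < |a|/(1+T)} with \eqn{T} = \code{threshold}, else
#'     \code{unchanged}.
#' }
#' The ratio form makes the classification antisymmetric: swapping the
#' two conditions exchanges induced with suppressed (and de-novo with
#' abolished) exactly, which a one-sided relative change
#' \eqn{(|b|-|a|)/|a|} compared against \eqn{\pm T} would not.  That
#' relative change is still reported as \code{relative_change} for
#' reference.  The default threshold 0.20 keeps only changes of more than
#' 20 percent.
#'
#' @param flux_a,flux_b fluxes in the before/after condition.
#' @param threshold relative-change threshold (> 0), default 0.20.
#' @param zero_tol absolute tolerance below which a flux counts as zero.
#' @return one-row data.frame with \code{flux_a}, \code{flux_b},
#'   \code{relative_change} and \code{class}.
#' @export
classify_change <- function(flux_a, flux_b, threshold = 0.20,
                            zero_tol = 1e-6) {
  stopifnot(threshold > 0, zero_tol >= 0)
  a <- abs(flux_a); b <- abs(flux_b)
  rel <- if (a >= zero_tol) (b - a) / a else NA_real_
  cls <- if (a < zero_tol && b < zero_tol) "unchanged"
    else if (a < zero_tol) "de-novo"
    else if (b < zero_tol) "abolished"
    else if (sign(flux_a) != sign(flux_b)) "inverted"
    else if (b > (1 + threshold) * a) "induced"
    else if (b < a / (1 + threshold)) "suppressed"
    else "unchanged"
  data.frame(flux_a = flux_a, flux_b = flux_b, relative_change = rel,
             class = cls, stringsAsFactors = FALSE)
}

#' Compare two simulated flux distributions reaction by reaction
#'
#' @param sol_a,sol_b optimal \code{flux_solution}s over the same model
#'   (before and after a condition shift).
#' @param threshold,zero_tol forwarded to [classify_change()].
#' @param collapse collapse the six-way classification to the three-group
#'   scheme used in pathway maps (\code{inverted}/\code{de-novo} count as
#'   \code{induced}, \code{abolished} as \code{suppressed}).
#' @return data.frame with one row per shared reaction, ordered by
#'   reaction id: \code{reaction_id}, \code{flux_a}, \code{flux_b},
#'   \code{relative_change}, \code{class}.
#' @export
compare_conditions <- function(sol_a, sol_b, threshold = 0.20,
                               zero_tol = 1e-6, collapse = FALSE) {
  for (s in list(sol_a, sol_b))
    if (!inherits(s, "flux_solution") || !identical(s$status, "optimal"))
      stop("compare_conditions() needs two optimal flux solutions")
  shared <- sort(intersect(names(sol_a$fluxes), names(sol_b$fluxes)))
  if (!length(shared)) stop("the two solutions share no reactions")
  rows <- lapply(shared, function(r)
    classify_change(sol_a$fluxes[[r]], sol_b$fluxes[[r]],
                    threshold = threshold, zero_tol = zero_tol))
  out <- cbind(data.frame(reaction_id = shared, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  if (collapse) out$class <- collapse_classes(out$class)
  out
}

#' @rdname compare_conditions
#' @param classes character vector of six-way classes.
#' @export
collapse_classes <- function(classes) {
  out <- classes
  out[classes %in% c("inverted", "de-novo")] <- "induced"
  out[classes == "abolished"] <- "suppressed"
  out
}

#' Summarise flux changes by metabolic pathway
#'
#' @param changes data.frame from [compare_conditions()].
#' @param pathway_map data.frame with columns \code{reaction_id},
#'   \code{pathway}; unmapped reactions are grouped under \code{"other"}.
#' @return data.frame with one row per pathway: \code{pathway},
#'   \code{n_reactions}, one count column per class, and a
#'   comma-separated \code{members} column.  Counts partition the change
#'   set.
#' @export
summarize_by_pathway <- function(changes, pathway_map) {
  if (!nrow(changes))
    return(data.frame(pathway = character(), n_reactions = integer()))
  pw <- stats::setNames(pathway_map$pathway, pathway_map$reaction_id)
  grp <- ifelse(changes$reaction_id %in% names(pw),
                pw[changes$reaction_id], "other")
  classes <- c("induced", "suppressed", "unchanged", "inverted",
               "de-novo", "abolished")
  sp <- split(changes, grp)
  out <- Map(function(label, d) {
    counts <- vapply(classes, function(cl) sum(d$class == cl), integer(1))
    cbind(data.frame(pathway = label, n_reactions = nrow(d)),
          as.data.frame(as.list(counts), check.names = FALSE),
          data.frame(members = paste(d$reaction_id, collapse = ",")))
  }, names(sp), sp)
  out <- do.call(rbind, unname(out))
  rownames(out) <- NULL
  ## deterministic order: the central pathways first, then the rest
  canon <- c("glycolysis", "pentose phosphate pathway", "TCA cycle",
             "acetate fermentation", "GABA shunt", "other")
  out[order(match(out$pathway, canon, nomatch = length(canon) + 1),
            out$pathway), , drop = FALSE]
}

#' Read a reaction-to-pathway mapping file
#' @param path two-column delimited file (\code{reaction_id},
#'   \code{pathway}).
#' @return data.frame with those columns.
#' @export
read_pathway_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "pathway") %in% names(map)))
  map
}
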