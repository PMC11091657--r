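#' Flux solutions
#'
#' Result container for [fba()], [pfba()], [lad_fit()] and
#' [simulate_condition()]: a named flux vector (mmol/gDCW/h; the biomass
#' flux is the growth rate in h^-1), the objective value, the solver
#' status and the method, plus method-specific details (stage objectives,
#' tolerances, backend).
#'
#' @keywords internal
flux_solution <- function(fluxes, objective_value, status, method,
                          details = list()) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, method = method, details = details),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> method:", x$method, " status:", x$status,
      " objective:", format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

## shared LP skeleton: S v = 0, bounds from the reaction table
model_lp_parts <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  list(S = S, n = ncol(S), m = nrow(S),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       rxns = model$reactions$id)
}

#' Flux balance analysis
#'
#' Solves \eqn{\max / \min \; c^\top v} subject to \eqn{S v = 0},
#' \eqn{lb \le v \le ub}: the steady-state mass-balance LP over the
#' model's flux bounds.
#'
#' @param model a [metabolic_model()].
#' @param objective objective reaction id; defaults to the model objective.
#' @param sense \code{"max"} (default) or \code{"min"}.
#' @param backend LP backend, see [solve_lp()].
#' @param tol solver tolerance.
#' @return a \code{flux_solution} with method \code{"fba"}; on infeasible
#'   or unbounded problems \code{fluxes} is \code{NULL} and \code{status}
#'   reflects the solver outcome.
#' @export
fba <- function(model, objective = model$objective,
                sense = c("max", "min"),
                backend = getOption("fluxgaba.lp_backend", "simplex"),
                tol = 1e-9) {
  sense <- match.arg(sense)
  if (is.na(objective) || !(objective %in% model$reactions$id))
    stop("objective reaction '", objective, "' not in the model")
  p <- model_lp_parts(model)
  obj <- as.numeric(p$rxns == objective)
  lp <- lp_problem(objective = obj, A = p$S, rhs = rep(0, p$m),
                   lb = p$lb, ub = p$ub, maximize = (sense == "max"),
                   var_names = p$rxns)
  res <- solve_lp(lp, backend = backend, tol = tol)
  flux_solution(fluxes = res$x, objective_value = res$objective,
                status = res$status, method = "fba",
                details = list(objective_reaction = objective,
                               sense = sense, backend = backend))
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: stage 1 is plain FBA on the objective reaction; stage 2
#' fixes \eqn{c^\top v \ge f \cdot Z^*} (with \eqn{f} =
#' \code{optimum_fraction} of the stage-1 optimum \eqn{Z^*}) and minimises
#' the total absolute flux \eqn{\sum_i |v_i|} through the split
#' \eqn{v = v^+ - v^-}, \eqn{v^\pm \ge 0}.  Among growth-optimal flux
#' states this selects a minimal-total-flux representative; in particular
#' any stoichiometrically balanced internal cycle carries zero flux.
#'
#' @inheritParams fba
#' @param optimum_fraction fraction of the stage-1 optimum retained in
#'   stage 2, in (0, 1]; default 1.
#' @return a \code{flux_solution} with method \code{"pfba"};
#'   \code{objective_value} is the stage-1 objective actually achieved and
#'   \code{details$total_flux} the minimised \eqn{\sum_i |v_i|}.
#' @export
pfba <- function(model, objective = model$objective,
                 optimum_fraction = 1,
                 backend = getOption("fluxgaba.lp_backend", "simplex"),
                 tol = 1e-9) {
  stopifnot(optimum_fraction > 0, optimum_fraction <= 1)
  stage1 <- fba(model, objective, sense = "max", backend = backend,
                tol = tol)
  if (!identical(stage1$status, "optimal"))
    return(flux_solution(NULL, NA_real_, stage1$status, "pfba",
                         details = list(stage = "fba")))
  zstar <- stage1$objective_value

  p <- model_lp_parts(model)
  ## v = pos - neg with box bounds carrying the original bounds
  lb_pos <- pmax(p$lb, 0); ub_pos <- pmax(p$ub, 0)
  lb_neg <- pmax(-p$ub, 0); ub_neg <- pmax(-p$lb, 0)
  A <- cbind(p$S, -p$S)
  cvec <- as.numeric(p$rxns == objective)
  A <- rbind(A, c(cvec, -cvec))
  sense <- c(rep("=", p$m), ">=")
  rhs <- c(rep(0, p$m), optimum_fraction * zstar)
  lp <- lp_problem(objective = rep(1, 2 * p$n), A = A, rhs = rhs,
                   lb = c(lb_pos, lb_neg), ub = c(ub_pos, ub_neg),
                   sense = sense, maximize = FALSE)
  res <- solve_lp(lp, backend = backend, tol = tol)
  if (!identical(res$status, "optimal"))
    return(flux_solution(NULL, NA_real_, res$status, "pfba",
                         details = list(stage = "pfba")))
  v <- res$x[seq_len(p$n)] - res$x[p$n + seq_len(p$n)]
  names(v) <- p$rxns
  flux_solution(fluxes = v, objective_value = sum(cvec * v),
                status = "optimal", method = "pfba",
                details = list(objective_reaction = objective,
                               fba_objective = zstar,
                               optimum_fraction = optimum_fraction,
                               total_flux = res$objective,
                               backend = backend))
}

#' Least-absolute-deviation flux fitting
#'
#' Finds a steady-state flux distribution as close as possible (weighted
#' L1 norm) to a set of measured reference fluxes:
#' \deqn{\min \sum_i w_i (d_i^+ + d_i^-) \quad \mathrm{s.t.}\quad S v = 0,
#'   \; lb \le v \le ub, \; v_i - \hat v_i = d_i^+ - d_i^-, \; d^\pm \ge 0.}
#' When the reference vector is jointly feasible the residual is zero and
#' every referenced flux equals its reference.
#'
#' @inheritParams fba
#' @param refs data.frame with columns \code{reaction_id}, \code{value}
#'   and optionally \code{weight} (default 1); signed, in model convention
#'   (uptake negative).
#' @return a \code{flux_solution} with method \code{"lad"};
#'   \code{objective_value} is the weighted L1 residual.
#' @export
lad_fit <- function(model, refs,
                    backend = getOption("fluxgaba.lp_backend", "simplex"),
                    tol = 1e-9) {
  refs <- as.data.frame(refs)
  stopifnot(all(c("reaction_id", "value") %in% names(refs)),
            nrow(refs) > 0)
  if (is.null(refs$weight)) refs$weight <- 1
  if (any(refs$weight < 0)) stop("LAD weights must be non-negative")
  bad <- setdiff(refs$reaction_id, model$reactions$id)
  if (length(bad))
    stop("reference(s) for unknown reaction(s): ",
         paste(bad, collapse = ", "))
  p <- model_lp_parts(model)
  k <- nrow(refs)
  ridx <- match(refs$reaction_id, p$rxns)
  ## columns: v (n), d+ (k), d- (k)
  A <- cbind(p$S, matrix(0, p$m, 2 * k))
  link <- matrix(0, k, p$n + 2 * k)
  link[cbind(seq_len(k), ridx)] <- 1
  link[cbind(seq_len(k), p$n + seq_len(k))] <- -1
  link[cbind(seq_len(k), p$n + k + seq_len(k))] <- 1
  lp <- lp_problem(
    objective = c(rep(0, p$n), rep(refs$weight, 2)),
    A = rbind(A, link),
    rhs = c(rep(0, p$m), refs$value),
    lb = c(p$lb, rep(0, 2 * k)), ub = c(p$ub, rep(Inf, 2 * k)),
    maximize = FALSE)
  res <- solve_lp(lp, backend = backend, tol = tol)
  if (!identical(res$status, "optimal"))
    return(flux_solution(NULL, NA_real_, res$status, "lad"))
  v <- stats::setNames(res$x[seq_len(p$n)], p$rxns)
  flux_solution(fluxes = v, objective_value = res$objective,
                status = "optimal", method = "lad",
                details = list(references = refs, backend = backend))
}

#' Simulate a culture condition
#'
#' Runs the full constrained simulation for one condition.  With the
#' default \code{"lad-then-pfba"} strategy the measured exchange rates and
#' growth rate are first reconciled with the model by [lad_fit()]; the
#' fitted values of the referenced reactions are then pinned as hard
#' bounds and parsimonious FBA on growth picks a minimal-total-flux
#' distribution among the reconciled states.  \code{"hard-pfba"} skips the
#' reconciliation and pins the measured values directly.
#'
#' @inheritParams fba
#' @param constraints a [condition_constraints()].
#' @param exchange_map species-to-exchange mapping, see
#'   [read_exchange_map()].
#' @param strategy \code{"lad-then-pfba"} or \code{"hard-pfba"}.
#' @param pin_tol half-width used when pinning fitted/measured values as
#'   bounds (absorbs solver round-off).
#' @param hard_tol half-width of the measured-rate bounds in
#'   \code{"hard-pfba"} mode.
#' @return a \code{flux_solution} with method \code{"simulate"}; details
#'   carry the strategy and both stage objectives
#'   (\code{lad_residual}, \code{growth}, \code{total_flux}).
#' @export
simulate_condition <- function(model, constraints, exchange_map,
                               strategy = c("lad-then-pfba", "hard-pfba"),
                               backend = getOption("fluxgaba.lp_backend",
                                                   "simplex"),
                               pin_tol = 1e-8, hard_tol = 0,
                               tol = 1e-9) {
  strategy <- match.arg(strategy)
  targets <- constraint_targets(model, constraints, exchange_map)
  details <- list(strategy = strategy, condition = constraints$label,
                  backend = backend)
  if (strategy == "lad-then-pfba") {
    refs <- data.frame(reaction_id = targets$reaction_id,
                       value = targets$value, weight = 1)
    lad <- lad_fit(model, refs, backend = backend, tol = tol)
    if (!identical(lad$status, "optimal"))
      return(flux_solution(NULL, NA_real_, lad$status, "simulate",
                           details = c(details, list(stage = "lad"))))
    details$lad_residual <- lad$objective_value
    pin <- lad$fluxes[targets$reaction_id]
  } else {
    details$lad_residual <- NA_real_
    pin <- stats::setNames(targets$value, targets$reaction_id)
    pin_tol <- max(pin_tol, hard_tol)
  }
  idx <- match(names(pin), model$reactions$id)
  model$reactions$lower_bound[idx] <- unname(pin) - pin_tol
  model$reactions$upper_bound[idx] <- unname(pin) + pin_tol
  sol <- pfba(model, backend = backend, tol = tol)
  if (!identical(sol$status, "optimal"))
    return(flux_solution(NULL, NA_real_, sol$status, "simulate",
                         details = c(details, list(stage = "pfba"))))
  details$growth <- sol$objective_value
  details$total_flux <- sol$details$total_flux
  flux_solution(fluxes = sol$fluxes,
                objective_value = sol$objective_value,
                status = "optimal", method = "simulate",
                details = details)
}

#' Write / read a flux solution
#'
#' The flux vector goes to a two-column tab-separated file
#' (\code{reaction_id}, \code{flux}); status, objectives, method and
#' details go to a JSON header next to it (same stem, \code{.json}).
#'
#' @param solution a \code{flux_solution}.
#' @param stem output path without extension.
#' @return the TSV path (writer) or a \code{flux_solution} (reader).
#' @export
write_flux_solution <- function(solution, stem) {
  tsv <- paste0(stem, ".tsv"); hdr <- paste0(stem, ".json")
  utils::write.table(
    data.frame(reaction_id = names(solution$fluxes),
               flux = unname(solution$fluxes)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  details <- solution$details
  details$references <- NULL  # tabular payload does not belong in a header
  jsonlite::write_json(
    list(status = solution$status, method = solution$method,
         objective_value = solution$objective_value, details = details),
    hdr, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(tsv)
}

#' @rdname write_flux_solution
#' @export
read_flux_solution <- function(stem) {
  tab <- utils::read.delim(paste0(stem, ".tsv"))
  hdr <- jsonlite::fromJSON(paste0(stem, ".json"))
  flux_solution(fluxes = stats::setNames(tab$flux, tab$reaction_id),
                objective_value = hdr$objective_value,
                status = hdr$status, method = hdr$method,
                details = hdr$details)
}
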