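#' Build the central-carbon toy model
#'
#' Returns the hand-curated toy network (glycolysis, pentose phosphate
#' pathway, TCA cycle with anaplerosis, acetate and lactate overflow, GABA
#' shunt, lumped respiration and a lumped biomass drain) used throughout
#' the package as a self-contained stand-in for a genome-scale model.
#'
#' At build time the model is checked structurally (elemental balance of
#' every non-lumped reaction) and, when \code{check_feasibility} is on,
#' each bundled measured-rate vector is verified to be jointly attainable
#' by the knockout strain (AKGDH and ABTA closed) via a feasibility LP --
#' an infeasible row would be a fixture bug, not a data property.
#'
#' @param include_ppp include the pentose phosphate pathway (when dropped,
#'   the biomass drain loses its r5p/e4p terms so the model stays viable).
#' @param include_acetate_branch include phosphotransacetylase/acetate
#'   kinase overflow and the acetate exchange.
#' @param knockouts reaction ids to close (e.g. \code{c("AKGDH", "ABTA")}
#'   for the production strain), applied via [apply_knockouts()].
#' @param exchange_caps named vector of uptake caps (mmol/gDCW/h,
#'   magnitudes) keyed by exchange reaction id, e.g.
#'   \code{c(EX_glc__D_e = 8)} sets that lower bound to -8.
#' @param check_feasibility verify the bundled rate table against the
#'   knockout strain (only done on the full network).
#' @return a validated [metabolic_model()].
#' @export
build_toy_core <- function(include_ppp = TRUE,
                           include_acetate_branch = TRUE,
                           knockouts = character(),
                           exchange_caps = NULL,
                           check_feasibility = TRUE) {
  model <- toy_core_model()

  if (!include_ppp)
    model <- toy_drop(model, c("G6PDHL", "GND", "RPI", "RPE", "TKT1",
                               "TALA", "TKT2"),
                      drop_biomass = c("r5p_c", "e4p_c"))
  if (!include_acetate_branch)
    model <- toy_drop(model, c("PTAr", "ACKr", "ACt2r", "EX_ac_e"))

  bal <- check_mass_balance(model, exempt = "BIOMASS")
  if (nrow(bal))
    stop("toy_core fixture bug: unbalanced reaction(s) ",
         paste(unique(bal$reaction_id), collapse = ", "))

  if (!is.null(exchange_caps)) {
    idx <- match(names(exchange_caps), model$reactions$id)
    if (anyNA(idx))
      stop("unknown exchange reaction(s): ",
           paste(names(exchange_caps)[is.na(idx)], collapse = ", "))
    model$reactions$lower_bound[idx] <- -abs(as.numeric(exchange_caps))
  }

  if (check_feasibility && include_ppp && include_acetate_branch)
    toy_check_rate_table(model)

  if (length(knockouts))
    model <- apply_knockouts(model, knockout_spec(reactions = knockouts))
  validate_model(model)
  model
}

toy_drop <- function(model, rxn_ids, drop_biomass = character()) {
  keep <- !(model$reactions$id %in% rxn_ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  if (length(drop_biomass)) {
    st <- model$stoichiometry[["BIOMASS"]]
    model$stoichiometry[["BIOMASS"]] <- st[setdiff(names(st), drop_biomass)]
  }
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                         drop = FALSE]
  model
}

## every bundled measured-rate vector must be feasible for the knockout
## strain; solved as a plain feasibility LP with the rates as hard bounds
toy_check_rate_table <- function(model) {
  map <- read_exchange_map(system.file("extdata", "toy_exchange_map.tsv",
                                       package = "fluxgaba"))
  conds <- read_rate_table(system.file("extdata", "table1_rates.tsv",
                                       package = "fluxgaba"), map)
  ko <- apply_knockouts(model, knockout_spec(reactions = c("AKGDH",
                                                           "ABTA")))
  for (cond in conds) {
    m <- set_exchange_bounds(ko, cond, map, mode = "hard", tol = 1e-9)
    sol <- fba(m, sense = "max")
    if (!identical(sol$status, "optimal"))
      stop("toy_core fixture bug: measured rates of condition '",
           cond$label, "' are infeasible on the knockout strain")
  }
  invisible(TRUE)
}

#' Generate a synthetic exponential-phase batch fermentation profile
#'
#' Emulates the exponential growth phase of an aerobic batch culture:
#' biomass grows as \eqn{X(t) = x_0 e^{\mu t}} (OD600 units) and each
#' metabolite follows the closed-form balanced-growth trajectory
#' \deqn{C_s(t) = C_s(0) + q_s \frac{M_s}{1000}\, f_X\,
#'   \frac{x_0 (e^{\mu t} - 1)}{\mu}}
#' where \eqn{q_s} is the signed specific rate (mmol/gDCW/h, uptake
#' negative), \eqn{M_s} the molar mass (g/mol) and \eqn{f_X} the
#' OD-to-dry-cell-weight factor (gDCW/l per OD unit).  Closed forms rather
#' than ODE integration give the rate estimator an exact analytic target.
#' Measurement error is multiplicative lognormal (concentrations and OD
#' are positive and HPLC error is roughly proportional), mean-corrected so
#' the expectation equals the noiseless value.
#'
#' @param mu specific growth rate (h^-1).
#' @param q named vector of signed specific rates (mmol/gDCW/h).
#' @param c0 named vector of initial concentrations (g/l); defaults to
#'   20 g/l glucose, 2 g/l succinic acid and 0 for products.
#' @param x0 initial OD600.
#' @param times sampling grid (hours, strictly increasing).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed integer seed for the noise (required when
#'   \code{noise_cv > 0}); the generator does not touch the global RNG
#'   stream.
#' @param biomass_factor gDCW/l per OD600 unit.
#' @param molar_masses named vector of molar masses (g/mol).
#' @param label condition label carried into the profile.
#' @return a [fermentation_profile()].
#' @export
generate_profile <- function(mu, q, c0 = NULL, x0 = 0.1, times = 0:12,
                             noise_cv = 0, seed = NULL,
                             biomass_factor = 0.36,
                             molar_masses = default_molar_masses(),
                             label = "synthetic") {
  stopifnot(x0 > 0, noise_cv >= 0, !is.unsorted(times, strictly = TRUE))
  if (is.null(c0)) {
    c0_default <- c(glucose = 20, succinic_acid = 2)
    c0 <- stats::setNames(ifelse(names(q) %in% names(c0_default),
                                 c0_default[names(q)], 0), names(q))
  }
  missing_mw <- setdiff(names(q), names(molar_masses))
  if (length(missing_mw))
    stop("no molar mass for species: ", paste(missing_mw, collapse = ", "))
  od <- x0 * exp(mu * times)
  growth_int <- if (abs(mu) < 1e-12) x0 * times
                else x0 * (exp(mu * times) - 1) / mu
  conc <- sapply(names(q), function(s)
    c0[[s]] + q[[s]] * molar_masses[[s]] / 1000 * biomass_factor *
      growth_int)
  conc <- matrix(conc, nrow = length(times),
                 dimnames = list(NULL, names(q)))
  clipped <- conc < 0
  if (any(clipped)) {
    warning("negative concentration trajectory floored at 0 for: ",
            paste(unique(colnames(conc)[col(conc)[clipped]]),
                  collapse = ", "))
    conc[clipped] <- 0
  }
  if (noise_cv > 0) {
    if (is.null(seed))
      stop("a seed is required for noisy profiles (reproducibility)")
    sdlog <- sqrt(log(1 + noise_cv^2))
    n_obs <- length(times) * (ncol(conc) + 1L)
    eps <- local_rng_lognormal(seed, n_obs, sdlog)
    od <- od * eps[seq_along(times)]
    conc <- conc * matrix(eps[-seq_along(times)], nrow = length(times))
  }
  fermentation_profile(times = times, od600 = od,
                       concentrations = as.data.frame(conc),
                       label = label)
}

## deterministic lognormal draws from a private RNG stream
local_rng_lognormal <- function(seed, n, sdlog) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}
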