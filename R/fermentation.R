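#' Batch fermentation time course
#'
#' Time series of a biomass proxy (OD600) and metabolite concentrations for
#' one batch run.  Concentrations are in g/l, time in hours.
#'
#' @param times strictly increasing sampling times (h).
#' @param od600 positive OD600 readings, one per time point.
#' @param concentrations data.frame of concentrations (g/l), one column per
#'   species, one row per time point; all values >= 0.
#' @param label free-text condition label.
#' @return object of class \code{fermentation_profile}.
#' @export
fermentation_profile <- function(times, od600, concentrations, label = "") {
  concentrations <- as.data.frame(concentrations)
  stopifnot(length(times) == length(od600),
            nrow(concentrations) == length(times))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(od600 <= 0)) stop("od600 must be positive")
  if (any(as.matrix(concentrations) < 0))
    stop("concentrations must be non-negative")
  structure(list(times = as.numeric(times), od600 = as.numeric(od600),
                 concentrations = concentrations, label = label),
            class = "fermentation_profile")
}

#' Read / write fermentation profiles as delimited text
#'
#' The on-disk format is a tab-separated table with a header row:
#' \code{time_h}, \code{od600}, then one column per species (g/l).
#'
#' @param path file path.
#' @param label condition label for the loaded profile.
#' @return a [fermentation_profile()] (reader) or \code{path} (writer).
#' @export
read_profile <- function(path, label = basename(path)) {
  tab <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("time_h", "od600") %in% names(tab)))
  species <- setdiff(names(tab), c("time_h", "od600"))
  fermentation_profile(tab$time_h, tab$od600,
                       tab[, species, drop = FALSE], label = label)
}

#' @rdname read_profile
#' @param profile a [fermentation_profile()].
#' @export
write_profile <- function(profile, path) {
  tab <- data.frame(time_h = profile$times, od600 = profile$od600,
                    profile$concentrations, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select the exponential-growth (log-phase) window of a batch profile
#'
#' Scans every contiguous window of the requested width and returns the one
#' whose in-window least-squares slope of \eqn{\ln(\mathrm{OD600})} against
#' time is highest -- the section of the growth curve with the highest
#' specific growth rate.  Ties are broken toward the earliest start.
#'
#' @param profile a [fermentation_profile()].
#' @param window_hours window width (h).
#' @param min_points minimum number of in-window samples for a fit.
#' @return numeric \code{c(t_start, t_end)} in hours.
#' @export
select_log_phase <- function(profile, window_hours, min_points = 3L) {
  t <- profile$times
  if (diff(range(t)) < window_hours)
    stop("profile spans less than the requested window")
  starts <- t[t + window_hours <= max(t) + 1e-9]
  best <- NULL; best_slope <- -Inf
  for (t0 in starts) {
    idx <- which(t >= t0 - 1e-9 & t <= t0 + window_hours + 1e-9)
    if (length(idx) < min_points) next
    slope <- stats::coef(stats::lm(log(profile$od600[idx]) ~ t[idx]))[[2]]
    if (slope > best_slope + 1e-12) {
      best_slope <- slope
      best <- c(t0, t0 + window_hours)
    }
  }
  if (is.null(best))
    stop("no window of ", window_hours, " h contains at least ",
         min_points, " samples")
  best
}

#' Estimate the specific growth rate over a window
#'
#' Least-squares slope of \eqn{\ln(\mathrm{OD600})} against time within the
#' window; exact for exponential growth.
#'
#' @param profile a [fermentation_profile()].
#' @param window numeric \code{c(t_start, t_end)}.
#' @return growth rate mu (h^-1).
#' @export
estimate_growth_rate <- function(profile, window) {
  idx <- window_index(profile, window)
  if (any(profile$od600[idx] <= 0))
    stop("non-positive OD600 inside the fitting window")
  stats::coef(stats::lm(log(profile$od600[idx]) ~
                          profile$times[idx]))[[2]]
}

#' Estimate specific exchange rates over a window
#'
#' For each species the concentration (converted to mmol/l) is regressed
#' against the biomass concentration \eqn{X(t) = f_X \cdot \mathrm{OD}(t)}
#' (gDCW/l) within the window, and the specific rate is
#' \eqn{q = \mu \, dC/dX} -- the yield-times-growth form, exact under
#' balanced exponential growth.  Signs follow the fitted slope, so consumed
#' species get negative rates.
#'
#' @param profile a [fermentation_profile()].
#' @param window numeric \code{c(t_start, t_end)}.
#' @param biomass_factor gDCW/l per OD600 unit.
#' @param molar_masses named vector of molar masses (g/mol); must cover
#'   every profiled species.
#' @return object of class \code{rate_estimate}: list with \code{mu}
#'   (h^-1), \code{q} (named signed vector, mmol/gDCW/h), \code{window},
#'   and per-fit \code{r_squared}.
#' @export
estimate_specific_rates <- function(profile, window,
                                    biomass_factor = 0.36,
                                    molar_masses =
                                      default_molar_masses()) {
  species <- colnames(profile$concentrations)
  missing_mw <- setdiff(species, names(molar_masses))
  if (length(missing_mw))
    stop("no molar mass for species: ", paste(missing_mw, collapse = ", "))
  idx <- window_index(profile, window)
  mu <- estimate_growth_rate(profile, window)
  X <- biomass_factor * profile$od600[idx]
  fits <- lapply(species, function(s) {
    C_mmol <- profile$concentrations[idx, s] * 1000 / molar_masses[[s]]
    fit <- stats::lm(C_mmol ~ X)
    ## R^2 by hand: summary.lm() warns on the noiseless profiles the
    ## generator produces; a flat response counts as a perfect fit
    ss_tot <- sum((C_mmol - mean(C_mmol))^2)
    r2 <- if (ss_tot < 1e-12) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    list(q = mu * stats::coef(fit)[[2]], r2 = r2)
  })
  structure(list(mu = mu,
                 q = stats::setNames(vapply(fits, `[[`, numeric(1), "q"),
                                     species),
                 window = window,
                 r_squared = stats::setNames(
                   vapply(fits, `[[`, numeric(1), "r2"), species),
                 label = profile$label),
            class = "rate_estimate")
}

window_index <- function(profile, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < min(profile$times) - 1e-9 ||
      window[2] > max(profile$times) + 1e-9)
    stop("window lies outside the profile's time range")
  idx <- which(profile$times >= window[1] - 1e-9 &
               profile$times <= window[2] + 1e-9)
  if (length(idx) < 3) stop("fewer than 3 samples inside the window")
  idx
}

#' Convert a rate estimate into condition constraints
#'
#' Splits each signed specific rate into a magnitude and an
#' uptake/secretion direction and attaches the growth rate, yielding the
#' constraint set a flux simulation consumes.  Species whose fitted rate is
#' exactly zero are tagged by their physiological default when a mapping is
#' given, otherwise as secretion at magnitude zero.
#'
#' @param est a [estimate_specific_rates()] result.
#' @param exchange_map optional mapping (see [read_exchange_map()]) used
#'   only to direction-tag zero rates.
#' @return a [condition_constraints()] with provenance \code{"estimated"}.
#' @export
to_condition_constraints <- function(est, exchange_map = NULL) {
  stopifnot(inherits(est, "rate_estimate"))
  dir <- ifelse(est$q < 0, "uptake", "secretion")
  if (!is.null(exchange_map)) {
    zero <- est$q == 0
    md <- stats::setNames(exchange_map$direction, exchange_map$species)
    hit <- zero & names(est$q) %in% names(md)
    dir[hit] <- md[names(est$q)[hit]]
  }
  condition_constraints(
    growth_rate = est$mu,
    rates = data.frame(species = names(est$q),
                       magnitude = abs(unname(est$q)),
                       direction = unname(dir), stringsAsFactors = FALSE),
    provenance = "estimated", label = est$label)
}

#' Default molar masses of the profiled species (g/mol)
#'
#' Glucose, succinic acid, GABA, glutamate, acetic acid and, for the
#' synthetic overflow product, D-lactate.
#'
#' @return named numeric vector.
#' @export
default_molar_masses <- function() {
  c(glucose = 180.16, succinic_acid = 118.09, gaba = 103.12,
    glutamate = 147.13, acetic_acid = 60.05, lactate = 90.08)
}
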