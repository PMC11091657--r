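#' Run configuration
#'
#' Validated configuration for the condition-simulation workflow, readable
#' from YAML.  Unknown keys are rejected so that typos fail loudly instead
#' of silently falling back to defaults; the full effective configuration
#' is echoed into every run log.
#'
#' @param config named list or path to a YAML file.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(
    model = NULL,                 # path to a model file, or NULL for toy_core
    model_format = "auto",
    knockout_genes = character(),
    knockout_reactions = c("AKGDH", "ABTA"),
    rate_table = system.file("extdata", "table1_rates.tsv",
                             package = "fluxgaba"),
    exchange_map = system.file("extdata", "toy_exchange_map.tsv",
                               package = "fluxgaba"),
    pathway_map = system.file("extdata", "toy_pathways.tsv",
                              package = "fluxgaba"),
    strategy = "lad-then-pfba",
    threshold = 0.20,
    zero_tol = 1e-6,
    window_hours = 4,
    biomass_factor = 0.36,
    molar_masses = as.list(default_molar_masses()),
    backend = getOption("fluxgaba.lp_backend", "simplex"),
    seed = 1L,
    output_dir = "results")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$threshold > 0, cfg$zero_tol >= 0, cfg$window_hours > 0,
            cfg$biomass_factor > 0,
            cfg$strategy %in% c("lad-then-pfba", "hard-pfba"))
  structure(cfg, class = "run_config")
}

config_model <- function(cfg) {
  path <- cfg[["model"]]  # exact match: "model" may be absent entirely
  if (is.null(path))
    build_toy_core(check_feasibility = FALSE)
  else
    load_model(path, format = cfg$model_format)
}

run_log <- function(cfg, path, lines) {
  hdr <- c(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  " fluxgaba ",
                  as.character(utils::packageVersion("fluxgaba"))),
           paste0("backend: ", cfg$backend),
           "config:",
           paste0("  ", strsplit(yaml::as.yaml(unclass(cfg)),
                                 "\n")[[1]]))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Estimate condition constraints from a fermentation profile
#'
#' Stage one of the workflow: reads a profile, selects the log phase,
#' estimates the specific growth and exchange rates, and writes the
#' resulting constraints (JSON) plus a provenance log into the output
#' directory.
#'
#' @param cfg a [run_config()].
#' @param profile_path path to a profile file (see [read_profile()]).
#' @param name output stem; defaults to the profile file name.
#' @return the [condition_constraints()], invisibly.
#' @export
run_estimate <- function(cfg, profile_path, name = NULL) {
  cfg <- run_config(unclass(cfg))
  if (!file.exists(profile_path))
    stop("estimate stage: profile file not found: ", profile_path)
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(profile_path))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- read_profile(profile_path, label = name)
  window <- select_log_phase(profile, cfg$window_hours)
  est <- estimate_specific_rates(
    profile, window, biomass_factor = cfg$biomass_factor,
    molar_masses = unlist(cfg$molar_masses))
  map <- read_exchange_map(cfg$exchange_map)
  cons <- to_condition_constraints(est, exchange_map = map)
  out <- file.path(cfg$output_dir, paste0(name, "_constraints.json"))
  jsonlite::write_json(
    list(label = cons$label, growth_rate = cons$growth_rate,
         rates = cons$rates, provenance = cons$provenance,
         window = list(t_start = window[1], t_end = window[2]),
         r_squared = as.list(est$r_squared)),
    out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(cfg, file.path(cfg$output_dir, paste0(name, "_estimate.log")),
          c(paste0("profile: ", profile_path),
            sprintf("log phase: %.3f to %.3f h", window[1], window[2]),
            sprintf("growth rate: %.6f 1/h", est$mu),
            sprintf("%s: %.6f mmol/gDCW/h", names(est$q), est$q)))
  invisible(cons)
}

#' Simulate one culture condition and write the flux solution
#'
#' Stage two: loads the model (the bundled toy network by default),
#' applies the knockouts, runs [simulate_condition()] against the named
#' row of the measured-rate table, and writes the flux vector, its JSON
#' header, and a provenance log.
#'
#' @param cfg a [run_config()].
#' @param condition name of the rate-table row to simulate.
#' @return the \code{flux_solution}, invisibly.
#' @export
run_simulate <- function(cfg, condition) {
  cfg <- run_config(unclass(cfg))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config_model(cfg)
  model <- apply_knockouts(model,
                           knockout_spec(genes = cfg$knockout_genes,
                                         reactions = cfg$knockout_reactions))
  map <- read_exchange_map(cfg$exchange_map)
  conds <- read_rate_table(cfg$rate_table, map)
  if (!condition %in% names(conds))
    stop("simulate stage: condition '", condition,
         "' not in the rate table (have: ",
         paste(names(conds), collapse = ", "), ")")
  sol <- simulate_condition(model, conds[[condition]], map,
                            strategy = cfg$strategy,
                            backend = cfg$backend)
  if (!identical(sol$status, "optimal"))
    stop("simulate stage: solver returned status '", sol$status,
         "' for condition '", condition, "'")
  stem <- file.path(cfg$output_dir, paste0("fluxes_", condition))
  write_flux_solution(sol, stem)
  run_log(cfg, file.path(cfg$output_dir,
                         paste0("simulate_", condition, ".log")),
          c(paste0("condition: ", condition),
            paste0("model: ", model$id),
            paste0("knocked reactions: ",
                   paste(attr(model, "knocked_reactions"),
                         collapse = ", ")),
            sprintf("LAD residual: %.9g", sol$details$lad_residual),
            sprintf("growth: %.6f 1/h", sol$objective_value),
            sprintf("total |v|: %.6f", sol$details$total_flux)))
  invisible(sol)
}

#' Compare two flux solutions and write the change report
#'
#' Stage three: classifies per-reaction flux changes between two solutions
#' and writes the change table (TSV) plus the pathway summary (JSON).
#'
#' @param cfg a [run_config()].
#' @param sol_a,sol_b \code{flux_solution}s or stems of solution files
#'   written by [run_simulate()].
#' @param name output stem for the report files.
#' @return the change table, invisibly.
#' @export
run_compare <- function(cfg, sol_a, sol_b, name = "comparison") {
  cfg <- run_config(unclass(cfg))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(sol_a)) sol_a <- read_flux_solution(sol_a)
  if (is.character(sol_b)) sol_b <- read_flux_solution(sol_b)
  only_a <- setdiff(names(sol_a$fluxes), names(sol_b$fluxes))
  only_b <- setdiff(names(sol_b$fluxes), names(sol_a$fluxes))
  if (length(only_a) || length(only_b))
    stop("compare stage: reaction sets differ; only in A: {",
         paste(only_a, collapse = ", "), "}, only in B: {",
         paste(only_b, collapse = ", "), "}")
  changes <- compare_conditions(sol_a, sol_b, threshold = cfg$threshold,
                                zero_tol = cfg$zero_tol)
  summary <- summarize_by_pathway(changes,
                                  read_pathway_map(cfg$pathway_map))
  utils::write.table(changes,
                     file.path(cfg$output_dir, paste0(name, "_changes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary,
                       file.path(cfg$output_dir,
                                 paste0(name, "_pathways.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(changes)
}

#' Replay the full three-condition study
#'
#' Convenience wrapper: simulates every condition in the bundled
#' measured-rate table and writes the two condition-pair comparisons the
#' study design defines (pH shift at 2 g/l succinate; succinate dose at
#' acidic pH).
#'
#' @param cfg a [run_config()].
#' @return named list with \code{solutions} and \code{comparisons},
#'   invisibly.
#' @export
run_replay <- function(cfg = run_config()) {
  cfg <- run_config(unclass(cfg))
  map <- read_exchange_map(cfg$exchange_map)
  conds <- names(read_rate_table(cfg$rate_table, map))
  sols <- lapply(conds, function(cn) run_simulate(cfg, cn))
  names(sols) <- conds
  pairs <- list()
  if (all(c("neutral_2gl", "acidic_2gl") %in% conds))
    pairs$ph_shift <- run_compare(cfg, sols$neutral_2gl, sols$acidic_2gl,
                                  name = "ph_shift")
  if (all(c("acidic_2gl", "acidic_4gl") %in% conds))
    pairs$succinate_dose <- run_compare(cfg, sols$acidic_2gl,
                                        sols$acidic_4gl,
                                        name = "succinate_dose")
  invisible(list(solutions = sols, comparisons = pairs))
}
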