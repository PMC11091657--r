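# Fixtures are built in code: small hand-written models with known LP
# solutions, plus a seeded generator of random small feasible networks.

simple_model <- function(reactions, stoich, objective,
                         mets = NULL, id = "test") {
  if (is.null(mets))
    mets <- sort(unique(unlist(lapply(stoich, names))))
  metabolic_model(
    id = id,
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             formula = NA_character_),
    reactions = reactions, stoichiometry = stoich, objective = objective)
}

# EX_A (uptake, max 10) -> R1: A->B -> R2: B->C -> EX_C
chain_model <- function() {
  simple_model(
    reactions = data.frame(
      id = c("EX_A", "R1", "R2", "EX_C"),
      name = c("A exchange", "A to B", "B to C", "C exchange"),
      lower_bound = c(-10, 0, 0, 0), upper_bound = c(0, 1000, 1000, 1000),
      gpr = c("", "g1", "g2a or g2b", "")),
    stoich = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                  R2 = c(B = -1, C = 1), EX_C = c(C = -1)),
    objective = "EX_C")
}

# chain plus a redundant parallel A->B reaction with equal stoichiometry
chain_model_parallel <- function() {
  m <- chain_model()
  m$reactions <- rbind(m$reactions, data.frame(
    id = "R1b", name = "A to B (isozyme)", lower_bound = 0,
    upper_bound = 1000, gpr = "", subsystem = NA_character_))
  m$stoichiometry$R1b <- c(A = -1, B = 1)
  validate_model(m)
  m
}

# chain plus a stoichiometrically balanced internal 2-cycle B <-> D
chain_model_cycle <- function() {
  m <- chain_model()
  m$reactions <- rbind(m$reactions, data.frame(
    id = c("C1", "C2"), name = c("B to D", "D to B"),
    lower_bound = 0, upper_bound = 1000, gpr = "",
    subsystem = NA_character_))
  m$stoichiometry$C1 <- c(B = -1, D = 1)
  m$stoichiometry$C2 <- c(D = -1, B = 1)
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "D", name = "D", compartment = "c", formula = NA_character_))
  validate_model(m)
  m
}

# seeded random network of at most `max_rxns` reactions: a few exchange
# columns plus random sparse internal columns; always feasible (v = 0)
random_small_model <- function(seed, max_rxns = 12) {
  set.seed(seed)
  n_mets <- sample(3:6, 1)
  n_rxns <- sample(6:max_rxns, 1)
  n_ex <- min(n_mets, sample(2:4, 1))
  mets <- paste0("m", seq_len(n_mets))
  stoich <- list(); ids <- character(); lb <- ub <- numeric()
  for (k in seq_len(n_ex)) {
    ids[k] <- paste0("EX_", k)
    stoich[[ids[k]]] <- stats::setNames(-1, mets[k])
    lb[k] <- -10; ub[k] <- stats::runif(1, 0, 10)
  }
  for (k in (n_ex + 1):n_rxns) {
    ids[k] <- paste0("R", k)
    sz <- sample(2:3, 1)
    picked <- sample(mets, sz)
    stoich[[ids[k]]] <- stats::setNames(
      sample(c(-2, -1, 1, 2), sz, replace = TRUE), picked)
    lb[k] <- if (stats::runif(1) < 0.5) -10 else 0
    ub[k] <- 10
  }
  simple_model(
    reactions = data.frame(id = ids, name = ids, lower_bound = lb,
                           upper_bound = ub, gpr = ""),
    stoich = stoich, objective = ids[1], mets = mets,
    id = paste0("rand", seed))
}

toy_map <- function()
  read_exchange_map(system.file("extdata", "toy_exchange_map.tsv",
                                package = "fluxgaba"))

toy_conds <- function()
  read_rate_table(system.file("extdata", "table1_rates.tsv",
                              package = "fluxgaba"), toy_map())

toy_ko <- function()
  build_toy_core(knockouts = c("AKGDH", "ABTA"),
                 check_feasibility = FALSE)

# signed rate vector of a condition keyed by species, for generators
condition_truth <- function(cond) {
  list(mu = cond$growth_rate, q = signed_rates(cond))
}

max_mass_imbalance <- function(model, fluxes) {
  S <- as.matrix(stoichiometric_matrix(model))
  max(abs(S %*% fluxes[colnames(S)]))
}
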