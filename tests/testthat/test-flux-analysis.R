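test_that("FBA finds the uptake-limited optimum of a linear chain", {
  m <- chain_model()
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_lte(max_mass_imbalance(m, sol$fluxes), 1e-6)
  # severing the path drops the optimum to zero
  ko <- apply_knockouts(m, "R1")
  expect_equal(fba(ko)$objective_value, 0, tolerance = 1e-9)
  # minimisation sense
  expect_equal(fba(m, sense = "min")$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA propagates infeasibility as a status, not an error", {
  m <- chain_model()
  i <- match("R2", m$reactions$id)
  m$reactions$lower_bound[i] <- 20  # beyond the uptake bound
  sol <- fba(m)
  expect_identical(sol$status, "infeasible")
  expect_null(sol$fluxes)
})

test_that("pFBA minimises total absolute flux at the growth optimum", {
  sol <- pfba(chain_model())
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(sol$details$total_flux, 40, tolerance = 1e-9)

  # a redundant parallel route does not change the minimal total flux
  solp <- pfba(chain_model_parallel())
  expect_equal(solp$details$total_flux, 40, tolerance = 1e-9)
  expect_equal(solp$fluxes[["R1"]] + solp$fluxes[["R1b"]], 10,
               tolerance = 1e-9)

  # a balanced internal cycle carries zero flux in the parsimonious optimum
  solc <- pfba(chain_model_cycle())
  expect_equal(solc$fluxes[["C1"]], 0, tolerance = 1e-9)
  expect_equal(solc$fluxes[["C2"]], 0, tolerance = 1e-9)
})

test_that("pFBA matches an independently formulated two-stage solve", {
  for (seed in c(3, 7, 11, 19)) {
    m <- random_small_model(seed)
    mine <- pfba(m)
    # oracle: formulate both stages from scratch and hand them to HiGHS
    S <- as.matrix(stoichiometric_matrix(m))
    n <- ncol(S); lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
    cvec <- as.numeric(m$reactions$id == m$objective)
    st1 <- solve_lp(lp_problem(cvec, S, rep(0, nrow(S)), lb, ub,
                               maximize = TRUE), backend = "highs")
    A2 <- rbind(cbind(S, -S), c(cvec, -cvec))
    st2 <- solve_lp(lp_problem(
      rep(1, 2 * n), A2, c(rep(0, nrow(S)), st1$objective),
      lb = c(pmax(lb, 0), pmax(-ub, 0)), ub = c(pmax(ub, 0), pmax(-lb, 0)),
      sense = c(rep("=", nrow(S)), ">="), maximize = FALSE),
      backend = "highs")
    expect_equal(mine$objective_value, st1$objective, tolerance = 1e-6,
                 label = paste("stage-1 optimum, seed", seed))
    expect_equal(mine$details$total_flux, st2$objective, tolerance = 1e-6,
                 label = paste("total |v|, seed", seed))
  }
})

test_that("LAD reproduces feasible references and clamps infeasible ones", {
  m <- chain_model()
  # feasible reference: fitted exactly, zero residual
  sol <- lad_fit(m, data.frame(reaction_id = "EX_C", value = 5))
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  expect_equal(sol$fluxes[["EX_C"]], 5, tolerance = 1e-9)
  # reference beyond the uptake bound: L1 projection clamps to the box edge
  sol2 <- lad_fit(m, data.frame(reaction_id = "EX_C", value = 15))
  expect_equal(sol2$fluxes[["EX_C"]], 10, tolerance = 1e-9)
  expect_equal(sol2$objective_value, 5, tolerance = 1e-9)
  # weights scale the residual
  sol3 <- lad_fit(m, data.frame(reaction_id = "EX_C", value = 15,
                                weight = 2))
  expect_equal(sol3$objective_value, 10, tolerance = 1e-9)
})

test_that("LAD residual is zero exactly when the references are feasible", {
  set.seed(33)
  for (rep in 1:10) {
    m <- random_small_model(rep + 200)
    k <- sample(2:3, 1)
    rid <- sample(m$reactions$id, k)
    refs <- data.frame(reaction_id = rid,
                       value = round(runif(k, -8, 8), 2))
    sol <- lad_fit(m, refs)
    expect_identical(sol$status, "optimal")
    # oracle: the references are jointly attainable iff each lies inside
    # its reaction's box and the pinned steady-state LP is feasible
    idx <- match(rid, m$reactions$id)
    inside <- all(refs$value >= m$reactions$lower_bound[idx] - 1e-12 &
                  refs$value <= m$reactions$upper_bound[idx] + 1e-12)
    feasible <- FALSE
    if (inside) {
      m2 <- m
      m2$reactions$lower_bound[idx] <- refs$value
      m2$reactions$upper_bound[idx] <- refs$value
      S <- as.matrix(stoichiometric_matrix(m2))
      feas <- solve_lp(lp_problem(rep(0, ncol(S)), S, rep(0, nrow(S)),
                                  m2$reactions$lower_bound,
                                  m2$reactions$upper_bound),
                       backend = "highs")
      feasible <- identical(feas$status, "optimal")
    }
    if (feasible)
      expect_lt(sol$objective_value, 1e-7)
    else
      expect_gt(sol$objective_value, 1e-7)
  }
})

test_that("tightening a bound never decreases the LAD residual", {
  m <- chain_model()
  refs <- data.frame(reaction_id = "EX_C", value = 8)
  base <- lad_fit(m, refs)$objective_value
  for (cap in c(9, 6, 4, 2)) {
    m2 <- m
    m2$reactions$upper_bound[match("R1", m2$reactions$id)] <- cap
    expect_gte(lad_fit(m2, refs)$objective_value + 1e-9, base)
    base <- lad_fit(m2, refs)$objective_value
  }
})

test_that("scaling references and bounds by k scales the fitted fluxes", {
  m <- random_small_model(91)
  refs <- data.frame(reaction_id = m$reactions$id[c(1, 3)],
                     value = c(-4, 2.5))
  s1 <- lad_fit(m, refs)
  k <- 3.7
  m2 <- m
  m2$reactions$lower_bound <- k * m2$reactions$lower_bound
  m2$reactions$upper_bound <- k * m2$reactions$upper_bound
  refs2 <- transform(refs, value = k * value)
  s2 <- lad_fit(m2, refs2)
  expect_equal(s2$objective_value, k * s1$objective_value,
               tolerance = 1e-6)
  expect_equal(s2$fluxes[refs$reaction_id],
               k * s1$fluxes[refs$reaction_id], tolerance = 1e-6)
})

test_that("condition simulation pins measured rates and reports stages", {
  model <- toy_ko(); map <- toy_map(); conds <- toy_conds()
  sol <- simulate_condition(model, conds$neutral_2gl, map)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, conds$neutral_2gl$growth_rate,
               tolerance = 1e-6)
  expect_equal(sol$details$lad_residual, 0, tolerance = 1e-8)
  expect_equal(sol$fluxes[["EX_glc__D_e"]], -1.806954, tolerance = 1e-6)
  expect_lte(max_mass_imbalance(model, sol$fluxes), 1e-6)
  # feasible references: both strategies land on the same solution
  hard <- simulate_condition(model, conds$neutral_2gl, map,
                             strategy = "hard-pfba")
  expect_equal(hard$fluxes, sol$fluxes, tolerance = 1e-5)
})

test_that("an unattainable rate vector yields a positive LAD residual", {
  model <- toy_ko(); map <- toy_map(); conds <- toy_conds()
  broken <- conds$neutral_2gl
  # demand more glutamate carbon than the feed provides
  broken$rates$magnitude[broken$rates$species == "glutamate"] <- 5
  sol <- simulate_condition(model, broken, map)
  expect_identical(sol$status, "optimal")
  expect_gt(sol$details$lad_residual, 0.1)
})

test_that("flux solutions round-trip through their file form", {
  sol <- pfba(chain_model())
  stem <- tempfile()
  write_flux_solution(sol, stem)
  back <- read_flux_solution(stem)
  expect_equal(back$fluxes, sol$fluxes, tolerance = 1e-12)
  expect_identical(back$status, "optimal")
  expect_identical(back$method, "pfba")
})
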