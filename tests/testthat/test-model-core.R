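test_that("a hand-written 2-metabolite, 3-reaction model transcribes to S", {
  m <- simple_model(
    reactions = data.frame(id = c("EX_A", "R", "EX_B"),
                           name = c("in", "conv", "out"),
                           lower_bound = c(-5, 0, 0),
                           upper_bound = c(0, 100, 100), gpr = ""),
    stoich = list(EX_A = c(A = -1), R = c(A = -1, B = 2),
                  EX_B = c(B = -1)),
    objective = "EX_B")
  S <- stoichiometric_matrix(m, sparse = FALSE)
  expect_equal(dim(S), c(2, 3))
  expect_equal(S["A", "R"], -1)
  expect_equal(S["B", "R"], 2)
  expect_equal(S["A", "EX_A"], -1)
  expect_equal(S["B", "EX_B"], -1)
})

test_that("structural invariants are enforced", {
  good <- chain_model()
  bad <- good
  bad$reactions$lower_bound[2] <- 2000  # above the upper bound
  expect_error(validate_model(bad), "lower_bound")
  bad <- good
  bad$stoichiometry$R1 <- c(A = -1, Z = 1)  # unknown metabolite
  expect_error(validate_model(bad), "unknown metabolite")
  bad <- good
  bad$reactions$gpr[2] <- "nosuchgene"
  bad$genes <- "g1"
  expect_error(validate_model(bad), "gene")
  bad <- good
  bad$objective <- "NOPE"
  expect_error(validate_model(bad), "objective")
})

test_that("the bundled toy fixture loads and matches its declared sizes", {
  path <- system.file("extdata", "toy_core.json", package = "fluxgaba")
  m <- load_model(path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(nrow(m$metabolites), length(doc$metabolites))
  expect_equal(nrow(m$reactions), length(doc$reactions))
  expect_equal(length(m$genes), length(doc$genes))
  expect_identical(m$objective, "BIOMASS")
})

test_that("JSON write/read round-trips bit-identically on the fixture", {
  path <- system.file("extdata", "toy_core.json", package = "fluxgaba")
  m1 <- load_model(path)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model_json(m1, f1)
  m2 <- load_model(f1)
  write_model_json(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(m2$stoichiometry[m1$reactions$id],
               m1$stoichiometry[m1$reactions$id])
  expect_equal(m2$reactions$lower_bound, m1$reactions$lower_bound)
  expect_identical(m2$reactions$gpr, m1$reactions$gpr)
})

test_that("SBML/FBC write/read round-trips the fixture", {
  m1 <- build_toy_core(check_feasibility = FALSE)
  f <- tempfile(fileext = ".xml")
  write_model_sbml(m1, f)
  m2 <- load_model(f, format = "sbml")
  expect_setequal(m2$reactions$id, m1$reactions$id)
  idx <- match(m1$reactions$id, m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[idx], m1$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound[idx], m1$reactions$upper_bound)
  expect_identical(m2$objective, m1$objective)
  expect_setequal(m2$genes, m1$genes)
  for (rid in m1$reactions$id) {
    a <- m1$stoichiometry[[rid]]; b <- m2$stoichiometry[[rid]]
    expect_equal(b[sort(names(b))], a[sort(names(a))], label = rid)
  }
  # GPR truth tables survive the round trip
  for (rid in c("AKGDH", "GLUDC", "PFK", "PDH")) {
    a <- m1$reactions$gpr[m1$reactions$id == rid]
    b <- m2$reactions$gpr[m2$reactions$id == rid]
    expect_setequal(gpr_genes(a), gpr_genes(b))
    for (g in gpr_genes(a))
      expect_identical(evaluate_gpr(a, g), evaluate_gpr(b, g),
                       label = paste(rid, g))
  }
  # second write is bit-identical (stable serialisation)
  f2 <- tempfile(fileext = ".xml")
  write_model_sbml(m2, f2)
  m3 <- load_model(f2, format = "sbml")
  expect_equal(m3$reactions$lower_bound,
               m2$reactions$lower_bound)
})

test_that("loader errors name the problem", {
  expect_error(load_model("/nonexistent/model.json"), "not found")
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(load_model(f), "format error")
  # model without an objective: explicit error, loadable on request
  m <- chain_model(); m$objective <- NA_character_
  f2 <- tempfile(fileext = ".json")
  write_model_json(m, f2)
  expect_error(load_model(f2), "no objective")
  m2 <- load_model(f2, require_objective = FALSE)
  expect_true(is.na(m2$objective))
})

test_that("every non-lumped toy reaction is elementally balanced", {
  toy <- build_toy_core(check_feasibility = FALSE)
  bal <- check_mass_balance(toy, exempt = "BIOMASS")
  expect_identical(nrow(bal), 0L)
  # and the checker does flag a deliberate imbalance
  broken <- toy
  broken$stoichiometry$PGI["f6p_c"] <- 2
  expect_gt(nrow(check_mass_balance(broken, exempt = "BIOMASS")), 0)
})

test_that("exchange reactions are the single-metabolite boundary set", {
  toy <- build_toy_core(check_feasibility = FALSE)
  ex <- exchange_reactions(toy)
  expect_true(all(startsWith(ex, "EX_")))
  expect_setequal(ex, toy$reactions$id[startsWith(toy$reactions$id, "EX_")])
})
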