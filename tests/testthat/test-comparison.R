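test_that("classification follows the threshold rule", {
  cls <- function(a, b, ...) classify_change(a, b, ...)$class
  expect_identical(cls(1.0, 1.3), "induced")      # +30% > 20%
  expect_identical(cls(1.0, 0.9), "unchanged")    # -10% inside the band
  expect_identical(cls(1.0, 0.7), "suppressed")   # -30%
  expect_identical(cls(0.5, -0.5), "inverted")
  expect_identical(cls(0, 0), "unchanged")
  expect_identical(cls(0, 0.4), "de-novo")
  expect_identical(cls(0.4, 0), "abolished")
  # the comparison is on magnitudes: a more negative flux is induced
  expect_identical(cls(-1.0, -1.5), "induced")
  # boundary: exactly the threshold is not a significant change
  expect_identical(cls(1.0, 1.2), "unchanged")
  expect_error(classify_change(1, 2, threshold = 0), "threshold")
})

test_that("swapping conditions maps classes antisymmetrically", {
  set.seed(55)
  for (rep in 1:200) {
    a <- round(runif(1, -3, 3), 3); b <- round(runif(1, -3, 3), 3)
    ab <- classify_change(a, b)$class
    ba <- classify_change(b, a)$class
    expected <- c(induced = "suppressed", suppressed = "induced",
                  `de-novo` = "abolished", abolished = "de-novo",
                  inverted = "inverted", unchanged = "unchanged")
    expect_identical(ba, unname(expected[ab]),
                     label = sprintf("a=%g b=%g", a, b))
  }
})

test_that("positive rescaling never changes the class", {
  set.seed(56)
  for (rep in 1:200) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2); k <- runif(1, 0.1, 50)
    expect_identical(classify_change(k * a, k * b)$class,
                     classify_change(a, b)$class,
                     label = sprintf("a=%g b=%g k=%g", a, b, k))
  }
})

test_that("every reaction gets exactly one class", {
  classes <- c("induced", "suppressed", "unchanged", "inverted",
               "de-novo", "abolished")
  set.seed(57)
  vals <- c(0, 1e-9, 1e-6, runif(20, -2, 2))
  for (a in vals) for (b in vals) {
    cl <- classify_change(a, b)$class
    expect_length(cl, 1)
    expect_true(cl %in% classes)
  }
})

test_that("identical solutions compare as all-unchanged", {
  sol <- pfba(chain_model())
  ch <- compare_conditions(sol, sol)
  expect_true(all(ch$class == "unchanged"))
  expect_identical(ch$reaction_id, sort(names(sol$fluxes)))
})

test_that("comparison requires optimal solutions", {
  sol <- pfba(chain_model())
  bad <- sol; bad$status <- "infeasible"
  expect_error(compare_conditions(sol, bad), "optimal")
})

test_that("an extreme threshold leaves only sign-structure classes", {
  a <- flux_a <- c(R1 = 1, R2 = -2, R3 = 0, R4 = 0.5)
  b <- c(R1 = 5, R2 = -0.1, R3 = 1, R4 = -0.5)
  sa <- structure(list(fluxes = a, status = "optimal", method = "fba",
                       objective_value = 1), class = "flux_solution")
  sb <- structure(list(fluxes = b, status = "optimal", method = "fba",
                       objective_value = 1), class = "flux_solution")
  ch <- compare_conditions(sa, sb, threshold = 1e9)
  expect_setequal(ch$class[ch$reaction_id %in% c("R1", "R2")],
                  "unchanged")
  expect_identical(ch$class[ch$reaction_id == "R3"], "de-novo")
  expect_identical(ch$class[ch$reaction_id == "R4"], "inverted")
})

test_that("collapsing maps the six classes onto the three-group scheme", {
  six <- c("induced", "suppressed", "unchanged", "inverted", "de-novo",
           "abolished")
  expect_identical(collapse_classes(six),
                   c("induced", "suppressed", "unchanged", "induced",
                     "induced", "suppressed"))
})

test_that("pathway summaries partition the change set", {
  sol <- pfba(chain_model())
  sol2 <- sol; sol2$fluxes <- sol$fluxes * 2
  ch <- compare_conditions(sol, sol2)
  # empty change set
  empty <- summarize_by_pathway(ch[0, ], data.frame(
    reaction_id = character(), pathway = character()))
  expect_identical(nrow(empty), 0L)
  # all reactions in one pathway: one row, counts sum to the member count
  map1 <- data.frame(reaction_id = ch$reaction_id, pathway = "glycolysis")
  s1 <- summarize_by_pathway(ch, map1)
  expect_identical(nrow(s1), 1L)
  expect_equal(sum(unlist(s1[, c("induced", "suppressed", "unchanged",
                                 "inverted", "de-novo", "abolished")])),
               nrow(ch))
  # unmapped reactions fall into "other"
  map2 <- map1[1, , drop = FALSE]
  s2 <- summarize_by_pathway(ch, map2)
  expect_setequal(s2$pathway, c("glycolysis", "other"))
  expect_equal(sum(s2$n_reactions), nrow(ch))
})
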