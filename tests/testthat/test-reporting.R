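test_that("unknown configuration keys are rejected", {
  expect_error(run_config(list(thresold = 0.3)), "thresold")
  cfg <- run_config(list(threshold = 0.5))
  expect_equal(cfg$threshold, 0.5)
  expect_equal(cfg$strategy, "lad-then-pfba")
})

test_that("configurations round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(threshold = 0.35, backend = "simplex",
                        window_hours = 3), f)
  cfg <- run_config(f)
  expect_equal(cfg$threshold, 0.35)
  expect_equal(cfg$window_hours, 3)
})

test_that("the estimate stage recovers generator truth and is repeatable", {
  out <- tempfile()
  cfg <- run_config(list(output_dir = out))
  cond <- toy_conds()$neutral_2gl
  truth <- condition_truth(cond)
  prof_file <- tempfile(fileext = ".tsv")
  write_profile(generate_profile(mu = truth$mu, q = truth$q,
                                 times = 0:12), prof_file)
  cons <- run_estimate(cfg, prof_file, name = "neutral")
  expect_equal(cons$growth_rate, truth$mu, tolerance = 1e-6)
  got <- signed_rates(cons)
  expect_equal(got[names(truth$q)], truth$q, tolerance = 1e-6)
  js <- file.path(out, "neutral_constraints.json")
  expect_true(file.exists(js))
  expect_true(file.exists(file.path(out, "neutral_estimate.log")))

  # noisy profile with a fixed seed: bitwise identical outputs on rerun
  noisy_file <- tempfile(fileext = ".tsv")
  write_profile(generate_profile(mu = truth$mu, q = truth$q, times = 0:12,
                                 noise_cv = 0.02, seed = 7), noisy_file)
  run_estimate(cfg, noisy_file, name = "noisy")
  first <- readLines(file.path(out, "noisy_constraints.json"))
  run_estimate(cfg, noisy_file, name = "noisy")
  expect_identical(readLines(file.path(out, "noisy_constraints.json")),
                   first)
})

test_that("estimate-stage failures carry the stage context", {
  cfg <- run_config(list(output_dir = tempfile()))
  expect_error(run_estimate(cfg, "/no/such/profile.tsv"),
               "estimate stage")
  short <- tempfile(fileext = ".tsv")
  write_profile(fermentation_profile(c(0, 1), c(0.1, 0.12),
                                     data.frame(glucose = c(5, 5))),
                short)
  expect_error(run_estimate(cfg, short), "window|samples")
})

test_that("the simulate stage writes the worked-example solution", {
  out <- tempfile()
  cfg <- run_config(list(output_dir = out))
  sol <- run_simulate(cfg, "acidic_2gl")
  expect_equal(sol$objective_value, 0.140696, tolerance = 1e-6)
  expect_equal(sol$fluxes[["EX_gaba_e"]], 0.177, tolerance = 1e-6)
  expect_equal(sol$fluxes[["AKGDH"]], 0)
  expect_equal(sol$fluxes[["ABTA"]], 0)
  expect_true(file.exists(file.path(out, "fluxes_acidic_2gl.tsv")))
  expect_true(file.exists(file.path(out, "fluxes_acidic_2gl.json")))
  log <- readLines(file.path(out, "simulate_acidic_2gl.log"))
  expect_true(any(grepl("backend", log)))
  expect_true(any(grepl("LAD residual", log)))
  expect_error(run_simulate(cfg, "no_such_condition"), "not in the rate")
  bad <- run_config(list(model = "/no/such/model.json"))
  expect_error(run_simulate(bad, "acidic_2gl"), "/no/such/model.json")
})

test_that("the compare stage reports changes and pathway groups", {
  out <- tempfile()
  cfg <- run_config(list(output_dir = out))
  a <- run_simulate(cfg, "neutral_2gl")
  b <- run_simulate(cfg, "acidic_2gl")
  ch <- run_compare(cfg, a, b, name = "ph")
  expect_true(file.exists(file.path(out, "ph_changes.tsv")))
  expect_true(file.exists(file.path(out, "ph_pathways.json")))
  expect_identical(ch$class[ch$reaction_id == "GLUDC"], "induced")
  # identical inputs: everything unchanged
  same <- run_compare(cfg, a, a, name = "self")
  expect_true(all(same$class == "unchanged"))
  # mismatched reaction sets are rejected with the symmetric difference
  a2 <- a; a2$fluxes <- a$fluxes[-1]
  expect_error(run_compare(cfg, a2, b), names(a$fluxes)[1])
})

test_that("the replay convenience runs all conditions and both pairs", {
  out <- tempfile()
  res <- run_replay(run_config(list(output_dir = out)))
  expect_setequal(names(res$solutions),
                  c("neutral_2gl", "acidic_2gl", "acidic_4gl"))
  expect_setequal(names(res$comparisons), c("ph_shift", "succinate_dose"))
  expect_true(file.exists(file.path(out, "ph_shift_pathways.json")))
  expect_true(file.exists(file.path(out, "succinate_dose_changes.tsv")))
})
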