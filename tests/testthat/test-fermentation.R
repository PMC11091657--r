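test_that("growth rate is recovered exactly from noiseless exponentials", {
  mu <- 0.221086
  p <- generate_profile(mu = mu, q = c(glucose = -1.8), times = 0:12)
  w <- select_log_phase(p, 4)
  expect_equal(estimate_growth_rate(p, w), mu, tolerance = 1e-9)
  # constant OD means zero growth
  flat <- fermentation_profile(0:10, rep(2, 11),
                               data.frame(glucose = rep(5, 11)))
  expect_equal(estimate_growth_rate(flat, c(0, 10)), 0, tolerance = 1e-12)
})

test_that("a constant-slope profile ties to the earliest window", {
  p <- generate_profile(mu = 0.2, q = c(glucose = -1), times = 0:24)
  expect_equal(select_log_phase(p, 4), c(0, 4))
})

test_that("window selection matches an exhaustive scan on a logistic curve", {
  t <- seq(0, 24, by = 0.5)
  od <- 8 / (1 + exp(-0.45 * (t - 10)))   # logistic, inflection at 10 h
  p <- fermentation_profile(t, od, data.frame(glucose = rep(1, length(t))))
  got <- select_log_phase(p, 5)
  # brute-force oracle over every candidate start
  slopes <- vapply(t[t + 5 <= max(t)], function(t0) {
    idx <- which(t >= t0 & t <= t0 + 5)
    stats::coef(stats::lm(log(od[idx]) ~ t[idx]))[[2]]
  }, numeric(1))
  best <- t[t + 5 <= max(t)][which.max(slopes)]
  expect_equal(got, c(best, best + 5))
})

test_that("a profile shaped like the acidic run selects the 5-9 h window", {
  # lag until 5 h, exponential growth at the acidic-condition rate from
  # 5 to 9 h, then a plateau approaching stationary phase
  t <- 0:24
  # step increments: the rate at index i governs the interval ending at t_i
  mu_seg <- ifelse(t <= 5, 0.03, ifelse(t <= 9, 0.140696, 0.015))
  od <- 0.2 * exp(cumsum(c(0, diff(t)) * mu_seg))
  p <- fermentation_profile(t, od, data.frame(glucose = rep(1, 25)))
  expect_equal(select_log_phase(p, 4), c(5, 9))
  expect_equal(estimate_growth_rate(p, c(5, 9)), 0.140696,
               tolerance = 1e-6)
})

test_that("window selection guards its preconditions", {
  p <- generate_profile(mu = 0.2, q = c(glucose = -1), times = 0:3)
  expect_error(select_log_phase(p, 10), "window")
  sparse <- fermentation_profile(c(0, 6, 12), c(0.1, 0.4, 1.2),
                                 data.frame(glucose = c(5, 4, 3)))
  expect_error(select_log_phase(sparse, 4), "samples")
  expect_error(estimate_growth_rate(p, c(0, 50)), "range")
})

test_that("specific rates are recovered with sign from generator truth", {
  q <- c(glucose = -1.201905, gaba = 0.2756, acetic_acid = 0)
  p <- generate_profile(mu = 0.14, q = q, times = 0:12)
  est <- estimate_specific_rates(p, c(0, 12))
  expect_equal(est$q[["glucose"]], -1.201905, tolerance = 1e-6)
  expect_equal(est$q[["gaba"]], 0.2756, tolerance = 1e-6)
  expect_equal(est$q[["acetic_acid"]], 0, tolerance = 1e-9)
  expect_equal(est$mu, 0.14, tolerance = 1e-9)
  expect_true(all(est$r_squared > 0.999))
})

test_that("rates scale exactly with the unit parameters", {
  q <- c(glucose = -1.5)
  p <- generate_profile(mu = 0.2, q = q, times = 0:10)
  base <- estimate_specific_rates(p, c(0, 10))$q[["glucose"]]
  # doubling the OD-to-biomass factor halves the specific rate
  half <- estimate_specific_rates(p, c(0, 10),
                                  biomass_factor = 0.72)$q[["glucose"]]
  expect_equal(half, base / 2, tolerance = 1e-9)
  # doubling the molar mass halves the molar rate
  mm <- default_molar_masses(); mm[["glucose"]] <- 2 * mm[["glucose"]]
  halved <- estimate_specific_rates(p, c(0, 10),
                                    molar_masses = mm)$q[["glucose"]]
  expect_equal(halved, base / 2, tolerance = 1e-9)
  expect_error(estimate_specific_rates(p, c(0, 10),
                                       molar_masses = c(x = 1)),
               "glucose")
})

test_that("1 percent noise still recovers growth within a few percent", {
  mu <- 0.221086
  errs <- vapply(1:20, function(s) {
    p <- generate_profile(mu = mu, q = c(glucose = -1.8), times = 0:12,
                          noise_cv = 0.01, seed = s)
    w <- select_log_phase(p, 4)
    abs(estimate_growth_rate(p, w) - mu) / mu
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("signed rates split into magnitude plus direction", {
  est <- structure(list(mu = 0.2,
                        q = c(glucose = -1.8, gaba = 0.3, acetic_acid = 0),
                        window = c(0, 8),
                        r_squared = c(glucose = 1, gaba = 1,
                                      acetic_acid = 1),
                        label = "x"), class = "rate_estimate")
  cons <- to_condition_constraints(est, exchange_map = toy_map())
  expect_identical(cons$provenance, "estimated")
  expect_equal(cons$growth_rate, 0.2)
  r <- cons$rates
  expect_identical(r$direction[r$species == "glucose"], "uptake")
  expect_equal(r$magnitude[r$species == "glucose"], 1.8)
  expect_identical(r$direction[r$species == "gaba"], "secretion")
  # zero rates take the physiological direction from the mapping
  expect_identical(r$direction[r$species == "acetic_acid"], "secretion")
  # all-zero input gives all-zero constraints
  est0 <- est; est0$q[] <- 0; est0$mu <- 0
  expect_true(all(to_condition_constraints(est0)$rates$magnitude == 0))
})

test_that("the bundled rate table transcribes into constraints verbatim", {
  conds <- toy_conds()
  neutral <- conds$neutral_2gl
  expect_equal(neutral$growth_rate, 0.221086)
  sr <- signed_rates(neutral)
  expect_equal(sr[["glucose"]], -1.806954)
  expect_equal(sr[["succinic_acid"]], -0.086198)
  expect_equal(sr[["gaba"]], 0.008443)
  expect_equal(sr[["glutamate"]], 1.021887)
  expect_equal(sr[["acetic_acid"]], 0.306986)
  expect_identical(neutral$provenance, "measured-table")
})

test_that("profiles round-trip through the delimited text format", {
  p <- generate_profile(mu = 0.18, q = c(glucose = -1.2, gaba = 0.1),
                        times = 0:8, noise_cv = 0.02, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_profile(p, f)
  back <- read_profile(f)
  expect_equal(back$times, p$times)
  expect_equal(back$od600, p$od600, tolerance = 1e-12)
  expect_equal(back$concentrations, p$concentrations, tolerance = 1e-12)
})
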