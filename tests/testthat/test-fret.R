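test_that("burst generator draws the configured mixture", {
  # pure leg-placed population: sample mean near E_LP (away from the
  # truncation boundary so the truncated mean is essentially E_LP)
  m <- population_model(E_LP = 0.3, E_Trap = 0.8, f_LP = 1)
  b <- generate_bursts(m, 2000, seed = 4)
  expect_true(all(b$efficiencies >= 0 & b$efficiencies <= 1))
  expect_lt(abs(mean(b$efficiencies) - 0.3), 3 * 0.1 / sqrt(2000))
  # mixture assignment fraction within the binomial bound
  m2 <- population_model(f_LP = 0.7)
  b2 <- generate_bursts(m2, 5000, seed = 5)
  expect_lt(abs(b2$n_lp_true / 5000 - 0.7), 3 * sqrt(0.21 / 5000))
  # degenerate model warns about unidentifiability
  expect_warning(
    generate_bursts(population_model(E_LP = 0.5, E_Trap = 0.5), 100, seed = 1),
    "unidentifiable"
  )
})

test_that("burst sets are deterministic and export byte-for-byte", {
  m <- population_model(f_LP = 0.4)
  b1 <- generate_bursts(m, 500, seed = 77, d_nm = 15, F1_M = 1e-8)
  b2 <- generate_bursts(m, 500, seed = 77, d_nm = 15, F1_M = 1e-8)
  expect_identical(b1$efficiencies, b2$efficiencies)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_bursts(b1, f1); write_bursts(b2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip through CSV
  back <- read_bursts(f1)[[1]]
  expect_equal(back$efficiencies, b1$efficiencies, tolerance = 1e-12)
  expect_equal(unname(back$condition), c(15, 1e-8))
  unlink(c(f1, f2))
})

test_that("mixture estimator recovers the leg-placed fraction", {
  m <- population_model(f_LP = 0.7)   # 6 sd separation
  b <- generate_bursts(m, 5000, seed = 99)
  fit <- estimate_fractions(b, population_model(), n_boot = 200)
  expect_true(fit$converged)
  expect_gt(fit$f_LP_hat, 0.68)
  expect_lt(fit$f_LP_hat, 0.72)
  expect_true(fit$ci_low <= 0.7 && 0.7 <= fit$ci_high)
  expect_true(fit$ci_low <= fit$f_LP_hat && fit$f_LP_hat <= fit$ci_high)
  # all leg-placed input
  b1 <- generate_bursts(population_model(f_LP = 1), 1000, seed = 3)
  expect_gte(estimate_fractions(b1, population_model(), n_boot = 0)$f_LP_hat,
             0.99)
  # guards
  expect_error(
    estimate_fractions(generate_bursts(m, 40, seed = 1), population_model()),
    "at least 50"
  )
  expect_error(
    suppressWarnings(estimate_fractions(
      b, population_model(E_LP = 0.5, E_Trap = 0.5))),
    "unidentifiable"
  )
})

test_that("component labelling follows proximity to the leg-placed mean", {
  b <- generate_bursts(population_model(f_LP = 0.7), 5000, seed = 99)
  f_fwd <- estimate_fractions(b, population_model(E_LP = 0.2, E_Trap = 0.8),
                              n_boot = 0)$f_LP_hat
  # swapping which state is called leg-placed returns the complement
  f_swp <- estimate_fractions(b, population_model(E_LP = 0.8, E_Trap = 0.2),
                              n_boot = 0)$f_LP_hat
  expect_equal(f_fwd + f_swp, 1, tolerance = 1e-6)
  # free-means fits are robust to the initial guesses
  fa <- estimate_fractions(b, population_model(E_LP = 0.35, E_Trap = 0.65),
                           fix_means = FALSE, n_boot = 0)$f_LP_hat
  fb <- estimate_fractions(b, population_model(E_LP = 0.05, E_Trap = 0.95),
                           fix_means = FALSE, n_boot = 0)$f_LP_hat
  expect_equal(fa, fb, tolerance = 1e-3)
  expect_equal(fa, f_fwd, tolerance = 0.02)
})

test_that("estimator is nearly unbiased with well-separated populations", {
  # 50 replicates at n = 5000, 6 sd separation: |mean error| < 0.02
  errs <- vapply(1:50, function(i) {
    b <- generate_bursts(population_model(f_LP = 0.6), 5000, seed = 1000 + i)
    estimate_fractions(b, population_model(), n_boot = 0)$f_LP_hat - 0.6
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("bootstrap intervals achieve reasonable coverage", {
  # loose bound (>= 85% at nominal 95%) over 50 replicates
  hits <- vapply(1:50, function(i) {
    b <- generate_bursts(population_model(f_LP = 0.45), 2000, seed = 3000 + i)
    fit <- estimate_fractions(b, population_model(), n_boot = 100)
    fit$ci_low <= 0.45 && 0.45 <= fit$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("synthetic experiments follow the kinetic competition", {
  ks <- c(`10` = 4, `20` = 2, `30` = 0.02)
  sim <- synthesize_experiment(ks, k_FB = 2.3e5, F1_list = c(0, 1e-5),
                               model = population_model(), n_bursts = 200,
                               seed = 8)
  expect_length(sim$bursts, 6)
  # no fuel: the true table records complete leg placement
  tr <- sim$truth
  expect_true(all(tr$yield[tr$fuel_conc_M == 0] == 1))
  expect_equal(tr$yield[tr$fuel_conc_M == 1e-5 & tr$step_size_nm == 10],
               yield_from_rates(4, 2.3e5, 1e-5))
  # determinism across calls
  sim2 <- synthesize_experiment(ks, 2.3e5, c(0, 1e-5), population_model(),
                                200, seed = 8)
  expect_identical(sim$bursts[[1]]$efficiencies,
                   sim2$bursts[[1]]$efficiencies)
})

test_that("more bursts means better yield estimates", {
  ks <- stats::setNames(10^seq(-1, 1, length.out = 10),
                        round(seq(5, 32, length.out = 10), 1))
  err_for <- function(n_bursts) {
    sim <- synthesize_experiment(ks, 2.3e5, c(1e-6, 1e-5),
                                 population_model(), n_bursts, seed = 55)
    vapply(seq_along(sim$bursts), function(i) {
      fit <- estimate_fractions(sim$bursts[[i]], population_model(),
                                n_boot = 0)
      abs(fit$f_LP_hat - sim$truth$yield[i])
    }, numeric(1))
  }
  e_small <- err_for(500)
  e_big <- err_for(2000)
  expect_lt(median(e_big), median(e_small))
})
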