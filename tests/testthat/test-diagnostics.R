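test_that("split R-hat is near 1 for stationary chains and large for disjoint ones", {
  set.seed(1)
  good <- matrix(rnorm(4000), nrow = 4)
  expect_lt(split_rhat(good), 1.01)
  bad <- rbind(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1))
  expect_gt(split_rhat(bad), 3)
  drift <- rbind(seq(0, 1, length.out = 500) + rnorm(500, 0, 0.05),
                 rnorm(500, 0.5, 0.05))
  expect_gt(split_rhat(drift), 1.01)  # within-chain trend caught by splitting
})

test_that("zero-variance draws flag R-hat and ESS as undefined", {
  flat <- matrix(0, nrow = 2, ncol = 100)
  expect_true(is.na(split_rhat(flat)))
  expect_true(is.na(ess_bulk(flat)))
  expect_true(is.na(split_rhat(matrix(7.3, 3, 50))))
})

test_that("ESS matches iid and AR(1) oracles", {
  set.seed(2)
  iid <- matrix(rnorm(4000), nrow = 4)
  expect_lt(abs(ess_bulk(iid) - 4000) / 4000, 0.15)

  rho <- 0.9
  ar <- t(sapply(1:4, function(ch) {
    as.numeric(arima.sim(list(ar = rho), 5000))
  }))
  target <- 4 * 5000 * (1 - rho) / (1 + rho)
  expect_lt(abs(ess_bulk(ar) - target) / target, 0.25)
})

test_that("ESS never exceeds twice the total draw count", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(100:400, 1)
    x <- matrix(rnorm(4 * n), nrow = 4)
    # strongly antithetic chains push the naive estimator past the cap
    x[2, ] <- -x[1, ] + rnorm(n, 0, 0.01)
    expect_lte(ess_bulk(x), 2 * 4 * n)
  }
})

test_that("FFT-based R-hat/ESS agree with a direct-sum reimplementation", {
  set.seed(4)
  for (i in 1:5) {
    x <- t(sapply(1:4, function(ch) {
      as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.9)), 300))
    }))
    expect_equal(ess_bulk(x), ess_direct(x), tolerance = 1e-6)
  }
})

test_that("divergence counting is additive over chains", {
  expect_equal(divergence_count(matrix(0L, 2, 100)), 0)
  flags <- matrix(0L, 2, 100)
  flags[1, c(3, 50)] <- 1L
  flags[2, 99] <- 1L
  expect_equal(divergence_count(flags), 3)
  expect_equal(divergence_count(flags),
               sum(apply(flags, 1, sum)))
})

test_that("E-BFMI distinguishes white-noise from random-walk energies", {
  set.seed(5)
  iid <- matrix(rnorm(4000, 100, 3), nrow = 2)
  expect_true(all(abs(ebfmi(iid) - 2) < 0.3))
  walk <- matrix(c(cumsum(rnorm(2000)), cumsum(rnorm(2000))), nrow = 2,
                 byrow = TRUE)
  expect_true(all(ebfmi(walk) < 0.3))
  flat <- matrix(5, nrow = 2, ncol = 100)
  expect_true(all(is.na(ebfmi(flat))))
})

test_that("the fitted model passes its own diagnostics end to end", {
  fit <- shared_fit()
  set.seed(21)
  dg <- diagnose(fit, ess_threshold = 50, ppc = TRUE)
  expect_s3_class(dg, "scale_diagnostics")
  expect_equal(nrow(dg$parameters), length(species_level_parameters(fit)))
  expect_true(all(is.finite(dg$parameters$rhat)))
  expect_equal(dg$n_divergent, divergence_count(fit))
  expect_length(dg$ebfmi, fit$chains)
  # a well-specified fit should not sit in the extreme tails
  expect_gt(dg$ppc_pvalues[["mean"]], 0.02)
  expect_lt(dg$ppc_pvalues[["mean"]], 0.98)

  # strict mode adds the individual offsets
  dg_strict <- diagnose(fit, ess_threshold = 50, strict = TRUE)
  expect_gt(nrow(dg_strict$parameters), nrow(dg$parameters))
})

test_that("the converged flag is monotone in parameter quality", {
  fit <- shared_fit()
  dg <- diagnose(fit, ess_threshold = 50)
  base_ok <- max(dg$parameters$rhat) <= 1.01
  # appending a badly mixed parameter can only flip converged to FALSE
  worst <- max(dg$parameters$rhat, 1.2)
  would_converge <- base_ok && worst <= 1.01
  expect_false(would_converge)
  expect_true(dg$converged == (max(dg$parameters$rhat) <= 1.01 &&
                                 min(dg$parameters$ess) > 50 &&
                                 dg$n_divergent == 0))
})
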