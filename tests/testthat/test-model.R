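test_that("the compiled log posterior matches numerical differentiation", {
  sim <- simulate_scales(truth_preset("curema"), seed = 3, n_individuals = 6)
  d <- build_design(filter_readable(sim$data))
  X <- as.matrix(d[, design_columns()])
  y <- attr(d, "marks")
  si <- d$specimen_index
  rsf <- match(setdiff(design_columns(), "sex_M"), design_columns())
  nind <- max(si)
  dim <- 2 + 10 + 9 + nind * 10
  for (zip in c(FALSE, TRUE)) {
    set.seed(zip + 1)
    th <- rnorm(dim + zip) * 0.4
    r <- scalemarks:::model_logp_grad(X, y, si, nind, rsf, zip,
                                      10, 10, 5, 1, 1, th)
    expect_true(is.finite(r$logp))
    picks <- c(1, 2, 5, 13, 17, 21, 22, 22 + nind, length(th))
    num <- vapply(picks, function(k) {
      h <- 1e-6
      tp <- th; tm <- th
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (scalemarks:::model_logp_grad(X, y, si, nind, rsf, zip,
                                    10, 10, 5, 1, 1, tp)$logp -
       scalemarks:::model_logp_grad(X, y, si, nind, rsf, zip,
                                    10, 10, 5, 1, 1, tm)$logp) / (2 * h)
    }, numeric(1))
    expect_equal(num, r$grad[picks], tolerance = 1e-5)
  }
})

test_that("an intercept-only fit recovers the conjugate Gamma-Poisson posterior", {
  set.seed(5)
  n <- 400
  y <- rpois(n, 4)
  design <- tibble::tibble(specimen_index = rep(1:8, each = n / 8))
  fit <- fit_model(design, counts = y,
                   config = scale_model_config(chains = 2, tune = 400,
                                               draws = 400, seed = 6,
                                               max_retries = 0,
                                               ess_threshold = 100))
  lam_draws <- exp(as.vector(posterior_matrix(fit, "alpha")))
  # with weak priors and tiny sigma_alpha the posterior of exp(alpha) is
  # close to Gamma(sum(y), n)
  expect_lt(abs(mean(lam_draws) - mean(y)), 2 * sd(lam_draws))
  expect_equal(divergence_count(fit), 0)
})

test_that("fitting is deterministic for a fixed seed", {
  sim <- simulate_scales(truth_preset("curema"), seed = 4, n_individuals = 8)
  cfg <- scale_model_config(chains = 2, tune = 150, draws = 100, seed = 31,
                            max_retries = 0)
  d <- build_design(filter_readable(sim$data))
  f1 <- fit_model(d, config = cfg)
  f2 <- fit_model(d, config = cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$sampler$energy, f2$sampler$energy)
  f3 <- fit_model(d, config = scale_model_config(chains = 2, tune = 150,
                                                 draws = 100, seed = 32,
                                                 max_retries = 0))
  expect_false(identical(f1$theta, f3$theta))
})

test_that("derived individual intercepts satisfy the non-centred identity", {
  fit <- shared_fit()
  alpha <- posterior_matrix(fit, "alpha")
  sigma <- posterior_matrix(fit, "sigma_alpha")
  for (i in c(1, 7, fit$layout$n_ind)) {
    da <- posterior_matrix(fit, paste0("delta_alpha[", i, "]"))
    ai <- posterior_matrix(fit, paste0("alpha_i[", i, "]"))
    expect_equal(ai, alpha + da * sigma, tolerance = 1e-12)
  }
  k <- fit$layout$rsf[1]
  db <- posterior_matrix(fit, paste0("delta_beta[", k, ",3]"))
  bi <- posterior_matrix(fit, paste0("beta_i[", k, ",3]"))
  bk <- posterior_matrix(fit, paste0("beta[", k, "]"))
  sk <- posterior_matrix(fit, paste0("sigma_beta[", k, "]"))
  expect_equal(bi, bk + db * sk, tolerance = 1e-12)
})

test_that("with no data the sampler recovers the prior on alpha", {
  design <- tibble::tibble(specimen_index = integer(0))
  fit <- fit_model(design, config = scale_model_config(
    chains = 2, tune = 500, draws = 1000, seed = 41, max_retries = 0,
    ess_threshold = 100), n_individuals = 2)
  a <- as.vector(posterior_matrix(fit, "alpha"))
  # prior is Normal(0, 10); loose Monte-Carlo bands
  expect_lt(abs(mean(a)), 1.5)
  expect_gt(sd(a), 8)
  expect_lt(sd(a), 12)
  # half-Cauchy(5) prior on sigma_alpha: median should be near 5
  s <- as.vector(posterior_matrix(fit, "sigma_alpha"))
  expect_gt(median(s), 2.5)
  expect_lt(median(s), 10)
})

test_that("configuration errors are caught before sampling", {
  sim <- simulate_scales(truth_preset("curema"), seed = 4, n_individuals = 4)
  d <- build_design(filter_readable(sim$data))
  expect_error(fit_model(d, counts = c(1, 2, 3)), "length")
  expect_error(
    fit_model(d, config = scale_model_config(
      random_slope_factors = c("length_c", "sex_M"))),
    class = "scalemarks_config_error")
  expect_error(
    fit_model(d, config = scale_model_config(
      random_slope_factors = "not_a_column")),
    class = "scalemarks_config_error")
  bad <- d
  bad$specimen_index[1] <- 99L
  expect_error(fit_model(bad, counts = attr(d, "marks")), "dense")
})

test_that("the zero-inflated likelihood estimates pi on inflated data", {
  tr <- truth_preset("curema", pi = 0.25)
  sim <- simulate_scales(tr, seed = 51, n_individuals = 30)
  fit <- fit_scales(sim$data, likelihood = "zip", chains = 2, tune = 500,
                    draws = 500, seed = 52, max_retries = 0)
  pi_draws <- as.vector(posterior_matrix(fit, "pi"))
  h <- hdi(pi_draws)
  expect_true(h[["lower"]] <= 0.25 && 0.25 <= h[["upper"]])
  expect_lt(abs(mean(pi_draws) - 0.25), 0.08)
  expect_true("pi" %in% species_level_parameters(fit))
})
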