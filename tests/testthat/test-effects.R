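test_that("hdi handles point masses, ties, and symmetric samples", {
  x <- c(rep(0, 95), rep(100, 5))
  expect_equal(unname(hdi(x, 0.95)), c(0, 0))

  # 1..100: every window of 95 has the same width; the earliest wins
  expect_equal(unname(hdi(1:100, 0.95)), c(1, 95))

  set.seed(1)
  z <- rnorm(100000)
  h <- hdi(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.05)
  expect_lt(abs(h[["upper"]] - 1.96), 0.05)

  expect_error(hdi(1:100, 1.2), "prob")
  expect_error(hdi(1:3, 0.95), "few")
})

test_that("hdi contains exactly ceiling(prob * n) samples", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(50:1000, 1)
    prob <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), sample(1:10, n, replace = TRUE))
    h <- hdi(x, prob)
    inside <- sum(x >= h[["lower"]] & x <= h[["upper"]])
    expect_gte(inside, ceiling(prob * n))  # ties can only add members
    s <- sort(x)
    m <- ceiling(prob * n)
    i0 <- match(h[["lower"]], s)
    expect_equal(s[i0 + m - 1], h[["upper"]])
  }
})

test_that("hdi equals the brute-force window minimizer", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(20:1000, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rgamma(n, 2), sample(1:15, n, replace = TRUE))
    expect_equal(unname(hdi(x, 0.9)), hdi_bruteforce(x, 0.9))
    expect_equal(unname(hdi(x, 0.95)), hdi_bruteforce(x, 0.95))
  }
})

test_that("prob_direction counts strict sides and partitions correctly", {
  expect_equal(prob_direction(c(2, 3, 4)), 1)
  expect_equal(prob_direction(c(0.9, 0.9, 1.1, 1.1)), 0.5)
  expect_equal(prob_direction(c(0.9, 1.1, 1.1, 1.1)), 0.75)

  set.seed(4)
  x <- c(rnorm(500, 1, 0.3), rep(1, 37))
  above <- mean(x > 1); below <- mean(x < 1); at <- mean(x == 1)
  expect_equal(above + below + at, 1)
  expect_equal(prob_direction(x, 1), max(above, below))

  z <- rnorm(200000)
  expect_lt(abs(prob_direction(z, 0) - 0.5), 0.01)
})

test_that("effect summaries exponentiate and respect Jensen's inequality", {
  fit <- shared_fit()
  eff <- effect_summary(fit)
  expect_setequal(eff$factor, design_columns())
  expect_true(all(eff$hdi_low < eff$hdi_high))
  expect_true(all(eff$mean_effect > 0))
  expect_true(all(eff$prob_direction >= 0.5 - 1e-12))
  for (f in c("sex_M", "length_c", "V_V")) {
    log_draws <- as.vector(posterior_matrix(fit, paste0("beta[", f, "]")))
    row <- eff[eff$factor == f, ]
    expect_gt(row$mean_effect, exp(mean(log_draws)))  # strict for non-degenerate
    expect_equal(row$prob_direction,
                 prob_direction(exp(log_draws), 1))
    # exp is monotone: the HDI on the effect scale is the exp of a log-scale
    # sample window, so its endpoints are exp() of sample values
    expect_true(any(abs(exp(log_draws) - row$hdi_low) < 1e-12))
    expect_true(any(abs(exp(log_draws) - row$hdi_high) < 1e-12))
  }
})

test_that("the interaction surface has nine coherent cells", {
  fit <- shared_fit()
  surf <- interaction_surface(fit)
  expect_equal(nrow(surf), 9)
  expect_setequal(surf$area, scale_areas())
  expect_true(all(surf$hdi_low <= surf$mean_count + 1e-12))
  expect_true(all(surf$mean_count <= surf$hdi_high + 1e-12))
  # conditioning on males shifts every cell by the same factor at species
  # level, so the orderings agree
  surf_m <- interaction_surface(fit, sex = "M")
  expect_equal(order(surf$mean_count), order(surf_m$mean_count))
})

test_that("recovery reports flag truths outside the interval", {
  fit <- shared_fit()
  eff <- effect_summary(fit)
  rec <- recovery_report(shared_sim()$truth, eff)
  expect_equal(rec$table$covered,
               rec$table$hdi_low <= rec$table$truth &
                 rec$table$truth <= rec$table$hdi_high)
  expect_equal(rec$coverage_fraction, mean(rec$table$covered))

  forced <- eff
  forced$hdi_low <- 0.9
  forced$hdi_high <- 1.2
  tr10 <- shared_sim()$truth
  tr10$beta[] <- log(10)
  rec0 <- recovery_report(tr10, forced)
  expect_equal(rec0$coverage_fraction, 0)

  wrong <- eff
  wrong$factor[1] <- "bogus"
  expect_error(recovery_report(shared_sim()$truth, wrong), "match")
})

test_that("tidy and glance expose broom-style summaries", {
  fit <- shared_fit()
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, species_level_parameters(fit))
  expect_true(all(c("estimate", "std.error", "hdi_low", "hdi_high",
                    "rhat", "ess") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$nobs, nrow(fit$data$X))
  expect_equal(gl$divergences, divergence_count(fit))
})

test_that("autoplot returns ggplot objects for the result types", {
  fit <- shared_fit()
  expect_s3_class(autoplot(effect_summary(fit)), "ggplot")
  expect_s3_class(autoplot(interaction_surface(fit)), "ggplot")
  expect_s3_class(plot_energy(fit), "ggplot")
})
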