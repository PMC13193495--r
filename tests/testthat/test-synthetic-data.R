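test_that("species presets carry the published effect sizes", {
  cu <- truth_preset("curema")
  expect_equal(cu$beta[["sex_M"]], log(1.07))
  expect_equal(cu$beta[["length_c"]], log(1.06))
  expect_equal(cu$beta[["V_V"]], log(1.07))
  expect_equal(cu$alpha, log(3.37))
  expect_equal(exp(cu$beta[["HxV_AD"]]), 1.03)

  ce <- truth_preset("cephalus")
  expect_equal(exp(ce$beta[["sex_M"]]), 0.98)
  expect_equal(ce$alpha, log(5.75))
  # the injected interaction pattern: counts fall A->P along the middle
  # band and rise A->P along the dorsal and ventral bands
  cell <- function(h, v) {
    x <- scalemarks:::design_row("F", paste0(h, v), 0)
    sum(x * ce$beta)
  }
  expect_true(cell("A", "M") > cell("C", "M"))
  expect_true(cell("C", "M") > cell("P", "M"))
  expect_true(cell("A", "D") < cell("C", "D"))
  expect_true(cell("C", "D") < cell("P", "D"))
  expect_true(cell("A", "V") < cell("C", "V"))
  expect_true(cell("C", "V") < cell("P", "V"))

  expect_error(truth_preset("salmo"))
})

test_that("simulation is deterministic in the seed and structurally valid", {
  tr <- truth_preset("curema")
  a <- simulate_scales(tr, seed = 5, n_individuals = 8)
  b <- simulate_scales(tr, seed = 5, n_individuals = 8)
  expect_identical(a$data, b$data)
  expect_identical(a$individual_effects, b$individual_effects)
  c <- simulate_scales(tr, seed = 6, n_individuals = 8)
  expect_false(identical(a$data, c$data))

  # 9 areas x 3-4 scales each => 27..36 scales per specimen
  per_spec <- dplyr::count(a$data, specimen_id)
  expect_true(all(per_spec$n >= 27 & per_spec$n <= 36))
  expect_equal(sort(unique(a$data$area)), sort(scale_areas()))
  expect_setequal(a$individual_effects$specimen_id,
                  unique(a$data$specimen_id))
})

test_that("a null truth reproduces the plain Poisson mean", {
  cols <- design_columns()
  tr <- scale_truth(
    species = "curema", alpha = log(4), sigma_alpha = 0,
    beta = stats::setNames(numeric(10), cols),
    sigma_beta = stats::setNames(numeric(0), character(0)),
    pi = 0,
    status_probs = stats::setNames(rep(0, 9), scale_areas()),
    p_male = 0.5,
    length_model = list(
      localities = tibble::tibble(locality = "LM", weight = 1,
                                  sl_mean = 22, sl_sd = 1.5),
      slope = 0.35, intercept = 0, noise_sd = 0.5)
  )
  sim <- simulate_scales(tr, seed = 3, n_individuals = 320)  # ~10k scales
  marks <- sim$data$marks
  expect_gt(length(marks), 8000)
  se <- sd(marks) / sqrt(length(marks))
  expect_lt(abs(mean(marks) - 4), 3 * se)
})

test_that("full zero inflation forces every count to zero", {
  tr <- truth_preset("curema", pi = 1)
  sim <- simulate_scales(tr, seed = 4, n_individuals = 10)
  marks <- dplyr::filter(sim$data, status == "good")$marks
  expect_true(all(marks == 0))
})

test_that("zero-inflated counts match the (1 - pi) * lambda moment", {
  tr <- truth_preset("curema", pi = 0.2, sigma_alpha = 0, sigma_slope = 0)
  sim <- simulate_scales(tr, seed = 9, n_individuals = 250)
  good <- dplyr::filter(sim$data, status == "good")
  # average lambda over realized scales from the known truth
  centre <- sim$centre
  eff <- sim$individual_effects
  idx <- match(good$specimen_id, eff$specimen_id)
  eta <- vapply(seq_len(nrow(good)), function(j) {
    x <- scalemarks:::design_row(good$sex[j], good$area[j],
                                 good$scale_length[j] - centre)
    eff$alpha_i[idx[j]] + sum(x * unlist(eff[idx[j], names(x)]))
  }, numeric(1))
  expected <- (1 - tr$pi) * mean(exp(eta))
  se <- sd(good$marks) / sqrt(nrow(good))
  expect_lt(abs(mean(good$marks) - expected), 4 * se)
})

test_that("non-centred individual intercepts match direct normal draws", {
  tr <- truth_preset("curema")
  sim <- simulate_scales(tr, seed = 21, n_individuals = 5000)
  realized <- sim$individual_effects$alpha_i
  set.seed(99)
  direct <- rnorm(5000, tr$alpha, tr$sigma_alpha)
  ks <- suppressWarnings(stats::ks.test(realized, direct))
  expect_gt(ks$p.value, 0.01)
})

test_that("status frequencies converge to the configured probabilities", {
  tr <- truth_preset("curema")
  sim <- simulate_scales(tr, seed = 8, n_individuals = 400)
  freq <- dplyr::summarise(dplyr::group_by(sim$data, area),
                           n = dplyr::n(),
                           p_hat = mean(status != "good"))
  p_true <- tr$status_probs[freq$area]
  # 4-sigma binomial tolerance per area
  tol <- 4 * sqrt(p_true * (1 - p_true) / freq$n)
  expect_true(all(abs(freq$p_hat - p_true) < tol))
})

test_that("scale length correlates with standard length as configured", {
  ce <- simulate_scales(truth_preset("cephalus"), seed = 13,
                        n_individuals = 100)  # ~3000 scales
  expect_lt(abs(length_correlation(ce$data) - 0.83), 0.05)
  cu <- simulate_scales(truth_preset("curema"), seed = 13,
                        n_individuals = 100)
  expect_lt(abs(length_correlation(cu$data) - 0.6), 0.07)
})

test_that("truth YAML round trip is faithful", {
  tr <- truth_preset("cephalus", pi = 0.1)
  path <- withr::local_tempfile(fileext = ".yml")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$beta, tr$beta)
  expect_equal(back$sigma_beta, tr$sigma_beta)
  expect_equal(back$status_probs, tr$status_probs)
  expect_equal(back$length_model$noise_sd, tr$length_model$noise_sd)
  expect_identical(simulate_scales(back, seed = 2, n_individuals = 4)$data,
                   simulate_scales(tr, seed = 2, n_individuals = 4)$data)
})

test_that("mismatched beta names are a configuration error", {
  cols <- design_columns()
  bad_beta <- stats::setNames(numeric(10), c(cols[-1], "bogus"))
  expect_error(
    scale_truth(species = "curema", alpha = 1, sigma_alpha = 0.1,
                beta = bad_beta, sigma_beta = numeric(0),
                status_probs = stats::setNames(rep(0.1, 9), scale_areas()),
                length_model = list(
                  localities = tibble::tibble(locality = "LM", weight = 1,
                                              sl_mean = 22, sl_sd = 1.5),
                  slope = 0.35, noise_sd = 0.5)),
    class = "scalemarks_config_error")
})
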