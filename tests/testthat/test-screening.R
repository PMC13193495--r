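make_status_data <- function(spec) {
  # spec: tibble with area, locality, n_good, n_bad
  rows <- purrr::pmap(spec, function(area, locality, n_good, n_bad) {
    n <- n_good + n_bad
    tibble::tibble(
      specimen_id = paste0("s_", locality), species = "curema",
      locality = locality, sex = "F", standard_length_cm = 22,
      area = area, scale_length = 7, scale_width = NA_real_,
      scale_radius = NA_real_,
      status = rep(c("good", "damaged"), c(n_good, n_bad)),
      marks = c(rep(2L, n_good), rep(NA_integer_, n_bad)))
  })
  dplyr::bind_rows(rows)
}

test_that("status percentages are exact cell-wise ratios", {
  d <- make_status_data(tibble::tibble(
    area = c("AD", "CM"), locality = c("LM", "LM"),
    n_good = c(7L, 10L), n_bad = c(3L, 0L)))
  st <- status_table(d)
  ad <- st$cells[st$cells$area == "AD", ]
  expect_equal(ad$pct, 30)
  expect_equal(ad$pct_1dp, 30.0)
  expect_equal(st$cells$pct[st$cells$area == "CM"], 0)
})

test_that("an all-good dataset gives a zero table with zero spread", {
  sim <- simulate_scales(
    truth_preset("curema") |>
      (\(tr) { tr$status_probs[] <- 0; tr })(),
    seed = 2, n_individuals = 10)
  st <- status_table(sim$data)
  expect_true(all(st$cells$pct == 0))
  expect_true(all(st$summary$mean_pct == 0))
  expect_true(all(st$summary$sd_pct == 0))
})

test_that("locality summaries use the sample SD over area percentages", {
  d <- make_status_data(tibble::tibble(
    area = c("AD", "CM", "PV"), locality = "TA",
    n_good = c(9L, 8L, 7L), n_bad = c(1L, 2L, 3L)))
  st <- status_table(d)  # percentages 10, 20, 30
  expect_equal(sort(st$cells$pct), c(10, 20, 30))
  expect_equal(st$summary$mean_pct, 20)
  expect_equal(st$summary$sd_pct, 10)  # sd with n-1 denominator
  expect_equal(st$summary$n_areas, 3)
})

test_that("percentage cells agree with filter_readable bookkeeping", {
  sim <- simulate_scales(truth_preset("cephalus"), seed = 31,
                         n_individuals = 30)
  st <- status_table(sim$data)
  kept <- filter_readable(sim$data)
  expect_equal(sum(st$cells$n_scales), nrow(sim$data))
  expect_equal(sum(st$cells$n_unreadable), nrow(sim$data) - nrow(kept))
  recomputed <- 100 * st$cells$n_unreadable / st$cells$n_scales
  expect_equal(st$cells$pct, recomputed)
})

test_that("half-up presentation rounding differs from banker's rounding", {
  expect_equal(scalemarks:::round_half_up(0.25, 1), 0.3)
  expect_equal(scalemarks:::round_half_up(-0.25, 1), -0.3)
  expect_equal(scalemarks:::round_half_up(12.34, 1), 12.3)
})

test_that("Kruskal-Wallis H matches hand-computed values", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # N=6, R1=6, R2=15: H = 12/42 * (12 + 75) - 21 = 27/7
  expect_equal(r$H, 27 / 7, tolerance = 1e-12)
  expect_equal(round(r$H, 3), 3.857)
  expect_equal(r$df, 1)
  expect_equal(r$tie_correction, 1)

  sym <- kruskal_wallis(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(sym$H, 0, tolerance = 1e-12)

  singletons <- kruskal_wallis(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(singletons$H, 2, tolerance = 1e-12)
  expect_equal(singletons$df, 2)
})

test_that("H is invariant under strictly increasing transforms", {
  set.seed(42)
  x <- sample(1:8, 20, replace = TRUE)  # plenty of ties
  g <- sample(c("u", "v", "w"), 20, replace = TRUE)
  expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(x^3, g)$H,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(exp(x / 2), g)$H,
               tolerance = 1e-12)
})

test_that("H and p agree with brute force and stats::kruskal.test on small inputs", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(2:3, 1)
    vals <- sample(1:5, n, replace = TRUE)          # heavy tie patterns
    grp <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    if (length(unique(vals)) == 1) next
    r <- kruskal_wallis(vals, grp)
    expect_equal(r$H, kw_bruteforce(vals, grp), tolerance = 1e-12)
    ref <- stats::kruskal.test(vals, factor(grp))
    expect_equal(r$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(r$df, unname(ref$parameter))
  }
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(kruskal_wallis(c(3, 3, 3, 3), c("a", "a", "b", "b")),
               class = "scalemarks_degenerate_error")
  expect_error(kruskal_wallis(1:4, rep("a", 4)),
               class = "scalemarks_degenerate_error")
})

test_that("locality screen defaults to per-individual means", {
  sim <- simulate_scales(truth_preset("curema"), seed = 17,
                         n_individuals = 40)
  r_ind <- kw_locality_screen(sim$data)
  per_ind <- dplyr::summarise(
    dplyr::group_by(filter_readable(sim$data), specimen_id, locality),
    m = mean(marks), .groups = "drop")
  expect_equal(r_ind$n, nrow(per_ind))
  r_scale <- kw_locality_screen(sim$data, per_scale = TRUE)
  expect_equal(r_scale$n, nrow(filter_readable(sim$data)))
  expect_true(r_ind$p_value >= 0 && r_ind$p_value <= 1)
})

test_that("length correlation handles exact, null, and degenerate cases", {
  tab <- tiny_scale_table()
  tab$scale_length <- 2 * tab$standard_length_cm
  expect_equal(length_correlation(tab), 1.0)

  set.seed(3)
  n <- 10000
  big <- tibble::tibble(
    specimen_id = paste0("s", seq_len(n)), species = "curema",
    locality = "LM", sex = "F",
    standard_length_cm = runif(n, 18, 30), area = "CM",
    scale_length = runif(n, 5, 9), scale_width = NA_real_,
    scale_radius = NA_real_, status = "good", marks = 2L)
  expect_lt(abs(length_correlation(big)), 0.05)

  flat <- tab
  flat$scale_length <- 7
  expect_error(length_correlation(flat),
               class = "scalemarks_degenerate_error")
})
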