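# Shared fixtures and independent oracles, built in code.

# A small valid scale table constructed by hand.
tiny_scale_table <- function() {
  tibble::tibble(
    specimen_id = rep(c("cur_1", "cur_2"), each = 3),
    species = "curema",
    locality = rep(c("LM", "TA"), each = 3),
    sex = rep(c("F", "M"), each = 3),
    standard_length_cm = rep(c(22.1, 23.4), each = 3),
    area = c("AD", "CM", "PV", "AD", "CM", "PV"),
    scale_length = c(7.1, 7.4, 7.2, 8.0, 7.9, 8.1),
    scale_width = NA_real_,
    scale_radius = NA_real_,
    status = c("good", "good", "damaged", "good", "regenerated", "good"),
    marks = c(3L, 2L, NA, 4L, NA, 0L)
  )
}

# One moderately sized fit shared across test files (computed lazily once).
.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_scales(truth_preset("curema"), seed = 11,
                                        n_individuals = 25)
  }
  .fixture_env$sim
}

shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- fit_scales(shared_sim()$data, chains = 2, tune = 400,
                                   draws = 400, seed = 12, max_retries = 0)
  }
  .fixture_env$fit
}

# --- independent oracles -------------------------------------------------

# Kruskal-Wallis H from an explicit rank table (no shared code with the
# package's midrank formula beyond base rank()).
kw_bruteforce <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  H0 <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tapply(r, groups, length)) - 3 * (n + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H0 / C
}

# HDI by exhaustive scan over every contiguous sorted window.
hdi_bruteforce <- function(samples, prob = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# Direct O(n^2) autocovariance (biased, 1/n), for checking the FFT path.
acov_direct <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  vapply(0:(n - 1), function(lag) {
    sum(x[seq_len(n - lag)] * x[(1 + lag):n]) / n
  }, numeric(1))
}

# ESS recomputed with direct-sum autocovariances and explicit Geyer pairing;
# mirrors the definition, shares no code with the package's FFT version.
ess_direct <- function(chains) {
  half <- ncol(chains) %/% 2
  x <- rbind(chains[, seq_len(half), drop = FALSE],
             chains[, (ncol(chains) - half + 1):ncol(chains), drop = FALSE])
  m <- nrow(x); n <- ncol(x)
  w <- mean(apply(x, 1, var))
  var_plus <- (n - 1) / n * w + var(rowMeans(x))
  mean_acov <- colMeans(t(apply(x, 1, acov_direct)))
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1
  tau <- -1; prev <- Inf
  for (k in 0:(floor(n / 2) - 1)) {
    p <- rho[2 * k + 1] + if (2 * k + 2 <= n) rho[2 * k + 2] else 0
    if (k > 0 && p < 0) break
    p <- min(max(p, 0), prev); prev <- p
    tau <- tau + 2 * p
  }
  tau <- max(tau, 1 / log10(m * n + 10))
  min(m * n / tau, 2 * m * n)
}
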