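# MCMC convergence and goodness-of-fit diagnostics.
#
# Conventions follow the modern Hamiltonian-MC workflow: split R-hat
# (half-chains, stricter than the classic Gelman-Rubin factor), bulk ESS
# from combined-chain autocorrelations with Geyer's initial-monotone
# truncation, divergence counts, per-chain E-BFMI, and posterior-predictive
# Bayesian p-values.

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor
#' `sqrt((N - 1)/N + B/(N * W))` computed over the half-chains, where `W`
#' is the mean within-chain variance and `B` the between-chain variance of
#' the half-chain means (times N). Values near 1 indicate the chains
#' explore the same distribution; the conventional threshold is 1.01.
#'
#' @param chains Numeric matrix of draws, `chains x draws`, with at least
#'   2 chains of at least 4 draws.
#' @return The R-hat value, or `NA` when the draws have (numerically) zero
#'   variance, for which the ratio is undefined.
#' @export
split_rhat <- function(chains) {
  x <- split_chains(chains)
  n <- ncol(x)
  if (!all(is.finite(x))) return(NA_real_)
  chain_vars <- apply(x, 1, var)
  chain_means <- rowMeans(x)
  w <- mean(chain_vars)
  if (w == 0 || !is.finite(w) ||
      mean(abs(x - mean(x))) < 1e-10 * (1 + abs(mean(x)))) {
    return(NA_real_)
  }
  b <- n * var(chain_means)
  sqrt((n - 1) / n + b / (n * w))
}

split_chains <- function(chains) {
  if (!is.matrix(chains)) chains <- matrix(chains, nrow = 1)
  if (nrow(chains) < 2) abort("Need at least 2 chains.")
  n <- ncol(chains)
  if (n < 4) abort("Need at least 4 draws per chain.")
  half <- n %/% 2
  rbind(chains[, seq_len(half), drop = FALSE],
        chains[, (n - half + 1):n, drop = FALSE])
}

# Biased (1/N) autocovariance of one vector via FFT.
autocovariance_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  acov <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / m
  acov / n
}

#' Bulk effective sample size
#'
#' Autocorrelation-based ESS over split half-chains: per-lag
#' autocorrelations are combined across chains through the multi-chain
#' variance estimate, summed in Geyer pairs with initial-positive and
#' initial-monotone truncation, and the total
#' `ESS = (chains * draws) / (-1 + 2 * sum(pairs))` returned, capped at
#' twice the total draw count (the estimator's practical ceiling for
#' antithetic chains).
#'
#' @inheritParams split_rhat
#' @return Total effective sample size across chains, or `NA` for
#'   zero-variance input.
#' @export
ess_bulk <- function(chains) {
  x <- split_chains(chains)
  m <- nrow(x); n <- ncol(x)
  if (!all(is.finite(x))) return(NA_real_)
  chain_vars <- apply(x, 1, var)
  w <- mean(chain_vars)
  if (w == 0 || mean(abs(x - mean(x))) < 1e-10 * (1 + abs(mean(x)))) {
    return(NA_real_)
  }
  b_over_n <- var(rowMeans(x))
  var_plus <- (n - 1) / n * w + b_over_n
  acov <- t(apply(x, 1, autocovariance_fft))  # m x n, lag 0 .. n-1
  mean_acov <- colMeans(acov)
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1

  # Geyer paired sums with initial-positive / initial-monotone truncation
  max_pairs <- floor(n / 2) - 1
  tau <- -1
  prev_pair <- Inf
  for (k in 0:max_pairs) {
    p <- rho[2 * k + 1] + if (2 * k + 2 <= n) rho[2 * k + 2] else 0
    if (k > 0 && p < 0) break
    p <- max(p, 0)
    p <- min(p, prev_pair)
    prev_pair <- p
    tau <- tau + 2 * p
  }
  tau <- max(tau, 1 / log10(m * n + 10))
  min(m * n / tau, 2 * m * n)
}

#' Count divergent transitions
#'
#' Total post-warmup divergences across chains. A divergence signals a
#' trajectory whose Hamiltonian error exploded, i.e. posterior regions the
#' sampler cannot traverse; any nonzero count makes estimates suspect.
#'
#' @param x A `scale_fit`, or a matrix/vector of 0/1 divergence flags.
#' @return Non-negative integer count.
#' @export
divergence_count <- function(x) {
  flags <- if (inherits(x, "scale_fit")) x$sampler$divergent else x
  sum(as.integer(flags))
}

#' Energy-based Bayesian fraction of missing information
#'
#' Per chain, `E-BFMI = mean(diff(E)^2) / var(E)`: the ratio of the energy
#' transition variance to the marginal energy variance. Values well below
#' 1 (conventionally < 0.3) indicate momentum resampling cannot explore
#' the energy distribution. For independent Gaussian energies the ratio is
#' about 2.
#'
#' @param energy A `scale_fit`, or a `chains x draws` matrix of
#'   Hamiltonian energies.
#' @return Numeric vector of per-chain E-BFMI values (`NA` where the
#'   energy is constant).
#' @export
ebfmi <- function(energy) {
  e <- if (inherits(energy, "scale_fit")) energy$sampler$energy else energy
  if (!is.matrix(e)) e <- matrix(e, nrow = 1)
  if (ncol(e) < 2) abort("Need at least 2 draws per chain.")
  apply(e, 1, function(ch) {
    v <- var(ch)
    if (!is.finite(v) || v == 0) return(NA_real_)
    mean(diff(ch)^2) / v
  })
}

#' Posterior-predictive Bayesian p-value
#'
#' For each retained posterior draw, a replicate dataset is simulated from
#' the likelihood at that draw's parameters (individual effects included)
#' and a test statistic compared with its observed value:
#' `p = P(T(rep) >= T(obs))`. `statistic = "mean"` uses the sample mean of
#' the counts; `"dispersion"` the variance/mean ratio, which detects
#' overdispersion a Poisson model cannot absorb. Calibrated fits give p
#' close to 0.5; values near 0 or 1 flag misfit (both tails matter, so
#' `1 - p` is equally informative).
#'
#' @param fit A `scale_fit`.
#' @param statistic `"mean"` or `"dispersion"`.
#' @param draw_chunk Internal chunk size over draws.
#' @return The p-value.
#' @export
ppc_pvalue <- function(fit, statistic = c("mean", "dispersion"),
                       draw_chunk = 500) {
  stopifnot(inherits(fit, "scale_fit"))
  statistic <- match.arg(statistic)
  y <- fit$data$counts
  stat_fun <- switch(statistic,
                     mean = mean,
                     dispersion = function(v) var(v) / mean(v))
  t_obs <- stat_fun(y)
  n <- length(y)
  S <- fit$chains * fit$draws
  zip <- fit$layout$zip
  exceed <- 0L
  for (start in seq(1, S, by = draw_chunk)) {
    idx <- start:min(start + draw_chunk - 1, S)
    lam <- lambda_draws(fit, idx)
    if (zip) {
      pis <- as.vector(posterior_matrix(fit, "pi"))[idx]
    }
    for (j in seq_along(idx)) {
      rep_y <- rpois(n, lam[, j])
      if (zip) rep_y[runif(n) < pis[j]] <- 0L
      exceed <- exceed + (stat_fun(rep_y) >= t_obs)
    }
  }
  exceed / S
}

#' Convergence diagnostics report for a fit
#'
#' Applies the convergence criteria to a fit: split R-hat and bulk ESS for
#' every monitored parameter, the divergence count, and per-chain E-BFMI.
#' `converged` requires max R-hat <= 1.01, min total ESS above
#' `ess_threshold`, and zero divergences. By default monitoring covers the
#' species-level parameters and shrinkage scales; `strict = TRUE` extends
#' it to every standardized individual offset.
#'
#' @param fit A `scale_fit`.
#' @param ess_threshold Minimum total ESS (default 2000).
#' @param strict Also monitor all individual-level offsets.
#' @param ppc Compute posterior-predictive p-values (mean and dispersion
#'   statistics); adds simulation cost.
#' @return A list of class `scale_diagnostics`: `parameters` (tibble with
#'   `parameter`, `rhat`, `ess`), `n_divergent`, `ebfmi`, `ppc_pvalues`
#'   (named vector or `NULL`), `converged`.
#' @export
diagnose <- function(fit, ess_threshold = 2000, strict = FALSE, ppc = FALSE) {
  stopifnot(inherits(fit, "scale_fit"))
  pars <- species_level_parameters(fit)
  if (strict) {
    lay <- fit$layout
    pars <- c(pars, paste0("delta_alpha[", seq_len(lay$n_ind), "]"),
              unlist(lapply(lay$rsf, function(f)
                paste0("delta_beta[", f, ",", seq_len(lay$n_ind), "]"))))
  }
  mats <- lapply(pars, posterior_matrix, fit = fit)
  tab <- tibble::tibble(
    parameter = pars,
    rhat = vapply(mats, split_rhat, numeric(1)),
    ess = vapply(mats, ess_bulk, numeric(1))
  )
  n_div <- divergence_count(fit)
  bfmi <- ebfmi(fit)
  pv <- NULL
  if (ppc) {
    pv <- c(mean = ppc_pvalue(fit, "mean"),
            dispersion = ppc_pvalue(fit, "dispersion"))
  }
  converged <- all(is.finite(tab$rhat)) && max(tab$rhat) <= 1.01 &&
    all(is.finite(tab$ess)) && min(tab$ess) > ess_threshold &&
    n_div == 0
  structure(list(parameters = tab, n_divergent = n_div, ebfmi = bfmi,
                 ppc_pvalues = pv, converged = converged,
                 ess_threshold = ess_threshold),
            class = "scale_diagnostics")
}

#' @export
print.scale_diagnostics <- function(x, ...) {
  cat(sprintf("Convergence: %s\n",
              if (x$converged) "PASSED" else "FAILED"))
  cat(sprintf("  max R-hat %.4f (<= 1.01), min ESS %.0f (> %g), %d divergences\n",
              max(x$parameters$rhat), min(x$parameters$ess),
              x$ess_threshold, x$n_divergent))
  cat("  E-BFMI per chain:", paste(sprintf("%.2f", x$ebfmi), collapse = " "),
      "\n")
  if (!is.null(x$ppc_pvalues)) {
    for (nm in names(x$ppc_pvalues)) {
      p <- x$ppc_pvalues[[nm]]
      cat(sprintf("  PPC %s statistic: p = %.3f (1 - p = %.3f)\n", nm, p, 1 - p))
    }
  }
  invisible(x)
}
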