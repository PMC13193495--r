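# Fitting the non-centred hierarchical (zero-inflated) Poisson model.
#
# The model, per species:
#   shared:      alpha ~ Normal(0, 10); sigma_alpha ~ HalfCauchy(5)
#                beta_f ~ Normal(0, 10); sigma_beta_f ~ HalfCauchy(5)
#   individual:  delta_alpha_i ~ Normal(0, 1);  alpha_i = alpha + delta_alpha_i * sigma_alpha
#                delta_beta_{i,f} ~ Normal(0, 1); beta_{i,f} = beta_f + delta_beta_{i,f} * sigma_beta_f
#                (only for factors that vary within an individual)
#   likelihood:  marks ~ Poisson(lambda) or ZIP(pi, lambda),
#                lambda = exp(alpha_i + X . beta_i),  pi ~ Beta(1, 1)
#
# Individual effects are always sampled in the non-centred form; the
# centred quantities (alpha_i, beta_{i,f}) are derived deterministically.

#' Model configuration
#'
#' Collects every tunable of [fit_model()]: the likelihood family, prior
#' scales, sampler settings, and the set of factors that carry individual
#' (random) slopes.
#'
#' @param likelihood `"poisson"` or `"zip"` (zero-inflated Poisson).
#' @param prior_intercept_sd,prior_slope_sd SDs of the Normal priors on the
#'   species-level intercept and slopes (log scale).
#' @param prior_shrinkage_scale Scale of the half-Cauchy priors on the
#'   individual-effect SDs.
#' @param pi_prior Length-2 Beta prior parameters for the zero-inflation
#'   weight (ZIP only).
#' @param chains Number of MCMC chains (at least 2, run sequentially).
#' @param tune Warmup iterations per chain (adaptation, discarded).
#' @param draws Retained draws per chain.
#' @param target_accept Target acceptance statistic for step-size
#'   adaptation; raise toward 1 for difficult posteriors.
#' @param max_treedepth Cap on trajectory doublings per iteration.
#' @param seed Integer seed; all chains derive from it deterministically.
#' @param max_retries If convergence criteria fail, refit this many times
#'   with doubled `tune` and `draws`.
#' @param ess_threshold Total-ESS convergence criterion for monitored
#'   parameters.
#' @param random_slope_factors Design columns with individual-level slopes,
#'   or `NULL` for every column that varies within an individual (all but
#'   `sex_M`).
#' @return A list of class `scale_model_config`.
#' @export
scale_model_config <- function(likelihood = c("poisson", "zip"),
                               prior_intercept_sd = 10, prior_slope_sd = 10,
                               prior_shrinkage_scale = 5, pi_prior = c(1, 1),
                               chains = 4, tune = 2000, draws = 1000,
                               target_accept = 0.9, max_treedepth = 10,
                               seed = 1, max_retries = 1,
                               ess_threshold = 2000,
                               random_slope_factors = NULL) {
  likelihood <- match.arg(likelihood)
  stopifnot(prior_intercept_sd > 0, prior_slope_sd > 0,
            prior_shrinkage_scale > 0, length(pi_prior) == 2,
            all(pi_prior > 0), chains >= 2, tune >= 10, draws >= 10,
            target_accept > 0, target_accept < 1, max_treedepth >= 1,
            max_retries >= 0)
  structure(list(likelihood = likelihood,
                 prior_intercept_sd = prior_intercept_sd,
                 prior_slope_sd = prior_slope_sd,
                 prior_shrinkage_scale = prior_shrinkage_scale,
                 pi_prior = pi_prior, chains = as.integer(chains),
                 tune = as.integer(tune), draws = as.integer(draws),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth),
                 seed = as.integer(seed), max_retries = as.integer(max_retries),
                 ess_threshold = ess_threshold,
                 random_slope_factors = random_slope_factors),
            class = "scale_model_config")
}

#' Fit the hierarchical count model to a design matrix
#'
#' Samples the posterior with the package's No-U-Turn sampler using the
#' non-centred parameterization: standardized offsets
#' `delta_alpha_i ~ Normal(0, 1)` are sampled and the individual intercepts
#' recovered as `alpha_i = alpha + delta_alpha_i * sigma_alpha` (and
#' likewise for individual slopes). If the convergence criteria (max split
#' R-hat <= 1.01 over monitored parameters, total ESS above the threshold,
#' zero divergences) fail and retries remain, the fit is repeated once with
#' doubled warmup and draws.
#'
#' @param design A [build_design()] result, or any data frame holding a
#'   subset of [design_columns()] plus `specimen_index` (an intercept-only
#'   model uses a design with no covariate columns).
#' @param counts Non-negative integer mark counts aligned with the design
#'   rows; defaults to the counts attached by [build_design()].
#' @param config A [scale_model_config()].
#' @param n_individuals Number of individuals; defaults to the largest
#'   `specimen_index`. Only needed explicitly for a zero-row design, which
#'   samples the prior (no likelihood contribution).
#' @return An object of class `scale_fit`. Access draws with
#'   [posterior_matrix()]; summarize with [effect_summary()], [tidy()] and
#'   [glance()]; check with [diagnose()].
#' @export
fit_model <- function(design, counts = attr(design, "marks"),
                      config = scale_model_config(),
                      n_individuals = NULL) {
  stopifnot(inherits(config, "scale_model_config"))
  if (!is.data.frame(design)) abort("`design` must be a data frame.")
  if (!"specimen_index" %in% names(design)) {
    abort("`design` must contain a `specimen_index` column.")
  }
  cols <- intersect(design_columns(), names(design))
  X <- as.matrix(design[cols])
  if (is.null(counts) && nrow(design) == 0) counts <- integer(0)
  if (is.null(counts)) abort("`counts` is missing and the design carries none.")
  if (length(counts) != nrow(design)) {
    abort("`counts` length does not match the number of design rows.")
  }
  if (any(is.na(counts) | counts < 0 | counts != floor(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  specimen_index <- as.integer(design$specimen_index)
  n_ind <- as.integer(n_individuals %||% max(specimen_index, 0L))
  if (nrow(design) > 0 &&
      !setequal(unique(specimen_index), seq_len(n_ind))) {
    abort("`specimen_index` must be dense 1..n_individuals.")
  }
  if (n_ind < 2) abort("The hierarchical model needs at least 2 individuals.")

  rsf <- config$random_slope_factors %||% setdiff(cols, "sex_M")
  if (!all(rsf %in% cols)) {
    abort("`random_slope_factors` must be design columns present in `design`.",
          class = "scalemarks_config_error")
  }
  if ("sex_M" %in% rsf) {
    abort("sex_M cannot carry an individual slope (constant within individual).",
          class = "scalemarks_config_error")
  }

  run <- function(tune, draws) {
    sample_chains(X, counts, specimen_index, n_ind, cols, rsf, config,
                  tune, draws)
  }

  set.seed(config$seed)
  tune <- config$tune; draws <- config$draws
  fit_raw <- run(tune, draws)
  retried <- 0L
  for (retry in seq_len(config$max_retries)) {
    fit_tmp <- as_scale_fit(fit_raw, X, counts, specimen_index, n_ind, cols,
                            rsf, config, design, tune, draws, retried)
    if (meets_convergence(fit_tmp, config$ess_threshold)) break
    tune <- 2L * tune; draws <- 2L * draws
    retried <- retry
    fit_raw <- run(tune, draws)
  }
  as_scale_fit(fit_raw, X, counts, specimen_index, n_ind, cols, rsf, config,
               design, tune, draws, retried)
}

# Run all chains sequentially under the current RNG state.
sample_chains <- function(X, counts, specimen_index, n_ind, cols, rsf,
                          config, tune, draws) {
  zip <- config$likelihood == "zip"
  K <- length(rsf)
  dim <- 2L + ncol(X) + K + n_ind + n_ind * K + as.integer(zip)
  alpha0 <- if (length(counts) > 0) log(mean(counts) + 0.1) else 0
  rsf_idx <- match(rsf, cols)
  if (K == 0) rsf_idx <- integer(0)
  b <- config$prior_shrinkage_scale
  # between-individual covariates (constant within specimen, no random
  # slope) are eligible for the interweaving update in the sampler
  between <- character(0)
  if (nrow(X) > 0) {
    first_row <- match(seq_len(n_ind), specimen_index)
    between <- Filter(function(f) {
      x <- X[, f]
      all(tapply(x, specimen_index, function(v) max(v) - min(v)) == 0)
    }, setdiff(cols, rsf))
  }
  between_cols <- match(between, cols)
  between_x <- if (length(between) > 0) {
    matrix(X[first_row, between, drop = FALSE], nrow = n_ind)
  } else {
    matrix(0, nrow = n_ind, ncol = 0)
  }
  lapply(seq_len(config$chains), function(ch) {
    init <- runif(dim, -0.5, 0.5)
    init[1] <- alpha0 + runif(1, -0.2, 0.2)
    init[2] <- z_from_sigma(0.5, b) + runif(1, -0.2, 0.2)  # sigma_alpha near 0.5
    if (K > 0) {
      init[2 + ncol(X) + seq_len(K)] <- z_from_sigma(0.2, b) + runif(K, -0.2, 0.2)
    }
    nuts_chain(X, as.numeric(counts), specimen_index, n_ind, rsf_idx, zip,
               config$prior_intercept_sd, config$prior_slope_sd,
               config$prior_shrinkage_scale, config$pi_prior[1],
               config$pi_prior[2], init, tune, draws,
               config$target_accept, config$max_treedepth,
               between_x, as.integer(between_cols))
  })
}

# The sampler carries half-Cauchy scale parameters through a
# standard-normal coordinate z with sigma = scale * cot((pi/2) * Phi(-z)),
# which maps a Normal(0, 1) draw to an exact HalfCauchy(scale) draw.
sigma_from_z <- function(z, scale) {
  scale / tan(pi / 2 * stats::pnorm(z, lower.tail = FALSE))
}
z_from_sigma <- function(sigma, scale) stats::qnorm(2 / pi * atan(sigma / scale))

# Assemble the scale_fit object from per-chain raw sampler output.
as_scale_fit <- function(raw, X, counts, specimen_index, n_ind, cols, rsf,
                         config, design, tune, draws, retried) {
  chains <- length(raw)
  theta <- array(NA_real_, dim = c(chains, draws, ncol(raw[[1]]$draws)))
  for (ch in seq_len(chains)) theta[ch, , ] <- raw[[ch]]$draws
  gather <- function(field) {
    t(vapply(raw, function(r) as.numeric(r[[field]]), numeric(draws)))
  }
  structure(list(
    theta = theta,
    layout = list(P = ncol(X), K = length(rsf), n_ind = n_ind,
                  zip = config$likelihood == "zip", cols = cols, rsf = rsf,
                  specimen_ids = attr(design, "specimen_ids") %||%
                    as.character(seq_len(n_ind))),
    sampler = list(divergent = gather("divergent"),
                   energy = gather("energy"),
                   treedepth = gather("treedepth"),
                   n_leapfrog = gather("n_leapfrog"),
                   accept_stat = gather("accept_stat"),
                   step_size = vapply(raw, `[[`, numeric(1), "step_size")),
    data = list(X = X, counts = counts, specimen_index = specimen_index,
                centre = attr(design, "centre") %||% 0,
                species = attr(design, "species") %||% NA_character_),
    config = config, tune = tune, draws = draws, chains = chains,
    retried = retried
  ), class = "scale_fit")
}

meets_convergence <- function(fit, ess_threshold) {
  pars <- species_level_parameters(fit)
  rhats <- vapply(pars, function(p) split_rhat(posterior_matrix(fit, p)),
                  numeric(1))
  esss <- vapply(pars, function(p) ess_bulk(posterior_matrix(fit, p)),
                 numeric(1))
  all(is.finite(rhats)) && max(rhats) <= 1.01 &&
    all(is.finite(esss)) && min(esss) >= ess_threshold &&
    divergence_count(fit) == 0
}

#' Monitored species-level parameter names of a fit
#'
#' The shared (species-level) parameters: `alpha`, `sigma_alpha`, one
#' `beta[<factor>]` per design column, one `sigma_beta[<factor>]` per
#' random-slope factor, and `pi` for zero-inflated fits.
#'
#' @param fit A `scale_fit`.
#' @return Character vector of parameter names.
#' @export
species_level_parameters <- function(fit) {
  stopifnot(inherits(fit, "scale_fit"))
  lay <- fit$layout
  c("alpha", "sigma_alpha",
    if (lay$P > 0) paste0("beta[", lay$cols, "]"),
    if (lay$K > 0) paste0("sigma_beta[", lay$rsf, "]"),
    if (lay$zip) "pi")
}

#' Extract posterior draws of one parameter as a chains-by-draws matrix
#'
#' Parameters are addressed by name: `"alpha"`, `"sigma_alpha"`, `"pi"`,
#' `"beta[sex_M]"`, `"sigma_beta[length_c]"`, `"delta_alpha[7]"`,
#' `"alpha_i[7]"` (the derived individual intercept
#' `alpha + delta_alpha[7] * sigma_alpha`), `"delta_beta[length_c,7]"` and
#' `"beta_i[length_c,7]"`. Scale parameters are returned on their natural
#' (positive) scale.
#'
#' @param fit A `scale_fit`.
#' @param parameter Parameter name.
#' @return Numeric matrix, `chains x draws`.
#' @export
posterior_matrix <- function(fit, parameter) {
  stopifnot(inherits(fit, "scale_fit"))
  lay <- fit$layout
  sl <- function(k) fit$theta[, , k, drop = FALSE][, , 1]
  off_da <- 2L + lay$P + lay$K
  off_db <- off_da + lay$n_ind
  m <- regmatches(parameter, regexec("^([a-z_]+)(\\[([^],]+)(,([0-9]+))?\\])?$",
                                     parameter))[[1]]
  if (length(m) == 0) abort(paste0("Cannot parse parameter name: ", parameter))
  base <- m[2]; key <- m[4]; idx <- suppressWarnings(as.integer(m[6]))
  get_beta_col <- function(key) {
    j <- match(key, lay$cols)
    if (is.na(j)) abort(paste0("Unknown design column: ", key))
    j
  }
  get_rsf_col <- function(key) {
    k <- match(key, lay$rsf)
    if (is.na(k)) abort(paste0("Not a random-slope factor: ", key))
    k
  }
  b <- fit$config$prior_shrinkage_scale
  out <- switch(
    base,
    alpha = sl(1),
    sigma_alpha = sigma_from_z(sl(2), b),
    beta = sl(2L + get_beta_col(key)),
    sigma_beta = sigma_from_z(sl(2L + lay$P + get_rsf_col(key)), b),
    pi = {
      if (!lay$zip) abort("`pi` exists only for zero-inflated fits.")
      stats::plogis(sl(dim(fit$theta)[3]))
    },
    delta_alpha = {
      i <- as.integer(key)
      stopifnot(i >= 1, i <= lay$n_ind)
      sl(off_da + i)
    },
    alpha_i = {
      i <- as.integer(key)
      stopifnot(i >= 1, i <= lay$n_ind)
      sl(1) + sl(off_da + i) * sigma_from_z(sl(2), b)
    },
    delta_beta = {
      k <- get_rsf_col(key)
      stopifnot(!is.na(idx), idx >= 1, idx <= lay$n_ind)
      sl(off_db + (k - 1L) * lay$n_ind + idx)
    },
    beta_i = {
      k <- get_rsf_col(key)
      stopifnot(!is.na(idx), idx >= 1, idx <= lay$n_ind)
      j <- get_beta_col(key)
      sl(2L + j) +
        sl(off_db + (k - 1L) * lay$n_ind + idx) *
          sigma_from_z(sl(2L + lay$P + k), b)
    },
    abort(paste0("Unknown parameter: ", parameter))
  )
  matrix(out, nrow = fit$chains)
}

# Per-row expected-count draws lambda[row, draw] for a subset of flattened
# draw indices, using the fit's own data rows (individual effects included).
lambda_draws <- function(fit, draw_idx) {
  lay <- fit$layout
  flat <- function(k) as.vector(fit$theta[, , k])[draw_idx]
  n <- nrow(fit$data$X)
  S <- length(draw_idx)
  off_da <- 2L + lay$P + lay$K
  off_db <- off_da + lay$n_ind
  b <- fit$config$prior_shrinkage_scale
  eta <- matrix(rep(flat(1), each = n), nrow = n)
  sa <- sigma_from_z(flat(2), b)
  dalpha <- vapply(seq_len(lay$n_ind), function(i) flat(off_da + i),
                   numeric(S))                      # S x I
  eta <- eta + t(dalpha)[fit$data$specimen_index, , drop = FALSE] *
    matrix(rep(sa, each = n), nrow = n)
  if (lay$P > 0) {
    beta <- vapply(seq_len(lay$P), function(j) flat(2L + j), numeric(S))
    eta <- eta + fit$data$X %*% t(beta)
  }
  for (k in seq_len(lay$K)) {
    sb <- sigma_from_z(flat(2L + lay$P + k), b)
    db <- vapply(seq_len(lay$n_ind),
                 function(i) flat(off_db + (k - 1L) * lay$n_ind + i),
                 numeric(S))                        # S x I
    xc <- fit$data$X[, match(lay$rsf[k], lay$cols)]
    eta <- eta + xc * t(db)[fit$data$specimen_index, , drop = FALSE] *
      matrix(rep(sb, each = n), nrow = n)
  }
  exp(eta)
}

#' Fit the model straight from a scale table
#'
#' Convenience pipeline surface: filters readable scales, builds the
#' design, and fits. The table must contain a single species (one model
#' per species).
#'
#' @param data A valid scale table.
#' @param ... Passed to [scale_model_config()].
#' @param centre Scale-length centring, as in [build_design()].
#' @return A `scale_fit`.
#' @export
#' @examples
#' \dontrun{
#' sim <- simulate_scales(truth_preset("curema"), seed = 1, n_individuals = 40)
#' fit <- fit_scales(sim$data, chains = 2, tune = 500, draws = 500, seed = 2)
#' }
fit_scales <- function(data, ..., centre = "auto") {
  design <- build_design(filter_readable(data), centre = centre)
  fit_model(design, config = scale_model_config(...))
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("<scale_fit> %s likelihood, %d chains x %d draws (tune %d%s)\n",
              x$config$likelihood, x$chains, x$draws, x$tune,
              if (x$retried > 0) sprintf(", retried %d", x$retried) else ""))
  cat(sprintf("  %d scales, %d individuals, %d divergences\n",
              nrow(x$data$X), x$layout$n_ind, divergence_count(x)))
  print(tidy(x), n = Inf)
  invisible(x)
}
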