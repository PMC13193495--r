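# Posterior summarization on the effect (exp) scale: highest-density
# intervals, direction probabilities, Figure-style effect tables and
# interaction surfaces, and truth-recovery reports for synthetic runs.

#' Highest-density interval of a sample
#'
#' The shortest contiguous window of the sorted sample containing
#' `ceiling(prob * n)` draws; ties in width are broken by the earliest
#' window. Deterministic (no density smoothing), so it is exactly
#' checkable against a brute-force scan of all windows. Appropriate for
#' unimodal posteriors.
#'
#' @param samples Numeric draws.
#' @param prob Interval mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(1:100, 0.95)  # c(1, 95): all windows tie, earliest wins
hdi <- function(samples, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1) {
    abort("`prob` must be a single value in (0, 1).")
  }
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  m <- ceiling(prob * n)
  if (n < ceiling(1 / (1 - prob)) || m > n) {
    abort("Too few samples for the requested interval mass.")
  }
  s <- sort(samples)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)  # first minimum = earliest window
  c(lower = s[i], upper = s[i + m - 1])
}

#' Posterior direction probability
#'
#' The larger of the two directional posterior fractions,
#' `max(P(x > reference), P(x < reference))`; draws exactly equal to the
#' reference count toward neither side. On the effect (exp) scale the
#' natural reference is 1 (no effect): a value of 1 means every draw lies
#' on one side of "no effect", 0.5 means perfect ambivalence.
#'
#' @param samples Numeric draws.
#' @param reference Reference value (default 1).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' prob_direction(c(0.9, 1.1, 1.1, 1.1))  # 0.75
prob_direction <- function(samples, reference = 1) {
  stopifnot(length(samples) > 0)
  max(mean(samples > reference), mean(samples < reference))
}

#' Exp-scale effect summary of a fit
#'
#' For every species-level factor, the posterior of `exp(beta_f)` is
#' summarized by its mean, 95% HDI and direction probability relative to 1
#' (no effect) — the multiplicative change in expected mark count per unit
#' of the factor.
#'
#' @param fit A `scale_fit`.
#' @param prob HDI mass.
#' @return A tibble of class `effect_summary`: `factor`, `mean_effect`,
#'   `hdi_low`, `hdi_high`, `prob_direction`.
#' @export
effect_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "scale_fit"))
  cols <- fit$layout$cols
  if (length(cols) == 0) abort("The fit has no species-level factors.")
  rows <- lapply(cols, function(f) {
    eff <- exp(as.vector(posterior_matrix(fit, paste0("beta[", f, "]"))))
    h <- hdi(eff, prob)
    tibble::tibble(factor = f, mean_effect = mean(eff),
                   hdi_low = h[["lower"]], hdi_high = h[["upper"]],
                   prob_direction = prob_direction(eff, 1))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("effect_summary", class(out))
  attr(out, "species") <- fit$data$species
  attr(out, "prob") <- prob
  out
}

#' Posterior expected counts over the 3 x 3 body-area grid
#'
#' For every horizontal-by-vertical area combination, the posterior of the
#' expected mark count at species level (no individual offsets), for a
#' scale of average length (`length_c = 0` unless overridden) and the
#' given sex, summarized by mean and 95% HDI. This surface exposes
#' horizontal-vertical interactions: bands whose anterior-to-posterior
#' trends differ.
#'
#' @param fit A `scale_fit` with the full area coding.
#' @param sex Conditioning sex (default `"F"`).
#' @param length_c Centred scale length at which to evaluate (0 = mean).
#' @param prob HDI mass.
#' @return A tibble of class `interaction_surface`: `horizontal`,
#'   `vertical`, `area`, `mean_count`, `hdi_low`, `hdi_high`.
#' @export
interaction_surface <- function(fit, sex = c("F", "M"), length_c = 0,
                                prob = 0.95) {
  stopifnot(inherits(fit, "scale_fit"))
  sex <- match.arg(sex)
  cols <- fit$layout$cols
  needed <- setdiff(design_columns(), "length_c")
  if (!all(needed %in% cols)) {
    abort("The fit lacks the full area coding needed for a surface.")
  }
  alpha <- as.vector(posterior_matrix(fit, "alpha"))
  betas <- vapply(cols, function(f)
    as.vector(posterior_matrix(fit, paste0("beta[", f, "]"))),
    numeric(length(alpha)))
  rows <- list()
  for (h in c("A", "C", "P")) {
    for (v in c("D", "M", "V")) {
      x <- design_row(sex, paste0(h, v), length_c)[cols]
      lam <- exp(alpha + as.vector(betas %*% x))
      hd <- hdi(lam, prob)
      rows[[paste0(h, v)]] <- tibble::tibble(
        horizontal = h, vertical = v, area = paste0(h, v),
        mean_count = mean(lam),
        hdi_low = hd[["lower"]], hdi_high = hd[["upper"]])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("interaction_surface", class(out))
  attr(out, "sex") <- sex
  out
}

#' Truth-recovery report for a synthetic fit
#'
#' Compares an [effect_summary()] with the generative truth it was
#' simulated from: per factor, whether the true exp-scale effect lies
#' inside the 95% HDI, plus the overall coverage fraction. Over repeated
#' simulations the coverage should be statistically consistent with the
#' interval mass.
#'
#' @param truth A [scale_truth()].
#' @param summary An [effect_summary()] from a fit to data simulated under
#'   `truth`.
#' @return A list of class `recovery_report`: `table` (tibble: `factor`,
#'   `truth`, `mean_effect`, `hdi_low`, `hdi_high`, `covered`) and
#'   `coverage_fraction`.
#' @export
recovery_report <- function(truth, summary) {
  stopifnot(inherits(truth, "scale_truth"), inherits(summary, "effect_summary"))
  if (!setequal(summary$factor, names(truth$beta))) {
    abort("Summary factors do not match the truth's beta names.")
  }
  tab <- summary
  tab$truth <- exp(truth$beta[tab$factor])
  tab$covered <- tab$hdi_low <= tab$truth & tab$truth <= tab$hdi_high
  tab <- tab[, c("factor", "truth", "mean_effect", "hdi_low", "hdi_high",
                 "covered")]
  structure(list(table = tibble::as_tibble(tab),
                 coverage_fraction = mean(tab$covered)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Truth recovery: %.0f%% of factors covered by their HDI\n",
              100 * x$coverage_fraction))
  print(x$table, n = Inf)
  invisible(x)
}

#' @rdname fit_model
#' @param x A `scale_fit`.
#' @param prob HDI mass for the interval columns.
#' @param ... Unused.
#' @method tidy scale_fit
#' @export
tidy.scale_fit <- function(x, prob = 0.95, ...) {
  pars <- species_level_parameters(x)
  rows <- lapply(pars, function(p) {
    m <- posterior_matrix(x, p)
    v <- as.vector(m)
    h <- hdi(v, prob)
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   hdi_low = h[["lower"]], hdi_high = h[["upper"]],
                   rhat = split_rhat(m), ess = ess_bulk(m))
  })
  dplyr::bind_rows(rows)
}

#' @rdname fit_model
#' @method glance scale_fit
#' @export
glance.scale_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    nobs = nrow(x$data$X), n_individuals = x$layout$n_ind,
    likelihood = x$config$likelihood, chains = x$chains, draws = x$draws,
    tune = x$tune, retried = x$retried,
    divergences = divergence_count(x),
    max_rhat = max(td$rhat), min_ess = min(td$ess),
    min_ebfmi = min(ebfmi(x)),
    converged = max(td$rhat) <= 1.01 & min(td$ess) > x$config$ess_threshold &
      divergence_count(x) == 0
  )
}
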