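# Covariate coding for the hierarchical model.

#' Build the model design matrix from readable scales
#'
#' Encodes the covariates of the count model for a single species: a male
#' indicator, scale length centred at `centre` (the sample mean when
#' `"auto"`), horizontal-position dummies with central (C) as reference,
#' vertical-position dummies with middle (M) as reference, and the four
#' horizontal-by-vertical interaction dummies (products of the main-effect
#' dummies). The reference cell is therefore a female scale of average
#' length from the central-middle (CM) area. A dense 1-based
#' `specimen_index` maps each row to its individual.
#'
#' @param data A valid scale table containing only good scales of one
#'   species.
#' @param centre Centring constant for scale length, or `"auto"` for the
#'   sample mean.
#' @return A tibble of class `scale_design` with the 10 covariate columns
#'   of [design_columns()] plus `specimen_index`; attributes `centre`,
#'   `specimen_ids` (index-ordered), `species` and `marks` (the aligned
#'   counts).
#' @export
build_design <- function(data, centre = "auto") {
  data <- validate_scales(data)
  if (any(data$status != "good")) {
    abort("Design requires readable scales only; run filter_readable() first.")
  }
  if (dplyr::n_distinct(data$species) > 1) {
    abort("Design requires a single species; one model is fitted per species.")
  }
  if (identical(centre, "auto")) centre <- mean(data$scale_length)
  stopifnot(is.numeric(centre), length(centre) == 1)

  h <- substr(data$area, 1, 1)
  v <- substr(data$area, 2, 2)
  ids <- unique(data$specimen_id)
  design <- tibble::tibble(
    sex_M = as.numeric(data$sex == "M"),
    length_c = data$scale_length - centre,
    H_A = as.numeric(h == "A"),
    H_P = as.numeric(h == "P"),
    V_D = as.numeric(v == "D"),
    V_V = as.numeric(v == "V")
  )
  design$HxV_AD <- design$H_A * design$V_D
  design$HxV_AV <- design$H_A * design$V_V
  design$HxV_PD <- design$H_P * design$V_D
  design$HxV_PV <- design$H_P * design$V_V
  design$specimen_index <- match(data$specimen_id, ids)

  structure(design,
            class = c("scale_design", class(design)),
            centre = centre, specimen_ids = ids,
            species = data$species[1], marks = data$marks)
}

#' Evaluate the linear predictor of the count model
#'
#' The expected count for one scale,
#' `lambda = exp(alpha_i + sum_f x_f * beta_{i,f})`, evaluated in log space
#' so it is always strictly positive and overflow-safe for plausible
#' inputs.
#'
#' @param alpha_i Individual-level intercept (log scale).
#' @param beta_i Named numeric vector of individual-level effects; names
#'   must cover the non-zero entries of `x`.
#' @param x Named numeric design row.
#' @return The positive expected count.
#' @export
#' @examples
#' linear_predictor(log(4), c(sex_M = log(1.07)), c(sex_M = 0))
linear_predictor <- function(alpha_i, beta_i, x) {
  active <- names(x)[x != 0]
  missing_beta <- setdiff(active, names(beta_i))
  if (length(missing_beta) > 0) {
    abort(paste0("beta_i lacks coefficients for active columns: ",
                 paste(missing_beta, collapse = ", ")))
  }
  eta <- alpha_i + sum(x[active] * beta_i[active])
  exp(eta)
}

#' Zero-inflated Poisson log probability mass
#'
#' `log P(Y = y)` for the mixture that puts probability `pi` on a
#' structural zero and `1 - pi` on `Poisson(lambda)`:
#' `y = 0` has mass `pi + (1 - pi) exp(-lambda)`; `y > 0` has mass
#' `(1 - pi) * dpois(y, lambda)`. With `pi = 0` this is exactly the Poisson
#' log-pmf. Vectorized over `y`.
#'
#' @param y Non-negative integer count(s).
#' @param lambda Positive Poisson mean.
#' @param pi Zero-inflation probability in `[0, 1)`.
#' @return Log probability mass, same length as `y`.
#' @export
#' @examples
#' zip_logpmf(0, lambda = 1, pi = 0)    # -1
#' zip_logpmf(0, lambda = 1, pi = 0.5)  # log(0.5 + 0.5 * exp(-1))
zip_logpmf <- function(y, lambda, pi = 0) {
  if (any(lambda <= 0)) abort("`lambda` must be strictly positive.")
  if (any(pi < 0 | pi >= 1)) abort("`pi` must lie in [0, 1).")
  if (any(y < 0 | y != floor(y))) abort("`y` must be non-negative integers.")
  out <- log1p(-pi) + stats::dpois(y, lambda, log = TRUE)
  n <- length(out)
  zero <- rep_len(y == 0, n)
  if (any(zero)) {
    lam <- rep_len(lambda, n)[zero]
    p <- rep_len(pi, n)[zero]
    out[zero] <- log(p + (1 - p) * exp(-lam))
  }
  out
}
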