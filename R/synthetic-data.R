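# Synthetic scale-mark datasets with known ground truth.
#
# The generator draws from the same generative process the model assumes:
# specimen covariates (locality, sex, standard length), per-specimen
# non-centred random effects, 9 body areas x 3-4 scales, area-dependent
# damage/regeneration, and (zero-inflated) Poisson mark counts on the log
# link. Because the truth is known, every downstream stage (screening, fit,
# diagnostics, effect summaries) can be validated end-to-end.

#' Design-matrix column names
#'
#' Fixed covariate coding shared by the generator and the model: a male
#' indicator, centred scale length, horizontal dummies (reference C),
#' vertical dummies (reference M), and the four horizontal-by-vertical
#' interaction dummies.
#'
#' @return Character vector of the 10 column names.
#' @export
design_columns <- function() {
  c("sex_M", "length_c", "H_A", "H_P", "V_D", "V_V",
    "HxV_AD", "HxV_AV", "HxV_PD", "HxV_PV")
}

#' Construct a generative truth for scale-mark simulation
#'
#' Bundles every parameter of the generative model: the species-level
#' log-scale intercept `alpha` and its individual shrinkage scale
#' `sigma_alpha`; log-scale factor effects `beta` (one per design column)
#' and individual-slope scales `sigma_beta` (for the factors that vary
#' within an individual); the zero-inflation weight `pi`; per-area
#' damage/regeneration probabilities; and the specimen covariate model
#' (locality mixture for standard length, sex ratio, and a linear
#' scale-length-on-standard-length map with Gaussian noise).
#'
#' @param species `"cephalus"` or `"curema"`.
#' @param alpha Species-level intercept on the log scale.
#' @param sigma_alpha Non-negative scale of individual intercept offsets.
#' @param beta Named numeric vector of log-scale effects; names must be
#'   exactly [design_columns()].
#' @param sigma_beta Named non-negative numeric vector of individual-slope
#'   scales; names must be a subset of [design_columns()]. Factors constant
#'   within an individual (sex) cannot carry an individual slope.
#' @param pi Zero-inflation probability in `[0, 1]`.
#' @param status_probs Named probability vector over [scale_areas()]: the
#'   chance a scale from that area is damaged or regenerated.
#' @param n_individuals Default number of specimens to simulate.
#' @param scales_per_area Integer range (length-2 vector) of scales
#'   collected per body area; draws are uniform over the range.
#' @param p_male Probability a specimen is male.
#' @param length_model List with `localities` (data frame: `locality`,
#'   `weight`, `sl_mean`, `sl_sd` in cm), `slope` and `intercept` mapping
#'   standard length to expected scale length, and `noise_sd` for the
#'   per-scale Gaussian residual.
#' @return An object of class `scale_truth`.
#' @seealso [truth_preset()] for presets, [simulate_scales()] to draw data.
#' @export
scale_truth <- function(species, alpha, sigma_alpha, beta, sigma_beta, pi = 0,
                        status_probs, n_individuals = 100,
                        scales_per_area = c(3L, 4L), p_male = 0.5,
                        length_model) {
  if (!species %in% scale_species) abort("Unknown species.")
  cols <- design_columns()
  if (!setequal(names(beta), cols)) {
    abort(paste0("`beta` names must match the design columns exactly; got: ",
                 paste(names(beta), collapse = ", ")),
          class = "scalemarks_config_error")
  }
  beta <- beta[cols]
  if (length(sigma_beta) > 0 && !all(names(sigma_beta) %in% cols)) {
    abort("`sigma_beta` names must be design columns.",
          class = "scalemarks_config_error")
  }
  if ("sex_M" %in% names(sigma_beta)) {
    abort("sex is constant within an individual and cannot carry an individual slope.",
          class = "scalemarks_config_error")
  }
  stopifnot(sigma_alpha >= 0, all(sigma_beta >= 0), pi >= 0, pi <= 1,
            n_individuals >= 1, p_male >= 0, p_male <= 1,
            length(scales_per_area) == 2, scales_per_area[1] <= scales_per_area[2],
            scales_per_area[1] >= 1)
  if (!setequal(names(status_probs), scale_areas())) {
    abort("`status_probs` must name all nine areas.",
          class = "scalemarks_config_error")
  }
  status_probs <- status_probs[scale_areas()]
  stopifnot(all(status_probs >= 0), all(status_probs <= 1))
  lm_df <- tibble::as_tibble(length_model$localities)
  stopifnot(all(c("locality", "weight", "sl_mean", "sl_sd") %in% names(lm_df)),
            all(lm_df$locality %in% scale_localities),
            is.numeric(length_model$slope), is.numeric(length_model$noise_sd),
            length_model$noise_sd >= 0)
  lm_df$weight <- lm_df$weight / sum(lm_df$weight)
  structure(
    list(species = species, alpha = alpha, sigma_alpha = sigma_alpha,
         beta = beta, sigma_beta = sigma_beta, pi = pi,
         status_probs = status_probs, n_individuals = as.integer(n_individuals),
         scales_per_area = as.integer(scales_per_area), p_male = p_male,
         length_model = list(localities = lm_df,
                             slope = length_model$slope,
                             intercept = length_model$intercept %||% 0,
                             noise_sd = length_model$noise_sd)),
    class = "scale_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scale_truth <- function(x, ...) {
  cat("<scale_truth> species:", x$species, "\n")
  cat("  alpha =", format(x$alpha, digits = 4),
      " sigma_alpha =", format(x$sigma_alpha, digits = 4),
      " pi =", format(x$pi, digits = 4), "\n")
  cat("  exp(beta):\n")
  print(round(exp(x$beta), 3))
  invisible(x)
}

# Marginal mean/SD of standard length under the locality mixture.
mixture_sl_moments <- function(length_model) {
  d <- length_model$localities
  d$weight <- d$weight / sum(d$weight)
  m <- sum(d$weight * d$sl_mean)
  v <- sum(d$weight * (d$sl_sd^2 + d$sl_mean^2)) - m^2
  list(mean = m, sd = sqrt(v))
}

# Expected (population-mean) scale length under the truth; the generator
# centres scale length here so that alpha is the log expected count at the
# average scale.
truth_mean_scale_length <- function(truth) {
  lm <- truth$length_model
  lm$intercept + lm$slope * mixture_sl_moments(lm)$mean
}

# Noise SD achieving a target Pearson correlation r between per-scale scale
# length and specimen standard length, given the locality mixture.
noise_sd_for_correlation <- function(length_model, r) {
  stopifnot(r > 0, r < 1)
  abs(length_model$slope) * mixture_sl_moments(length_model)$sd * sqrt(1 / r^2 - 1)
}

#' Preset generative truths calibrated to the two mullet species
#'
#' Returns a ready-made [scale_truth()] whose headline effects match the
#' fitted species-level summaries reported for Gulf-of-Mexico mullets:
#'
#' * `curema`: baseline mean count `exp(alpha) = 3.37`; males carry 7% more
#'   marks (`exp(beta_sex) = 1.07`); +6% marks per unit scale length;
#'   ventral areas +7% over the middle reference; a mild (+3%)
#'   dorsal-by-horizontal interaction; other area effects null.
#' * `cephalus`: baseline `exp(alpha) = 5.75`; a negligible sex effect
#'   (`exp(beta_sex) = 0.98`); area effects within 5-10% arranged so mark
#'   counts decrease anterior-to-posterior along the middle band but
#'   increase anterior-to-posterior along the dorsal and ventral bands.
#'
#' Specimen covariates (locality mixture, standard-length means and SDs,
#' sex ratios) follow the study's sampling tables, and the scale-length
#' noise is calibrated so the scale-length/standard-length Pearson
#' correlation is 0.6 (curema) or 0.83 (cephalus). Damage/regeneration
#' probabilities per area follow the observed percentage table (anterior
#' and ventral areas elevated, roughly 10-35%).
#'
#' @param species `"cephalus"` or `"curema"`.
#' @param pi Zero-inflation probability; 0 gives the plain Poisson process.
#' @param sigma_alpha,sigma_slope Individual heterogeneity scales for the
#'   intercept and for the within-individual slopes.
#' @return A `scale_truth`.
#' @export
#' @examples
#' truth_preset("curema")
truth_preset <- function(species = c("curema", "cephalus"), pi = 0,
                         sigma_alpha = 0.25, sigma_slope = 0.05) {
  species <- match.arg(species)
  cols <- design_columns()
  beta <- stats::setNames(numeric(length(cols)), cols)
  rsf <- setdiff(cols, "sex_M")
  sigma_beta <- stats::setNames(rep(sigma_slope, length(rsf)), rsf)

  if (species == "curema") {
    beta["sex_M"] <- log(1.07)
    beta["length_c"] <- log(1.06)
    beta["V_V"] <- log(1.07)
    beta["HxV_AD"] <- log(1.03)
    beta["HxV_PD"] <- log(1.03)
    status_probs <- c(AD = 0.190, AM = 0.227, AV = 0.204, CD = 0.165,
                      CM = 0.203, CV = 0.189, PD = 0.154, PM = 0.192,
                      PV = 0.162)
    localities <- tibble::tibble(
      locality = c("LM", "TA", "CA", "ME"),
      weight = c(51, 46, 50, 53),
      sl_mean = c(22.4, 23.8, 24.3, 22.5),
      sl_sd = c(1.0, 1.5, 1.6, 3.4)
    )
    alpha <- log(3.37); p_male <- 47 / 200
    n_individuals <- 200L; target_r <- 0.6
  } else {
    beta["sex_M"] <- log(0.98)
    beta["length_c"] <- log(1.05)
    beta["H_A"] <- log(1.05)
    beta["H_P"] <- log(0.95)
    beta["V_D"] <- log(1.05)
    beta["V_V"] <- log(1.07)
    # Interactions flip the horizontal trend off the middle band: counts
    # fall A -> P along M but rise A -> P along D and V.
    beta["HxV_AD"] <- log(0.90)
    beta["HxV_AV"] <- log(0.90)
    beta["HxV_PD"] <- log(1.10)
    beta["HxV_PV"] <- log(1.10)
    status_probs <- c(AD = 0.236, AM = 0.160, AV = 0.373, CD = 0.238,
                      CM = 0.173, CV = 0.319, PD = 0.169, PM = 0.102,
                      PV = 0.145)
    localities <- tibble::tibble(
      locality = c("SL", "SAB", "LM"),
      weight = c(50, 22, 45),
      sl_mean = c(27.0, 27.4, 24.3),
      sl_sd = c(3.5, 2.9, 1.7)
    )
    alpha <- log(5.75); p_male <- 53 / 117
    n_individuals <- 117L; target_r <- 0.83
  }

  length_model <- list(localities = localities, slope = 0.35, intercept = 0)
  length_model$noise_sd <- noise_sd_for_correlation(length_model, target_r)

  scale_truth(species = species, alpha = alpha, sigma_alpha = sigma_alpha,
              beta = beta, sigma_beta = sigma_beta, pi = pi,
              status_probs = status_probs, n_individuals = n_individuals,
              p_male = p_male, length_model = length_model)
}

# Design row (named vector over design_columns()) for one scale.
design_row <- function(sex, area, length_c) {
  h <- substr(area, 1, 1); v <- substr(area, 2, 2)
  c(sex_M = as.numeric(sex == "M"), length_c = length_c,
    H_A = as.numeric(h == "A"), H_P = as.numeric(h == "P"),
    V_D = as.numeric(v == "D"), V_V = as.numeric(v == "V"),
    HxV_AD = as.numeric(h == "A" && v == "D"),
    HxV_AV = as.numeric(h == "A" && v == "V"),
    HxV_PD = as.numeric(h == "P" && v == "D"),
    HxV_PV = as.numeric(h == "P" && v == "V"))
}

#' Simulate a scale-mark dataset from a known truth
#'
#' Draws a full dataset from the generative model. Per specimen: locality
#' (weighted by sample sizes), sex, standard length (locality-specific
#' normal, truncated positive); non-centred random effects
#' `alpha_i = alpha + delta_i * sigma_alpha` with `delta_i ~ Normal(0, 1)`,
#' and analogously `beta_{i,f}` for within-individual factors. Per body
#' area, 3-4 scales are drawn; scale length is linear in standard length
#' plus noise; status is damaged-or-regenerated with the area's
#' probability (split evenly between the two labels); good scales receive
#' `marks ~ ZIPoisson(pi, lambda)` with
#' `lambda = exp(alpha_i + x . beta_i)`, where scale length enters centred
#' at its population mean.
#'
#' The same `(truth, seed, n_individuals)` always yields a field-identical
#' result.
#'
#' @param truth A [scale_truth()].
#' @param seed Integer seed; all randomness derives from it.
#' @param n_individuals Number of specimens (default from the truth).
#' @return An object of class `scale_sim`: a list with `data` (a valid
#'   scale table), `truth`, `individual_effects` (tibble of realized
#'   per-specimen `delta_alpha`, `alpha_i` and slope values), `seed`, and
#'   `centre` (the scale-length centring constant used in generation).
#' @export
#' @examples
#' sim <- simulate_scales(truth_preset("curema"), seed = 1, n_individuals = 5)
#' dplyr::count(sim$data, status)
simulate_scales <- function(truth, seed, n_individuals = truth$n_individuals) {
  stopifnot(inherits(truth, "scale_truth"))
  set.seed(as.integer(seed))
  cols <- design_columns()
  rsf <- names(truth$sigma_beta)
  lmod <- truth$length_model
  centre <- truth_mean_scale_length(truth)
  areas <- scale_areas()
  spa <- truth$scales_per_area

  rtrunc_pos <- function(n, mean, sd, lower) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }

  ind <- tibble::tibble(
    specimen_id = sprintf("%s_%04d", substr(truth$species, 1, 3),
                          seq_len(n_individuals)),
    locality = sample(lmod$localities$locality, n_individuals, replace = TRUE,
                      prob = lmod$localities$weight),
    sex = ifelse(runif(n_individuals) < truth$p_male, "M", "F")
  )
  loc_idx <- match(ind$locality, lmod$localities$locality)
  ind$standard_length_cm <- rtrunc_pos(
    n_individuals, lmod$localities$sl_mean[loc_idx],
    lmod$localities$sl_sd[loc_idx], lower = 1)

  ind$delta_alpha <- rnorm(n_individuals)
  ind$alpha_i <- truth$alpha + ind$delta_alpha * truth$sigma_alpha
  delta_beta <- matrix(rnorm(n_individuals * length(rsf)),
                       nrow = n_individuals,
                       dimnames = list(NULL, rsf))
  beta_i <- matrix(rep(truth$beta, each = n_individuals),
                   nrow = n_individuals, dimnames = list(NULL, cols))
  if (length(rsf) > 0) {
    beta_i[, rsf] <- beta_i[, rsf] +
      sweep(delta_beta, 2, truth$sigma_beta[rsf], `*`)
  }

  # per-area additive effect (main dummies + interaction) per individual
  area_design <- t(vapply(areas, function(a) design_row("F", a, 0),
                          numeric(length(cols))))
  area_cols <- setdiff(cols, c("sex_M", "length_c"))

  rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    n_per_area <- sample(seq(spa[1], spa[2]), length(areas), replace = TRUE)
    area <- rep(areas, times = n_per_area)
    n_sc <- length(area)
    lsc <- rtrunc_pos(n_sc,
                      lmod$intercept + lmod$slope * ind$standard_length_cm[i],
                      lmod$noise_sd, lower = 0.05)
    unreadable <- runif(n_sc) < truth$status_probs[area]
    status <- ifelse(unreadable,
                     ifelse(runif(n_sc) < 0.5, "damaged", "regenerated"),
                     "good")
    area_eff <- as.vector(area_design[, area_cols, drop = FALSE] %*%
                            beta_i[i, area_cols])
    names(area_eff) <- areas
    eta <- ind$alpha_i[i] +
      (ind$sex[i] == "M") * beta_i[i, "sex_M"] +
      (lsc - centre) * beta_i[i, "length_c"] +
      area_eff[area]
    marks <- rep(NA_integer_, n_sc)
    good <- status == "good"
    if (any(good)) {
      lam <- exp(eta[good])
      y <- rpois(sum(good), lam)
      if (truth$pi > 0) y[runif(sum(good)) < truth$pi] <- 0L
      marks[good] <- y
    }
    rows[[i]] <- tibble::tibble(
      specimen_id = ind$specimen_id[i], species = truth$species,
      locality = ind$locality[i], sex = ind$sex[i],
      standard_length_cm = ind$standard_length_cm[i], area = area,
      scale_length = lsc,
      scale_width = lsc * 0.75, scale_radius = lsc * 0.6,
      status = status, marks = marks)
  }
  data <- validate_scales(dplyr::bind_rows(rows))

  effects <- dplyr::bind_cols(
    ind[, c("specimen_id", "delta_alpha", "alpha_i")],
    tibble::as_tibble(beta_i)
  )
  structure(list(data = data, truth = truth, individual_effects = effects,
                 seed = as.integer(seed), centre = centre),
            class = "scale_sim")
}

#' @export
print.scale_sim <- function(x, ...) {
  cat("<scale_sim>", nrow(x$data), "scales from",
      nrow(x$individual_effects), x$truth$species, "specimens (seed",
      paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write / read a generative truth as a YAML config
#'
#' Serializes every field of a [scale_truth()] to a flat YAML mapping so a
#' simulation is reproducible from a plain-text config.
#'
#' @param truth A `scale_truth`.
#' @param path File path.
#' @return `write_truth()` the path invisibly; `read_truth()` the
#'   reconstructed `scale_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scale_truth"))
  lst <- list(
    species = truth$species, alpha = truth$alpha,
    sigma_alpha = truth$sigma_alpha,
    beta = as.list(truth$beta), sigma_beta = as.list(truth$sigma_beta),
    pi = truth$pi, status_probs = as.list(truth$status_probs),
    n_individuals = truth$n_individuals,
    scales_per_area = truth$scales_per_area, p_male = truth$p_male,
    length_model = list(
      locality = truth$length_model$localities$locality,
      weight = truth$length_model$localities$weight,
      sl_mean = truth$length_model$localities$sl_mean,
      sl_sd = truth$length_model$localities$sl_sd,
      slope = truth$length_model$slope,
      intercept = truth$length_model$intercept,
      noise_sd = truth$length_model$noise_sd)
  )
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}

#' @rdname write_truth
#' @param path File path.
#' @export
read_truth <- function(path) {
  lst <- yaml::read_yaml(path)
  scale_truth(
    species = lst$species, alpha = lst$alpha, sigma_alpha = lst$sigma_alpha,
    beta = unlist(lst$beta), sigma_beta = unlist(lst$sigma_beta),
    pi = lst$pi, status_probs = unlist(lst$status_probs),
    n_individuals = lst$n_individuals,
    scales_per_area = unlist(lst$scales_per_area), p_male = lst$p_male,
    length_model = list(
      localities = tibble::tibble(
        locality = lst$length_model$locality,
        weight = lst$length_model$weight,
        sl_mean = lst$length_model$sl_mean,
        sl_sd = lst$length_model$sl_sd),
      slope = lst$length_model$slope,
      intercept = lst$length_model$intercept,
      noise_sd = lst$length_model$noise_sd)
  )
}
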