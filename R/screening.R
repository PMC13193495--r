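# Pre-model screening: damage/regeneration percentage table, the
# Kruskal-Wallis locality screen, and the scale-length / standard-length
# correlation.

#' Percentage of damaged or regenerated scales by area and locality
#'
#' For every body-area-by-locality cell, the percentage of scales that are
#' damaged or regenerated, together with a per-locality summary (mean and
#' sample SD over the nine area percentages). Percentages are kept at full
#' precision in the `pct` column; `pct_1dp` carries the half-up 1-decimal
#' presentation rounding.
#'
#' @param data A valid scale table.
#' @return A list of class `status_table` with `cells` (tibble: `area`,
#'   `locality`, `n_scales`, `n_unreadable`, `pct`, `pct_1dp`) and
#'   `summary` (tibble: `locality`, `n_areas`, `mean_pct`, `sd_pct`).
#'   Area-by-locality combinations with no scales are absent from `cells`;
#'   locality summaries are computed over the areas present.
#' @export
status_table <- function(data) {
  data <- validate_scales(data)
  cells <- dplyr::summarise(
    dplyr::group_by(data, .data$area, .data$locality),
    n_scales = dplyr::n(),
    n_unreadable = sum(.data$status != "good"),
    .groups = "drop"
  )
  cells$pct <- 100 * cells$n_unreadable / cells$n_scales
  cells$pct_1dp <- round_half_up(cells$pct, 1)
  cells <- dplyr::arrange(cells, match(.data$area, scale_areas()),
                          match(.data$locality, scale_localities))
  summary <- dplyr::summarise(
    dplyr::group_by(cells, .data$locality),
    n_areas = dplyr::n(),
    mean_pct = mean(.data$pct),
    sd_pct = if (dplyr::n() > 1) sd(.data$pct) else 0,
    .groups = "drop"
  )
  structure(list(cells = cells, summary = summary), class = "status_table")
}

# round() uses banker's rounding; percentage tables conventionally print
# half-up.
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.status_table <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$cells[, c("area", "locality", "pct_1dp")],
                             names_from = "locality", values_from = "pct_1dp")
  cat("Percentage of damaged or regenerated scales by area and locality\n")
  print(wide)
  cat("\nPer-locality mean +/- SD over areas:\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.1f +/- %.1f (over %d areas)\n", s$locality[i],
                s$mean_pct[i], s$sd_pct[i], s$n_areas[i]))
  }
  invisible(x)
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' The H statistic with midranks and the tie correction
#' `C = 1 - sum(t^3 - t) / (N^3 - N)`, referred to the upper tail of a
#' chi-square with `k - 1` degrees of freedom. The statistic depends on the
#' data only through ranks, so it is invariant under strictly increasing
#' transformations.
#'
#' @param values Numeric observations.
#' @param groups Parallel vector of group labels (at least two non-empty
#'   groups).
#' @return A list of class `kw_result`: `H`, `df`, `p_value`,
#'   `tie_correction`, `n`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) > 0)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  k <- length(unique(groups))
  if (k < 2) abort("Kruskal-Wallis needs at least two groups.",
                   class = "scalemarks_degenerate_error")
  n <- length(values)
  r <- rank(values)  # midranks
  tie_sizes <- table(values)
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n)
  if (C <= 0) {
    abort("All observations are tied; the Kruskal-Wallis statistic is undefined.",
          class = "scalemarks_degenerate_error")
  }
  rank_sums <- tapply(r, groups, sum)
  sizes <- tapply(r, groups, length)
  H <- (12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)) / C
  df <- k - 1
  structure(list(H = as.numeric(H), df = df,
                 p_value = pchisq(H, df, lower.tail = FALSE),
                 tie_correction = as.numeric(C), n = n),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (tie correction %.4f, n = %d)\n",
              x$H, x$df, x$p_value, x$tie_correction, x$n))
  invisible(x)
}

#' Kruskal-Wallis screen of locality effects on mark counts
#'
#' Tests whether mark counts differ between sampling localities before any
#' modelling. By default the unit of analysis is the individual (its mean
#' mark count over readable scales), avoiding pseudo-replication from the
#' repeated measures within a specimen; `per_scale = TRUE` uses every
#' readable scale as an observation instead.
#'
#' @param data A valid scale table (a single species; filter first if
#'   mixed).
#' @param per_scale Use individual scales rather than per-specimen means.
#' @return A `kw_result`.
#' @export
kw_locality_screen <- function(data, per_scale = FALSE) {
  data <- filter_readable(data)
  if (per_scale) {
    kruskal_wallis(data$marks, data$locality)
  } else {
    per_ind <- dplyr::summarise(
      dplyr::group_by(data, .data$specimen_id, .data$locality),
      mean_marks = mean(.data$marks), .groups = "drop")
    kruskal_wallis(per_ind$mean_marks, per_ind$locality)
  }
}

#' Pearson correlation between scale length and standard length
#'
#' Computed across scales, pairing each scale's length with its specimen's
#' standard length.
#'
#' @param data A valid scale table.
#' @return The correlation coefficient.
#' @export
length_correlation <- function(data) {
  data <- validate_scales(data)
  ok <- !is.na(data$scale_length) & !is.na(data$standard_length_cm)
  x <- data$scale_length[ok]; y <- data$standard_length_cm[ok]
  if (length(x) < 3) abort("Need at least 3 complete length pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a length variable has zero variance.",
          class = "scalemarks_degenerate_error")
  }
  cor(x, y)
}
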