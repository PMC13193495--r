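# Per-scale records: schema, validation, CSV I/O, readability filter.
#
# One row = one scale from one body area of one specimen. Mark counts are
# structurally absent (NA) for damaged/regenerated scales: zero is a legal
# count for a readable scale and must not be conflated with "not counted".

#' Canonical column order for a scale table
#' @keywords internal
scale_table_columns <- c(
  "specimen_id", "species", "locality", "sex", "standard_length_cm",
  "area", "scale_length", "scale_width", "scale_radius", "status", "marks"
)

#' Valid body-area codes
#'
#' The lateral surface is divided into nine areas: horizontal position
#' (A = anterior, C = central, P = posterior) crossed with vertical position
#' (D = dorsal, M = middle, V = ventral).
#'
#' @return Character vector of the nine two-letter codes ("AD", "AM", ...).
#' @export
#' @examples
#' scale_areas()
scale_areas <- function() {
  as.vector(t(outer(c("A", "C", "P"), c("D", "M", "V"), paste0)))
}

scale_species <- c("cephalus", "curema")
scale_localities <- c("SL", "SAB", "LM", "TA", "CA", "ME")
scale_sexes <- c("F", "M")
scale_statuses <- c("good", "damaged", "regenerated")

#' Validate a scale table
#'
#' Checks the schema and row-level invariants of a per-scale data frame:
#' known category levels, strictly positive lengths, valid area codes, mark
#' counts present exactly for scales in good status, and within-specimen
#' consistency of species, locality, sex and standard length.
#'
#' @param data A data frame of per-scale records with the columns of
#'   [scale_table_columns].
#' @return The validated data as a tibble (invisibly identical content),
#'   with `marks` as integer and categorical columns as character.
#' @export
validate_scales <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of scale records.")
  missing_cols <- setdiff(scale_table_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Scale table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), class = "scalemarks_schema_error")
  }
  unknown <- setdiff(names(data), scale_table_columns)
  if (length(unknown) > 0) {
    abort(paste0("Scale table has unknown column(s): ",
                 paste(unknown, collapse = ", ")), class = "scalemarks_schema_error")
  }
  data <- tibble::as_tibble(data)[scale_table_columns]
  if (nrow(data) == 0) abort("Scale table must contain at least one record.")

  data$specimen_id <- as.character(data$specimen_id)
  for (col in c("species", "locality", "sex", "area", "status")) {
    data[[col]] <- as.character(data[[col]])
  }
  data$marks <- suppressWarnings(as.integer(data$marks))

  row_fail <- function(ok, what) {
    if (all(ok)) return(invisible(NULL))
    rows <- which(!ok)
    abort(paste0("Invalid ", what, " in row(s): ",
                 paste(head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5) else ""),
          class = "scalemarks_validation_error")
  }

  row_fail(data$species %in% scale_species, "species")
  row_fail(data$locality %in% scale_localities, "locality")
  row_fail(data$sex %in% scale_sexes, "sex")
  row_fail(data$area %in% scale_areas(), "area code")
  row_fail(data$status %in% scale_statuses, "status")
  row_fail(is.finite(data$standard_length_cm) & data$standard_length_cm > 0,
           "standard_length_cm (must be a positive real)")
  row_fail(is.finite(data$scale_length) & data$scale_length > 0,
           "scale_length (must be a positive real)")
  row_fail(is.na(data$scale_width) | data$scale_width > 0,
           "scale_width (must be positive when present)")
  row_fail(is.na(data$scale_radius) | data$scale_radius > 0,
           "scale_radius (must be positive when present)")
  good <- data$status == "good"
  row_fail(!good | (!is.na(data$marks) & data$marks >= 0),
           "marks (must be a non-negative integer for good scales)")
  row_fail(good | is.na(data$marks),
           "marks (must be absent for damaged/regenerated scales)")

  per_spec <- dplyr::summarise(
    dplyr::group_by(data, .data$specimen_id),
    n_species = dplyr::n_distinct(.data$species),
    n_locality = dplyr::n_distinct(.data$locality),
    n_sex = dplyr::n_distinct(.data$sex),
    n_sl = dplyr::n_distinct(.data$standard_length_cm),
    .groups = "drop"
  )
  bad <- per_spec$specimen_id[per_spec$n_species > 1 | per_spec$n_locality > 1 |
                                per_spec$n_sex > 1 | per_spec$n_sl > 1]
  if (length(bad) > 0) {
    abort(paste0("Specimen-level covariates disagree across rows for specimen(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "scalemarks_validation_error")
  }
  data
}

#' Read a scale table from CSV
#'
#' Reads a per-scale CSV with the canonical header (see
#' [scale_table_columns]) and validates it. An empty `marks` field is read as
#' absent (NA), which is only legal for damaged/regenerated scales.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of scale records, row order preserved.
#' @seealso [write_scale_table()], [validate_scales()]
#' @export
read_scale_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      specimen_id = readr::col_character(),
      species = readr::col_character(),
      locality = readr::col_character(),
      sex = readr::col_character(),
      standard_length_cm = readr::col_double(),
      area = readr::col_character(),
      scale_length = readr::col_double(),
      scale_width = readr::col_double(),
      scale_radius = readr::col_double(),
      status = readr::col_character(),
      marks = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE, lazy = FALSE
  )
  validate_scales(data)
}

#' Write a scale table to CSV
#'
#' Writes the canonical comma-separated UTF-8 representation: header row,
#' one row per scale, absent marks as an empty field. A write/read round
#' trip reproduces the table field-by-field, and write-read-write is
#' byte-identical.
#'
#' @param data A valid scale table (validated before writing).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_scale_table <- function(data, path) {
  data <- validate_scales(data)
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Keep only readable scales
#'
#' Drops damaged and regenerated scales, whose abnormal regrowth invalidates
#' the growth-mark record; every retained row has a mark count.
#'
#' @param data A valid scale table.
#' @return Tibble of the rows with `status == "good"`.
#' @export
filter_readable <- function(data) {
  data <- validate_scales(data)
  kept <- dplyr::filter(data, .data$status == "good")
  if (nrow(kept) == 0) {
    abort("No readable scales: every record is damaged or regenerated.",
          class = "scalemarks_no_readable_error")
  }
  kept
}
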