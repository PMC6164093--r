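#' Read a food composition table
#'
#' Delimited text with columns `product_id`, `name`, `vitd_ug_per_100g`,
#' and optionally `group_id` (group tags enable the per-group
#' decomposition of record intakes).
#'
#' @param path File path (CSV).
#' @return Composition tibble.
#' @export
read_composition <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    product_id = readr::col_character(),
    name = readr::col_character(),
    vitd_ug_per_100g = readr::col_double(),
    .default = readr::col_character()
  ))
  check_composition(tab)
}

check_composition <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("product_id", "vitd_ug_per_100g")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("Composition table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(table$product_id)) {
    abort("Composition table has duplicated product_ids")
  }
  if (any(!is.finite(table$vitd_ug_per_100g) | table$vitd_ug_per_100g < 0)) {
    abort("Composition contents must be finite and >= 0")
  }
  table
}

#' Derive a composition table from a questionnaire specification
#'
#' Turns every fixed item and every candidate product of an instrument
#' into a composition-table row, converting the per-serving content back
#' to micrograms per 100 g via the item's serving size. Used by the
#' synthetic cohort generator so records and FFQ answers draw on one
#' consistent content source; real studies supply national food
#' composition tables instead.
#'
#' @param spec An `ffq_spec`.
#' @return Composition tibble (`product_id`, `name`, `vitd_ug_per_100g`,
#'   `group_id`).
#' @export
spec_composition <- function(spec) {
  stopifnot(inherits(spec, "ffq_spec"))
  fixed <- spec$items |>
    dplyr::filter(.data$selection_mode == "FIXED") |>
    dplyr::transmute(product_id = .data$item_id, name = .data$description,
                     vitd_ug_per_100g = 100 * .data$content_per_serving_ug /
                       .data$serving_grams,
                     group_id = .data$group_id)
  cand <- spec_candidates(spec)
  if (nrow(cand) > 0) {
    items <- spec$items
    cand <- cand |>
      dplyr::transmute(
        product_id = .data$product_id, name = .data$name,
        vitd_ug_per_100g = 100 * .data$content_per_serving_ug /
          items$serving_grams[match(.data$item_id, items$item_id)],
        group_id = items$group_id[match(.data$item_id, items$item_id)])
  }
  check_composition(dplyr::bind_rows(fixed, cand))
}

validate_record_days <- function(entries) {
  days <- dplyr::distinct(entries, .data$respondent_id, .data$day_index,
                          .data$day_type)
  per <- days |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day_index),
      ok_index = all(.data$day_index %in% 1:3),
      n_weekday = sum(.data$day_type == "WEEKDAY"),
      n_weekend = sum(.data$day_type == "WEEKEND"),
      .groups = "drop")
  bad <- per[per$n_days != 3 | !per$ok_index |
               per$n_weekday != 2 | per$n_weekend != 1, ]
  if (nrow(bad) > 0) {
    abort(paste0("Invalid 3-day record (need day_index 1-3, two WEEKDAY and ",
                 "one WEEKEND day) for respondent(s): ",
                 paste(utils::head(bad$respondent_id, 5), collapse = ", ")))
  }
  invisible(entries)
}

#' Score 3-day dietary records into mean daily vitamin D intake
#'
#' Each respondent's record must cover exactly three days (indices 1-3,
#' two weekdays and one weekend day). The daily intake is the grand sum of
#' grams x content/100 g over all entries divided by 3; a day on which
#' nothing vitamin-D-bearing was eaten still counts in the divisor.
#'
#' @param entries Data frame with columns `respondent_id`, `day_index`
#'   (1-3), `day_type` (`"WEEKDAY"`/`"WEEKEND"`), `product_id`, `grams`
#'   (> 0). Extra columns (meal time, location) pass through unused.
#' @param composition Composition tibble (see [read_composition()]); a
#'   `group_id` column enables per-group decomposition, otherwise all
#'   intake lands in the single group `"unassigned"`.
#' @return Tibble in the same shape as [score_ffq()] with
#'   `source = "RECORD"`.
#' @export
score_record <- function(entries, composition) {
  entries <- tibble::as_tibble(entries)
  composition <- check_composition(composition)
  need <- c("respondent_id", "day_index", "day_type", "product_id", "grams")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols) > 0) {
    abort(paste0("Record entries lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(entries$grams) | entries$grams <= 0)) {
    abort("Record entry grams must be finite and > 0")
  }
  validate_record_days(entries)
  pos <- match(entries$product_id, composition$product_id)
  if (anyNA(pos)) {
    abort(paste0("Unknown product_id(s) in records: ",
                 paste(unique(entries$product_id[is.na(pos)]), collapse = ", ")))
  }
  entries$entry_ug <- entries$grams * composition$vitd_ug_per_100g[pos] / 100
  entries$group_id <- if ("group_id" %in% names(composition)) {
    dplyr::coalesce(composition$group_id[pos], "unassigned")
  } else {
    "unassigned"
  }
  group_order <- unique(entries$group_id)
  per_group <- entries |>
    dplyr::group_by(.data$respondent_id, .data$group_id) |>
    dplyr::summarise(group_ug = sum(.data$entry_ug) / 3, .groups = "drop")
  grid <- tidyr::expand_grid(
    respondent_id = unique(entries$respondent_id),
    group_id = group_order
  )
  dplyr::left_join(grid, per_group, by = c("respondent_id", "group_id")) |>
    dplyr::mutate(group_ug = dplyr::coalesce(.data$group_ug, 0),
                  source = "RECORD", .after = "respondent_id") |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::mutate(
      total_ug = sum(.data$group_ug),
      share_pct = dplyr::if_else(.data$total_ug > 0,
                                 100 * .data$group_ug / .data$total_ug, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("respondent_id", "source", "group_id", "group_ug",
                  "share_pct", "total_ug") |>
    dplyr::arrange(.data$respondent_id, match(.data$group_id, group_order))
}

#' Read and write the delimited 3-day record format
#'
#' @param path File path (CSV).
#' @return `read_records()` returns the entries tibble.
#' @export
read_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    day_index = readr::col_integer(),
    day_type = readr::col_character(),
    product_id = readr::col_character(),
    grams = readr::col_double(),
    .default = readr::col_character()
  ))
}

#' @rdname read_records
#' @param entries Record entries tibble.
#' @export
write_records <- function(entries, path) {
  readr::write_csv(tibble::as_tibble(entries), path)
  invisible(path)
}

#' Classify vitamin D intake adequacy against the EAR cutpoint
#'
#' The Estimated Average Requirement for vitamin D is 10 micrograms/day
#' (Institute of Medicine); an intake exactly at the cutpoint counts as
#' adequate.
#'
#' @param intake_ug Numeric vector of daily intakes (micrograms, >= 0).
#' @param ear_ug EAR cutpoint, default 10.
#' @return Character vector, `"ADEQUATE"` or `"INADEQUATE"`.
#' @examples
#' classify_adequacy(c(9.99, 10))
#' @export
classify_adequacy <- function(intake_ug, ear_ug = 10) {
  if (any(!is.finite(intake_ug) | intake_ug < 0)) {
    abort("Intakes must be finite and >= 0")
  }
  ifelse(intake_ug >= ear_ug, "ADEQUATE", "INADEQUATE")
}
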