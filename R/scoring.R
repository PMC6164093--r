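#' Resolve the per-serving vitamin D content for one answered item
#'
#' Implements the individualized calculation key. Fixed items return the
#' instrument's content. Choose-from-list items (fish questions) return the
#' arithmetic mean of the per-serving contents of the 1-2 products the
#' respondent selected; with a single selection the mean is that product's
#' content. Free-text items return the caller-supplied content.
#'
#' @param spec An `ffq_spec`.
#' @param item_id Item to resolve.
#' @param selected_products Character vector of product ids (length 1-2),
#'   required for choose-from-list items.
#' @param free_text_content_ug Content in micrograms per serving for
#'   free-text items.
#' @param respondent_id Used only to name the respondent in error messages.
#' @return Vitamin D content in micrograms per serving (scalar).
#' @examples
#' spec <- cro_video_ffq()
#' resolve_item_content(spec, "fish_high_vitd", c("salmon", "herring"))
#' @export
resolve_item_content <- function(spec, item_id,
                                 selected_products = character(),
                                 free_text_content_ug = NULL,
                                 respondent_id = NULL) {
  stopifnot(inherits(spec, "ffq_spec"))
  idx <- match(item_id, spec$items$item_id)
  if (is.na(idx)) abort(paste0("Unknown item_id: ", item_id))
  row <- spec$items[idx, ]
  who <- if (is.null(respondent_id)) "" else paste0(" (respondent ", respondent_id, ")")
  mode <- row$selection_mode
  if (mode == "FIXED") {
    return(row$content_per_serving_ug)
  }
  if (mode == "CHOOSE_FROM_LIST") {
    selected_products <- selected_products[!is.na(selected_products) &
                                             nzchar(selected_products)]
    if (length(selected_products) < 1 || length(selected_products) > 2) {
      abort(paste0("Item ", item_id, who,
                   ": choose-from-list items need 1-2 selected products"))
    }
    cand <- row$candidates[[1]]
    pos <- match(selected_products, cand$product_id)
    if (anyNA(pos)) {
      abort(paste0("Item ", item_id, who, ": unknown product_id ",
                   paste(selected_products[is.na(pos)], collapse = ", ")))
    }
    return(mean(cand$content_per_serving_ug[pos]))
  }
  # FREE_TEXT
  if (is.null(free_text_content_ug) || is.na(free_text_content_ug)) {
    abort(paste0("Item ", item_id, who,
                 ": free-text items with nonzero frequency need a supplied",
                 " content (ug per serving)"))
  }
  as.numeric(free_text_content_ug)
}

normalize_responses <- function(responses) {
  responses <- tibble::as_tibble(responses)
  need <- c("respondent_id", "item_id", "servings_per_period")
  missing_cols <- setdiff(need, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("Responses lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"administration" %in% names(responses)) responses$administration <- "FFQ1"
  if (!"selected_products" %in% names(responses)) {
    responses$selected_products <- NA_character_
  }
  if (!"free_text_content_ug" %in% names(responses)) {
    responses$free_text_content_ug <- NA_real_
  }
  responses
}

#' Score FFQ responses into daily vitamin D intake
#'
#' Converts frequency answers into micrograms of vitamin D per day:
#' for each item, servings-per-period times the period's daily conversion
#' factor times the resolved per-serving content, summed over items, with
#' a per-group decomposition. All respondents and administrations present
#' in `responses` are scored in one call.
#'
#' Each (respondent, administration) must answer every questionnaire item
#' exactly once; a zero frequency is a valid answer, a missing one is an
#' error. Zero-frequency answers never require product selections or
#' free-text content.
#'
#' @param responses Data frame with columns `respondent_id`,
#'   `administration` (`"FFQ1"`/`"FFQ2"`; defaults to FFQ1 when absent),
#'   `item_id`, `servings_per_period` (non-negative, fractions allowed),
#'   `selected_products` (semicolon-joined product ids for
#'   choose-from-list items), `free_text_content_ug`.
#' @param spec An `ffq_spec`.
#' @return A tibble with one row per respondent x administration x group:
#'   `respondent_id`, `source`, `group_id`, `group_ug` (micrograms/day from
#'   that group), `share_pct` (percent of the total; all zero when the
#'   total is zero), `total_ug` (the respondent's daily total, repeated
#'   across that respondent's rows). Groups appear in instrument order.
#' @examples
#' spec <- cro_video_ffq()
#' resp <- blank_responses(spec, "r1")
#' resp$servings_per_period[resp$item_id == "egg"] <- 3  # 3 eggs a week
#' score_ffq(resp, spec)
#' @export
score_ffq <- function(responses, spec) {
  stopifnot(inherits(spec, "ffq_spec"))
  responses <- normalize_responses(responses)
  items <- spec$items
  # coverage: every item exactly once per respondent x administration
  counts <- dplyr::count(responses, .data$respondent_id, .data$administration,
                         .data$item_id)
  bad_dup <- counts[counts$n > 1, ]
  if (nrow(bad_dup) > 0) {
    abort(paste0("Duplicate answers: ",
                 paste(utils::head(paste(bad_dup$respondent_id, bad_dup$item_id,
                                         sep = "/"), 5), collapse = ", ")))
  }
  unknown <- setdiff(unique(responses$item_id), items$item_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown item_id in responses: ",
                 paste(unknown, collapse = ", ")))
  }
  full <- tidyr::expand_grid(
    dplyr::distinct(responses, .data$respondent_id, .data$administration),
    item_id = items$item_id
  )
  missing_ans <- dplyr::anti_join(
    full, responses, by = c("respondent_id", "administration", "item_id"))
  if (nrow(missing_ans) > 0) {
    abort(paste0("Missing answers (zero frequency must be stated): ",
                 paste(utils::head(paste(missing_ans$respondent_id,
                                         missing_ans$item_id, sep = "/"), 5),
                       collapse = ", ")))
  }
  if (any(responses$servings_per_period < 0 |
            !is.finite(responses$servings_per_period))) {
    abort("servings_per_period must be finite and >= 0")
  }

  scored <- responses
  scored$daily_factor <- period_to_daily_factor(
    items$period[match(scored$item_id, items$item_id)])
  scored$group_id <- items$group_id[match(scored$item_id, items$item_id)]
  scored$content_ug <- purrr::pmap_dbl(
    list(scored$item_id, scored$selected_products,
         scored$free_text_content_ug, scored$servings_per_period,
         scored$respondent_id),
    function(item, sel, free, freq, who) {
      if (freq == 0) return(0)  # content irrelevant at zero frequency
      sel_vec <- if (is.na(sel) || !nzchar(sel)) character() else {
        strsplit(sel, ";", fixed = TRUE)[[1]]
      }
      resolve_item_content(spec, item, sel_vec, free, respondent_id = who)
    })
  scored$item_ug <- scored$servings_per_period * scored$daily_factor *
    scored$content_ug

  per_group <- scored |>
    dplyr::group_by(.data$respondent_id, source = .data$administration,
                    .data$group_id) |>
    dplyr::summarise(group_ug = sum(.data$item_ug), .groups = "drop")
  # zero-fill groups so every respondent carries every group in spec order
  grid <- tidyr::expand_grid(
    dplyr::distinct(per_group, .data$respondent_id, .data$source),
    group_id = spec$groups$group_id
  )
  per_group <- dplyr::left_join(grid, per_group,
                                by = c("respondent_id", "source", "group_id")) |>
    dplyr::mutate(group_ug = dplyr::coalesce(.data$group_ug, 0)) |>
    dplyr::group_by(.data$respondent_id, .data$source) |>
    dplyr::mutate(
      total_ug = sum(.data$group_ug),
      share_pct = dplyr::if_else(.data$total_ug > 0,
                                 100 * .data$group_ug / .data$total_ug, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("respondent_id", "source", "group_id", "group_ug",
                  "share_pct", "total_ug") |>
    dplyr::arrange(.data$respondent_id, .data$source,
                   match(.data$group_id, spec$groups$group_id))
  per_group
}

#' All-zero responses for a set of respondents
#'
#' Convenience constructor: one zero-frequency answer per item for each
#' respondent, ready to be edited.
#'
#' @param spec An `ffq_spec`.
#' @param respondent_ids Character vector.
#' @param administration `"FFQ1"` or `"FFQ2"`.
#' @return Responses tibble accepted by [score_ffq()].
#' @export
blank_responses <- function(spec, respondent_ids, administration = "FFQ1") {
  stopifnot(inherits(spec, "ffq_spec"))
  tidyr::expand_grid(
    respondent_id = respondent_ids,
    administration = administration,
    item_id = spec$items$item_id
  ) |>
    dplyr::mutate(servings_per_period = 0,
                  selected_products = NA_character_,
                  free_text_content_ug = NA_real_)
}

#' Collapse scores to one row per respondent and source
#'
#' @param scores Output of [score_ffq()] or [score_record()].
#' @return Tibble `respondent_id`, `source`, `total_ug`.
#' @export
intake_totals <- function(scores) {
  dplyr::distinct(tibble::as_tibble(scores), .data$respondent_id,
                  .data$source, .data$total_ug)
}

#' Summarise the per-group contribution to daily vitamin D intake
#'
#' For a cohort scored from one source, summarises each product group's
#' absolute contribution (micrograms/day) and its percent share of the
#' respondent's total. Respondents with zero total intake have undefined
#' shares and are excluded from the share summaries (their microgram
#' contributions still count).
#'
#' @param scores Output of [score_ffq()] (or [score_record()] with group
#'   tags), all rows from the same source.
#' @return Tibble, one row per group in instrument order: mean, sd, median,
#'   min, max of the percent share, and the same summaries of micrograms
#'   per day.
#' @export
group_shares <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) abort("group_shares() needs at least one scored respondent")
  if (dplyr::n_distinct(scores$source) != 1) {
    abort("group_shares() expects scores from a single source")
  }
  group_order <- unique(scores$group_id)
  ug <- scores |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      mean_ug = mean(.data$group_ug), sd_ug = sd(.data$group_ug),
      median_ug = median(.data$group_ug),
      min_ug = min(.data$group_ug), max_ug = max(.data$group_ug),
      .groups = "drop")
  pct <- scores |>
    dplyr::filter(.data$total_ug > 0) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      mean_pct = mean(.data$share_pct), sd_pct = sd(.data$share_pct),
      median_pct = median(.data$share_pct),
      min_pct = min(.data$share_pct), max_pct = max(.data$share_pct),
      .groups = "drop")
  dplyr::left_join(pct, ug, by = "group_id") |>
    dplyr::arrange(match(.data$group_id, group_order))
}

#' Read and write the delimited respondent-response format
#'
#' One row per (respondent, administration, item): `respondent_id`,
#' `administration`, `item_id`, `servings_per_period`,
#' `selected_products` (semicolon-joined), `free_text_content_ug`.
#'
#' @param path File path (CSV).
#' @return `read_responses()` returns the responses tibble;
#'   `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    administration = readr::col_character(),
    item_id = readr::col_character(),
    servings_per_period = readr::col_double(),
    selected_products = readr::col_character(),
    free_text_content_ug = readr::col_double()
  ))
}

#' @rdname read_responses
#' @param responses Responses tibble.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(normalize_responses(responses), path)
  invisible(path)
}

#' Write scored intakes as delimited text
#'
#' @param scores Output of [score_ffq()] or [score_record()].
#' @param path File path (CSV).
#' @export
write_intakes <- function(scores, path) {
  readr::write_csv(tibble::as_tibble(scores), path)
  invisible(path)
}
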