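#' Frequency periods and their daily conversion factors
#'
#' Questionnaire items ask for servings consumed per day, week, or month.
#' All intakes are expressed per day; a month is taken as 365.25 / 12 days
#' so that daily, weekly, and monthly factors compose to exactly one year.
#'
#' @param period Character vector with values `"DAILY"`, `"WEEKLY"`, or
#'   `"MONTHLY"`.
#' @return Numeric vector of multipliers converting servings-per-period to
#'   servings-per-day: 1, 1/7, and 12/365.25 respectively.
#' @examples
#' period_to_daily_factor(c("DAILY", "WEEKLY", "MONTHLY"))
#' @export
period_to_daily_factor <- function(period) {
  factors <- c(DAILY = 1, WEEKLY = 1 / 7, MONTHLY = 12 / 365.25)
  bad <- setdiff(unique(period), names(factors))
  if (length(bad) > 0) {
    abort(paste0("Unknown frequency period: ", paste(bad, collapse = ", ")))
  }
  unname(factors[period])
}

ffq_periods <- c("DAILY", "WEEKLY", "MONTHLY")
ffq_selection_modes <- c("FIXED", "CHOOSE_FROM_LIST", "FREE_TEXT")

#' Construct a questionnaire specification
#'
#' Builds an `ffq_spec` object from its components. Most users load a spec
#' from a config file with [load_questionnaire()] or use the packaged
#' instrument [cro_video_ffq()].
#'
#' @param name Instrument name.
#' @param groups Data frame with columns `group_id`, `label` (ordered).
#' @param items Data frame with columns `item_id`, `group_id`,
#'   `description`, `serving_grams`, `household_measure`, `period`,
#'   `selection_mode`, `content_per_serving_ug` (NA when unresolved), and a
#'   list-column `candidates` of data frames (`product_id`, `name`,
#'   `content_per_serving_ug`) for choose-from-list items.
#' @param validate Abort if the spec violates its invariants? Default TRUE.
#' @return An `ffq_spec` object.
#' @export
ffq_spec <- function(name, groups, items, validate = TRUE) {
  groups <- tibble::as_tibble(groups)
  items <- tibble::as_tibble(items)
  if (!"candidates" %in% names(items)) {
    items$candidates <- vector("list", nrow(items))
  }
  if (!"content_per_serving_ug" %in% names(items)) {
    items$content_per_serving_ug <- NA_real_
  }
  items$candidates <- lapply(items$candidates, function(cand) {
    if (is.null(cand)) NULL else tibble::as_tibble(cand)
  })
  spec <- structure(
    list(name = as.character(name), groups = groups, items = items),
    class = "ffq_spec"
  )
  if (validate) {
    problems <- validate_questionnaire(spec)
    if (length(problems) > 0) {
      abort(c("Invalid questionnaire specification:", problems))
    }
  }
  spec
}

#' @export
print.ffq_spec <- function(x, ...) {
  cat("<ffq_spec> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$items), " items in ", nrow(x$groups), " groups\n", sep = "")
  counts <- table(factor(x$items$selection_mode, levels = ffq_selection_modes))
  cat("  selection modes: ",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load a questionnaire specification from a YAML config file
#'
#' The config dialect is plain YAML: a `name`, an ordered `groups` list
#' (`group_id`, `label`), and an ordered `items` list carrying serving size
#' in grams, frequency period, selection mode, and the vitamin D content
#' per serving in micrograms (stored per serving, as the calculation key
#' defines it). Choose-from-list items carry `candidates`; free-text items
#' leave content unresolved until scoring.
#'
#' @param path Path to the YAML file.
#' @return An `ffq_spec` object; aborts with a format error when the file
#'   does not parse and with a validation error naming the offending item
#'   when an invariant is violated.
#' @seealso [cro_video_ffq()], [write_questionnaire()],
#'   [validate_questionnaire()]
#' @export
load_questionnaire <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Questionnaire config not found: ", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort(paste0("Format error parsing questionnaire config '", path,
                   "': ", conditionMessage(e)))
    }
  )
  if (is.null(raw) || !is.list(raw) ||
      !all(c("name", "groups", "items") %in% names(raw))) {
    abort(paste0("Format error: '", path,
                 "' is empty or lacks the name/groups/items keys"))
  }
  groups <- dplyr::bind_rows(lapply(raw$groups, tibble::as_tibble))
  items <- dplyr::bind_rows(lapply(raw$items, function(it) {
    cand <- it$candidates
    it$candidates <- NULL
    row <- tibble::as_tibble(it)
    if (!"content_per_serving_ug" %in% names(row)) {
      row$content_per_serving_ug <- NA_real_
    }
    row$serving_grams <- as.numeric(row$serving_grams)
    row$content_per_serving_ug <- as.numeric(row$content_per_serving_ug)
    row$candidates <- if (is.null(cand)) {
      list(NULL)
    } else {
      list(dplyr::bind_rows(lapply(cand, tibble::as_tibble)))
    }
    row
  }))
  cols <- c("item_id", "group_id", "description", "serving_grams",
            "household_measure", "period", "selection_mode",
            "content_per_serving_ug", "candidates")
  missing_cols <- setdiff(cols, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("Format error: items lack fields ",
                 paste(missing_cols, collapse = ", ")))
  }
  ffq_spec(raw$name, groups, items[cols])
}

#' Serialize a questionnaire specification to YAML
#'
#' Writing then reloading yields a field-by-field identical spec.
#'
#' @param spec An `ffq_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(spec, path) {
  stopifnot(inherits(spec, "ffq_spec"))
  items <- lapply(seq_len(nrow(spec$items)), function(i) {
    row <- spec$items[i, ]
    out <- list(
      item_id = row$item_id,
      group_id = row$group_id,
      description = row$description,
      serving_grams = row$serving_grams,
      household_measure = row$household_measure,
      period = row$period,
      selection_mode = row$selection_mode
    )
    if (!is.na(row$content_per_serving_ug)) {
      out$content_per_serving_ug <- row$content_per_serving_ug
    }
    cand <- row$candidates[[1]]
    if (!is.null(cand) && nrow(cand) > 0) {
      out$candidates <- lapply(seq_len(nrow(cand)), function(j) {
        as.list(cand[j, c("product_id", "name", "content_per_serving_ug")])
      })
    }
    out
  })
  groups <- lapply(seq_len(nrow(spec$groups)), function(i) {
    as.list(spec$groups[i, c("group_id", "label")])
  })
  yaml::write_yaml(list(name = spec$name, groups = groups, items = items),
                   path, precision = 15)
  invisible(path)
}

#' Check a questionnaire specification against its invariants
#'
#' Never raises; returns one message per violation (empty character vector
#' when the spec is valid). Checked invariants: unique item ids, known
#' groups, positive serving sizes, valid periods and selection modes,
#' resolved non-negative content for fixed items, at least two candidates
#' for choose-from-list items, globally unique candidate product ids, and
#' the instrument's content floor of 0.01 ug per 100 g (scaled to the
#' serving) for every resolved content.
#'
#' @param spec An `ffq_spec` (or a list shaped like one).
#' @return Character vector of violation messages.
#' @export
validate_questionnaire <- function(spec) {
  msgs <- character()
  say <- function(...) msgs <<- c(msgs, paste0(...))
  items <- spec$items
  groups <- spec$groups
  dup <- unique(items$item_id[duplicated(items$item_id)])
  for (d in dup) say("duplicate item_id: ", d)
  unknown_group <- setdiff(unique(items$group_id), groups$group_id)
  for (g in unknown_group) {
    ids <- items$item_id[items$group_id == g]
    say("item(s) ", paste(ids, collapse = ", "), " reference unknown group: ", g)
  }
  all_products <- character()
  for (i in seq_len(nrow(items))) {
    row <- items[i, ]
    id <- row$item_id
    if (!is.finite(row$serving_grams) || row$serving_grams <= 0) {
      say("item ", id, ": serving_grams must be > 0")
    }
    if (!row$period %in% ffq_periods) {
      say("item ", id, ": unknown period '", row$period, "'")
    }
    if (!row$selection_mode %in% ffq_selection_modes) {
      say("item ", id, ": unknown selection_mode '", row$selection_mode, "'")
      next
    }
    cand <- row$candidates[[1]]
    floor_ug <- 0.01 * row$serving_grams / 100  # 0.01 ug/100 g at this serving
    if (row$selection_mode == "FIXED") {
      if (is.na(row$content_per_serving_ug)) {
        say("item ", id, ": FIXED items need a resolved content_per_serving_ug")
      } else if (row$content_per_serving_ug < floor_ug) {
        say("item ", id, ": content below the 0.01 ug/100 g floor")
      }
    } else if (row$selection_mode == "CHOOSE_FROM_LIST") {
      if (is.null(cand) || nrow(cand) < 2) {
        say("item ", id, ": CHOOSE_FROM_LIST items need >= 2 candidate products")
      } else {
        bad <- cand$product_id[!is.finite(cand$content_per_serving_ug) |
                                 cand$content_per_serving_ug < floor_ug]
        for (p in bad) say("item ", id, ": candidate ", p,
                           " content below the 0.01 ug/100 g floor")
      }
    }
    if (!is.null(cand) && nrow(cand) > 0) {
      all_products <- c(all_products, cand$product_id)
    }
  }
  dup_prod <- unique(all_products[duplicated(all_products)])
  for (p in dup_prod) {
    say("candidate product ", p, " belongs to more than one item")
  }
  msgs
}

#' The packaged Cro-VIDEO-FFQ instrument
#'
#' Loads the packaged key of the Croatian adaptation of the vitamin-D-only
#' brief FFQ: 22 question-level items in 7 product groups, each with its
#' serving size, frequency period, and vitamin D content per serving in
#' micrograms. The three fresh/smoked-fish questions are choose-from-list
#' items resolved per respondent as the mean content of the 1-2 products
#' they most commonly consume; the "other fish" and "fortified dairy"
#' questions are free-text items whose content the caller supplies at
#' scoring time.
#'
#' @return An `ffq_spec` with 22 items and 7 groups.
#' @examples
#' spec <- cro_video_ffq()
#' nrow(spec$items)
#' @export
cro_video_ffq <- function() {
  path <- system.file("extdata", "cro_video_ffq.yaml", package = "vidffq",
                      mustWork = TRUE)
  load_questionnaire(path)
}

#' Candidate products of a questionnaire, one row per product
#'
#' @param spec An `ffq_spec`.
#' @return Tibble with `item_id`, `product_id`, `name`,
#'   `content_per_serving_ug`.
#' @export
spec_candidates <- function(spec) {
  stopifnot(inherits(spec, "ffq_spec"))
  rows <- purrr::map2(spec$items$item_id, spec$items$candidates,
                      function(id, cand) {
                        if (is.null(cand) || nrow(cand) == 0) return(NULL)
                        dplyr::mutate(cand, item_id = id, .before = 1)
                      })
  dplyr::bind_rows(rows)
}
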