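format_pval <- function(p, digits = 4) {
  # printed reports never show a p of exactly 0
  ifelse(p < 1e-4, "<0.0001", formatC(round_half_up(p, digits),
                                      format = "f", digits = digits))
}

#' Full method-agreement report for one pair of intake methods
#'
#' Runs the whole agreement battery on one aligned pair of intake vectors:
#' Bland-Altman on both the log and natural scales, quartile
#' cross-classification with linearly weighted kappa, adequacy
#' cross-classification against the EAR cutpoint, Spearman rank
#' correlation, and ICC(3,1), then applies the a-priori decision criteria.
#'
#' @param pairs Data frame with columns `respondent_id`, `x`, `y` (see
#'   [pair_intakes()]); `x` is the questionnaire (first method), `y` the
#'   comparison method.
#' @param pair_label Human-readable label for the pair.
#' @param ba_scale Which Bland-Altman scale feeds the decision criteria:
#'   `"log"` (default, appropriate for right-skewed intakes) or
#'   `"natural"`.
#' @param ear_ug EAR cutpoint for adequacy classification, default 10.
#' @return A `vidffq_agreement` object with fields `bland_altman` (the
#'   criterion scale), `bland_altman_natural`, `bland_altman_log`,
#'   `quartiles`, `adequacy`, `spearman`, `icc`, `verdicts`.
#' @export
compare_methods <- function(pairs, pair_label = "method pair",
                            ba_scale = c("log", "natural"), ear_ug = 10) {
  ba_scale <- match.arg(ba_scale)
  pairs <- check_pairs(pairs, min_n = 8)
  ba_log <- bland_altman(pairs, scale = "log")
  ba_nat <- bland_altman(pairs, scale = "natural")
  report <- structure(list(
    pair_label = pair_label,
    ba_scale = toupper(ba_scale),
    bland_altman = if (ba_scale == "log") ba_log else ba_nat,
    bland_altman_log = ba_log,
    bland_altman_natural = ba_nat,
    quartiles = quartile_crossclass(pairs),
    adequacy = adequacy_crossclass(classify_adequacy(pairs$x, ear_ug),
                                   classify_adequacy(pairs$y, ear_ug)),
    spearman = spearman_r(pairs),
    icc = icc_consistency(pairs),
    n = nrow(pairs),
    ear_ug = ear_ug
  ), class = "vidffq_agreement")
  report$verdicts <- apply_criteria(report)
  report
}

#' Apply the a-priori validation decision criteria to a report
#'
#' Rules: Bland-Altman index at most 5% is PASS, above 5% up to the
#' a-priori 10% bound is BORDERLINE, above 10% FAIL; quartile
#' cross-classification passes when at least 50% are correctly classified
#' and, at the same time, fewer than 10% are grossly misclassified;
#' Spearman passes when r exceeds 0.5. Weighted kappa and ICC receive
#' their interpretation labels (Landis-Koch, Cicchetti) rather than
#' pass/fail verdicts.
#'
#' A pure function of the report: re-applying it yields the same verdicts.
#'
#' @param report A `vidffq_agreement` object.
#' @return Tibble `criterion`, `value`, `rule`, `verdict`.
#' @export
apply_criteria <- function(report) {
  stopifnot(inherits(report, "vidffq_agreement"))
  ba <- report$bland_altman$ba_index_pct
  q <- report$quartiles
  r <- report$spearman$r
  tibble::tibble(
    criterion = c("bland_altman_index", "quartile_crossclass",
                  "spearman_correlation", "weighted_kappa", "icc"),
    value = c(ba, q$correct_pct, r, q$weighted_kappa, report$icc$icc),
    rule = c(
      "index <= 5% positive; <= 10% borderline (a priori); else fail",
      ">= 50% correctly classified and < 10% grossly misclassified",
      "r > 0.5 positive",
      "Landis-Koch interpretation label",
      "Cicchetti interpretation label"
    ),
    verdict = c(
      if (ba <= 5) "PASS" else if (ba <= 10) "BORDERLINE" else "FAIL",
      if (q$correct_pct >= 50 && q$gross_pct < 10) "PASS" else "FAIL",
      if (r > 0.5) "PASS" else "FAIL",
      q$kappa_label,
      report$icc$label
    )
  )
}

#' @export
print.vidffq_agreement <- function(x, ...) {
  cat("<agreement report> ", x$pair_label, " (n=", x$n, ")\n", sep = "")
  print(x$bland_altman)
  print(x$quartiles)
  print(x$icc)
  cat("  Spearman r ", format(x$spearman$r, digits = 3), " (p ",
      format_pval(x$spearman$p), ")\n", sep = "")
  cat("  verdicts:\n")
  v <- x$verdicts
  for (i in seq_len(nrow(v))) {
    cat("    ", v$criterion[i], ": ", v$verdict[i],
        " (", format(v$value[i], digits = 3), "; ", v$rule[i], ")\n", sep = "")
  }
  invisible(x)
}

summarise_intake <- function(totals, ear_ug) {
  adequacy <- classify_adequacy(totals$total_ug, ear_ug)
  n <- nrow(totals)
  sh <- shapiro_normality(totals$total_ug)
  tibble::tibble(
    source = totals$source[1],
    n = n,
    mean_ug = mean(totals$total_ug),
    sd_ug = sd(totals$total_ug),
    median_ug = median(totals$total_ug),
    min_ug = min(totals$total_ug),
    max_ug = max(totals$total_ug),
    adequate_n = sum(adequacy == "ADEQUATE"),
    adequate_pct = 100 * sum(adequacy == "ADEQUATE") / n,
    inadequate_n = sum(adequacy == "INADEQUATE"),
    inadequate_pct = 100 * sum(adequacy == "INADEQUATE") / n,
    shapiro_w = sh$w,
    shapiro_p = sh$p,
    normal = sh$normal
  )
}

#' Run the full two-stage validation of a questionnaire
#'
#' Scores the first and second questionnaire administrations and the
#' 3-day dietary records of a cohort, restricts the analysis set to
#' completers (respondents present in all three collections), and runs
#' the whole validation battery: validity compares the first
#' administration with the record, reproducibility compares the two
#' administrations. Also produced: the per-source intake summary with
#' EAR adequacy and Shapiro-Wilk screening, Mann-Whitney comparisons of
#' the record vs first administration and first vs second administration,
#' and the per-group contribution summary from the first administration.
#'
#' Excluded (non-completer) respondents are reported by id; a cohort below
#' the recommended minimum of 50 respondents triggers a warning, and
#' fewer than 8 completers is an error (quartiles are not meaningful).
#'
#' @param responses Responses tibble covering administrations `"FFQ1"`
#'   and `"FFQ2"` (see [score_ffq()]).
#' @param records 3-day record entries tibble (see [score_record()]).
#' @param spec An `ffq_spec`.
#' @param composition Composition table for the records.
#' @param ear_ug EAR cutpoint, default 10.
#' @param ba_scale Bland-Altman scale feeding the criteria, default log.
#' @return A `vidffq_validation` object: `validity` and `reproducibility`
#'   agreement reports, `intake_summary`, `group_contributions`,
#'   `mann_whitney`, `n`, `excluded`.
#' @export
run_validation <- function(responses, records, spec, composition,
                           ear_ug = 10, ba_scale = c("log", "natural")) {
  ba_scale <- match.arg(ba_scale)
  responses <- normalize_responses(responses)
  records <- tibble::as_tibble(records)
  have_ffq1 <- unique(responses$respondent_id[responses$administration == "FFQ1"])
  have_ffq2 <- unique(responses$respondent_id[responses$administration == "FFQ2"])
  have_rec <- unique(records$respondent_id)
  completers <- intersect(intersect(have_ffq1, have_ffq2), have_rec)
  excluded <- setdiff(unique(c(have_ffq1, have_ffq2, have_rec)), completers)
  if (length(excluded) > 0) {
    inform(paste0("Excluding ", length(excluded),
                  " respondent(s) not present in all three collections: ",
                  paste(utils::head(sort(excluded), 10), collapse = ", "),
                  if (length(excluded) > 10) ", ..." else ""))
  }
  n <- length(completers)
  if (n < 8) abort("Need at least 8 completers for a meaningful validation")
  if (n < 50) {
    warn(paste0("Only ", n, " completers; at least 50-100 respondents are ",
                "recommended for FFQ validation"))
  }
  resp <- responses[responses$respondent_id %in% completers, ]
  recs <- records[records$respondent_id %in% completers, ]
  ffq_scores <- score_ffq(resp, spec)
  ffq1 <- ffq_scores[ffq_scores$source == "FFQ1", ]
  ffq2 <- ffq_scores[ffq_scores$source == "FFQ2", ]
  rec_scores <- score_record(recs, composition)
  t1 <- intake_totals(ffq1)
  t2 <- intake_totals(ffq2)
  tr <- intake_totals(rec_scores)
  validity <- compare_methods(pair_intakes(ffq1, rec_scores),
                              pair_label = "validity: FFQ1 vs 3-day record",
                              ba_scale = ba_scale, ear_ug = ear_ug)
  reproducibility <- compare_methods(pair_intakes(ffq1, ffq2),
                                     pair_label = "reproducibility: FFQ1 vs FFQ2",
                                     ba_scale = ba_scale, ear_ug = ear_ug)
  mw <- dplyr::bind_rows(
    dplyr::mutate(mann_whitney(tr$total_ug, t1$total_ug),
                  comparison = "RECORD vs FFQ1", .before = 1),
    dplyr::mutate(mann_whitney(t1$total_ug, t2$total_ug),
                  comparison = "FFQ1 vs FFQ2", .before = 1)
  )
  structure(list(
    n = n,
    completers = sort(completers),
    excluded = sort(excluded),
    validity = validity,
    reproducibility = reproducibility,
    intake_summary = dplyr::bind_rows(
      summarise_intake(tr, ear_ug),
      summarise_intake(t1, ear_ug),
      summarise_intake(t2, ear_ug)
    ),
    group_contributions = group_shares(ffq1),
    mann_whitney = mw,
    scores = list(ffq1 = ffq1, ffq2 = ffq2, record = rec_scores),
    ear_ug = ear_ug,
    ba_scale = toupper(ba_scale)
  ), class = "vidffq_validation")
}

#' @export
print.vidffq_validation <- function(x, ...) {
  cat("<validation run> n = ", x$n, " completers (",
      length(x$excluded), " excluded)\n\n", sep = "")
  print(x$validity)
  cat("\n")
  print(x$reproducibility)
  invisible(x)
}

validation_to_list <- function(x) {
  ag <- function(a) list(
    pair_label = a$pair_label,
    ba_scale = a$ba_scale,
    bland_altman_log = as.list(glance(a$bland_altman_log)),
    bland_altman_natural = as.list(glance(a$bland_altman_natural)),
    quartiles = c(as.list(glance(a$quartiles)),
                  list(matrix = unname(apply(a$quartiles$matrix, 1, as.list)))),
    adequacy = as.list(glance(a$adequacy)),
    spearman = as.list(a$spearman),
    icc = as.list(glance(a$icc)),
    verdicts = lapply(seq_len(nrow(a$verdicts)),
                      function(i) as.list(a$verdicts[i, ]))
  )
  list(
    n = x$n,
    excluded = as.list(x$excluded),
    ear_ug = x$ear_ug,
    ba_scale = x$ba_scale,
    validity = ag(x$validity),
    reproducibility = ag(x$reproducibility),
    intake_summary = lapply(seq_len(nrow(x$intake_summary)),
                            function(i) as.list(x$intake_summary[i, ])),
    group_contributions = lapply(seq_len(nrow(x$group_contributions)),
                                 function(i) as.list(x$group_contributions[i, ])),
    mann_whitney = lapply(seq_len(nrow(x$mann_whitney)),
                          function(i) as.list(x$mann_whitney[i, ]))
  )
}

render_text_report <- function(x) {
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  add("Questionnaire validation report (n = ", x$n, " completers)")
  add(strrep("=", 60))
  if (length(x$excluded) > 0) {
    add("Excluded (not in all collections): ",
        paste(x$excluded, collapse = ", "))
  }
  add("")
  add("Intake summary (ug vitamin D / day)")
  s <- x$intake_summary
  for (i in seq_len(nrow(s))) {
    add(sprintf("  %-7s mean %s  median %s  range %s-%s  adequate %d (%s%%)",
                s$source[i],
                formatC(round_half_up(s$mean_ug[i], 1), format = "f", digits = 1),
                formatC(round_half_up(s$median_ug[i], 1), format = "f", digits = 1),
                formatC(round_half_up(s$min_ug[i], 1), format = "f", digits = 1),
                formatC(round_half_up(s$max_ug[i], 1), format = "f", digits = 1),
                s$adequate_n[i],
                formatC(round_half_up(s$adequate_pct[i], 1), format = "f",
                        digits = 1)))
  }
  mw <- x$mann_whitney
  for (i in seq_len(nrow(mw))) {
    add("  Mann-Whitney ", mw$comparison[i], ": p = ", format_pval(mw$p[i]))
  }
  add("")
  add("Group contributions (first administration)")
  g <- x$group_contributions
  for (i in seq_len(nrow(g))) {
    add(sprintf("  %-16s share median %s%%  intake median %s ug",
                g$group_id[i],
                formatC(round_half_up(g$median_pct[i], 1), format = "f", digits = 1),
                formatC(round_half_up(g$median_ug[i], 1), format = "f", digits = 1)))
  }
  for (part in list(x$validity, x$reproducibility)) {
    add("")
    add(part$pair_label)
    add(strrep("-", 60))
    ba <- part$bland_altman
    add("  Bland-Altman (", ba$scale, "): mean difference ",
        formatC(ba$mean_difference, format = "f", digits = 4),
        ", LoA ", formatC(ba$loa_lower, format = "f", digits = 4), " to ",
        formatC(ba$loa_upper, format = "f", digits = 4))
    add("  Bland-Altman index: ",
        formatC(round_half_up(ba$ba_index_pct, 1), format = "f", digits = 1),
        "% (", ba$n_total - ba$n_within, " of ", ba$n_total, " outside LoA)")
    q <- part$quartiles
    add("  Quartiles: correct ", q$correct_n, " (",
        round_half_up(q$correct_pct, 0), "%), gross ", q$gross_n, " (",
        round_half_up(q$gross_pct, 0), "%)")
    add("  Weighted kappa: ", formatC(q$weighted_kappa, format = "f", digits = 2),
        " (", q$kappa_label, ")")
    a <- part$adequacy
    add("  Adequacy vs EAR ", x$ear_ug, " ug: correct ", a$correct_n, " (",
        formatC(round_half_up(a$correct_pct, 1), format = "f", digits = 1),
        "%), misclassified ", a$gross_n, " (",
        formatC(round_half_up(a$gross_pct, 1), format = "f", digits = 1), "%)")
    add("  Spearman r: ", formatC(part$spearman$r, format = "f", digits = 2),
        " (p = ", format_pval(part$spearman$p), ")")
    icc <- part$icc
    add("  ICC(3,1): ", formatC(icc$icc, format = "f", digits = 2), " (",
        icc$label, "), 95% CI ",
        formatC(icc$ci_low, format = "f", digits = 2), "-",
        formatC(icc$ci_high, format = "f", digits = 2))
    v <- part$verdicts
    for (i in seq_len(nrow(v))) {
      add("  verdict ", v$criterion[i], ": ", v$verdict[i], " [value ",
          format(v$value[i], digits = 3), "; rule: ", v$rule[i], "]")
    }
  }
  ln
}

#' Render a validation run to files
#'
#' Writes the report in up to three formats plus the Bland-Altman figures.
#' Output is deterministic: identical inputs give byte-identical text
#' files.
#'
#' @param validation A `vidffq_validation` object.
#' @param dir Output directory (created if needed).
#' @param formats Any of `"text"` (report.txt, the printed-table shape),
#'   `"delimited"` (CSV tables), `"structured"` (report.json, which
#'   round-trips through [jsonlite::read_json()]).
#' @param plots Also write `ba_validity.png` and `ba_reproducibility.png`?
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(validation, dir,
                          formats = c("text", "delimited", "structured"),
                          plots = TRUE) {
  stopifnot(inherits(validation, "vidffq_validation"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) abort(paste0("Cannot create directory: ", dir))
  }
  written <- character()
  if ("text" %in% formats) {
    f <- file.path(dir, "report.txt")
    writeLines(render_text_report(validation), f)
    written <- c(written, f)
  }
  if ("delimited" %in% formats) {
    tabs <- list(
      intake_summary = validation$intake_summary,
      group_contributions = validation$group_contributions,
      mann_whitney = validation$mann_whitney,
      verdicts = dplyr::bind_rows(
        dplyr::mutate(validation$validity$verdicts,
                      pair = "validity", .before = 1),
        dplyr::mutate(validation$reproducibility$verdicts,
                      pair = "reproducibility", .before = 1))
    )
    for (nm in names(tabs)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(tabs[[nm]], f)
      written <- c(written, f)
    }
  }
  if ("structured" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(validation_to_list(validation), f,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  if (plots) {
    for (part in c("validity", "reproducibility")) {
      f <- file.path(dir, paste0("ba_", part, ".png"))
      p <- autoplot(validation[[part]]$bland_altman) +
        ggplot2::ggtitle(validation[[part]]$pair_label)
      ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 150)
      written <- c(written, f)
    }
  }
  invisible(written)
}
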