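#' Pair two sets of scored intakes by respondent
#'
#' Inner-joins the per-respondent totals of two scored sources; only
#' respondents present in both appear, aligned by id.
#'
#' @param scores_x,scores_y Outputs of [score_ffq()]/[score_record()] (or
#'   tibbles from [intake_totals()]).
#' @return Tibble `respondent_id`, `x`, `y`.
#' @export
pair_intakes <- function(scores_x, scores_y) {
  tx <- intake_totals(scores_x)
  ty <- intake_totals(scores_y)
  dplyr::inner_join(
    dplyr::select(tx, "respondent_id", x = "total_ug"),
    dplyr::select(ty, "respondent_id", y = "total_ug"),
    by = "respondent_id"
  )
}

check_pairs <- function(pairs, min_n = 3) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("x", "y") %in% names(pairs))) {
    abort("Paired intakes need columns x and y")
  }
  if (!"respondent_id" %in% names(pairs)) {
    pairs$respondent_id <- sprintf("pair_%03d", seq_len(nrow(pairs)))
  }
  if (nrow(pairs) < min_n) {
    abort(paste0("Need at least ", min_n, " paired observations"))
  }
  if (any(!is.finite(pairs$x)) || any(!is.finite(pairs$y))) {
    abort("Paired intakes must be finite")
  }
  pairs
}

#' Bland-Altman analysis of two intake assessment methods
#'
#' Computes per-pair differences (natural scale, or differences of natural
#' logs for right-skewed intakes), the mean difference, the limits of
#' agreement mean +/- `loa_multiplier` x sd, and the Bland-Altman index:
#' the percentage of pairs falling outside the limits (membership is
#' inclusive). In FFQ validation an index at or below 5% is read as a
#' positive validation and at or below 10% as borderline.
#'
#' @param pairs Data frame with columns `x`, `y` (and optionally
#'   `respondent_id`), e.g. from [pair_intakes()].
#' @param scale `"log"` (default, requires strictly positive intakes) or
#'   `"natural"`.
#' @param loa_multiplier Half-width of the limits in sd units, default 1.96.
#' @return A `vidffq_ba` object; see [tidy.vidffq_ba()],
#'   [glance.vidffq_ba()], [autoplot.vidffq_ba()].
#' @export
bland_altman <- function(pairs, scale = c("log", "natural"),
                         loa_multiplier = 1.96) {
  scale <- match.arg(scale)
  pairs <- check_pairs(pairs)
  if (scale == "log") {
    bad <- pairs$respondent_id[pairs$x <= 0 | pairs$y <= 0]
    if (length(bad) > 0) {
      abort(paste0("Log-scale Bland-Altman needs positive intakes; ",
                   "offending respondent(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    vx <- log(pairs$x); vy <- log(pairs$y)
  } else {
    vx <- pairs$x; vy <- pairs$y
  }
  diffs <- vx - vy
  means <- (vx + vy) / 2
  md <- mean(diffs)
  sdd <- sd(diffs)
  lo <- md - loa_multiplier * sdd
  hi <- md + loa_multiplier * sdd
  # inclusive membership, with a machine-precision guard so that methods
  # agreeing up to floating-point round-off count as within zero-width limits
  tol <- .Machine$double.eps^0.5 * max(abs(c(vx, vy)), 1)
  within <- diffs >= lo - tol & diffs <= hi + tol
  structure(list(
    scale = toupper(scale),
    loa_multiplier = loa_multiplier,
    mean_difference = md,
    sd_difference = sdd,
    loa_lower = lo,
    loa_upper = hi,
    n_total = length(diffs),
    n_within = sum(within),
    ba_index_pct = 100 * (length(diffs) - sum(within)) / length(diffs),
    data = tibble::tibble(respondent_id = pairs$respondent_id,
                          mean = means, difference = diffs, within = within)
  ), class = "vidffq_ba")
}

#' @export
print.vidffq_ba <- function(x, ...) {
  cat("<Bland-Altman> scale=", x$scale,
      " n=", x$n_total, "\n",
      "  mean difference ", format(x$mean_difference, digits = 4),
      ", LoA [", format(x$loa_lower, digits = 4), ", ",
      format(x$loa_upper, digits = 4), "]\n",
      "  index ", round_half_up(x$ba_index_pct, 1), "% (",
      x$n_total - x$n_within, " of ", x$n_total, " outside)\n", sep = "")
  invisible(x)
}

#' Linearly weighted Cohen's kappa from a contingency table
#'
#' Chance-corrected agreement for ordered categories,
#' kappa_w = 1 - sum(w o) / sum(w e), with disagreement weights
#' w_ij = |i - j| / (k - 1), observed proportions o, and chance-expected
#' proportions e from the marginal products. At k = 2 linear weights
#' reduce to the unweighted kappa. When the marginals admit no chance
#' disagreement the statistic is defined as 1 if no disagreement was
#' observed, and is an error otherwise.
#'
#' @param matrix k x k count matrix (rows: first method, columns: second).
#' @param weighting Only `"linear"` is implemented.
#' @return Kappa in \[-1, 1\].
#' @export
weighted_kappa <- function(matrix, weighting = "linear") {
  weighting <- match.arg(weighting)
  m <- as.matrix(matrix)
  k <- nrow(m)
  if (k < 2 || ncol(m) != k) abort("Need a square matrix with k >= 2")
  n <- sum(m)
  if (n < 1) abort("Need at least one observation")
  o <- m / n
  e <- outer(rowSums(o), colSums(o))
  idx <- seq_len(k)
  w <- abs(outer(idx, idx, "-")) / (k - 1)
  obs_dis <- sum(w * o)
  exp_dis <- sum(w * e)
  if (exp_dis == 0) {
    if (obs_dis == 0) return(1)
    abort("Degenerate marginals: expected disagreement is zero")
  }
  1 - obs_dis / exp_dis
}

#' Landis-Koch agreement label for a kappa value
#'
#' Bands: up to 0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.0 almost perfect. Negative values fall in
#' the slight band.
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of labels.
#' @examples
#' kappa_label(c(0.21, 0.62, 1))
#' @export
kappa_label <- function(kappa) {
  if (any(!is.finite(kappa) | kappa < -1 | kappa > 1)) {
    abort("kappa must lie in [-1, 1]")
  }
  lab <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  lab[findInterval(kappa, c(0.20, 0.40, 0.60, 0.80), left.open = TRUE) + 1]
}

#' Cicchetti agreement label for an intraclass correlation
#'
#' Bands: below 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good,
#' 0.75-1.0 excellent.
#'
#' @param icc Numeric vector, at most 1.
#' @return Character vector of labels.
#' @examples
#' icc_label(c(0.56, 0.81))
#' @export
icc_label <- function(icc) {
  if (any(!is.finite(icc) | icc > 1)) abort("icc must be finite and <= 1")
  lab <- c("poor", "fair", "good", "excellent")
  lab[findInterval(icc, c(0.40, 0.60, 0.75)) + 1]
}

assign_quartile <- function(v) {
  # each method cut at its own empirical quartiles (linear-interpolation
  # quantile convention); values exactly on a cut go to the lower category
  br <- quantile(v, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (v > br[1]) + (v > br[2]) + (v > br[3])
}

crossclass_result <- function(m, k, warnings = character()) {
  n <- sum(m)
  correct_n <- sum(diag(m))
  gross_n <- m[1, k] + m[k, 1]
  kap <- weighted_kappa(m)
  structure(list(
    k = k,
    matrix = m,
    n = n,
    correct_n = correct_n,
    correct_pct = 100 * correct_n / n,
    gross_n = gross_n,
    gross_pct = 100 * gross_n / n,
    weighted_kappa = kap,
    kappa_label = kappa_label(kap),
    warnings = warnings
  ), class = "vidffq_crossclass")
}

#' @export
print.vidffq_crossclass <- function(x, ...) {
  cat("<cross-classification> k=", x$k, " n=", x$n, "\n",
      "  correct ", x$correct_n, " (", round_half_up(x$correct_pct,
        if (x$k == 2) 1 else 0), "%), opposite-extreme ", x$gross_n,
      " (", round_half_up(x$gross_pct, if (x$k == 2) 1 else 0), "%)\n",
      "  weighted kappa ", format(x$weighted_kappa, digits = 3),
      " (", x$kappa_label, ")\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", x$warnings, "\n")
  invisible(x)
}

#' Cross-classification result from a pre-tabulated count matrix
#'
#' Computes the correctly classified share (diagonal), the grossly
#' misclassified share (the two opposite-extreme cells), and the linearly
#' weighted kappa with its Landis-Koch label from a k x k table of counts.
#'
#' @param matrix k x k count matrix (rows: first method, columns: second).
#' @return A `vidffq_crossclass` object.
#' @examples
#' m <- diag(c(20, 15, 15, 13)); m[1, 4] <- 0
#' crossclass_from_matrix(m)
#' @export
crossclass_from_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || nrow(m) < 2) abort("Need a square matrix, k >= 2")
  crossclass_result(m, nrow(m))
}

#' Quartile cross-classification of two intake methods
#'
#' Each method's intakes are cut at that method's own empirical quartiles;
#' the 4 x 4 table of joint categories yields the correctly classified
#' share (same quartile), the grossly misclassified share (opposite
#' quartiles), and the linearly weighted kappa. Heavy ties that leave a
#' quartile category empty are recorded as a warning in the result, not an
#' error.
#'
#' @param pairs Data frame with columns `x`, `y`; n >= 8.
#' @return A `vidffq_crossclass` object with `k = 4`.
#' @export
quartile_crossclass <- function(pairs) {
  pairs <- check_pairs(pairs, min_n = 8)
  qx <- assign_quartile(pairs$x)
  qy <- assign_quartile(pairs$y)
  m <- table(factor(qx, levels = 1:4), factor(qy, levels = 1:4))
  m <- matrix(as.integer(m), 4, 4)
  warnings <- character()
  empty <- which(rowSums(m) == 0 | colSums(m) == 0)
  if (length(empty) > 0) {
    warnings <- paste0("empty quartile category (heavy ties): ",
                       paste(empty, collapse = ", "))
  }
  crossclass_result(m, 4L, warnings)
}

#' Cross-classification of adequacy categories from two methods
#'
#' Tabulates ADEQUATE/INADEQUATE calls from two methods into a 2 x 2
#' cross-classification: correct = same category, misclassified = opposite
#' category (at k = 2 these exhaust the table).
#'
#' @param class_x,class_y Aligned character vectors of
#'   `"ADEQUATE"`/`"INADEQUATE"` calls (see [classify_adequacy()]).
#' @return A `vidffq_crossclass` object with `k = 2`.
#' @export
adequacy_crossclass <- function(class_x, class_y) {
  if (length(class_x) != length(class_y)) {
    abort("Adequacy vectors must have equal length")
  }
  lev <- c("INADEQUATE", "ADEQUATE")
  if (!all(c(class_x, class_y) %in% lev)) {
    abort("Adequacy classes must be ADEQUATE or INADEQUATE")
  }
  m <- table(factor(class_x, levels = lev), factor(class_y, levels = lev))
  crossclass_result(matrix(as.integer(m), 2, 2), 2L)
}

#' Intraclass correlation ICC(3,1): two-way mixed, consistency
#'
#' Single-measurement consistency ICC from the two-way mixed-effects
#' model (Shrout & Fleiss): ICC(3,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)
#' with subjects as rows and the k = 2 administrations/methods as fixed
#' columns. The confidence interval follows the F-distribution bounds of
#' Shrout & Fleiss; the label uses the Cicchetti bands. Consistency ICC is
#' invariant to adding a constant to one method.
#'
#' @param pairs Data frame with columns `x`, `y`; n >= 3 and non-zero
#'   between-subject variance.
#' @param confidence Confidence level, default 0.95.
#' @return A `vidffq_icc` object with fields `icc`, `ci_low`, `ci_high`,
#'   `label`, `n`.
#' @export
icc_consistency <- function(pairs, confidence = 0.95) {
  pairs <- check_pairs(pairs, min_n = 3)
  dat <- cbind(pairs$x, pairs$y)
  n <- nrow(dat)
  k <- ncol(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  if (var(row_means) == 0) {
    abort("ICC undefined: zero between-subject variance")
  }
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((dat - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  # the error sum of squares is non-negative by construction; guard the
  # subtraction against cancellation when the raters agree exactly
  ms_e <- max(ss_err, 0) / ((n - 1) * (k - 1))
  icc <- min((ms_r - ms_e) / (ms_r + (k - 1) * ms_e), 1)
  alpha <- 1 - confidence
  f_obs <- if (ms_e == 0) Inf else ms_r / ms_e
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f_l <- f_obs / qf(1 - alpha / 2, df1, df2)
  f_u <- f_obs * qf(1 - alpha / 2, df2, df1)
  ci_low <- (f_l - 1) / (f_l + k - 1)
  ci_high <- (f_u - 1) / (f_u + k - 1)
  structure(list(
    icc = icc, ci_low = ci_low, ci_high = ci_high,
    confidence = confidence, label = icc_label(icc), n = n, k = k,
    ms_rows = ms_r, ms_cols = ss_cols / (k - 1), ms_error = ms_e
  ), class = "vidffq_icc")
}

#' @export
print.vidffq_icc <- function(x, ...) {
  cat("<ICC(3,1) consistency> n=", x$n, "\n",
      "  ICC ", format(x$icc, digits = 3), " (", x$label, "), ",
      100 * x$confidence, "% CI [", format(x$ci_low, digits = 3), ", ",
      format(x$ci_high, digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation of paired intakes
#'
#' Pearson correlation of mid-ranks with a two-sided p-value (asymptotic,
#' as appropriate for tied intake data).
#'
#' @param pairs Data frame with columns `x`, `y`; n >= 3, neither constant.
#' @return One-row tibble `r`, `p`, `n`.
#' @export
spearman_r <- function(pairs) {
  pairs <- check_pairs(pairs, min_n = 3)
  if (sd(pairs$x) == 0 || sd(pairs$y) == 0) {
    abort("Spearman correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(
    cor.test(pairs$x, pairs$y, method = "spearman", exact = FALSE))
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Mann-Whitney U test for two intake samples
#'
#' Two-sided rank-sum test comparing the medians of two independent
#' samples: exact enumeration for small untied samples (both n <= 20),
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors (n >= 1 each).
#' @return One-row tibble `u`, `p`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("Both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(u = unname(wt$statistic), p = wt$p.value,
                 n_x = length(x), n_y = length(y))
}

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric vector, 3 <= n <= 5000, not constant.
#' @param alpha Significance level for the `normal` flag, default 0.05.
#' @return One-row tibble `w`, `p`, `normal` (TRUE when p > alpha).
#' @export
shapiro_normality <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (sd(x) == 0) abort("Shapiro-Wilk undefined for a constant vector")
  st <- shapiro.test(x)
  tibble::tibble(w = unname(st$statistic), p = st$p.value,
                 normal = st$p.value > alpha)
}

# half-up rounding to the precision printed in reports
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
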