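#' Tidy a Bland-Altman result
#'
#' @param x A `vidffq_ba` object.
#' @param ... Unused.
#' @return Tibble with one row per pair: `respondent_id`, `mean`,
#'   `difference`, `within`.
#' @method tidy vidffq_ba
#' @export
tidy.vidffq_ba <- function(x, ...) {
  x$data
}

#' One-row summary of a Bland-Altman result
#'
#' @param x A `vidffq_ba` object.
#' @param ... Unused.
#' @return One-row tibble: scale, mean difference, limits of agreement,
#'   counts, and the Bland-Altman index (percent outside the limits).
#' @method glance vidffq_ba
#' @export
glance.vidffq_ba <- function(x, ...) {
  tibble::tibble(
    scale = x$scale,
    mean_difference = x$mean_difference,
    sd_difference = x$sd_difference,
    loa_lower = x$loa_lower,
    loa_upper = x$loa_upper,
    n_within = x$n_within,
    n_total = x$n_total,
    ba_index_pct = x$ba_index_pct
  )
}

#' Bland-Altman plot
#'
#' Difference against mean per pair, with the mean-difference line and the
#' limits of agreement; the subtitle reports the Bland-Altman index.
#'
#' @param object A `vidffq_ba` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vidffq_ba
#' @export
autoplot.vidffq_ba <- function(object, ...) {
  lab <- if (object$scale == "LOG") "ln intake (ug/day)" else "intake (ug/day)"
  ggplot2::ggplot(object$data, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_hline(yintercept = object$mean_difference,
                        linetype = "solid", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(shape = within), show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(
      x = paste("Mean of methods,", lab),
      y = paste("Difference between methods,", lab),
      subtitle = paste0("Bland-Altman index ",
                        round_half_up(object$ba_index_pct, 1), "% (",
                        object$n_within, " of ", object$n_total,
                        " within the limits of agreement)")
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a cross-classification result
#'
#' @param x A `vidffq_crossclass` object.
#' @param ... Unused.
#' @return Tibble of cell counts: `category_x`, `category_y`, `n`.
#' @method tidy vidffq_crossclass
#' @export
tidy.vidffq_crossclass <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    category_x = rep(seq_len(x$k), times = x$k),
    category_y = rep(seq_len(x$k), each = x$k),
    n = as.integer(m[cbind(rep(seq_len(x$k), times = x$k),
                           rep(seq_len(x$k), each = x$k))])
  )
}

#' One-row summary of a cross-classification result
#'
#' @param x A `vidffq_crossclass` object.
#' @param ... Unused.
#' @return One-row tibble with counts, percentages, weighted kappa and its
#'   label.
#' @method glance vidffq_crossclass
#' @export
glance.vidffq_crossclass <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n,
    correct_n = x$correct_n, correct_pct = x$correct_pct,
    gross_n = x$gross_n, gross_pct = x$gross_pct,
    weighted_kappa = x$weighted_kappa, kappa_label = x$kappa_label
  )
}

#' One-row summary of an ICC result
#'
#' @param x A `vidffq_icc` object.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `label`, `n`.
#' @method glance vidffq_icc
#' @export
glance.vidffq_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 confidence = x$confidence, label = x$label, n = x$n)
}
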