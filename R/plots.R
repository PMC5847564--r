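#' Plot an enrichment result against its resampling null
#'
#' Histogram of the null overlap counts with the observed overlap marked.
#'
#' @param object A `famvar_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.famvar_enrichment <- function(object, ...) {
  df <- tibble::tibble(overlap = object$null_overlap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "null overlap with gene set",
      y = "draws",
      title = sprintf("%s: O = %d, E = %.1f, empirical p = %.3g",
                      ifelse(is.na(object$set_name), "enrichment",
                             object$set_name),
                      object$observed, object$expected, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of age of onset against disruptive-variant burden
#'
#' @param profiles Burden table from [burden_per_subject()].
#' @param scheme Affection scheme (broad by default, matching the onset
#'   analysis).
#' @param onset_window Typical-onset window, default `c(15, 50)`.
#' @return A ggplot object.
#' @export
plot_onset_burden <- function(profiles, scheme = affection_scheme("broad"),
                              onset_window = c(15, 50)) {
  status <- affection_status(profiles$phenotype, scheme)
  d <- profiles[!is.na(status) & status == "affected" &
                  !is.na(profiles$age_of_onset) &
                  profiles$age_of_onset >= onset_window[1] &
                  profiles$age_of_onset <= onset_window[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_of_onset,
                                  y = .data$n_lgd_brain)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "age of onset (years)",
                  y = "brain-expressed LGD burden") +
    ggplot2::theme_minimal()
}

#' Burden distributions of affected versus unaffected relatives
#'
#' @param profiles Burden table from [burden_per_subject()].
#' @param scheme Affection scheme, default strict.
#' @param which `"total"` or `"brain"`.
#' @return A ggplot object.
#' @export
plot_burden_groups <- function(profiles, scheme = affection_scheme("strict"),
                               which = c("total", "brain")) {
  which <- match.arg(which)
  col <- if (which == "total") "n_lgd_total" else "n_lgd_brain"
  status <- affection_status(profiles$phenotype, scheme)
  d <- profiles[!is.na(status), ]
  d$status <- status[!is.na(status)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status, y = .data[[col]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = sprintf("rare LGD burden (%s)", which)) +
    ggplot2::theme_minimal()
}
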