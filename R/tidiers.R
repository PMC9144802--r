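#' Tidy a mid_fit object
#'
#' One row per estimated quantity: the label-distribution entries
#' (`component = "mid"`, species `M0..Mn`) and the fragment ratios
#' (`component = "fragment"`).
#'
#' @param x A [fit_mid()] result.
#' @param ... Unused.
#' @return A tibble with columns `component`, `species`, `estimate`.
#' @export
tidy.mid_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component = "mid", species = names(x$mid),
                   estimate = unname(x$mid)),
    tibble::tibble(component = "fragment", species = names(x$r),
                   estimate = unname(x$r))
  )
}

#' One-row summary of a mid_fit object
#'
#' @param x A [fit_mid()] result.
#' @param ... Unused.
#' @return A tibble with columns `err` (residual sum of squares), `m0`,
#'   `enrichment` (mean fractional labeling, `sum(i * Mi) / n`),
#'   `r_mh` (`[M+H]+` share, `NA` if the fragment was not fitted),
#'   `n_iterations` and `ambiguous`.
#' @export
glance.mid_fit <- function(x, ...) {
  n <- x$n_bio
  enr <- if (n > 0) sum((0:n) * x$mid) / n else NA_real_
  tibble::tibble(
    err = x$err,
    m0 = unname(x$mid["M0"]),
    enrichment = enr,
    r_mh = if ("[M+H]+" %in% names(x$r)) unname(x$r["[M+H]+"]) else NA_real_,
    n_iterations = x$n_iterations,
    ambiguous = x$ambiguous
  )
}

#' Plot a mid_fit object
#'
#' Two panels: the measured versus reconstructed spectrum on the
#' nominal-mass axis, and the estimated label distribution with the
#' fragment ratios.
#'
#' @param object A [fit_mid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mid_fit <- function(object, ...) {
  spec <- dplyr::bind_rows(
    dplyr::mutate(object$raw, what = "measured"),
    dplyr::mutate(object$rec, what = "reconstructed")
  ) |>
    dplyr::mutate(panel = "spectrum", species = as.character(.data$offset))
  est <- tidy(object) |>
    dplyr::transmute(
      panel = ifelse(.data$component == "mid", "label distribution",
                     "fragment ratios"),
      species = .data$species, intensity = .data$estimate,
      what = "estimate"
    )
  dat <- dplyr::bind_rows(spec, est) |>
    dplyr::mutate(
      panel = factor(.data$panel,
                     c("spectrum", "label distribution", "fragment ratios")),
      species = factor(.data$species, unique(.data$species))
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$species, .data$intensity,
                                    fill = .data$what)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free") +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL,
                  title = paste0(object$formula, "  err = ",
                                 signif(object$err, 3))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a correction result table
#'
#' Stacked per-sample bars of the corrected label distribution, faceted
#' by compound — the standard way to eyeball labeling patterns across a
#' sample series.
#'
#' @param result A result table from [correct_table()] or
#'   [calibrate_then_correct()].
#' @return A ggplot object.
#' @export
plot_mid_results <- function(result) {
  dat <- result |>
    dplyr::filter(.data$component == "mid") |>
    dplyr::mutate(species = factor(.data$species,
                                   unique(.data$species[order(nchar(.data$species),
                                                              .data$species)])))
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample, .data$percent,
                                    fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound)) +
    ggplot2::scale_fill_viridis_d() +
    ggplot2::labs(x = NULL, y = "corrected MID (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
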