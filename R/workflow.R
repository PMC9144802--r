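#' Fit every compound and sample of an intensity table
#'
#' Runs [fit_mid()] on each sample column of each compound block and
#' returns a tidy result table: one row per compound, sample and
#' estimated component (label-distribution entries `M0..Mn` and fragment
#' ratios), with percentages rounded to two decimals plus the fit
#' diagnostics. Within a fit, the `mid` percentages and the `fragment`
#' percentages each sum to 100 (+/- rounding).
#'
#' @param tbl An intensity table, see [read_mid_table()].
#' @param fixed_r Optional fixed fragment ratios: a single named numeric
#'   vector applied to all compounds, or a per-compound tibble with
#'   columns `compound`, `fragment` and `ratio` (e.g. the output of
#'   [calibrate_fragments()]).
#' @param ... Further arguments passed to [fit_mid()] (`penalty`,
#'   `fragments`, `step_min`, `natural_abundance`, ...).
#' @return A tibble with columns `compound`, `sample`, `component`
#'   (`"mid"` or `"fragment"`), `species`, `percent`, `err`,
#'   `ambiguous`.
#' @export
correct_table <- function(tbl, fixed_r = NULL, ...) {
  per_compound_r <- is.data.frame(fixed_r)
  if (per_compound_r &&
      !all(c("compound", "fragment", "ratio") %in% names(fixed_r))) {
    abort("Per-compound `fixed_r` needs columns compound, fragment, ratio.")
  }
  samples <- sample_cols(tbl)
  if (length(samples) == 0) abort("Table contains no sample columns.")
  blocks <- split(tbl, tbl$compound)
  rows <- purrr::map(blocks, function(block) {
    cpd <- block$compound[1]
    r0 <- fixed_r
    if (per_compound_r) {
      sub <- fixed_r[fixed_r$compound == cpd, ]
      if (nrow(sub) == 0) {
        abort(paste0("No fixed fragment ratios provided for compound '", cpd, "'."))
      }
      r0 <- setNames(sub$ratio, sub$fragment)
      r0 <- r0 / sum(r0)
    }
    purrr::map(samples, function(s) {
      fit <- fit_mid(
        tibble::tibble(offset = block$offset, intensity = block[[s]]),
        formula = block$formula[1], n_bio = block$n_bio[1],
        fixed_r = r0, ...
      )
      tidy(fit) |>
        dplyr::transmute(
          compound = cpd, sample = s,
          component = .data$component, species = .data$species,
          percent = round(100 * .data$estimate, 2),
          err = fit$err, ambiguous = fit$ambiguous
        )
    }) |>
      purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}

#' Estimate fragment ratios from unlabeled control samples
#'
#' Stage 1 of the two-stage workflow. On control samples that carry no
#' tracer the label distribution is known (`M0 = 100%`), so fixing it
#' leaves only the fragment ratios to estimate; these are then aggregated
#' per compound across the control replicates (median by default). As a
#' screen for spectral impurities, each control is additionally fitted
#' with both vectors free: a compound is flagged (`qc_flag = TRUE`) when
#' the freely fitted `M0` falls below `qc_m0_min` in any control *and*
#' the unlabeled explanation is statistically inadequate — its
#' fixed-`M0` residual exceeds three times the noise level estimated
#' from the spread of the control replicates. The second condition
#' guards against the known instability of the free joint fit, which can
#' wander into a label-shifted solution family that interpolates one
#' noise realization marginally better even when `M0 = 100%` explains
#' the spectrum to within replicate noise; a genuine spectral impurity
#' fails both tests.
#'
#' @param controls An intensity table of unlabeled control samples.
#' @param stat Aggregation across control replicates: `"median"`
#'   (default) or `"mean"`; the aggregate is renormalized to sum 1.
#' @param qc_m0_min QC threshold on the freely fitted M0 fraction
#'   (default 0.95).
#' @param ... Further arguments passed to [fit_mid()].
#' @return A tibble with columns `compound`, `fragment`, `ratio` and
#'   `qc_flag`. The per-sample fits are attached as attribute
#'   `"detail"`.
#' @export
calibrate_fragments <- function(controls, stat = c("median", "mean"),
                                qc_m0_min = 0.95, ...) {
  stat <- match.arg(stat)
  agg <- if (stat == "median") median else mean
  samples <- sample_cols(controls)
  blocks <- split(controls, controls$compound)
  detail <- purrr::map(blocks, function(block) {
    cpd <- block$compound[1]
    n <- block$n_bio[1]
    m0_fixed <- c(1, numeric(n))
    ## expected residual of a clean replicate, from the spread of the
    ## normalized control spectra (0 when only one replicate is given)
    mat <- vapply(samples, function(s) {
      v <- pmax(block[[s]], 0)
      v / sum(v)
    }, numeric(nrow(block)))
    noise_err <- if (length(samples) >= 2) {
      sum(apply(mat, 1, stats::var))
    } else 0
    purrr::map(samples, function(s) {
      raw <- tibble::tibble(offset = block$offset, intensity = block[[s]])
      rfit <- fit_mid(raw, block$formula[1], n, fixed_mid = m0_fixed, ...)
      free <- fit_mid(raw, block$formula[1], n, ...)
      tibble::tibble(
        compound = cpd, sample = s,
        fragment = names(rfit$r), ratio = unname(rfit$r),
        m0_free = unname(free$mid["M0"]),
        err = rfit$err,
        m0_adequate = rfit$err <= pmax(3 * noise_err, 1e-9)
      )
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  out <- detail |>
    dplyr::group_by(.data$compound, .data$fragment) |>
    dplyr::summarise(ratio = agg(.data$ratio), .groups = "drop_last") |>
    dplyr::mutate(ratio = .data$ratio / sum(.data$ratio)) |>
    dplyr::ungroup()
  qc <- detail |>
    dplyr::distinct(.data$compound, .data$sample, .data$m0_free,
                    .data$m0_adequate) |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      qc_flag = any(.data$m0_free < qc_m0_min & !.data$m0_adequate),
      .groups = "drop"
    )
  out <- dplyr::left_join(out, qc, by = "compound")
  attr(out, "detail") <- detail
  out
}

#' Two-stage correction: calibrate fragment ratios, then fit labels
#'
#' The robust workflow for labeled sample series: fragment formation is
#' stable for a compound within a measurement series, so the fragment
#' ratios estimated from unlabeled controls (stage 1,
#' [calibrate_fragments()]) are fixed when fitting the label
#' distribution of each labeled sample (stage 2, [correct_table()]).
#' This avoids the degenerate joint solutions that a free fit can fall
#' into.
#'
#' @param controls Intensity table of unlabeled control samples.
#' @param labeled Intensity table of tracer-labeled samples; every
#'   compound must also be present in `controls`.
#' @param stat,qc_m0_min Stage-1 options, see [calibrate_fragments()].
#' @param ... Further arguments passed to [fit_mid()] in both stages.
#' @return The stage-2 result table of [correct_table()] with the
#'   stage-1 `qc_flag` joined per compound. The stage-1 calibration is
#'   attached as attribute `"calibration"`.
#' @export
calibrate_then_correct <- function(controls, labeled,
                                   stat = c("median", "mean"),
                                   qc_m0_min = 0.95, ...) {
  missing_cpd <- setdiff(unique(labeled$compound), unique(controls$compound))
  if (length(missing_cpd)) {
    abort(paste0("Compound(s) absent from controls: ",
                 paste(missing_cpd, collapse = ", "), "."))
  }
  cal <- calibrate_fragments(controls, stat = stat, qc_m0_min = qc_m0_min, ...)
  res <- correct_table(labeled, fixed_r = cal, ...) |>
    dplyr::left_join(dplyr::distinct(cal, .data$compound, .data$qc_flag),
                     by = "compound")
  attr(res, "calibration") <- cal
  res
}
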