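#' Simulate measured isotopologue intensity tables
#'
#' Generates synthetic rawMID replicates for one compound: the noiseless
#' superimposed spectrum from [reconstruct_mid()] perturbed by
#' multiplicative lognormal noise (coefficient of variation `noise_cv`)
#' and a uniform additive baseline on `[0, noise_floor]`, then clipped at
#' zero and normalized. All replicates share the same true fragment
#' ratios, mirroring the stability of in-source fragmentation within a
#' measurement series.
#'
#' @param formula Sum formula of the derivatized neutral molecule.
#' @param n_bio Number of biological carbon atoms.
#' @param mid True label distribution `M0..Mn` (length `n_bio + 1`).
#' @param r True fragment ratios (named as in `fragments`). Names
#'   restrict the fragment set, as in [fit_mid()].
#' @param n_rep Number of replicate samples (default 5).
#' @param noise_cv Multiplicative noise CV (default 0.02).
#' @param noise_floor Upper bound of the uniform additive baseline,
#'   on the normalized-intensity scale (default 1e-4).
#' @param seed Optional integer seed; fixes the full output.
#' @param compound Compound identifier for the output table.
#' @param sample_prefix Prefix of the generated sample names.
#' @param fragments,start_offset,axis_length,natural_abundance,isotopes
#'   Spectrum model arguments, see [reconstruct_mid()].
#' @return An intensity table: a tibble with columns `compound`,
#'   `formula`, `n_bio`, `offset` and one column per replicate, the
#'   format read and written by [read_mid_table()] and
#'   [write_mid_table()].
#' @examples
#' simulate_mids("C9H22O3Si2", 3, mid = c(0.5, 0, 0, 0.5),
#'               r = c("[M+H]+" = 1), n_rep = 2, seed = 1)
#' @export
simulate_mids <- function(formula, n_bio, mid, r,
                          n_rep = 5, noise_cv = 0.02, noise_floor = 1e-4,
                          seed = NULL, compound = "cpd1", sample_prefix = "S",
                          fragments = fragment_set(), start_offset = -2L,
                          axis_length = NULL, natural_abundance = TRUE,
                          isotopes = isotope_table()) {
  if (noise_cv < 0 || noise_floor < 0) abort("Noise parameters must be >= 0.")
  if (n_rep < 1) abort("`n_rep` must be >= 1.")
  if (length(mid) != n_bio + 1) abort("`mid` must have length n_bio + 1.")
  if (!is.null(names(r))) {
    fragments <- fragments[fragments$name %in% names(r), , drop = FALSE]
    validate_fragments(fragments)
  }
  rec <- reconstruct_mid(mid, r, formula, fragments = fragments,
                         start_offset = start_offset,
                         axis_length = axis_length,
                         natural_abundance = natural_abundance,
                         isotopes = isotopes)
  gen <- function() {
    L <- nrow(rec)
    out <- matrix(0, L, n_rep)
    for (j in seq_len(n_rep)) {
      v <- rec$intensity
      if (noise_cv > 0) {
        sdl <- sqrt(log(1 + noise_cv^2))
        v <- v * rlnorm(L, meanlog = -sdl^2 / 2, sdlog = sdl)
      }
      if (noise_floor > 0) v <- v + runif(L, 0, noise_floor)
      v[v < 0] <- 0
      out[, j] <- v / sum(v)
    }
    out
  }
  mat <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  colnames(mat) <- paste0(sample_prefix, seq_len(n_rep))
  dplyr::bind_cols(
    tibble::tibble(
      compound = compound,
      formula = formula_to_string(parse_formula(formula)),
      n_bio = as.integer(n_bio),
      offset = rec$offset
    ),
    tibble::as_tibble(mat)
  )
}
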