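#' In-source fragment definitions
#'
#' APCI spectra of silylated metabolites superimpose several ion species of
#' the same molecule. The four built-in fragments are, in order:
#' `[M-H]+`, `[M]+`, `[M+H]+` and `[M+H3O-CH4]+`, at integer nominal-mass
#' offsets -2, -1, 0 and +2 relative to `[M+H]+`. The water
#' adduct/methane loss lands about 30 mDa below the M+2 peak of `[M+H]+`,
#' unresolved at QTOF resolution, hence the +2 bin. Its lost methane
#' carbon is taken to come from a derivatization (TMS) methyl group, so
#' the count of biological carbons is unaffected.
#'
#' `delta` holds element-count changes relative to the *neutral* molecule
#' M; the isotope pattern of a fragment is computed from the molecule's
#' formula plus this delta.
#'
#' @param names Which fragments to include, a subset of the built-in
#'   names above (order is preserved as given).
#' @return A tibble with columns `name`, `offset` and `delta`
#'   (list-column of named element-count changes).
#' @examples
#' fragment_set()
#' fragment_set(c("[M]+", "[M+H]+"))
#' @export
fragment_set <- function(names = c("[M-H]+", "[M]+", "[M+H]+", "[M+H3O-CH4]+")) {
  builtin <- tibble::tibble(
    name = c("[M-H]+", "[M]+", "[M+H]+", "[M+H3O-CH4]+"),
    offset = c(-2L, -1L, 0L, 2L),
    delta = list(c(H = -1), c(H = 0), c(H = 1), c(C = -1, H = -1, O = 1))
  )
  bad <- setdiff(names, builtin$name)
  if (length(bad)) {
    abort(paste0(
      "Unknown fragment(s): ", paste(bad, collapse = ", "),
      ". Use fragment_tbl() for custom fragments."
    ))
  }
  out <- builtin[match(names, builtin$name), ]
  validate_fragments(out)
}

#' Build a custom fragment table
#'
#' For ionization chemistries beyond the four built-ins, a fragment set
#' can be declared directly: a name, an integer nominal-mass offset
#' relative to `[M+H]+`, and the element-count change relative to the
#' neutral molecule.
#'
#' @param name Character vector of fragment names.
#' @param offset Integer offsets relative to `[M+H]+` (must be unique).
#' @param delta List of named numeric vectors of element-count changes
#'   relative to the neutral molecule (e.g. `c(H = 1)` for `[M+H]+`).
#' @return A fragment tibble as used by [reconstruct_mid()] and
#'   [fit_mid()].
#' @export
fragment_tbl <- function(name, offset, delta) {
  out <- tibble::tibble(name = name, offset = as.integer(offset), delta = delta)
  validate_fragments(out)
}

validate_fragments <- function(frags) {
  if (nrow(frags) < 1) abort("Fragment set must contain at least one fragment.")
  if (anyDuplicated(frags$name)) abort("Fragment names must be unique.")
  if (anyDuplicated(frags$offset)) abort("Fragment offsets must be unique.")
  frags
}

## apply an element-count delta to a formula count vector
apply_delta <- function(counts, delta) {
  for (el in names(delta)) {
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + delta[[el]]
  }
  if (any(counts < 0)) {
    abort("Fragment formula delta leads to negative element counts.")
  }
  counts[counts > 0]
}

## One shifted-pattern matrix per fragment: S_k is axis_length x (n_bio+1),
## column j holding the isotope pattern of the fragment carrying j labeled
## carbons, placed at axis position offset_k + j. Mass falling outside the
## axis is clipped (it is not measured); recMID is renormalized downstream.
frag_matrices <- function(formula, n_bio, fragments, start_offset, axis_length,
                          natural_abundance = TRUE, isotopes = isotope_table(),
                          na_in_unlabeled = TRUE) {
  counts <- parse_formula(formula)
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_bio < 0 || n_bio > nC) {
    abort("`n_bio` must lie between 0 and the carbon count of the formula.")
  }
  positions <- start_offset + seq_len(axis_length) - 1L
  out <- vector("list", nrow(fragments))
  names(out) <- fragments$name
  for (k in seq_len(nrow(fragments))) {
    off <- fragments$offset[k]
    if (off < min(positions) || off > max(positions)) {
      abort(sprintf(
        "Fragment %s (offset %+d) lies outside the axis [%d, %d].",
        fragments$name[k], off, min(positions), max(positions)
      ))
    }
    fcounts <- apply_delta(counts, fragments$delta[[k]])
    S <- matrix(0, nrow = axis_length, ncol = n_bio + 1L)
    for (j in 0:n_bio) {
      if (natural_abundance) {
        excl <- if (na_in_unlabeled) j else n_bio
        pat <- natural_pattern(fcounts, exclude = excl, isotopes = isotopes)
      } else {
        pat <- 1
      }
      pos <- off + j + seq_along(pat) - 1L
      ok <- pos >= min(positions) & pos <= max(positions)
      if (!any(ok)) {
        abort(sprintf(
          "Isotopologue M%d of fragment %s falls entirely outside the axis.",
          j, fragments$name[k]
        ))
      }
      ## renormalize over the measured window, as the measured intensities
      ## of this isotopologue are: each column of S sums to 1 on the axis
      S[pos[ok] - start_offset + 1L, j + 1L] <- pat[ok] / sum(pat[ok])
    }
    out[[k]] <- S
  }
  out
}

## simplex validity check shared by CorMID and fragment vectors
check_simplex <- function(x, what, tol = 1e-9) {
  if (any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol)) {
    abort(paste0("`", what, "` entries must lie in [0, 1]."))
  }
  if (abs(sum(x) - 1) > tol) {
    abort(paste0("`", what, "` must sum to 1 (got ", format(sum(x)), ")."))
  }
  invisible(x)
}

#' Reconstruct a superimposed spectrum from label and fragment distributions
#'
#' Builds the reconstructed intensity vector (recMID): each in-source
#' fragment contributes the label distribution `mid`, convolved with the
#' natural-abundance isotope pattern of that fragment's formula and
#' shifted by the fragment's nominal-mass offset; contributions are mixed
#' by the fragment ratios `r` and the result is normalized to sum 1.
#'
#' @param mid Label distribution M0..Mn (length `n_bio + 1`, sums to 1).
#' @param r Fragment ratios, a named (by fragment) or positional numeric
#'   vector over the rows of `fragments`, summing to 1.
#' @param formula Sum formula of the derivatized neutral molecule.
#' @param fragments Fragment tibble, see [fragment_set()].
#' @param start_offset Integer position of the first axis entry relative
#'   to `[M+H]+` (default -2, covering `[M-H]+`).
#' @param axis_length Number of consecutive nominal-mass positions
#'   (default `n_bio + 5`).
#' @param natural_abundance Convolve with natural isotope patterns? Set
#'   `FALSE` for idealised spectra in which every atom is monoisotopic.
#' @param isotopes Isotope table, see [isotope_table()].
#' @param na_in_unlabeled Should the unlabeled biological carbons of a
#'   partially labeled isotopologue carry natural \eqn{^{13}}C (default
#'   `TRUE`, the standard correction-matrix convention)?
#' @return A tibble with columns `offset` (position relative to
#'   `[M+H]+`) and `intensity` (sums to 1).
#' @examples
#' reconstruct_mid(c(1, 0, 0, 0), c("[M+H]+" = 1), "C12H26O3Si2")
#' @export
reconstruct_mid <- function(mid, r, formula, fragments = fragment_set(),
                            start_offset = -2L, axis_length = NULL,
                            natural_abundance = TRUE,
                            isotopes = isotope_table(),
                            na_in_unlabeled = TRUE) {
  n_bio <- length(mid) - 1L
  if (n_bio < 0) abort("`mid` must have at least one entry.")
  check_simplex(mid, "mid")
  r <- match_ratios(r, fragments)
  if (is.null(axis_length)) axis_length <- n_bio + 5L
  S <- frag_matrices(formula, n_bio, fragments, start_offset, axis_length,
                     natural_abundance, isotopes, na_in_unlabeled)
  rec <- numeric(axis_length)
  for (k in seq_along(S)) rec <- rec + r[k] * (S[[k]] %*% mid)[, 1]
  if (sum(rec) <= 0) abort("Reconstruction has zero total intensity on this axis.")
  tibble::tibble(
    offset = start_offset + seq_len(axis_length) - 1L,
    intensity = rec / sum(rec)
  )
}

## align a ratio vector with a fragment table (by name when named)
match_ratios <- function(r, fragments) {
  if (!is.null(names(r))) {
    bad <- setdiff(names(r), fragments$name)
    if (length(bad)) {
      abort(paste0("Ratios given for unknown fragment(s): ",
                   paste(bad, collapse = ", "), "."))
    }
    full <- setNames(numeric(nrow(fragments)), fragments$name)
    full[names(r)] <- r
    r <- full
  }
  if (length(r) != nrow(fragments)) {
    abort("`r` must have one entry per fragment.")
  }
  check_simplex(r, "r")
  setNames(as.numeric(r), fragments$name)
}
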