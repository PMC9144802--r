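#' Natural isotope abundance table
#'
#' Returns the per-element isotope table used throughout the package:
#' one row per isotope with its integer nominal mass shift relative to the
#' most abundant isotope, its exact mass (Da) and its fractional abundance.
#' Within each element the abundances sum to 1.
#'
#' The default \eqn{^{13}}C fraction is 0.0107; silicon — dominant in the
#' spectra of TMS-derivatized metabolites — is fixed at
#' \eqn{^{28}}Si 92.2\%, \eqn{^{29}}Si 4.7\%, \eqn{^{30}}Si 3.1\%.
#' The heavy isotopes of H, N, O and S contribute little at nominal-mass
#' resolution and can be dropped with `minor = FALSE`, in which case their
#' abundance is folded back into the light isotope.
#'
#' @param c13 Fractional abundance of \eqn{^{13}}C (default 0.0107; use
#'   0.011 for the coarser "1.1 percent" convention).
#' @param minor Keep the low-abundance heavy isotopes of H, N, O and S?
#'   Carbon and silicon are always kept in full.
#' @return A tibble with columns `element`, `isotope`, `shift` (integer
#'   nominal mass shift), `mass` (Da) and `abundance`.
#' @examples
#' isotope_table()
#' isotope_table(c13 = 0.011, minor = FALSE)
#' @export
isotope_table <- function(c13 = 0.0107, minor = TRUE) {
  if (!is.numeric(c13) || length(c13) != 1 || c13 < 0 || c13 >= 1) {
    abort("`c13` must be a single fraction in [0, 1).")
  }
  tab <- tibble::tribble(
    ~element, ~isotope, ~shift, ~mass,        ~abundance,
    "C",  "12C", 0L, 12.000000000, 1 - c13,
    "C",  "13C", 1L, 13.003354835, c13,
    "H",  "1H",  0L, 1.0078250319, 0.999885,
    "H",  "2H",  1L, 2.0141017780, 0.000115,
    "N",  "14N", 0L, 14.003074005, 0.99636,
    "N",  "15N", 1L, 15.000108898, 0.00364,
    "O",  "16O", 0L, 15.994914620, 0.99757,
    "O",  "17O", 1L, 16.999131757, 0.00038,
    "O",  "18O", 2L, 17.999159613, 0.00205,
    "Si", "28Si", 0L, 27.976926535, 0.922,
    "Si", "29Si", 1L, 28.976494665, 0.047,
    "Si", "30Si", 2L, 29.973770137, 0.031,
    "S",  "32S", 0L, 31.972071174, 0.9499,
    "S",  "33S", 1L, 32.971458910, 0.0075,
    "S",  "34S", 2L, 33.967867004, 0.0425,
    "S",  "36S", 4L, 35.967080710, 0.0001,
    "P",  "31P", 0L, 30.973761998, 1.0
  )
  if (!minor) {
    keep_full <- c("C", "Si")
    tab <- tab |>
      dplyr::group_by(.data$element) |>
      dplyr::mutate(
        abundance = dplyr::if_else(
          .data$element %in% keep_full, .data$abundance,
          dplyr::if_else(.data$shift == 0L, 1, 0)
        )
      ) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$abundance > 0)
  }
  tab
}

#' Parse a Hill-notation sum formula
#'
#' Parses e.g. `"C9H22O3Si2"` into a named integer vector of element
#' counts. Only elements present in [isotope_table()] are accepted.
#'
#' @param text A sum formula string (Hill notation, no parentheses or
#'   charges).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(text) {
  if (is.numeric(text) && !is.null(names(text))) {
    return(as_formula_counts(text))
  }
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty formula string.")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    abort(paste0("Malformed formula: '", text, "'."))
  }
  el <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  known <- unique(isotope_table()$element)
  bad <- setdiff(el, known)
  if (length(bad)) {
    abort(paste0("Unknown element(s): ", paste(bad, collapse = ", "), "."))
  }
  counts <- tapply(cnt, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  as_formula_counts(out)
}

## validate + canonicalise a named count vector (Hill order: C, H, then A-Z)
as_formula_counts <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("Formula counts must be named by element symbol.")
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    abort("Element counts must be nonnegative integers.")
  }
  x <- x[x > 0]
  ord <- c(intersect(c("C", "H"), names(x)), sort(setdiff(names(x), c("C", "H"))))
  out <- as.integer(x[ord])
  names(out) <- ord
  out
}

#' Serialize element counts back to a Hill-notation string
#'
#' Inverse of [parse_formula()]: `formula_to_string(parse_formula(x))`
#' reproduces `x` up to Hill ordering.
#'
#' @param counts Named integer vector of element counts.
#' @return A formula string.
#' @examples
#' formula_to_string(c(C = 6, H = 12, O = 6))
#' @export
formula_to_string <- function(counts) {
  counts <- as_formula_counts(counts)
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecule or of one of its isotopologues
#'
#' Sums the exact masses of the most abundant isotope of every atom. The
#' mass of the isotopologue carrying `label` heavy carbons is offset by
#' `label` times the \eqn{^{13}}C-\eqn{^{12}}C mass gap (1.003355 Da).
#'
#' @param formula A formula string or named count vector.
#' @param label Number of \eqn{^{13}}C atoms in the isotopologue
#'   (default 0, the monoisotopic species).
#' @param isotopes Isotope table, see [isotope_table()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")            # 180.0634
#' monoisotopic_mass("C6H12O6", label = 6) # 186.0835
#' @export
monoisotopic_mass <- function(formula, label = 0, isotopes = isotope_table()) {
  counts <- parse_formula(formula)
  base <- isotopes |>
    dplyr::filter(.data$shift == 0L) |>
    dplyr::select("element", "mass")
  masses <- setNames(base$mass, base$element)
  if (label < 0 || (("C" %in% names(counts)) && label > counts[["C"]])) {
    abort("`label` must be between 0 and the number of carbon atoms.")
  }
  sum(counts * masses[names(counts)]) + label * 1.003355
}

C13_C12_GAP <- 1.003355

## distribution of the total nominal-mass shift of `n` atoms of one element,
## by binary-exponentiation convolution of the single-atom distribution
element_shift_dist <- function(shifts, probs, n, cap = 128L) {
  one <- numeric(max(shifts) + 1L)
  one[shifts + 1L] <- probs
  out <- 1
  base <- one
  while (n > 0) {
    if (n %% 2 == 1) out <- conv_trunc(out, base, cap)
    n <- n %/% 2
    if (n > 0) base <- conv_trunc(base, base, cap)
  }
  out
}

conv_trunc <- function(a, b, cap) {
  L <- min(length(a) + length(b) - 1L, cap)
  out <- numeric(L)
  for (i in seq_along(a)) {
    jmax <- min(length(b), L - i + 1L)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Natural-abundance isotope pattern of a molecule
#'
#' Computes, by discrete convolution at nominal-mass (1 Da bin) resolution,
#' the relative abundances of a molecule's isotopologue peaks arising from
#' natural isotope abundance. Abundances are indexed by integer mass shift
#' 0, 1, 2, ... above the monoisotopic peak and are normalized to sum 1.
#'
#' `exclude` carbon atoms can be removed from the convolution: these are
#' the biological carbons assumed to carry the \eqn{^{13}}C label (a
#' labeled carbon is fixed, not stochastic), so the pattern of the
#' isotopologue Mj of a compound is the pattern of its formula with
#' `exclude = j`.
#'
#' @param formula Formula string or named count vector.
#' @param exclude Number of carbon atoms to exclude from the convolution
#'   (0 to the carbon count).
#' @param isotopes Isotope table, see [isotope_table()].
#' @param max_shift Optional truncation length. When given, an error is
#'   raised if more than 1e-6 of the probability mass lies beyond it;
#'   when `NULL` the pattern is returned up to a tail mass below 1e-9.
#' @return Numeric vector of abundances; element `i` is the abundance at
#'   mass shift `i - 1`. Sums to 1.
#' @examples
#' natural_pattern("C3", isotopes = isotope_table(minor = FALSE))
#' natural_pattern("C9H20O3Si3")
#' @export
natural_pattern <- function(formula, exclude = 0, isotopes = isotope_table(),
                            max_shift = NULL) {
  empty <- length(formula) == 0 ||
    (is.character(formula) && length(formula) == 1 && !nzchar(formula))
  counts <- if (empty) integer(0) else parse_formula(formula)
  exclude <- as.integer(exclude)
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (exclude < 0 || exclude > nC) {
    abort("`exclude` must lie between 0 and the carbon count of the formula.")
  }
  if (nC > 0) counts[["C"]] <- nC - exclude
  counts <- counts[counts > 0]
  pat <- 1
  for (el in names(counts)) {
    iso <- isotopes[isotopes$element == el, ]
    if (nrow(iso) == 0) abort(paste0("Element '", el, "' missing from isotope table."))
    pat <- conv_trunc(
      pat, element_shift_dist(iso$shift, iso$abundance, counts[[el]]),
      cap = 128L
    )
  }
  pat <- pat / sum(pat)
  if (!is.null(max_shift)) {
    if (max_shift < 0) abort("`max_shift` must be >= 0.")
    if (length(pat) > max_shift + 1) {
      tail_mass <- sum(pat[(max_shift + 2):length(pat)])
      if (tail_mass > 1e-6) {
        abort(sprintf(
          "max_shift = %d truncates %.2g of the isotope pattern (limit 1e-6).",
          max_shift, tail_mass
        ))
      }
      pat <- pat[seq_len(max_shift + 1)]
    } else if (length(pat) < max_shift + 1) {
      pat <- c(pat, numeric(max_shift + 1 - length(pat)))
    }
  } else {
    keep <- length(pat)
    while (keep > 1 && sum(pat[keep:length(pat)]) < 1e-9) keep <- keep - 1L
    pat <- pat[seq_len(min(keep + 1L, length(pat)))]
  }
  pat / sum(pat)
}
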