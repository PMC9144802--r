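# Independent oracles used to freeze expected values. They deliberately
# avoid the package's convolution / matrix code paths: patterns are built
# by exhaustive enumeration of isotope placements, spectra by naive loops,
# and fits by brute-force evaluation of full simplex grids.

# isotope pattern by enumeration: for each element, list every way its
# atoms can be distributed over the isotopes (multinomial), then cross all
# elements and accumulate probability by total nominal shift
oracle_pattern <- function(counts, exclude = 0, isotopes = midfit::isotope_table()) {
  counts <- counts[counts > 0]
  if ("C" %in% names(counts)) {
    counts["C"] <- counts[["C"]] - exclude
    counts <- counts[counts > 0]
  }
  per_element <- lapply(names(counts), function(el) {
    iso <- isotopes[isotopes$element == el, ]
    n <- counts[[el]]
    combos <- expand.grid(rep(list(0:n), nrow(iso)))
    combos <- combos[rowSums(combos) == n, , drop = FALSE]
    prob <- apply(combos, 1, function(k) dmultinom(k, prob = iso$abundance))
    shift <- as.vector(as.matrix(combos) %*% iso$shift)
    data.frame(shift = shift, prob = prob)
  })
  dist <- data.frame(shift = 0, prob = 1)
  for (d in per_element) {
    cross <- merge(dist, d, by = NULL)
    dist <- aggregate(
      prob <- cross$prob.x * cross$prob.y,
      by = list(shift = cross$shift.x + cross$shift.y), FUN = sum
    )
    names(dist) <- c("shift", "prob")
  }
  out <- numeric(max(dist$shift) + 1)
  out[dist$shift + 1] <- dist$prob
  out / sum(out)
}

# naive reconstruction: loop over fragments, label states and isotope
# shifts, adding mass at each axis position
oracle_reconstruct <- function(mid, r, formula, fragments, start_offset,
                               axis_length, natural_abundance = TRUE,
                               isotopes = midfit::isotope_table(),
                               normalize = TRUE) {
  counts <- midfit::parse_formula(formula)
  positions <- start_offset:(start_offset + axis_length - 1)
  rec <- numeric(axis_length)
  for (k in seq_len(nrow(fragments))) {
    fc <- counts
    for (el in names(fragments$delta[[k]])) {
      fc[el] <- (if (el %in% names(fc)) fc[[el]] else 0) + fragments$delta[[k]][[el]]
    }
    fc <- fc[fc > 0]
    for (j in seq_along(mid) - 1) {
      pat <- if (natural_abundance) {
        oracle_pattern(fc, exclude = j, isotopes = isotopes)
      } else 1
      w <- numeric(axis_length)
      for (s in seq_along(pat) - 1) {
        pos <- fragments$offset[k] + j + s
        idx <- match(pos, positions)
        if (!is.na(idx)) w[idx] <- w[idx] + pat[s + 1]
      }
      # the on-axis share of this isotopologue is renormalized, matching
      # how measured window intensities are treated
      rec <- rec + r[k] * mid[j + 1] * w / sum(w)
    }
  }
  if (normalize) rec / sum(rec) else rec
}

# brute-force fit: evaluate the residual on full simplex grids
oracle_grid_fit <- function(raw, formula, n_bio, fragments, start_offset,
                            grid_step, fixed_r = NULL,
                            natural_abundance = TRUE) {
  raw <- raw / sum(raw)
  mid_grid <- midfit::simplex_grid(n_bio + 1, grid_step)
  r_grid <- if (is.null(fixed_r)) {
    midfit::simplex_grid(nrow(fragments), grid_step)
  } else {
    matrix(fixed_r, nrow = 1)
  }
  best <- list(err = Inf)
  for (ri in seq_len(nrow(r_grid))) {
    r <- r_grid[ri, ]
    errs <- vapply(seq_len(nrow(mid_grid)), function(mi) {
      rec <- oracle_reconstruct(mid_grid[mi, ], r, formula, fragments,
                                start_offset, length(raw),
                                natural_abundance)
      sum((raw - rec)^2)
    }, numeric(1))
    mi <- which.min(errs)
    if (errs[mi] < best$err) {
      best <- list(err = errs[mi], mid = mid_grid[mi, ], r = r)
    }
  }
  best
}

# a fast vectorised exhaustive search used where the naive one is too slow;
# still independent of the greedy search (full enumeration, no refinement)
exhaustive_min_err <- function(raw, formula, n_bio, fragments, start_offset,
                               grid_step, natural_abundance = TRUE) {
  raw <- raw / sum(raw)
  mid_grid <- midfit::simplex_grid(n_bio + 1, grid_step)
  r_grid <- midfit::simplex_grid(nrow(fragments), grid_step)
  cols <- lapply(seq_len(nrow(fragments)), function(k) {
    sapply(0:n_bio, function(j) {
      oracle_reconstruct(
        c(rep(0, j), 1, rep(0, n_bio - j)),
        r = c(rep(0, k - 1), 1, rep(0, nrow(fragments) - k)),
        formula, fragments, start_offset, length(raw), natural_abundance,
        normalize = FALSE
      )
    })
  })
  best <- Inf
  for (ri in seq_len(nrow(r_grid))) {
    B <- Reduce(`+`, Map(function(S, rk) rk * S, cols, r_grid[ri, ]))
    RECS <- B %*% t(mid_grid)
    RECS <- sweep(RECS, 2, colSums(RECS), "/")
    errs <- colSums((RECS - raw)^2)
    best <- min(best, min(errs))
  }
  best
}

# shared fixture formulas (TMS-derivatized small metabolites)
lactic2tms <- "C9H22O3Si2" # lactic acid + 2 TMS, 3 biological C
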