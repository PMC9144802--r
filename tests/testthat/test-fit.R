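test_that("residual sum of squares behaves as a squared distance", {
  expect_equal(residual_ss(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(residual_ss(c(1, 0), c(0, 1)), 2)
  set.seed(7)
  a <- runif(6); b <- runif(6)
  expect_equal(residual_ss(a, b), sum((a - b)^2))
  expect_error(residual_ss(1:3, 1:4), "different axes")
})

test_that("simplex grids enumerate exactly the expected candidate sets", {
  g <- simplex_grid(3, 0.5)
  want <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(nrow(g), 6)
  expect_identical(key(g), key(want))

  expect_equal(simplex_grid(2, 1), rbind(c(1, 0), c(0, 1)))
  # stars and bars: C(1/step + dim - 1, dim - 1)
  expect_equal(nrow(simplex_grid(4, 0.25)), choose(7, 3))
  expect_equal(nrow(simplex_grid(3, 0.1)), choose(12, 2))
  expect_true(all(abs(rowSums(simplex_grid(5, 0.2)) - 1) < 1e-12))
  expect_error(simplex_grid(0, 0.5), "positive integer")
  expect_error(simplex_grid(3, 0.3), "divide 1")
})

test_that("fixed-r fit on an idealized embedded spectrum is exact", {
  # fully labeled 6-carbon compound forming 10% [M-H]+, corrected under
  # the (wrong) pure-[M+H]+ assumption: label mass reappears at M4
  raw <- simulate_mids("C6H12O6", 6, mid = c(0, 0, 0, 0, 0, 0, 1),
                       r = c("[M-H]+" = 0.1, "[M+H]+" = 0.9),
                       n_rep = 1, noise_cv = 0, noise_floor = 0,
                       natural_abundance = FALSE)
  fit <- fit_mid(tibble::tibble(offset = raw$offset, intensity = raw$S1),
                 "C6H12O6", 6, fixed_r = c("[M+H]+" = 1),
                 natural_abundance = FALSE)
  expect_equal(unname(fit$mid["M4"]), 0.10, tolerance = 0.005)
  expect_equal(unname(fit$mid["M6"]), 0.90, tolerance = 0.001)
  expect_equal(sum(fit$mid), 1, tolerance = 1e-9)
  # the greedy solution matches the brute-force grid optimum
  oracle <- oracle_grid_fit(raw$S1, "C6H12O6", 6, fragment_set("[M+H]+"),
                            -2, grid_step = 0.1,
                            fixed_r = 1, natural_abundance = FALSE)
  expect_lte(fit$err, oracle$err + 1e-9)
})

test_that("natural-abundance correction of an unlabeled spectrum gives M0 = 100%", {
  for (f in c("C9H22O3Si2", "C14H32N2O3Si3")) {
    n <- 3
    pat <- natural_pattern(f)
    raw <- tibble::tibble(offset = seq_along(pat) - 1, intensity = pat)
    fit <- fit_mid(raw, f, n, fixed_r = c("[M+H]+" = 1))
    expect_equal(unname(fit$mid["M0"]), 1, tolerance = 0.005)
  }
})

test_that("noiseless joint fits reach machine-level residuals and fixed-r fits recover truth", {
  set.seed(11)
  frags <- fragment_set(c("[M-H]+", "[M]+", "[M+H]+"))
  for (i in 1:5) {
    mid <- simplex_grid(4, 0.05)[sample(nrow(simplex_grid(4, 0.05)), 1), ]
    r <- simplex_grid(3, 0.05)[sample(nrow(simplex_grid(3, 0.05)), 1), ]
    raw <- reconstruct_mid(mid, r, lactic2tms, fragments = frags)
    joint <- fit_mid(raw, lactic2tms, 3, fragments = frags)
    expect_lt(joint$err, 1e-8)
    fixed <- fit_mid(raw, lactic2tms, 3, fixed_r = setNames(r, frags$name),
                     fragments = frags)
    expect_lt(max(abs(fixed$mid - mid)), 0.01)
  }
})

test_that("degenerate spectra resolve toward the protonated species", {
  frags <- fragment_set(c("[M]+", "[M+H]+"))
  rec <- reconstruct_mid(c(0, 1, 0), c("[M]+" = 1), "C8H20O2Si2",
                         fragments = frags, start_offset = -1,
                         axis_length = 6, natural_abundance = FALSE)
  # both {0,1,0}/[M]+ and {1,0,0}/[M+H]+ explain the spectrum exactly;
  # the tie resolves to the [M+H]+-dominated solution, with and without
  # an explicit penalty, and the ambiguity is reported
  for (lambda in c(0, 1)) {
    fit <- fit_mid(rec, "C8H20O2Si2", 2, fragments = frags,
                   natural_abundance = FALSE, penalty = lambda)
    expect_equal(unname(fit$mid), c(1, 0, 0), tolerance = 1e-9)
    expect_equal(unname(fit$r["[M+H]+"]), 1, tolerance = 1e-9)
    expect_lt(fit$err, 1e-12)
    expect_true(fit$ambiguous)
  }
})

test_that("identical inputs give bit-identical fits", {
  raw <- reconstruct_mid(c(0.25, 0.3, 0.45), c(0.1, 0.2, 0.7, 0),
                         "C8H20O2Si2")
  f1 <- fit_mid(raw, "C8H20O2Si2", 2)
  f2 <- fit_mid(raw, "C8H20O2Si2", 2)
  expect_identical(f1$mid, f2$mid)
  expect_identical(f1$r, f2$r)
  expect_identical(f1$err, f2$err)
})

test_that("the greedy search never regresses below the coarse seed set", {
  set.seed(23)
  frags <- fragment_set(c("[M]+", "[M+H]+"))
  for (i in 1:5) {
    raw <- runif(8)
    raw <- raw / sum(raw)
    fit <- fit_mid(tibble::tibble(offset = -1:6, intensity = raw),
                   "C8H20O2Si2", 2, fixed_r = c("[M]+" = 0.3, "[M+H]+" = 0.7),
                   fragments = frags)
    seed_errs <- apply(simplex_grid(3, 0.5), 1, function(m) {
      rec <- reconstruct_mid(m, c("[M]+" = 0.3, "[M+H]+" = 0.7),
                             "C8H20O2Si2", fragments = frags,
                             start_offset = -1, axis_length = 8)
      sum((raw - rec$intensity)^2)
    })
    expect_lte(fit$err, min(seed_errs) + 1e-12)
  }
})

test_that("joint fit attains the exhaustive fine-grid minimum", {
  frags <- fragment_set(c("[M]+", "[M+H]+"))
  set.seed(31)
  mid <- c(0.15, 0.6, 0.25)
  r <- c(0.35, 0.65)
  raw <- reconstruct_mid(mid, r, "C8H20O2Si2", fragments = frags)
  fit <- fit_mid(raw, "C8H20O2Si2", 2, fragments = frags)
  brute <- exhaustive_min_err(raw$intensity, "C8H20O2Si2", 2, frags,
                              -2, grid_step = 0.01)
  expect_lte(fit$err, brute + 1e-9)
})

test_that("fit options are validated", {
  raw <- tibble::tibble(offset = -2:4, intensity = c(0, 0, 1, 0.1, 0, 0, 0))
  expect_error(fit_mid(raw, "C8H20O2Si2", 2,
                       fixed_r = c("[M+H]+" = 1), fixed_mid = c(1, 0, 0)),
               "nothing to fit")
  expect_error(fit_mid(raw, "C8H20O2Si2", 2, penalty = -1), ">= 0")
  expect_error(fit_mid(tibble::tibble(offset = -2:4, intensity = rep(0, 7)),
                       "C8H20O2Si2", 2), "zero total")
  expect_error(fit_mid(tibble::tibble(offset = -2:4,
                                      intensity = c(0, NA, 1, 0, 0, 0, 0)),
                       "C8H20O2Si2", 2), "non-finite")
  expect_error(fit_mid(tibble::tibble(offset = c(-2, 0, 1),
                                      intensity = c(0, 1, 0)),
                       "C8H20O2Si2", 2), "consecutive")
  expect_error(fit_mid(tibble::tibble(offset = 0:1, intensity = c(1, 0)),
                       "C8H20O2Si2", 2), "span")
})

test_that("tidy, glance and autoplot expose the fit", {
  raw <- reconstruct_mid(c(0, 0, 1), c("[M+H]+" = 0.8, "[M]+" = 0.2),
                         "C8H20O2Si2")
  fit <- fit_mid(raw, "C8H20O2Si2", 2,
                 fixed_r = c("[M+H]+" = 0.8, "[M]+" = 0.2))
  td <- tidy(fit)
  expect_named(td, c("component", "species", "estimate"))
  expect_equal(sum(td$estimate[td$component == "mid"]), 1, tolerance = 1e-9)
  expect_equal(sum(td$estimate[td$component == "fragment"]), 1,
               tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$enrichment, 1, tolerance = 0.01) # fully labeled
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "corMID")
})
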