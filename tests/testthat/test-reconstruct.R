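frags2 <- fragment_set(c("[M]+", "[M+H]+"))

test_that("two-fragment reconstruction is the stacked shifted-copy matrix", {
  # n = 2, axis of four positions starting at [M]+, abundance off:
  # recMID = r1 * {mid, 0} + r2 * {0, mid}
  mid <- c(0.2, 0.3, 0.5)
  r <- c(0.25, 0.75)
  rec <- reconstruct_mid(mid, r, "C8H20O2Si2", fragments = frags2,
                         start_offset = -1, axis_length = 4,
                         natural_abundance = FALSE)
  expect_equal(rec$offset, -1:2)
  expect_equal(rec$intensity, r[1] * c(mid, 0) + r[2] * c(0, mid))
})

test_that("a pure [M+H]+ spectrum embeds the label distribution unchanged", {
  mid <- c(0.1, 0, 0.2, 0.7)
  rec <- reconstruct_mid(mid, c("[M+H]+" = 1), "C9H22O3Si2",
                         fragments = fragment_set("[M+H]+"),
                         start_offset = -2, axis_length = 8,
                         natural_abundance = FALSE)
  expect_equal(rec$intensity, c(0, 0, mid, 0, 0))
})

test_that("shifted label and lighter fragment are exactly degenerate", {
  a <- reconstruct_mid(c(0, 1, 0), c("[M]+" = 1), "C8H20O2Si2",
                       fragments = frags2, start_offset = -1,
                       axis_length = 5, natural_abundance = FALSE)
  b <- reconstruct_mid(c(1, 0, 0), c("[M+H]+" = 1), "C8H20O2Si2",
                       fragments = frags2, start_offset = -1,
                       axis_length = 5, natural_abundance = FALSE)
  expect_identical(a$intensity, b$intensity)
})

test_that("reconstruction matches the dense convolution oracle", {
  # half-labeled lactic acid (2 TMS) with three in-source species
  frags3 <- fragment_set(c("[M-H]+", "[M]+", "[M+H]+"))
  mid <- c(0.5, 0, 0, 0.5)
  r <- c(0.4, 0.1, 0.5)
  rec <- reconstruct_mid(mid, r, lactic2tms, fragments = frags3,
                         start_offset = -2, axis_length = 8)
  want <- oracle_reconstruct(mid, r, lactic2tms, frags3, -2, 8)
  expect_equal(rec$intensity, want, tolerance = 1e-9)
  # and with natural abundance off
  rec0 <- reconstruct_mid(mid, r, lactic2tms, fragments = frags3,
                          start_offset = -2, axis_length = 8,
                          natural_abundance = FALSE)
  want0 <- oracle_reconstruct(mid, r, lactic2tms, frags3, -2, 8,
                              natural_abundance = FALSE)
  expect_equal(rec0$intensity, want0, tolerance = 1e-12)
})

test_that("reconstructions are normalized and linear in r", {
  set.seed(42)
  for (i in 1:10) {
    mid <- as.vector(rmultinom(1, 20, runif(4))) / 20
    r1 <- as.vector(rmultinom(1, 20, runif(4))) / 20
    r2 <- as.vector(rmultinom(1, 20, runif(4))) / 20
    a <- runif(1)
    rec1 <- reconstruct_mid(mid, r1, lactic2tms)
    rec2 <- reconstruct_mid(mid, r2, lactic2tms)
    mix <- reconstruct_mid(mid, a * r1 + (1 - a) * r2, lactic2tms)
    expect_equal(sum(rec1$intensity), 1, tolerance = 1e-9)
    expect_equal(sum(mix$intensity), 1, tolerance = 1e-9)
    expect_equal(mix$intensity,
                 a * rec1$intensity + (1 - a) * rec2$intensity,
                 tolerance = 1e-8)
  }
})

test_that("zero padding of the axis does not change fitted results", {
  mid <- c(0, 0.3, 0, 0.7)
  r <- c("[M]+" = 0.2, "[M+H]+" = 0.8)
  frag <- fragment_set(c("[M]+", "[M+H]+"))
  # axis wide enough that no isotope mass is clipped: padding with zeros
  # then leaves the objective, and hence the deterministic fit, unchanged
  rec <- reconstruct_mid(mid, r, lactic2tms, fragments = frag,
                         start_offset = -2, axis_length = 16)
  wide <- tibble::tibble(offset = -4:15,
                         intensity = c(0, 0, rec$intensity, 0, 0))
  f1 <- fit_mid(rec, lactic2tms, 3, fixed_r = r, fragments = frag)
  f2 <- fit_mid(wide, lactic2tms, 3, fixed_r = r, fragments = frag)
  expect_equal(f1$mid, f2$mid, tolerance = 1e-9)
})

test_that("invalid inputs are rejected", {
  expect_error(reconstruct_mid(c(0.5, 0.6), c("[M+H]+" = 1), "C2H6"),
               "sum to 1")
  expect_error(reconstruct_mid(c(1, 0), c("[M+H]+" = 2), "C2H6"), "lie in")
  expect_error(
    reconstruct_mid(c(1, 0), c("[M+H]+" = 1), "C2H6",
                    start_offset = 5, axis_length = 3),
    "outside the axis"
  )
  expect_error(fragment_set("[M+2H]+"), "Unknown fragment")
  expect_error(
    fragment_tbl(c("a", "b"), c(0, 0), list(c(H = 1), c(H = 0))),
    "offsets must be unique"
  )
})
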