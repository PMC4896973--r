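test_that("normalize_pattern handles regular and degenerate profiles", {
  expect_equal(normalize_pattern(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalize_pattern(rep(3.7, 5)), rep(1, 5))
  expect_equal(normalize_pattern(rep(0, 4)), rep(0, 4))
  expect_error(normalize_pattern(c(-1, 1)), "nonnegative")
})

test_that("raw Eq-style distance reproduces the 3-4-5 case", {
  d <- pattern_distance(c(0, 0), c(3, 4), scaled = FALSE)
  expect_equal(d$lambda_dist, 5)
})

test_that("identical patterns give complement 1 and tier good", {
  v <- runif(50)
  d <- pattern_distance(v, v)
  expect_equal(d$lambda_dist, 0)
  expect_equal(d$complement, 1)
  expect_equal(d$tier, "good")
  expect_error(pattern_distance(1:3, 1:4), "equal length")
})

test_that("scaled distance satisfies the metric axioms on random profiles", {
  set.seed(9)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    a <- normalize_pattern(runif(n))
    b <- normalize_pattern(runif(n))
    c_ <- normalize_pattern(runif(n))
    dab <- pattern_distance(a, b)$lambda_dist
    dba <- pattern_distance(b, a)$lambda_dist
    dac <- pattern_distance(a, c_)$lambda_dist
    dcb <- pattern_distance(c_, b)$lambda_dist
    expect_equal(dab, dba)                     # symmetry
    expect_gte(dab, 0)                         # nonnegativity
    expect_lte(dab, dac + dcb + 1e-12)         # triangle inequality
  }
  # identity of indiscernibles on max-normalized profiles
  a <- normalize_pattern(runif(30))
  expect_equal(pattern_distance(a, a)$lambda_dist, 0)
  b <- a; b[5] <- b[5] / 2 + 0.01
  expect_gt(pattern_distance(a, normalize_pattern(b))$lambda_dist, 0)
})

test_that("distance is grid-resolution independent for a fixed shape", {
  shape <- function(x) exp(-(x / 20)^2)
  x1 <- seq(-100, 100, by = 1)
  x2 <- seq(-100, 100, by = 0.25)
  ref1 <- normalize_pattern(shape(x1) + 0.2 * cos(x1 / 15)^2)
  ref2 <- normalize_pattern(shape(x2) + 0.2 * cos(x2 / 15)^2)
  alt1 <- normalize_pattern(shape(x1 - 8))
  alt2 <- normalize_pattern(shape(x2 - 8))
  d1 <- pattern_distance(ref1, alt1)$lambda_dist
  d2 <- pattern_distance(ref2, alt2)$lambda_dist
  expect_lt(abs(d1 - d2), 0.01)
})

test_that("tier boundaries are exactly right-closed at 0.8/0.6/0.4", {
  expect_equal(goodness_tier(0.8), "good")
  expect_equal(goodness_tier(0.8 - 1e-12), "medium")
  expect_equal(goodness_tier(0.6), "medium")
  expect_equal(goodness_tier(0.6 - 1e-12), "bad")
  expect_equal(goodness_tier(0.4), "bad")
  expect_equal(goodness_tier(0.4 - 1e-12), "reject")
  expect_equal(goodness_tier(c(1, 0.75, 0.5, 0.1)),
               c("good", "medium", "bad", "reject"))
})

make_boxcar_pattern <- function(en_nodes = 20, cia_nodes = 15, gap = 3,
                                dx = 1, half_length = 60) {
  g <- grid1d(half_length, dx, omega = 30)
  centre <- (g$n_points + 1) / 2
  en <- numeric(g$n_points)
  half_en <- floor(en_nodes / 2)
  en[(centre - half_en):(centre - half_en + en_nodes - 1)] <- 1
  cia <- numeric(g$n_points)
  left_start <- centre - half_en - gap - cia_nodes
  cia[left_start:(left_start + cia_nodes - 1)] <- 1
  right_start <- centre + (en_nodes - half_en) + gap
  cia[right_start:(right_start + cia_nodes - 1)] <- 1
  structure(list(grid = g, hh = numeric(g$n_points), ptchh = numeric(g$n_points),
                 cia = cia, en = en, converged = TRUE, n_iterations = 0L,
                 n_clamped = 0), class = "ocellar_pattern")
}

test_that("boxcar fixture yields exact domain lengths", {
  pat <- make_boxcar_pattern(en_nodes = 20, cia_nodes = 15, dx = 1)
  lens <- extract_domain_lengths(pat)
  expect_equal(lens$L_En, 20)
  expect_equal(lens$L_CiA, 15)
  # absent En domain has zero length
  pat2 <- make_boxcar_pattern()
  pat2$en <- numeric(pat2$grid$n_points)
  expect_equal(extract_domain_lengths(pat2)$L_En, 0)
})

test_that("domain lengths vary smoothly with theta at the control", {
  pat <- cached_control()$pattern
  thetas <- seq(0.3, 0.7, by = 0.05)
  lens <- vapply(thetas, function(th)
    extract_domain_lengths(pat, theta = th)$L_CiA, numeric(1))
  expect_true(all(abs(diff(lens)) <= 2 * pat$grid$dx))
})

test_that("morphospace coordinates follow the relative-deviation formula", {
  ctrl_len <- list(L_CiA = 20, L_En = 25)
  co <- morphospace_coords(list(L_CiA = 16, L_En = 31.25), ctrl_len)
  expect_equal(co$lambda_CiA, -0.2)
  expect_equal(co$lambda_En, 0.25)
  expect_equal(unlist(morphospace_coords(ctrl_len, ctrl_len)),
               c(lambda_CiA = 0, lambda_En = 0))
  # brute-force one-line oracle on random summaries
  set.seed(11)
  for (i in 1:100) {
    s <- list(L_CiA = runif(1, 1, 50), L_En = runif(1, 1, 50))
    co <- morphospace_coords(s, ctrl_len)
    expect_identical(co$lambda_CiA, (s$L_CiA - 20) / 20)
    expect_identical(co$lambda_En, (s$L_En - 25) / 25)
  }
  expect_error(morphospace_coords(ctrl_len, list(L_CiA = 0, L_En = 5)),
               "positive")
})

test_that("morphospace coordinates are scale-free", {
  set.seed(3)
  for (i in 1:20) {
    s <- list(L_CiA = runif(1, 5, 40), L_En = runif(1, 5, 40))
    ctrl <- list(L_CiA = runif(1, 5, 40), L_En = runif(1, 5, 40))
    c1 <- morphospace_coords(s, ctrl)
    k <- runif(1, 0.1, 10)
    c2 <- morphospace_coords(list(L_CiA = k * s$L_CiA, L_En = k * s$L_En),
                             list(L_CiA = k * ctrl$L_CiA,
                                  L_En = k * ctrl$L_En))
    expect_equal(c1$lambda_CiA, c2$lambda_CiA, tolerance = 1e-12)
    expect_equal(c1$lambda_En, c2$lambda_En, tolerance = 1e-12)
  }
})

test_that("reference-anchored thresholds respond to amplitude", {
  pat <- make_boxcar_pattern(en_nodes = 20, cia_nodes = 15, dx = 1)
  # against itself as reference: identical to the own-max reading
  self_ref <- extract_domain_lengths(pat, reference = pat)
  expect_equal(self_ref, extract_domain_lengths(pat))
  # halving all amplitudes against the original reference erases domains
  dim_pat <- pat
  dim_pat$cia <- 0.4 * pat$cia
  dim_pat$en <- 0.4 * pat$en
  lens <- extract_domain_lengths(dim_pat, reference = pat)
  expect_equal(lens$L_CiA, 0)
  expect_equal(lens$L_En, 0)
  # but alone (own max) the dim pattern reads the same lengths
  expect_equal(extract_domain_lengths(dim_pat), self_ref)
})
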