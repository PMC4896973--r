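test_that("grid construction is symmetric and consistent", {
  g <- grid1d(100, 1, omega = 30)
  expect_equal(g$n_points, 201L)
  expect_true(g$n_points %% 2 == 1)
  expect_equal(g$x, rev(-g$x))
  expect_equal(g$dx * (g$n_points - 1), 2 * g$half_length)
  expect_equal(g$source_mask, rev(g$source_mask))
  expect_equal(sum(g$source_mask), 31L)  # |x| <= 15 at dx = 1
  expect_error(grid1d(100, 3, 30), "integer multiple")
})

test_that("analytic Hh profile: symmetry, boundary value, monotone tail", {
  gp <- c(alpha_Hh = 2e-4, beta_Hh = 2e-4, D = 0.05, omega = 30)
  g <- grid1d(120, 0.5, omega = 30)
  hh <- hh_profile(gp, g)
  expect_true(all(hh >= 0))
  expect_equal(hh, rev(hh))  # even function, machine precision
  # continuous at the source edge, equal to the closed-form Hh_b
  ell <- gradient_length_scale(gp)
  hb <- hh_boundary_value(gp)
  expect_equal(hh[g$x == 15], hb, tolerance = 1e-12)
  expect_equal(hb, 0.5 * (1 - exp(-30 / ell)), tolerance = 1e-12)
  # non-increasing in |x| outside the source
  tail_idx <- which(g$x >= 15)
  expect_true(all(diff(hh[tail_idx]) <= 1e-14))
  # zero production limit
  gp0 <- gp; gp0[["alpha_Hh"]] <- 0
  expect_equal(hh_profile(gp0, g), rep(0, g$n_points))
  # parameter-domain errors
  gp_bad <- gp; gp_bad[["D"]] <- -1
  expect_error(hh_profile(gp_bad, g), "positive")
})

test_that("analytic Hh profile matches a time-dependent PDE oracle to <1%", {
  gp <- c(alpha_Hh = 1e-3, beta_Hh = 2e-3, D = 0.05, omega = 10)
  ell <- gradient_length_scale(gp)   # 5 um
  g <- grid1d(30, 0.25, omega = 10)  # dx = ell/20
  analytic <- hh_profile(gp, g)
  numeric <- oracle_hh_pde(gp, g)
  rel <- abs(numeric - analytic) / max(analytic)
  expect_lt(max(rel), 0.01)
})

test_that("reaction_rhs matches an independent transcription of the equations", {
  ip <- cached_control()$params$intracellular
  set.seed(4)
  for (i in 1:25) {
    st <- runif(4, 0, 2)  # P, C, E, hh
    ours <- reaction_rhs(st[1], st[2], st[3], st[4], ip)
    theirs <- oracle_rhs(st[1], st[2], st[3], st[4], ip)
    expect_equal(c(ours$dptchh, ours$dcia, ours$den), theirs,
                 tolerance = 1e-12)
  }
})

test_that("reaction_rhs trivial fixed points and contract checks", {
  ip <- cached_control()$params$intracellular
  # no ligand, no state: complex formation needs Hh
  d0 <- reaction_rhs(0, 0, 0, 0, ip)
  expect_equal(d0$dptchh, 0)
  expect_equal(d0$dcia, 0)
  expect_equal(d0$den, 0)
  # En below threshold with no CiA and low Hh decays
  d1 <- reaction_rhs(0, 0, 0.9 * ip[["zeta_En"]], 1e-6, ip)
  expect_lte(d1$den, 0)
  # negative concentrations rejected
  expect_error(reaction_rhs(-1, 0, 0, 0, ip), "nonnegative")
})

test_that("C++ solver agrees with explicit R Euler stepping", {
  ctrl <- cached_control()
  g <- grid1d(40, 2, omega = 30)
  p <- ctrl$params
  hh <- hh_profile(p$gradient, g)
  n_steps <- 250L
  dt <- 0.1 / max(p$intracellular[c("beta_PtcHh", "beta_CiA", "beta_En")])
  pat <- simulate_steady_state(p, g, stop_tol = 0, dt = dt,
                               max_steps = n_steps)
  expect_false(pat$converged)
  expect_equal(pat$n_iterations, n_steps)
  P <- C <- E <- numeric(g$n_points)
  for (s in seq_len(n_steps)) {
    d <- reaction_rhs(P, C, E, hh, p$intracellular)
    P <- pmax(P + dt * d$dptchh, 0)
    C <- pmax(C + dt * d$dcia, 0)
    E <- pmax(E + dt * d$den, 0)
  }
  expect_equal(pat$ptchh, P, tolerance = 1e-12)
  expect_equal(pat$cia, C, tolerance = 1e-12)
  expect_equal(pat$en, E, tolerance = 1e-12)
})

test_that("steady state: no source means no pathway activity", {
  ctrl <- cached_control()
  g <- grid1d(50, 2, omega = 30)
  p0 <- ctrl$params
  p0$gradient[["alpha_Hh"]] <- 0
  pat <- simulate_steady_state(p0, g)
  expect_true(pat$converged)
  expect_equal(max(pat$ptchh), 0)
  expect_equal(max(pat$en), 0)
})

test_that("control steady state shows the OC-IOC-OC architecture", {
  ctrl <- cached_control()
  pat <- ctrl$pattern
  expect_true(pat$converged)
  en_n <- normalize_pattern(pat$en)
  cia_n <- normalize_pattern(pat$cia)
  centre <- (pat$grid$n_points + 1) / 2
  # En-positive domain covers the centre (zone of maximal Hh)
  expect_gte(en_n[centre], 0.5)
  # thresholded En and CiA supports are spatially exclusive
  expect_equal(sum(en_n >= 0.5 & cia_n >= 0.5), 0L)
  # CiA domains exist on both sides of the En domain
  x <- pat$grid$x
  expect_true(any(cia_n >= 0.5 & x > 0))
  expect_true(any(cia_n >= 0.5 & x < 0))
  # En only self-maintained where Hh is near maximal: every En-on node has
  # Hh above the level at the En domain edge times a tolerance
  en_on <- which(en_n >= 0.5)
  expect_lt(max(abs(x[en_on])), ctrl$params$gradient[["omega"]])
})

test_that("steady-state patterns are mirror-symmetric", {
  ctrl <- cached_control()
  p <- set_param(ctrl$params, "alpha_CiA",
                 1.3 * param_value(ctrl$params, "alpha_CiA"))
  g <- grid1d(60, 2, omega = 30)
  pat <- simulate_steady_state(p, g)
  for (prof in list(pat$hh, pat$ptchh, pat$cia, pat$en))
    expect_lt(max(abs(prof - rev(prof))), 1e-8)
})

test_that("stop criterion is sound: 10x more iterations change little", {
  ctrl <- cached_control()
  g <- grid1d(60, 2, omega = 30)
  pat <- simulate_steady_state(ctrl$params, g)
  expect_true(pat$converged)
  longer <- simulate_steady_state(ctrl$params, g, stop_tol = 0,
                                  max_steps = 10L * pat$n_iterations)
  for (v in c("ptchh", "cia", "en"))
    expect_lt(sqrt(sum((pat[[v]] - longer[[v]])^2)), 0.01)
})

test_that("domain lengths are stable under grid refinement", {
  ctrl <- cached_control()
  omega <- ctrl$params$gradient[["omega"]]
  coarse <- simulate_steady_state(ctrl$params, grid1d(100, 1, omega))
  fine <- simulate_steady_state(ctrl$params, grid1d(100, 0.5, omega))
  lc <- extract_domain_lengths(coarse)
  lf <- extract_domain_lengths(fine)
  expect_lt(abs(lc$L_CiA - lf$L_CiA), 1)  # < 1 coarse cell
  expect_lt(abs(lc$L_En - lf$L_En), 1)
  # refined control pattern is nearly identical in shape
  cia_f <- fine$cia[seq(1, fine$grid$n_points, by = 2)]
  d <- pattern_distance(normalize_pattern(coarse$cia),
                        normalize_pattern(cia_f))
  expect_gte(d$complement, 0.99)
})

test_that("non-convergence is reported, and downstream refuses the pattern", {
  ctrl <- cached_control()
  g <- grid1d(40, 2, omega = 30)
  pat <- simulate_steady_state(ctrl$params, g, stop_tol = 0, max_steps = 50L)
  expect_false(pat$converged)
  expect_error(extract_domain_lengths(pat), "converge")
})
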