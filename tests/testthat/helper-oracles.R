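# Independent oracles used across the suite.  These re-derive quantities by
# routes separate from the package implementation (second transcription of
# the model equations, brute-force geometry, analytic rates) so agreement is
# evidence of correctness, not tautology.

# Second, independent transcription of the intracellular equations
# (deliberately written in a different style from reaction_rhs()).
oracle_rhs <- function(P, C, E, hh, ip) {
  ip <- as.list(ip)
  hill <- function(u, k, n) {
    t <- (u / k)^n
    t / (1 + t)
  }
  fb <- ip$alpha_PtcHh + ip$alpha_CiA_PtcHh * C / (ip$k_PtcHh + C)
  dP <- hh * fb / (1 + ip$alpha_En_PtcHh * E) - ip$beta_PtcHh * P
  dC <- ip$alpha_CiA * hill(P, ip$k_CiA, ip$n_CiA) /
    (1 + ip$alpha_En_CiA * E) - ip$beta_CiA * C
  en_prod <- if (E >= ip$zeta_En) ip$alpha_En_En
    else ip$alpha_En * hill(C, ip$k_En, ip$n_En)
  dE <- en_prod - ip$beta_En * E
  c(dP, dC, dE)
}

# Explicit time-dependent finite-difference integration of the Hh
# reaction-diffusion equation (production in the source, linear turnover,
# diffusion; zero-flux boundaries) run to steady state on an enlarged
# domain.  Oracle for the closed-form steady-state profile.
oracle_hh_pde <- function(gp, grid, pad_factor = 3) {
  gp <- unlist(gp)
  dx <- grid$dx
  half <- grid$half_length * pad_factor
  x <- seq(-half, half, by = dx)
  # trapezoidal weighting of the step source: boundary nodes carry half a
  # cell of production, matching the continuum source width
  src <- as.numeric(abs(x) <= gp[["omega"]] / 2 + 1e-12)
  edge <- abs(abs(x) - gp[["omega"]] / 2) < 1e-12
  src[edge] <- 0.5
  D <- gp[["D"]]; beta <- gp[["beta_Hh"]]; alpha <- gp[["alpha_Hh"]]
  dt <- 0.4 * dx^2 / (2 * D)
  dt <- min(dt, 0.2 / beta)
  h <- numeric(length(x))
  n_steps <- ceiling(12 / (beta * dt))  # ~12 turnover times
  n <- length(h)
  for (s in seq_len(n_steps)) {
    # zero-flux boundaries via mirrored ghost nodes
    lap <- (c(h[-1], h[n - 1]) - 2 * h + c(h[2], h[-n])) / dx^2
    h <- h + dt * (D * lap - beta * h + alpha * src)
  }
  h[match(round(grid$x, 9), round(x, 9))]
}

# Shoelace polygon area of the convex hull of a 2D point cloud.
oracle_hull_area <- function(x, y) {
  idx <- grDevices::chull(x, y)
  xs <- x[idx]; ys <- y[idx]
  n <- length(xs)
  j <- c(2:n, 1)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

# Independent coding of the phenotype class rules.
oracle_labels <- function(lc, le) {
  r <- sqrt(lc^2 + le^2)
  nf <- ifelse(le >= 0 & sign(lc) == sign(le),
               as.integer(r >= 0.3), NA_integer_)
  list(oc = as.integer(lc > 0),
       ioc = as.integer(le >= 0.15),
       nf = nf, radial = r)
}

# Small helper: a control reference on a reduced grid, cached per session.
cached_control <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- control_reference()
    cache
  }
})

# Cheap stand-in tier intervals (fixed relative widths around the control)
# for tests that exercise morphospace plumbing without the cost of running
# full sensitivity scans.
small_intervals <- function(ctrl) {
  lapply(setNames(nm = intracellular_param_names()), function(nm) {
    v <- param_value(ctrl$params, nm)
    list(good = v * c(0.97, 1.03),
         medium = v * c(1.03, 1.12),
         bad = v * c(1.12, 1.30))
  })
}
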