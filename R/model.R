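#' Local reaction rates of the intracellular three-node network
#'
#' Time derivatives of (PtcHh, CiA, En) at one or more nodes given the
#' local Hh concentration.  The network is purely local in space: Hh drives
#' PtcHh complex formation, CiA feeds back positively on PtcHh (saturating,
#' constant `k_PtcHh`), PtcHh activates CiA through a Hill term
#' (`k_CiA`, `n_CiA`), and En represses both PtcHh and CiA production
#' (weights `alpha_En_PtcHh`, `alpha_En_CiA`).  En is a low-sensitivity CiA
#' target (Hill `k_En`, `n_En`); once En exceeds the threshold `zeta_En` its
#' production switches to the Hh-independent self-maintenance rate
#' `alpha_En_En`.
#'
#' The equations are
#' \deqn{dP/dt = Hh (a_P + a_{CP} C/(k_P + C)) / (1 + w_{EP} E) - b_P P}
#' \deqn{dC/dt = a_C \frac{(P/k_C)^{n_C}}{1 + (P/k_C)^{n_C}} / (1 + w_{EC} E) - b_C C}
#' \deqn{dE/dt = \Phi(C, E) - b_E E, \quad
#'   \Phi = a_{EE} \textrm{ if } E \ge \zeta_{En},
#'   \textrm{ else } a_E \frac{(C/k_E)^{n_E}}{1 + (C/k_E)^{n_E}}}
#'
#' @param ptchh,cia,en Nonnegative concentrations (vectors of equal length).
#' @param hh_local Local Hh concentration(s) (scalar or same length).
#' @param ip Named vector/list of the 16 intracellular parameters, e.g.
#'   `control_parameters()$intracellular`.
#' @return A list with numeric vectors `dptchh`, `dcia`, `den`.
#' @export
#' @examples
#' ip <- control_parameters()$intracellular
#' reaction_rhs(0, 0, 0, hh_local = 0, ip = ip)  # all-zero fixed point
reaction_rhs <- function(ptchh, cia, en, hh_local, ip) {
  ip <- unlist(ip)
  if (any(ptchh < 0) || any(cia < 0) || any(en < 0) || any(hh_local < 0))
    stop("concentrations must be nonnegative")
  hillC <- (ptchh / ip[["k_CiA"]])^ip[["n_CiA"]]
  hillE <- (cia / ip[["k_En"]])^ip[["n_En"]]
  dptchh <- hh_local *
    (ip[["alpha_PtcHh"]] +
       ip[["alpha_CiA_PtcHh"]] * cia / (ip[["k_PtcHh"]] + cia)) /
    (1 + ip[["alpha_En_PtcHh"]] * en) -
    ip[["beta_PtcHh"]] * ptchh
  dcia <- ip[["alpha_CiA"]] * hillC / (1 + hillC) /
    (1 + ip[["alpha_En_CiA"]] * en) -
    ip[["beta_CiA"]] * cia
  prod_en <- ifelse(en >= ip[["zeta_En"]],
                    ip[["alpha_En_En"]],
                    ip[["alpha_En"]] * hillE / (1 + hillE))
  den <- prod_en - ip[["beta_En"]] * en
  list(dptchh = dptchh, dcia = as.numeric(dcia), den = as.numeric(den))
}

#' Relax the three-node GRN to its steady-state spatial pattern
#'
#' Fixes Hh to the analytic profile of [hh_profile()] and integrates the
#' intracellular equations at every grid node by explicit Euler steps from
#' homogeneous zero initial conditions.  Every `check_every` steps the
#' Euclidean (Norm-2) change of each raw profile since the previous check is
#' compared against `stop_tol`; the run stops when all three dynamic
#' variables change by less than `stop_tol`.  Negative Euler undershoots are
#' clamped to zero (count reported in `n_clamped`).
#'
#' @param p An [ocellar_params()] parameter set.
#' @param grid An [grid1d()] grid.
#' @param stop_tol Norm-2 convergence tolerance (default 0.01).  Use 0 to
#'   force exactly `max_steps` steps (no convergence test can pass).
#' @param dt Euler time step; default `0.1 / max(degradation rates)`,
#'   comfortably below the stiffness limit of the fastest decay.
#' @param max_steps Step budget; if exhausted the returned pattern has
#'   `converged = FALSE` and must be excluded from downstream statistics.
#' @param check_every Steps between convergence checks (default 100).
#' @return An object of class `ocellar_pattern`: list with `grid`, `hh`,
#'   `ptchh`, `cia`, `en`, `converged`, `n_iterations`, `n_clamped`.
#' @export
#' @examples
#' cfg <- default_config()
#' pat <- simulate_steady_state(cfg$params, cfg$grid)
#' pat$converged
simulate_steady_state <- function(p, grid, stop_tol = 0.01, dt = NULL,
                                  max_steps = 200000L, check_every = 100L) {
  stopifnot(inherits(p, "ocellar_params"), inherits(grid, "ocellar_grid"))
  ip <- p$intracellular
  if (is.null(dt))
    dt <- 0.1 / max(ip[["beta_PtcHh"]], ip[["beta_CiA"]], ip[["beta_En"]])
  hh <- hh_profile(p$gradient, grid)
  res <- solve_grn_cpp(hh, as.list(ip), dt, as.integer(max_steps),
                       as.integer(check_every), stop_tol)
  structure(list(grid = grid, hh = hh,
                 ptchh = res$ptchh, cia = res$cia, en = res$en,
                 converged = res$converged,
                 n_iterations = res$n_iterations,
                 n_clamped = res$n_clamped,
                 dt = dt),
            class = "ocellar_pattern")
}

#' @export
print.ocellar_pattern <- function(x, ...) {
  cat(sprintf(
    "ocellar steady-state pattern: %d nodes, %s after %d steps%s\n",
    x$grid$n_points,
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    x$n_iterations,
    if (x$n_clamped > 0) sprintf(" (%d negative values clamped)", x$n_clamped)
    else ""))
  invisible(x)
}

#' Plot the steady-state expression profiles
#'
#' @param x An `ocellar_pattern`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ocellar_pattern <- function(x, ...) {
  m <- cbind(Hh = x$hh / max(x$hh, 1e-12),
             PtcHh = x$ptchh / max(x$ptchh, 1e-12),
             CiA = x$cia / max(x$cia, 1e-12),
             En = x$en / max(x$en, 1e-12))
  graphics::matplot(x$grid$x, m, type = "l", lty = 1,
                    col = c("blue", "red", "darkorange", "darkgreen"),
                    xlab = "x (um)", ylab = "normalized concentration", ...)
  graphics::legend("topright", colnames(m), lty = 1,
                   col = c("blue", "red", "darkorange", "darkgreen"),
                   bty = "n")
  invisible(x)
}

#' Write a pattern to CSV with a JSON sidecar
#'
#' The CSV has columns `x`, `hh`, `ptchh`, `cia`, `en` (one row per node);
#' the sidecar `<file>.json` records convergence, iteration count and the
#' full parameter set.
#'
#' @param pattern An `ocellar_pattern`.
#' @param file Output CSV path.
#' @param params Optional `ocellar_params` recorded in the sidecar.
#' @return `file`, invisibly.
#' @export
write_pattern <- function(pattern, file, params = NULL) {
  df <- data.frame(x = pattern$grid$x, hh = pattern$hh,
                   ptchh = pattern$ptchh, cia = pattern$cia,
                   en = pattern$en)
  utils::write.csv(df, file, row.names = FALSE)
  side <- list(converged = pattern$converged,
               n_iterations = pattern$n_iterations,
               n_clamped = pattern$n_clamped)
  if (!is.null(params))
    side$parameters <- list(gradient = as.list(params$gradient),
                            intracellular = as.list(params$intracellular))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
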