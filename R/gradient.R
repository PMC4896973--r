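#' Steady-state Hh gradient length scale
#'
#' `ell = sqrt(D / beta_Hh)`, the decay length of the exponential tail of
#' the steady-state Hh profile outside the source.
#'
#' @param gp Named vector/list with at least `D` and `beta_Hh`, e.g. the
#'   `gradient` element of an [ocellar_params()] object.
#' @return Length scale in um.
#' @export
gradient_length_scale <- function(gp) {
  gp <- unlist(gp)
  sqrt(gp[["D"]] / gp[["beta_Hh"]])
}

#' Hh concentration at the source boundary
#'
#' The steady-state concentration at `|x| = omega / 2`,
#' `Hh_b = alpha_Hh / (2 beta_Hh) * (1 - exp(-omega / ell))` (the physically
#' decaying branch).
#'
#' @inheritParams gradient_length_scale
#' @return Concentration at the source edge.
#' @export
hh_boundary_value <- function(gp) {
  gp <- unlist(gp)
  ell <- sqrt(gp[["D"]] / gp[["beta_Hh"]])
  gp[["alpha_Hh"]] / (2 * gp[["beta_Hh"]]) * (1 - exp(-gp[["omega"]] / ell))
}

#' Analytic steady-state Hh profile
#'
#' Closed-form solution of the reaction-diffusion equation
#' `D Hh'' - beta_Hh Hh + alpha_Hh * 1(|x| <= omega/2) = 0` on an infinite
#' domain: a plateau-like interior solution
#' `alpha/beta * (1 - exp(-omega/(2 ell)) cosh(x/ell))` inside the source
#' and exponential decay `Hh_b * exp(-(|x| - omega/2)/ell)` outside, joined
#' continuously (with continuous flux) at the source edge.  The profile is
#' an even function of x and non-increasing in `|x|` outside the source.
#'
#' @param gp Gradient parameters (named vector/list with `alpha_Hh`,
#'   `beta_Hh`, `D`, `omega`), or a full `ocellar_params` object.
#' @param grid An [grid1d()] grid.
#' @return Numeric vector of Hh concentrations, one per grid node.
#' @export
#' @examples
#' p <- control_parameters()
#' g <- grid1d(100, 1, param_value(p, "omega"))
#' hh <- hh_profile(p, g)
hh_profile <- function(gp, grid) {
  if (inherits(gp, "ocellar_params")) gp <- gp$gradient
  gp <- unlist(gp)
  for (nm in c("beta_Hh", "D", "omega")) {
    v <- gp[[nm]]
    if (!is.finite(v) || v <= 0)
      stop("gradient parameter ", nm, " must be strictly positive")
  }
  if (!is.finite(gp[["alpha_Hh"]]) || gp[["alpha_Hh"]] < 0)
    stop("gradient parameter alpha_Hh must be non-negative")
  ell <- sqrt(gp[["D"]] / gp[["beta_Hh"]])
  a_over_b <- gp[["alpha_Hh"]] / gp[["beta_Hh"]]
  half_w <- gp[["omega"]] / 2
  hb <- a_over_b / 2 * (1 - exp(-gp[["omega"]] / ell))
  x <- abs(grid$x)
  inside <- x <= half_w
  hh <- numeric(grid$n_points)
  hh[inside] <- a_over_b * (1 - exp(-half_w / ell) * cosh(x[inside] / ell))
  hh[!inside] <- hb * exp(-(x[!inside] - half_w) / ell)
  pmax(hh, 0)
}
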