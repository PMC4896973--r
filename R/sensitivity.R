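#' Simulate one parameter set and score it against the control
#'
#' Internal workhorse shared by the sensitivity and morphospace stages:
#' simulates to steady state and returns the complement `1 - lambda` of the
#' normalized-CiA pattern distance to the control pattern, plus domain
#' lengths and morphospace coordinates.  Failed convergences are scored
#' `complement = 0` and carry `NA` coordinates.
#'
#' @param p An `ocellar_params`.
#' @param grid An `ocellar_grid`.
#' @param control A control reference as returned by [control_reference()].
#' @param solver List of solver options (`stop_tol`, `check_every`,
#'   `max_steps`, `dt`).
#' @return One-row data.frame with `complement`, `converged`, `L_CiA`,
#'   `L_En`, `lambda_CiA`, `lambda_En`.
#' @export
evaluate_params <- function(p, grid, control, solver = list()) {
  pat <- simulate_steady_state(
    p, grid,
    stop_tol = solver$stop_tol %||% 0.01,
    dt = solver$dt,
    max_steps = solver$max_steps %||% 200000L,
    check_every = solver$check_every %||% 100L)
  if (!isTRUE(pat$converged))
    return(data.frame(complement = 0, converged = FALSE,
                      L_CiA = NA_real_, L_En = NA_real_,
                      lambda_CiA = NA_real_, lambda_En = NA_real_))
  d <- pattern_distance(normalize_pattern(pat$cia), control$cia_norm)
  lens <- extract_domain_lengths(pat, reference = control$pattern)
  coords <- morphospace_coords(lens, control$lengths)
  data.frame(complement = d$complement, converged = TRUE,
             L_CiA = lens$L_CiA, L_En = lens$L_En,
             lambda_CiA = coords$lambda_CiA, lambda_En = coords$lambda_En)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the control reference pattern and summary
#'
#' Simulates the control parameter set once and caches the normalized CiA
#' and En profiles and the control domain lengths used by all downstream
#' distance and coordinate computations.
#'
#' @param params Control `ocellar_params` (default the shipped set).
#' @param grid Grid (default from the shipped configuration).
#' @param solver Solver options (default from the shipped configuration).
#' @return A list with `params`, `grid`, `solver`, `pattern`, `cia_norm`,
#'   `en_norm` and `lengths` (list `L_CiA`, `L_En`).
#' @export
control_reference <- function(params = NULL, grid = NULL, solver = NULL) {
  cfg <- default_config()
  params <- params %||% cfg$params
  grid <- grid %||% cfg$grid
  solver <- solver %||% cfg$solver
  pat <- simulate_steady_state(params, grid,
                               stop_tol = solver$stop_tol %||% 0.01,
                               dt = solver$dt,
                               max_steps = solver$max_steps %||% 200000L,
                               check_every = solver$check_every %||% 100L)
  if (!isTRUE(pat$converged))
    stop("control simulation did not converge")
  list(params = params, grid = grid, solver = solver, pattern = pat,
       cia_norm = normalize_pattern(pat$cia),
       en_norm = normalize_pattern(pat$en),
       lengths = extract_domain_lengths(pat))
}

#' One-at-a-time sensitivity scan of a single parameter
#'
#' Holds all parameters at their control values and randomizes one over two
#' orders of magnitude around its control value (log-uniform on
#' `[control/10, 10 * control]`).  Each draw is simulated and scored by the
#' complement `1 - lambda` of the normalized-CiA pattern distance to the
#' control; non-converged draws score 0.
#'
#' @param name One of the 16 intracellular parameter names (gradient
#'   parameters `D` and `beta_Hh` may also be scanned).
#' @param control A [control_reference()].
#' @param n_draws Number of random draws (default 300).
#' @param seed Integer seed; identical seeds give identical scans.
#' @param values Optional explicit vector of values to evaluate instead of
#'   random draws (e.g. a deterministic log-grid).
#' @return An object of class `sensitivity_scan`: list with
#'   `parameter_name`, `control_value`, `draws` (data.frame `value`,
#'   `complement`, `converged`) and `tier_intervals` (NULL until
#'   [derive_tier_intervals()] is called).
#' @export
scan_parameter <- function(name, control, n_draws = 300, seed = 1,
                           values = NULL) {
  if (!name %in% param_names(control$params))
    stop("unknown parameter: ", name)
  cv <- param_value(control$params, name)
  if (is.null(values)) {
    lo <- cv / 10
    hi <- cv * 10
    # Hill coefficients live on [1, Inf): truncate the scanned range at the
    # domain floor rather than drawing invalid exponents
    if (name %in% c("n_CiA", "n_En")) lo <- max(lo, 1)
    values <- 10^with_seed(seed, runif(n_draws, log10(lo), log10(hi)))
  }
  rows <- lapply(values, function(v) {
    # Hill coefficients below 1 are outside the model's domain; a draw there
    # is treated as a failed pattern (complement 0), like a non-convergence.
    if (v < 1 && name %in% c("n_CiA", "n_En"))
      return(data.frame(complement = 0, converged = FALSE,
                        L_CiA = NA_real_, L_En = NA_real_,
                        lambda_CiA = NA_real_, lambda_En = NA_real_))
    p <- set_param(control$params, name, v)
    evaluate_params(p, control$grid, control, control$solver)
  })
  draws <- do.call(rbind, rows)
  draws$value <- values
  structure(list(parameter_name = name, control_value = cv,
                 draws = draws[, c("value", "complement", "converged")],
                 n_failed = sum(!draws$converged),
                 tier_intervals = NULL),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat(sprintf("sensitivity scan of %s (control %.4g): %d draws, min 1-lambda %.3f, %d failed\n",
              x$parameter_name, x$control_value, nrow(x$draws),
              min(x$draws$complement), x$n_failed))
  if (!is.null(x$tier_intervals)) {
    for (tn in names(x$tier_intervals)) {
      b <- tier_bands(x$tier_intervals[[tn]])
      cat(sprintf("  %-6s %s\n", tn,
                  if (is.null(b)) "(empty)"
                  else paste(sprintf("[%.4g, %.4g]", b[, 1], b[, 2]),
                             collapse = " U ")))
    }
  }
  invisible(x)
}

#' Derive per-tier parameter value intervals from a sensitivity scan
#'
#' On each side of the control value the complement `1 - lambda` is
#' regressed isotonically (monotone non-increasing in the log-distance from
#' the control, anchored at complement 1 at the control itself), and the
#' fitted curve's crossings of the 0.8, 0.6 and 0.4 tier thresholds are
#' located.  The good interval is the contiguous region around the control
#' with fitted complement >= 0.8; the medium and bad intervals are taken
#' adjacent to it on the side where the decline is more gradual (the wider
#' candidate band), mirroring tiered ranges such as those printed for
#' `beta_Hh`.  A tier whose complement band is never attained yields a NULL
#' (empty) interval with a warning.
#'
#' @param scan A `sensitivity_scan` with at least 50 draws.
#' @return The scan with `tier_intervals` filled in: a list
#'   `good`/`medium`/`bad` of `c(lo, hi)` or NULL.
#' @export
derive_tier_intervals <- function(scan) {
  d <- scan$draws
  if (nrow(d) < 50) stop("need at least 50 draws to derive tier intervals")
  lv <- log10(d$value)
  cv <- log10(scan$control_value)
  lo_range <- min(c(lv, cv)); hi_range <- max(c(lv, cv))

  # isotonic (non-increasing) fit of complement vs log-distance, one side
  side_fit <- function(side) {
    sel <- if (side > 0) lv >= cv else lv <= cv
    x <- c(0, abs(lv[sel] - cv))
    y <- c(1, d$complement[sel])
    if (length(x) < 5) return(NULL)
    o <- order(x)
    fit <- stats::isoreg(x[o], -y[o])
    list(x = fit$x, y = -fit$yf)
  }
  # first crossing of the fitted curve below a threshold, interpolated
  side_cross <- function(fit, thr) {
    if (is.null(fit)) return(NA_real_)
    idx <- which(fit$y < thr)[1]
    if (is.na(idx)) return(NA_real_)
    if (idx == 1) return(0)
    x0 <- fit$x[idx - 1]; x1 <- fit$x[idx]
    y0 <- fit$y[idx - 1]; y1 <- fit$y[idx]
    if (y0 <= y1) return(x1)
    x0 + (y0 - thr) / (y0 - y1) * (x1 - x0)
  }
  f_lo <- side_fit(-1); f_hi <- side_fit(+1)
  cross <- function(thr)
    c(lo = { x <- side_cross(f_lo, thr); if (is.na(x)) NA_real_ else cv - x },
      hi = { x <- side_cross(f_hi, thr); if (is.na(x)) NA_real_ else cv + x })
  c08 <- cross(0.8); c06 <- cross(0.6); c04 <- cross(0.4)
  good <- c(if (is.na(c08[1])) lo_range else c08[1],
            if (is.na(c08[2])) hi_range else c08[2])

  side_interval <- function(side, outer_cross, inner_cross) {
    # band between two thresholds on one side of the control; NULL if the
    # outer threshold is never reached on that side
    inner <- if (side < 0) inner_cross[1] else inner_cross[2]
    outer <- if (side < 0) outer_cross[1] else outer_cross[2]
    if (is.na(inner)) inner <- if (side < 0) lo_range else hi_range
    if (is.na(outer)) return(NULL)
    iv <- sort(c(outer, inner))
    if (diff(iv) <= 0) return(NULL)
    iv
  }
  # medium and bad tiers keep the bands from BOTH sides of the control
  # (each a contiguous interval), so tier sampling mixes both directions
  # of parameter change, as the published phenotype clouds do
  both_bands <- function(outer_cross, inner_cross) {
    bands <- list(side_interval(-1, outer_cross, inner_cross),
                  side_interval(+1, outer_cross, inner_cross))
    bands <- bands[!vapply(bands, is.null, logical(1))]
    if (length(bands) == 0) NULL else bands
  }
  medium <- both_bands(c06, c08)
  bad <- both_bands(c04, c06)

  back1 <- function(iv) if (is.null(iv)) NULL else 10^iv
  backn <- function(bands) if (is.null(bands)) NULL else lapply(bands, back1)
  ivs <- list(good = back1(good), medium = backn(medium), bad = backn(bad))
  clip1 <- function(iv) {
    if (is.null(iv)) return(NULL)
    iv[1] <- max(iv[1], 1)
    if (iv[2] <= iv[1]) NULL else iv
  }
  if (scan$parameter_name %in% c("n_CiA", "n_En")) {
    # Hill coefficients live on [1, Inf): clip bands to the domain
    ivs$good <- clip1(ivs$good)
    for (tn in c("medium", "bad")) {
      if (is.null(ivs[[tn]])) next
      bands <- lapply(ivs[[tn]], clip1)
      bands <- bands[!vapply(bands, is.null, logical(1))]
      ivs[[tn]] <- if (length(bands) == 0) NULL else bands
    }
  }
  for (tn in c("medium", "bad"))
    if (is.null(ivs[[tn]]))
      warning("no draws attain the ", tn, " tier for ", scan$parameter_name,
              "; interval left empty", call. = FALSE)
  scan$tier_intervals <- ivs
  scan
}

#' @keywords internal
# normalize a tier entry (NULL, c(lo, hi), or list of such bands) to a
# 2-column matrix with one row per band
tier_bands <- function(iv) {
  if (is.null(iv)) return(NULL)
  if (is.numeric(iv)) return(matrix(iv, ncol = 2))
  do.call(rbind, lapply(iv, function(b) matrix(as.numeric(b), ncol = 2)))
}

#' @keywords internal
# n uniform draws from a union of bands (band chosen by relative width)
draw_from_tier <- function(n, iv) {
  b <- tier_bands(iv)
  w <- b[, 2] - b[, 1]
  which_band <- sample.int(nrow(b), n, replace = TRUE,
                           prob = pmax(w, 1e-12))
  runif(n, b[which_band, 1], b[which_band, 2])
}

#' Scan all intracellular parameters and derive tier intervals
#'
#' Runs [scan_parameter()] followed by [derive_tier_intervals()] for each of
#' the 16 intracellular parameters, deriving per-stage seeds from `seed`.
#' The printed literature ranges for the gradient parameters `D` and
#' `beta_Hh` are taken from the configuration (`gradient_tiers`) rather than
#' derived.
#'
#' @param control A [control_reference()].
#' @param n_draws Draws per parameter (default 300).
#' @param seed Master seed.
#' @param parameters Parameter names to scan (default all 16 intracellular).
#' @param include_gradient Also attach the configured `D`/`beta_Hh` tier
#'   intervals from the shipped configuration (default TRUE).
#' @return Named list of `sensitivity_scan` objects (with
#'   `tier_intervals`); configured gradient entries carry
#'   `derived = FALSE`.
#' @export
scan_all_parameters <- function(control, n_draws = 300, seed = 1,
                                parameters = intracellular_param_names(),
                                include_gradient = TRUE) {
  scans <- list()
  for (i in seq_along(parameters)) {
    nm <- parameters[i]
    scans[[nm]] <- derive_tier_intervals(
      scan_parameter(nm, control, n_draws = n_draws,
                     seed = stage_seed(seed, nm)))
  }
  if (include_gradient) {
    tiers <- default_config()$gradient_tiers
    for (nm in names(tiers)) {
      scans[[nm]] <- structure(
        list(parameter_name = nm,
             control_value = param_value(control$params, nm),
             draws = NULL, n_failed = 0L,
             tier_intervals = lapply(tiers[[nm]], as.numeric),
             derived = FALSE),
        class = "sensitivity_scan")
    }
  }
  scans
}

#' Extract the per-parameter tier interval table
#'
#' @param scans Named list of scans from [scan_all_parameters()].
#' @return Named list: for each parameter a list `good`/`medium`/`bad` of
#'   `c(lo, hi)` or NULL.
#' @export
tier_interval_table <- function(scans) {
  lapply(scans, function(s) s$tier_intervals)
}

#' Write/read tier intervals as YAML
#'
#' @param intervals A tier-interval table from [tier_interval_table()].
#' @param path File path.
#' @return `path` (write) or the interval table (read).
#' @export
write_tier_intervals <- function(intervals, path) {
  serialize_tier <- function(iv) {
    b <- tier_bands(iv)
    if (is.null(b)) return(NULL)
    lapply(seq_len(nrow(b)), function(i) as.numeric(b[i, ]))
  }
  yaml::write_yaml(lapply(intervals, function(tl)
    lapply(tl, serialize_tier)), path, precision = 12)
  invisible(path)
}

#' @rdname write_tier_intervals
#' @export
read_tier_intervals <- function(path) {
  parse_tier <- function(iv) {
    if (is.null(iv)) return(NULL)
    bands <- lapply(iv, as.numeric)
    if (length(bands) == 1) bands[[1]] else bands
  }
  lapply(yaml::read_yaml(path), function(tl) lapply(tl, parse_tier))
}
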