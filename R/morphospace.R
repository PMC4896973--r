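#' Sample the randomized-parameter morphospace
#'
#' For each goodness tier, every varied parameter is drawn independently
#' and uniformly from that parameter's tier interval, the model is
#' simulated, and the instance is placed in the (lambda_CiA, lambda_En)
#' plane of relative domain-length deviations from the control.  The tier
#' label records the interval the values were drawn from, not the resulting
#' pattern's own complement (both are stored).  The Hh gradient stays fixed
#' at control unless `D`/`beta_Hh` are included in `varied`.
#'
#' @param control A [control_reference()].
#' @param intervals Tier-interval table from [tier_interval_table()] (or
#'   [scan_all_parameters()] output).
#' @param n_per_tier Instances per tier (default 3000).
#' @param seed Integer seed; the full sample is reproducible from
#'   `(seed, n_per_tier, intervals)`.
#' @param varied Names of parameters to randomize (default all 16
#'   intracellular parameters).
#' @param tiers Tiers to sample (default good, medium, bad).
#' @return A data.frame of class `ocellar_morphospace`: one row per
#'   instance with all varied parameter values, `tier_requested`,
#'   `converged`, `L_CiA`, `L_En`, `lambda_CiA`, `lambda_En`, `complement`.
#'   Attributes: `control_lengths`, `seed`, `n_per_tier`, `varied`.
#' @export
sample_morphospace <- function(control, intervals, n_per_tier = 3000,
                               seed = 1,
                               varied = intracellular_param_names(),
                               tiers = c("good", "medium", "bad")) {
  if (inherits(intervals[[1]], "sensitivity_scan"))
    intervals <- tier_interval_table(intervals)
  for (nm in varied) {
    if (is.null(intervals[[nm]]))
      stop("no tier intervals available for parameter ", nm)
    for (tn in tiers)
      if (is.null(intervals[[nm]][[tn]]))
        stop("empty ", tn, " interval for parameter ", nm)
  }
  rows <- list()
  for (tn in tiers) {
    draws <- with_seed(stage_seed(seed, paste0("morphospace-", tn)), {
      m <- matrix(NA_real_, n_per_tier, length(varied),
                  dimnames = list(NULL, varied))
      for (nm in varied)
        m[, nm] <- draw_from_tier(n_per_tier, intervals[[nm]][[tn]])
      m
    })
    for (i in seq_len(n_per_tier)) {
      p <- control$params
      for (nm in varied) p <- set_param(p, nm, draws[i, nm])
      ev <- evaluate_params(p, control$grid, control, control$solver)
      rows[[length(rows) + 1L]] <-
        cbind(as.data.frame(t(draws[i, , drop = TRUE])),
              tier_requested = tn, ev)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_failed <- sum(!out$converged)
  if (n_failed > 0)
    message(n_failed, " of ", nrow(out),
            " morphospace simulations did not converge")
  structure(out,
            control_lengths = control$lengths, seed = seed,
            n_per_tier = n_per_tier, varied = varied,
            class = c("ocellar_morphospace", "data.frame"))
}

#' Covariation morphospace for a parameter subset
#'
#' Randomizes only `subset`, pinning all other parameters at control.  In
#' `"simultaneous"` mode each instance draws every subset parameter jointly;
#' in `"independent"` mode the sample is the union of single-parameter
#' randomizations (n split evenly across the subset).  Values are drawn
#' uniformly from each parameter's envelope interval, the union of its
#' good/medium/bad tier intervals.
#'
#' @param control A [control_reference()].
#' @param intervals Tier-interval table.
#' @param subset Character vector of parameter names to covary.
#' @param n Total number of instances (default 1000).
#' @param seed Integer seed.
#' @param mode `"simultaneous"` or `"independent"`.
#' @return An `ocellar_morphospace` data.frame (tier_requested = mode).
#' @export
covariation_morphospace <- function(control, intervals, subset, n = 1000,
                                    seed = 1,
                                    mode = c("simultaneous", "independent")) {
  mode <- match.arg(mode)
  if (length(subset) < 1) stop("subset must be non-empty")
  if (inherits(intervals[[1]], "sensitivity_scan"))
    intervals <- tier_interval_table(intervals)
  unknown <- setdiff(subset, param_names(control$params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  envelope <- lapply(subset, function(nm) {
    tl <- intervals[[nm]]
    if (is.null(tl)) stop("no tier intervals available for parameter ", nm)
    b <- do.call(rbind, lapply(tl[!vapply(tl, is.null, logical(1))],
                               tier_bands))
    c(min(b[, 1]), max(b[, 2]))
  })
  names(envelope) <- subset

  draw_matrix <- with_seed(stage_seed(seed, paste0("covary-", mode)), {
    m <- matrix(rep(vapply(subset, function(nm)
      param_value(control$params, nm), numeric(1)), each = n),
      n, length(subset), dimnames = list(NULL, subset))
    if (mode == "simultaneous") {
      for (nm in subset)
        m[, nm] <- runif(n, envelope[[nm]][1], envelope[[nm]][2])
    } else {
      # union of single-parameter randomizations
      grp <- rep(seq_along(subset), length.out = n)
      for (j in seq_along(subset)) {
        idx <- which(grp == j)
        nm <- subset[j]
        m[idx, nm] <- runif(length(idx), envelope[[nm]][1],
                            envelope[[nm]][2])
      }
    }
    m
  })
  rows <- lapply(seq_len(n), function(i) {
    p <- control$params
    for (nm in subset) p <- set_param(p, nm, draw_matrix[i, nm])
    ev <- evaluate_params(p, control$grid, control, control$solver)
    cbind(as.data.frame(t(draw_matrix[i, , drop = TRUE])),
          tier_requested = mode, ev)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            control_lengths = control$lengths, seed = seed,
            n_per_tier = n, varied = subset,
            class = c("ocellar_morphospace", "data.frame"))
}

#' Write a morphospace sample to CSV
#'
#' @param sample An `ocellar_morphospace`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_morphospace <- function(sample, file) {
  utils::write.csv(as.data.frame(sample), file, row.names = FALSE)
  invisible(file)
}

#' Plot a morphospace sample
#'
#' @param x An `ocellar_morphospace`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ocellar_morphospace <- function(x, ...) {
  ok <- x$converged
  cols <- c(good = "steelblue", medium = "firebrick", bad = "goldenrod",
            simultaneous = "grey30", independent = "grey60")
  graphics::plot(x$lambda_CiA[ok], x$lambda_En[ok],
                 col = cols[as.character(x$tier_requested[ok])],
                 pch = 16, cex = 0.5,
                 xlab = expression(lambda[CiA]), ylab = expression(lambda[En]),
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  invisible(x)
}
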