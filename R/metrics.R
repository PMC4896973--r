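#' Normalize an expression profile to [0, 1]
#'
#' Divides by the profile maximum; an all-zero profile is returned
#' unchanged.
#'
#' @param profile Nonnegative numeric vector.
#' @return Vector of the same length with values in `[0, 1]`.
#' @export
normalize_pattern <- function(profile) {
  if (any(profile < 0)) stop("profile must be nonnegative")
  m <- max(profile)
  if (m == 0) return(profile)
  profile / m
}

#' Assign a goodness tier from a complementary distance
#'
#' Tiers follow right-closed/left-open boundaries: `good` iff
#' `1 - lambda >= 0.8`, `medium` iff `0.6 <= 1 - lambda < 0.8`, `bad` iff
#' `0.4 <= 1 - lambda < 0.6`, `reject` otherwise.
#'
#' @param complement Complementary distance `1 - lambda` (vectorized).
#' @return Character vector of tier labels.
#' @export
goodness_tier <- function(complement) {
  ifelse(complement >= 0.8, "good",
         ifelse(complement >= 0.6, "medium",
                ifelse(complement >= 0.4, "bad", "reject")))
}

#' Euclidean distance between two normalized patterns
#'
#' The distance statistic `lambda = sqrt(sum((b_i - a_i)^2))` between two
#' equal-length normalized profiles.  By default (`scaled = TRUE`) each
#' profile is first rescaled to a unit Euclidean vector, so lambda measures
#' pure shape difference on a scale from 0 (identical shapes) to sqrt(2)
#' (disjoint supports), independent of grid resolution; the 0.8/0.6/0.4
#' tier thresholds are defined on this scale.  For max-normalized profiles
#' (maximum 1, as produced by [normalize_pattern()]) the scaled form is a
#' true metric: two such profiles with zero distance are identical.  Set
#' `scaled = FALSE` for the raw Euclidean form of the distance.
#'
#' @param a,b Numeric vectors of equal length (normalized profiles).
#' @param scaled Rescale both profiles to unit norm first (default TRUE).
#' @return A `goodness_score`: list with `lambda_dist`, `complement`
#'   (`1 - lambda_dist`) and `tier`.
#' @export
#' @examples
#' pattern_distance(c(0, 0), c(3, 4), scaled = FALSE)$lambda_dist  # 5
pattern_distance <- function(a, b, scaled = TRUE) {
  if (length(a) != length(b))
    stop("patterns must have equal length")
  if (scaled) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na > 0) a <- a / na
    if (nb > 0) b <- b / nb
  }
  lambda <- sqrt(sum((b - a)^2))
  structure(list(lambda_dist = lambda,
                 complement = 1 - lambda,
                 tier = goodness_tier(1 - lambda)),
            class = "goodness_score")
}

#' @keywords internal
contiguous_runs <- function(flag) {
  # start/end indices of maximal TRUE runs
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values],
             len = r$lengths[r$values])
}

#' Extract OC and IOC domain lengths from a steady-state pattern
#'
#' Domains are supports of the normalized profiles above the fraction
#' `theta` of their maximum, with the domain edges located by linear
#' interpolation between the bounding grid nodes (half a cell beyond the
#' boundary node when the run touches the grid edge), so lengths vary
#' continuously rather than in whole grid cells.  A boxcar profile of `k`
#' above-threshold nodes has length `k * dx` exactly.  `L_En` is the length
#' of the contiguous above-threshold En run covering (or nearest to)
#' x = 0; `L_CiA` is the mean length of the two largest above-threshold
#' CiA runs flanking the En domain (one per side).  Zero-length domains
#' are allowed.
#'
#' @param pat A converged `ocellar_pattern`.
#' @param theta Threshold fraction of the profile maximum (default 0.5).
#' @param reference Optional `ocellar_pattern` whose profile maxima anchor
#'   the thresholds (typically the control).  By default each profile is
#'   thresholded against its own maximum, which measures pure shape; with a
#'   reference, domains are regions exceeding a fixed concentration
#'   (`theta` times the reference maximum), so amplitude changes move the
#'   domain edges — the reading used throughout the morphospace pipeline,
#'   where domain identity corresponds to crossing a fixed target-gene
#'   activation threshold.
#' @return A list with `L_CiA` and `L_En` (um).
#' @export
extract_domain_lengths <- function(pat, theta = 0.5, reference = NULL) {
  if (!isTRUE(pat$converged))
    stop("pattern did not converge; domain lengths are undefined")
  dx <- pat$grid$dx
  np <- pat$grid$n_points
  centre <- (np + 1) / 2
  ref_cia <- if (is.null(reference)) max(pat$cia) else max(reference$cia)
  ref_en <- if (is.null(reference)) max(pat$en) else max(reference$en)

  run_length <- function(v, run) {
    # interpolated span of an above-threshold run [start, end] (node idx)
    i0 <- run$start; i1 <- run$end
    left <- if (i0 == 1) 0.5
      else (v[i0] - theta) / (v[i0] - v[i0 - 1]) + 0  # fraction of dx
    right <- if (i1 == np) 0.5
      else (v[i1] - theta) / (v[i1] - v[i1 + 1])
    # clamp degenerate interpolation (flat neighbours)
    left <- min(max(left, 0), 1)
    right <- min(max(right, 0), 1)
    ((i1 - i0) + left + right) * dx
  }

  en_n <- if (ref_en > 0) pat$en / ref_en else pat$en
  en_on <- en_n >= theta & ref_en > 0
  L_en <- 0
  if (any(en_on)) {
    runs <- contiguous_runs(en_on)
    hit <- runs$start <= centre & runs$end >= centre
    en_run <- if (any(hit)) runs[which(hit)[1], ]
      else runs[which.min(pmin(abs(runs$start - centre),
                               abs(runs$end - centre))), ]
    L_en <- run_length(en_n, en_run)
  }

  cia_n <- if (ref_cia > 0) pat$cia / ref_cia else pat$cia
  cia_on <- cia_n >= theta & ref_cia > 0
  L_cia <- 0
  if (any(cia_on)) {
    runs <- contiguous_runs(cia_on)
    left <- runs[runs$end <= centre, , drop = FALSE]
    right <- runs[runs$start >= centre, , drop = FALSE]
    straddle <- runs[runs$start < centre & runs$end > centre, , drop = FALSE]
    if (nrow(straddle) > 0 && nrow(left) == 0 && nrow(right) == 0) {
      # single central CiA run (degenerate: no En domain splits it)
      L_cia <- run_length(cia_n, straddle[which.max(straddle$len), ])
    } else {
      l_len <- if (nrow(left))
        run_length(cia_n, left[which.max(left$len), ]) else 0
      r_len <- if (nrow(right))
        run_length(cia_n, right[which.max(right$len), ]) else 0
      L_cia <- (l_len + r_len) / 2
    }
  }
  list(L_CiA = L_cia, L_En = L_en)
}

#' Morphospace coordinates: relative deviation of domain lengths
#'
#' `lambda_CiA = (L_CiA - L_CiA_control) / L_CiA_control` and the analogous
#' `lambda_En`.  The control maps to (0, 0); negative values mean smaller
#' domains than the control, positive larger.
#'
#' @param s List with `L_CiA`, `L_En` (e.g. from
#'   [extract_domain_lengths()]).
#' @param control Control summary with strictly positive `L_CiA`, `L_En`.
#' @return A list with `lambda_CiA` and `lambda_En`.
#' @export
#' @examples
#' morphospace_coords(list(L_CiA = 12, L_En = 25),
#'                    control = list(L_CiA = 15, L_En = 20))
morphospace_coords <- function(s, control) {
  if (control$L_CiA <= 0 || control$L_En <= 0)
    stop("control domain lengths must be strictly positive")
  list(lambda_CiA = (s$L_CiA - control$L_CiA) / control$L_CiA,
       lambda_En = (s$L_En - control$L_En) / control$L_En)
}
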