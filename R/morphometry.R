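#' Normalize specimen measurements by head size
#'
#' Left/right posterior-ocellus lengths and interocellar distances are
#' averaged and divided by the anterior orbital bristle distance (`aobd`),
#' the head-width proxy, making values unit-free and robust to overall head
#' size.  A missing side (NA) falls back to the available side and is
#' flagged.
#'
#' @param records Data.frame with columns `species`, `specimen_id`, `sex`,
#'   `aoc_len`, `poc_len_left`, `poc_len_right`, `ioc_left`, `ioc_right`,
#'   `aobd`.
#' @return The input with added columns `poc_norm`, `ioc_norm`,
#'   `side_missing` (logical).
#' @export
#' @examples
#' r <- data.frame(species = "s", specimen_id = 1, sex = "F", aoc_len = 11,
#'                 poc_len_left = 10, poc_len_right = 10,
#'                 ioc_left = 30, ioc_right = 30, aobd = 100)
#' normalize_specimen(r)[, c("poc_norm", "ioc_norm")]  # 0.10, 0.30
normalize_specimen <- function(records) {
  req <- c("species", "aobd", "poc_len_left", "poc_len_right",
           "ioc_left", "ioc_right")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$aobd <= 0, na.rm = TRUE))
    stop("aobd must be strictly positive")
  side_mean <- function(l, r) {
    out <- rowMeans(cbind(l, r), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  poc <- side_mean(records$poc_len_left, records$poc_len_right)
  ioc <- side_mean(records$ioc_left, records$ioc_right)
  records$poc_norm <- poc / records$aobd
  records$ioc_norm <- ioc / records$aobd
  records$side_missing <- is.na(records$poc_len_left) |
    is.na(records$poc_len_right) | is.na(records$ioc_left) |
    is.na(records$ioc_right)
  records
}

#' Place species in the empirical morphospace relative to a reference
#'
#' Computes per-species mean and SD of normalized posterior-ocellus and
#' interocellar lengths (females only, by default) and expresses each
#' species as relative deviations from the reference species:
#' `lambda_OC = (mean_pOC - mean_pOC_ref) / mean_pOC_ref` and analogously
#' `lambda_IOC`.  The reference maps exactly to (0, 0).
#'
#' @param records Specimen data.frame (see [normalize_specimen()]); a `sex`
#'   column is used for the female filter when present.
#' @param reference_species Species name used as the origin; must be
#'   present with at least 2 specimens.
#' @param females_only Keep only specimens with sex `"F"`/`"female"`
#'   (default TRUE).
#' @return Data.frame with one row per species: `species`, `n`,
#'   `mean_poc`, `sd_poc`, `mean_ioc`, `sd_ioc`, `lambda_OC`,
#'   `lambda_IOC`.
#' @export
species_morphospace <- function(records, reference_species,
                                females_only = TRUE) {
  df <- normalize_specimen(records)
  if (females_only && !is.null(df$sex))
    df <- df[toupper(substr(as.character(df$sex), 1, 1)) == "F", ,
             drop = FALSE]
  if (!reference_species %in% df$species)
    stop("reference species absent: ", reference_species)
  agg <- function(v, f) tapply(v, df$species, f)
  out <- data.frame(species = names(agg(df$poc_norm, mean)),
                    n = as.integer(agg(df$poc_norm, length)),
                    mean_poc = as.numeric(agg(df$poc_norm, mean)),
                    sd_poc = as.numeric(agg(df$poc_norm, sd)),
                    mean_ioc = as.numeric(agg(df$ioc_norm, mean)),
                    sd_ioc = as.numeric(agg(df$ioc_norm, sd)),
                    row.names = NULL)
  ref <- out[out$species == reference_species, ]
  if (ref$n < 2)
    stop("reference species needs at least 2 specimens")
  out$lambda_OC <- (out$mean_poc - ref$mean_poc) / ref$mean_poc
  out$lambda_IOC <- (out$mean_ioc - ref$mean_ioc) / ref$mean_ioc
  out
}

#' Overlap of an empirical species cloud with a simulated morphospace
#'
#' Fraction of species centres `(lambda_OC, lambda_IOC)` lying inside the
#' convex hull of the converged simulated cloud `(lambda_CiA, lambda_En)` -
#' a scalar operationalization of the qualitative overlap between measured
#' and predicted phenotypic spaces.
#'
#' @param species Data.frame from [species_morphospace()].
#' @param sample An `ocellar_morphospace`.
#' @return Fraction in `[0, 1]`.
#' @export
morphospace_overlap <- function(species, sample) {
  s <- as.data.frame(sample)
  s <- s[s$converged & is.finite(s$lambda_CiA), , drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 simulated points")
  hull <- s[grDevices::chull(s$lambda_CiA, s$lambda_En), ]
  inside <- vapply(seq_len(nrow(species)), function(i)
    point_in_polygon(species$lambda_OC[i], species$lambda_IOC[i],
                     hull$lambda_CiA, hull$lambda_En), logical(1))
  mean(inside)
}

# ray-casting point-in-polygon (boundary counts as inside)
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    # boundary tolerance
    d <- abs((vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]))
    if (d < 1e-12 &&
        px >= min(vx[i], vx[j]) - 1e-12 && px <= max(vx[i], vx[j]) + 1e-12 &&
        py >= min(vy[i], vy[j]) - 1e-12 && py <= max(vy[i], vy[j]) + 1e-12)
      return(TRUE)
    j <- i
  }
  inside
}
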