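#' Generate a synthetic species measurement table
#'
#' Emulates a multi-species ocellar morphometry survey: species centres are
#' scattered in the normalized (lambda_OC, lambda_IOC) plane with
#' quadrant-occupancy weights that under-populate the small-IOC
#' (`lambda_IOC < 0`) half (too-short interocellar distances are rarely
#' realized), a reference species sits at the origin, and each specimen
#' receives multiplicative measurement noise.  Fixtures are generated in
#' normalized-trait space and back-transformed to raw lengths through a
#' random per-specimen head size (`aobd`), so the normalization step stays
#' non-trivial under test.
#'
#' @param n_species Number of species, including the reference
#'   (default 41).
#' @param specimens_range Inclusive range of specimens per species
#'   (default `c(2, 14)`).
#' @param reference_species Name of the reference species
#'   (default `"D. melanogaster"`).
#' @param quadrant_weights Occupancy weights for the quadrants
#'   (`pp` = both larger, `np` = smaller OC/larger IOC, `pn`, `nn`); must
#'   sum to 1.  The default puts 0.8 of the mass at `lambda_IOC > 0`.
#' @param radial_spread SD of the half-normal coordinate magnitudes
#'   (default 0.25).
#' @param noise_sd Specimen-level multiplicative noise SD as a fraction of
#'   the mean (default 0.05).
#' @param ref_poc,ref_ioc Reference normalized trait values
#'   (defaults 0.10 and 0.30).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A list with `records` (specimen data.frame suitable for
#'   [species_morphospace()]) and `centers` (data.frame of the generating
#'   species coordinates `lambda_OC`, `lambda_IOC`).
#' @export
make_species_table <- function(n_species = 41, specimens_range = c(2, 14),
                               reference_species = "D. melanogaster",
                               quadrant_weights = c(pp = 0.40, np = 0.40,
                                                    pn = 0.10, nn = 0.10),
                               radial_spread = 0.25, noise_sd = 0.05,
                               ref_poc = 0.10, ref_ioc = 0.30, seed = 1) {
  if (abs(sum(quadrant_weights) - 1) > 1e-8)
    stop("quadrant weights must sum to 1")
  with_seed(seed, {
    signs <- list(pp = c(1, 1), np = c(-1, 1), pn = c(1, -1), nn = c(-1, -1))
    sp_names <- c(reference_species,
                  sprintf("species_%02d", seq_len(n_species - 1)))
    centers <- data.frame(species = sp_names,
                          lambda_OC = 0, lambda_IOC = 0)
    for (i in seq_len(n_species - 1) + 1) {
      q <- sample(names(quadrant_weights), 1, prob = quadrant_weights)
      mag <- pmin(abs(rnorm(2, 0, radial_spread)), 0.8)
      centers$lambda_OC[i] <- signs[[q]][1] * mag[1]
      centers$lambda_IOC[i] <- signs[[q]][2] * mag[2]
    }
    recs <- list()
    for (i in seq_len(n_species)) {
      n_spec <- sample(seq(specimens_range[1], specimens_range[2]), 1)
      poc_mean <- ref_poc * (1 + centers$lambda_OC[i])
      ioc_mean <- ref_ioc * (1 + centers$lambda_IOC[i])
      aobd <- rlnorm(n_spec, log(100), 0.08)
      noise <- function() 1 + rnorm(n_spec, 0, noise_sd)
      recs[[i]] <- data.frame(
        species = centers$species[i],
        specimen_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "",
                                              centers$species[i]),
                              seq_len(n_spec)),
        sex = "F",
        aoc_len = poc_mean * 1.1 * aobd * noise(),
        poc_len_left = poc_mean * aobd * noise(),
        poc_len_right = poc_mean * aobd * noise(),
        ioc_left = ioc_mean * aobd * noise(),
        ioc_right = ioc_mean * aobd * noise(),
        aobd = aobd)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    list(records = records, centers = centers)
  })
}

#' Generate a planted-signal classification dataset
#'
#' Parameter vectors are uniform on `[0, 1]`; the class is 1 exactly for
#' the top third of the informative parameter (by rank, so an
#' equal-frequency tercile boundary separates the classes exactly),
#' optionally corrupted by independent label flips.  The Bayes-optimal
#' accuracy is therefore `100 * (1 - noise)` percent.
#'
#' @param n Number of instances (>= 100).
#' @param n_params Number of parameter columns (default 8).
#' @param informative Name/index of the class-determining column
#'   (default the first).
#' @param noise Label-flip probability (default 0).
#' @param seed Integer seed.
#' @return A list with `features` (data.frame `x1..xp`), `labels` (0/1
#'   integer vector) and `bayes_accuracy` (percent).
#' @export
make_planted_classification_set <- function(n = 2000, n_params = 8,
                                            informative = "x1", noise = 0,
                                            seed = 1) {
  if (n < 100) stop("n must be at least 100")
  with_seed(seed, {
    features <- as.data.frame(matrix(runif(n * n_params), n, n_params,
                                     dimnames = list(NULL,
                                                     paste0("x", seq_len(n_params)))))
    v <- features[[informative]]
    labels <- as.integer(rank(v, ties.method = "first") > 2 * n / 3)
    if (noise > 0) {
      flip <- runif(n) < noise
      labels[flip] <- 1L - labels[flip]
    }
    list(features = features, labels = labels,
         bayes_accuracy = 100 * (1 - noise))
  })
}
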