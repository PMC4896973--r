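#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' package randomness never leaks into (or depends on) the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic, label-dependent, and kept below 2^31 so it is always a
#' valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param label Stage label (character).
#' @return Integer seed.
#' @export
stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483587 + 1)
}

#' Write a run manifest alongside stage outputs
#'
#' Records the command/stage name, seed, package version, timestamp, input
#' configuration hash (if a file is given) and the list of output files.
#'
#' @param path Manifest JSON path.
#' @param command Stage name.
#' @param seed Seed(s) used.
#' @param outputs Character vector of output file paths.
#' @param config_file Optional configuration file to hash (md5).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed, outputs,
                           config_file = NULL) {
  man <- list(command = command,
              seed = seed,
              package_version = as.character(utils::packageVersion("ocellar")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = as.list(outputs))
  if (!is.null(config_file) && file.exists(config_file))
    man$config_md5 <- unname(tools::md5sum(config_file))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
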