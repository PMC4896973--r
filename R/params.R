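#' @keywords internal
GRADIENT_PARAM_NAMES <- c("alpha_Hh", "beta_Hh", "D", "omega")

#' Names of the 16 intracellular parameters of the three-node GRN
#'
#' Basal production rates (`alpha_PtcHh`, `alpha_CiA`, `alpha_En`),
#' degradation rates (`beta_PtcHh`, `beta_CiA`, `beta_En`), interaction
#' strengths (`alpha_CiA_PtcHh`, `alpha_En_PtcHh`, `alpha_En_CiA`,
#' `alpha_En_En`), Hill constants (`k_PtcHh`, `k_CiA`, `k_En`), Hill
#' coefficients (`n_CiA`, `n_En`) and the En self-maintenance threshold
#' `zeta_En`.
#'
#' @return Character vector of length 16.
#' @export
intracellular_param_names <- function() {
  c("alpha_PtcHh", "alpha_CiA", "alpha_En",
    "beta_PtcHh", "beta_CiA", "beta_En",
    "alpha_CiA_PtcHh", "alpha_En_PtcHh", "alpha_En_CiA", "alpha_En_En",
    "k_PtcHh", "k_CiA", "k_En",
    "n_CiA", "n_En", "zeta_En")
}

#' Construct a validated parameter set for the three-node GRN
#'
#' @param gradient Named list/vector with `alpha_Hh` (Hh production,
#'   concentration s^-1), `beta_Hh` (Hh turnover, s^-1), `D` (effective Hh
#'   diffusion, um^2 s^-1) and `omega` (Hh source width, um).
#' @param intracellular Named list/vector with the 16 parameters listed by
#'   [intracellular_param_names()].  Intracellular rates are expressed in
#'   scaled concentration/time units; only their steady state matters.
#'
#' @return An object of class `ocellar_params`: a list with elements
#'   `gradient` and `intracellular` (both named numeric vectors).
#' @export
#' @examples
#' p <- control_parameters()
#' param_value(p, "zeta_En")
ocellar_params <- function(gradient, intracellular) {
  gradient <- unlist(gradient)
  intracellular <- unlist(intracellular)
  miss <- setdiff(GRADIENT_PARAM_NAMES, names(gradient))
  if (length(miss))
    stop("missing gradient parameter(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(gradient), GRADIENT_PARAM_NAMES)
  if (length(extra))
    stop("unknown gradient parameter(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(intracellular_param_names(), names(intracellular))
  if (length(miss))
    stop("missing intracellular parameter(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(intracellular), intracellular_param_names())
  if (length(extra))
    stop("unknown intracellular parameter(s): ", paste(extra, collapse = ", "))
  gradient <- gradient[GRADIENT_PARAM_NAMES]
  intracellular <- intracellular[intracellular_param_names()]
  all <- c(gradient, intracellular)
  bad <- names(all)[!is.finite(all) | all <= 0]
  bad <- setdiff(bad, if (is.finite(all[["alpha_Hh"]]) &&
                          all[["alpha_Hh"]] == 0) "alpha_Hh")
  if (length(bad))
    stop("parameter(s) must be strictly positive and finite: ",
         paste(bad, collapse = ", "))
  for (nm in c("n_CiA", "n_En"))
    if (intracellular[[nm]] < 1)
      stop("Hill coefficient ", nm, " must be >= 1")
  structure(list(gradient = gradient, intracellular = intracellular),
            class = "ocellar_params")
}

#' Flat accessors for a parameter set
#'
#' `param_names()` returns all parameter names (gradient then intracellular);
#' `param_value()` reads one parameter by name; `set_param()` returns a new
#' parameter set with one value replaced (re-validated).
#'
#' @param p An `ocellar_params` object.
#' @param name Parameter name.
#' @param value New positive value.
#' @return `param_names()`: character vector; `param_value()`: numeric
#'   scalar; `set_param()`: a new `ocellar_params`.
#' @export
param_names <- function(p) c(names(p$gradient), names(p$intracellular))

#' @rdname param_names
#' @export
param_value <- function(p, name) {
  if (name %in% names(p$gradient)) return(unname(p$gradient[[name]]))
  if (name %in% names(p$intracellular)) return(unname(p$intracellular[[name]]))
  stop("unknown parameter: ", name)
}

#' @rdname param_names
#' @export
set_param <- function(p, name, value) {
  g <- p$gradient; ic <- p$intracellular
  if (name %in% names(g)) g[[name]] <- value
  else if (name %in% names(ic)) ic[[name]] <- value
  else stop("unknown parameter: ", name)
  ocellar_params(g, ic)
}

#' @export
print.ocellar_params <- function(x, ...) {
  cat("Three-node ocellar GRN parameters\n")
  cat("  gradient:      ",
      paste(sprintf("%s=%.4g", names(x$gradient), x$gradient), collapse = ", "),
      "\n")
  cat("  length scale ell =", format(gradient_length_scale(x$gradient)),
      "um\n")
  cat("  intracellular:\n")
  ic <- x$intracellular
  for (i in seq(1, length(ic), by = 4)) {
    j <- seq(i, min(i + 3, length(ic)))
    cat("   ", paste(sprintf("%s=%.4g", names(ic)[j], ic[j]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' The shipped control parameter set
#'
#' The control represents a reference (D. melanogaster-like) ocellar
#' pattern: an En-positive IOC domain over the centre of the Hh source,
#' flanked by two CiA-positive OC domains.  All sensitivity and morphospace
#' analyses measure deviation from this set.  Values are read from the
#' package's default configuration file.
#'
#' @return An `ocellar_params` object.
#' @export
control_parameters <- function() {
  cfg <- load_config(system.file("extdata", "control_config.yaml",
                                 package = "ocellar"))
  cfg$params
}

#' Default configuration (grid, solver, gradient tier ranges)
#'
#' @return A list as returned by [load_config()] for the shipped default
#'   configuration file.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "control_config.yaml",
                          package = "ocellar"))
}

CONFIG_SECTIONS <- c("gradient", "intracellular", "grid", "solver",
                     "gradient_tiers")

#' Load and validate a model configuration file
#'
#' The YAML file has sections `gradient`, `intracellular`, `grid`, `solver`
#' and optionally `gradient_tiers` (per-tier value ranges for `D` and
#' `beta_Hh`).  Unknown sections or parameters are rejected; all model
#' parameters must be present and strictly positive.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `params` (`ocellar_params`), `grid`
#'   (`ocellar_grid`), `solver` (list of solver options) and
#'   `gradient_tiers` (list or NULL).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), CONFIG_SECTIONS)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (s in c("gradient", "intracellular", "grid", "solver"))
    if (is.null(cfg[[s]])) stop("config section missing: ", s)
  params <- ocellar_params(cfg$gradient, cfg$intracellular)
  gr <- cfg$grid
  extra <- setdiff(names(gr), c("half_length", "dx"))
  if (length(extra))
    stop("unknown grid option(s): ", paste(extra, collapse = ", "))
  grid <- grid1d(half_length = gr$half_length, dx = gr$dx,
                 omega = param_value(params, "omega"))
  sv <- cfg$solver
  extra <- setdiff(names(sv), c("stop_tol", "check_every", "max_steps", "dt"))
  if (length(extra))
    stop("unknown solver option(s): ", paste(extra, collapse = ", "))
  solver <- list(
    stop_tol = if (is.null(sv$stop_tol)) 0.01 else sv$stop_tol,
    check_every = if (is.null(sv$check_every)) 100L else as.integer(sv$check_every),
    max_steps = if (is.null(sv$max_steps)) 200000L else as.integer(sv$max_steps),
    dt = sv$dt)
  tiers <- cfg$gradient_tiers
  if (!is.null(tiers)) {
    extra <- setdiff(names(tiers), c("D", "beta_Hh"))
    if (length(extra))
      stop("unknown gradient_tiers entries: ", paste(extra, collapse = ", "))
    for (nm in names(tiers))
      for (tn in names(tiers[[nm]])) {
        iv <- tiers[[nm]][[tn]]
        if (!tn %in% c("good", "medium", "bad"))
          stop("unknown tier name in gradient_tiers: ", tn)
        if (length(iv) != 2 || any(!is.finite(iv)) || iv[1] > iv[2])
          stop("invalid interval for gradient_tiers ", nm, " ", tn)
      }
  }
  list(params = params, grid = grid, solver = solver, gradient_tiers = tiers)
}

#' Write a configuration file
#'
#' Serializes a parameter set (plus grid/solver options) back to YAML in the
#' layout accepted by [load_config()]; a load/save round trip preserves all
#' values.
#'
#' @param config A list as returned by [load_config()], or at least
#'   containing `params` and `grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params
  out <- list(
    gradient = as.list(p$gradient),
    intracellular = as.list(p$intracellular),
    grid = list(half_length = config$grid$half_length, dx = config$grid$dx),
    solver = config$solver[!vapply(config$solver, is.null, logical(1))])
  if (!is.null(config$gradient_tiers))
    out$gradient_tiers <- config$gradient_tiers
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
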