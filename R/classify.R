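#' Label morphospace instances into phenotype classes
#'
#' Three binary classes are defined on the (lambda_CiA, lambda_En) plane:
#' * `oc_class`: 1 iff `lambda_CiA > 0` (larger OC than control);
#' * `ioc_class`: 1 iff `lambda_En >= 0.15` (large IOC);
#' * `nf_class` (Near/Far): defined only where `lambda_En >= 0` and
#'   `sign(lambda_CiA) == sign(lambda_En)` (same-sign size variation);
#'   within that subset, 1 iff the radial distance
#'   `sqrt(lambda_CiA^2 + lambda_En^2)` is at least 0.3 (far), else 0
#'   (near).  Excluded instances carry `NA`.
#'
#' Non-converged instances are dropped.
#'
#' @param sample An `ocellar_morphospace` (or any data.frame with
#'   `lambda_CiA`, `lambda_En` and optionally `converged`).
#' @return The converged subset with added columns `radial`, `oc_class`,
#'   `ioc_class`, `nf_class`.
#' @export
label_instances <- function(sample) {
  df <- as.data.frame(sample)
  if (!is.null(df$converged)) df <- df[df$converged, , drop = FALSE]
  df$radial <- sqrt(df$lambda_CiA^2 + df$lambda_En^2)
  df$oc_class <- as.integer(df$lambda_CiA > 0)
  df$ioc_class <- as.integer(df$lambda_En >= 0.15)
  eligible <- df$lambda_En >= 0 & sign(df$lambda_CiA) == sign(df$lambda_En)
  df$nf_class <- ifelse(eligible, as.integer(df$radial >= 0.3), NA_integer_)
  rownames(df) <- NULL
  df
}

#' Equal-frequency discretization of parameter columns
#'
#' Bins each column into `n_bins` equal-frequency bins.  On training data
#' the assignment is rank-based, so bin populations differ by at most one
#' instance; the value cutpoints are recorded so the same edges can be
#' frozen and applied to held-out data.  A constant column collapses to a
#' single bin with a warning.
#'
#' @param x Data.frame of numeric columns.
#' @param n_bins Bins per column (default 3).
#' @param edges Optional previously computed edge list (from a training
#'   call); when given, bins are assigned by `findInterval` against those
#'   edges.
#' @return List with `data` (data.frame of integer bin indices), `edges`
#'   (named list of interior cutpoints) and `n_bins`.
#' @export
discretize_params <- function(x, n_bins = 3, edges = NULL) {
  x <- as.data.frame(x)
  if (is.null(edges)) {
    edges <- list()
    out <- x
    for (nm in names(x)) {
      v <- x[[nm]]
      if (length(unique(v)) == 1) {
        warning("column ", nm, " is constant; using a single bin",
                call. = FALSE)
        edges[[nm]] <- numeric(0)
        out[[nm]] <- rep(1L, length(v))
        next
      }
      n <- length(v)
      rk <- rank(v, ties.method = "first")
      bin <- ceiling(rk * n_bins / n)
      # value cutpoints midway between the bounding order statistics
      sv <- sort(v)
      cut_pos <- floor(seq_len(n_bins - 1) * n / n_bins)
      e <- (sv[cut_pos] + sv[pmin(cut_pos + 1, n)]) / 2
      edges[[nm]] <- e
      out[[nm]] <- as.integer(bin)
    }
  } else {
    out <- x
    for (nm in names(x)) {
      e <- edges[[nm]]
      if (is.null(e)) stop("no edges recorded for column ", nm)
      out[[nm]] <- as.integer(findInterval(x[[nm]], e) + 1L)
    }
  }
  list(data = out, edges = edges, n_bins = n_bins)
}

# ---- Bayesian network internals ------------------------------------------

# log Bayesian-Dirichlet family score with additive pseudocount `alpha` per
# CPT cell; child/parents are integer vectors/matrix with given arities
bd_family_score <- function(child, parents, arity_child, arity_parents,
                            alpha = 0.5) {
  q <- prod(arity_parents)
  if (length(arity_parents) == 0) q <- 1
  cfg <- rep(1L, length(child))
  mult <- 1L
  if (!is.null(parents) && ncol(parents) > 0) {
    for (j in seq_len(ncol(parents))) {
      cfg <- cfg + (parents[, j] - 1L) * mult
      mult <- mult * arity_parents[j]
    }
  }
  idx <- cfg + (child - 1L) * q
  njk <- tabulate(idx, nbins = q * arity_child)
  nj <- tabulate(cfg, nbins = q)
  a0 <- alpha * arity_child
  sum(lgamma(a0) - lgamma(a0 + nj)) +
    sum(lgamma(alpha + njk) - lgamma(alpha))
}

# cycle check among parameter nodes: would adding u -> v create a cycle?
creates_cycle <- function(parents, u, v) {
  # is u reachable from v following child -> parent ... actually follow
  # edges v -> ... -> u in the directed graph (edge p -> c stored as
  # parents[[c]] containing p); adding u -> v cycles iff v reaches u
  seen <- character(0)
  stack <- v
  children_of <- function(node)
    names(parents)[vapply(parents, function(ps) node %in% ps, logical(1))]
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur == u) return(TRUE)
    if (cur %in% seen) next
    seen <- c(seen, cur)
    stack <- c(stack, children_of(cur))
  }
  FALSE
}

#' Learn a Bayesian-network classifier by greedy structure search
#'
#' The class node sits at the top of the network (no parents).  Starting
#' from a naive structure (class -> every parameter), greedy hill-climbing
#' adds, deletes or reverses edges among parameter nodes (and deletes/adds
#' class -> parameter edges) to maximize a Bayesian-Dirichlet network score,
#' subject to at most `max_parents` parents per parameter node and
#' acyclicity.  Conditional probability tables are maximum-likelihood
#' estimates with additive smoothing (0.5 per cell), so every CPT row sums
#' to one.
#'
#' @param data Data.frame of integer bin indices (from
#'   [discretize_params()]) plus an integer/factor class column.
#' @param class_name Name of the class column (default `"class"`).
#' @param max_parents Maximum parameter-node parents (default 2, counting
#'   the class).
#' @param alpha Dirichlet pseudocount per CPT cell (default 0.5).
#' @param max_iter Hill-climbing move budget (default 200).
#' @return An object of class `ocellar_bn`: list with `nodes`, `class_name`,
#'   `parents` (named list), `cpts`, `arities`, `score`.
#' @export
learn_bn <- function(data, class_name = "class", max_parents = 2,
                     alpha = 0.5, max_iter = 200) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("empty training set")
  if (!class_name %in% names(data))
    stop("class column not found: ", class_name)
  for (nm in names(data)) {
    v <- data[[nm]]
    if (is.factor(v)) v <- as.integer(v) else v <- as.integer(v)
    if (anyNA(v) || any(v < 1))
      stop("column ", nm, " must hold positive integer bin indices")
    data[[nm]] <- v
  }
  params <- setdiff(names(data), class_name)
  arities <- vapply(data, max, integer(1))
  mat <- as.matrix(data)

  parents <- setNames(vector("list", length(params)), params)
  for (nm in params) parents[[nm]] <- class_name

  fam_score <- function(nm, ps) {
    pm <- if (length(ps)) mat[, ps, drop = FALSE] else NULL
    bd_family_score(mat[, nm], pm, arities[[nm]],
                    if (length(ps)) arities[ps] else integer(0), alpha)
  }
  scores <- vapply(params, function(nm) fam_score(nm, parents[[nm]]),
                   numeric(1))

  param_parents <- function(ps) setdiff(ps, class_name)
  for (iter in seq_len(max_iter)) {
    best <- NULL; best_delta <- 1e-9
    for (v in params) {
      ps <- parents[[v]]
      # toggle the class edge
      ps2 <- if (class_name %in% ps) setdiff(ps, class_name)
        else c(class_name, ps)
      if (length(ps2) <= max_parents || class_name %in% ps) {
        d <- fam_score(v, ps2) - scores[[v]]
        if (d > best_delta) { best <- list(v = v, ps = ps2); best_delta <- d }
      }
      # add / remove parameter parents
      for (u in params) {
        if (u == v) next
        if (u %in% ps) {
          ps2 <- setdiff(ps, u)
          d <- fam_score(v, ps2) - scores[[v]]
          if (d > best_delta) { best <- list(v = v, ps = ps2); best_delta <- d }
        } else if (length(ps) < max_parents) {
          pp <- lapply(parents, param_parents)
          if (!creates_cycle(pp, u, v)) {
            ps2 <- c(ps, u)
            d <- fam_score(v, ps2) - scores[[v]]
            if (d > best_delta) { best <- list(v = v, ps = ps2); best_delta <- d }
          }
        }
      }
    }
    if (is.null(best)) break
    parents[[best$v]] <- best$ps
    scores[[best$v]] <- fam_score(best$v, best$ps)
  }

  # CPTs with additive smoothing
  make_cpt <- function(nm, ps) {
    dims <- c(arities[[nm]], if (length(ps)) arities[ps] else integer(0))
    idx <- mat[, c(nm, ps), drop = FALSE]
    counts <- array(0, dims)
    cnt_arr <- tapply(rep(1, nrow(idx)),
                      lapply(seq_len(ncol(idx)),
                             function(j) factor(idx[, j],
                                                levels = seq_len(dims[j]))),
                      sum, default = 0)
    counts[] <- cnt_arr
    sm <- counts + alpha
    # normalize over the child dimension
    if (length(dims) == 1) return(sm / sum(sm))
    norm <- apply(sm, seq(2, length(dims)), sum)
    sweep(sm, seq(2, length(dims)), norm, "/")
  }
  cpts <- lapply(params, function(nm) make_cpt(nm, parents[[nm]]))
  names(cpts) <- params
  cc <- tabulate(mat[, class_name], nbins = arities[[class_name]]) + alpha
  class_prior <- cc / sum(cc)

  structure(list(nodes = c(class_name, params), class_name = class_name,
                 parents = parents, cpts = cpts,
                 class_prior = class_prior,
                 arities = arities, score = sum(scores),
                 alpha = alpha),
            class = "ocellar_bn")
}

#' @export
print.ocellar_bn <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, integer(1)))
  cat(sprintf("Bayesian-network classifier: class '%s', %d parameter nodes, %d edges\n",
              x$class_name, length(x$parents), n_edges))
  invisible(x)
}

#' Number of directed edges in a learned network
#' @param model An `ocellar_bn`.
#' @return Integer edge count.
#' @export
bn_edge_count <- function(model)
  sum(vapply(model$parents, length, integer(1)))

#' Predict classes with a learned Bayesian network
#'
#' With every parameter observed, the class posterior reduces to
#' `P(c | x) \propto P(c) * prod over nodes v with the class among their
#' parents of P(x_v | pa(v), c)`; remaining factors cancel.
#'
#' @param object An `ocellar_bn`.
#' @param newdata Data.frame of integer bin indices for all parameter
#'   nodes.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer class predictions (1-based bin index of the class
#'   variable) or a probability matrix.
#' @export
predict.ocellar_bn <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  rc <- object$arities[[object$class_name]]
  logp <- matrix(rep(log(object$class_prior), each = n), n, rc)
  for (v in names(object$parents)) {
    ps <- object$parents[[v]]
    if (!(object$class_name %in% ps)) next
    cpt <- object$cpts[[v]]
    dims <- dim(cpt)
    xv <- pmin(pmax(as.integer(newdata[[v]]), 1L), object$arities[[v]])
    for (cval in seq_len(rc)) {
      idx_list <- vector("list", length(ps) + 1)
      idx_list[[1]] <- xv
      for (j in seq_along(ps)) {
        pj <- ps[j]
        idx_list[[j + 1]] <- if (pj == object$class_name)
          rep(cval, n)
        else pmin(pmax(as.integer(newdata[[pj]]), 1L), object$arities[[pj]])
      }
      flat <- idx_list[[1]]
      mult <- 1
      for (j in seq_along(ps)) {
        mult <- mult * dims[j]
        flat <- flat + (idx_list[[j + 1]] - 1L) * mult
      }
      logp[, cval] <- logp[, cval] + log(cpt[flat])
    }
  }
  if (type == "prob") {
    m <- exp(logp - apply(logp, 1, max))
    return(m / rowSums(m))
  }
  max.col(logp, ties.method = "first")
}

#' Stratified k-fold assignment
#'
#' @param y Class vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per instance; errors if any class has fewer
#'   than `k` members (a class would be absent from some training fold's
#'   strata).
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  y <- as.factor(y)
  if (any(table(y) < k))
    stop("stratification error: a class has fewer than k = ", k,
         " instances")
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

#' Cross-validated accuracy of the Bayesian-network classifier
#'
#' Stratified k-fold cross-validation: per fold, discretization edges and
#' the network are learned on the training subset only, then applied to the
#' held-out subset.  The predictive accuracy is the percentage of correctly
#' predicted classes, averaged over folds.  A final model is fitted on the
#' full dataset for parameter ranking.
#'
#' @param features Data.frame of raw (continuous) parameter columns.
#' @param labels Binary class vector (0/1), same length.
#' @param class_name Label recorded in the report ("OC", "IOC", "NF", ...).
#' @param k Folds (default 10).
#' @param seed Integer seed (controls folds only).
#' @param n_bins Discretization bins (default 3).
#' @param max_parents,max_iter Passed to [learn_bn()].
#' @return An object of class `ocellar_cv`: list with `class_name`,
#'   `fold_accuracies` (percent), `mean_accuracy`, `model` (full-data fit),
#'   `binned` (full-data discretization), `majority_baseline`.
#' @export
cross_validate <- function(features, labels, class_name = "class", k = 10,
                           seed = 1, n_bins = 3, max_parents = 2,
                           max_iter = 200) {
  features <- as.data.frame(features)
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- as.integer(labels[keep])
  counts <- table(labels)
  if (length(counts) < 2 || min(counts) < 2) {
    # (near-)single-class dataset: no stratified split can expose both
    # classes to training and testing, so no learning happens and every
    # prediction falls back to the majority class
    maj <- 100 * max(counts) / length(labels)
    warning("degenerate class distribution for ", class_name,
            "; cross-validation falls back to the majority rate",
            call. = FALSE)
    return(structure(list(class_name = class_name,
                          fold_accuracies = rep(maj, k),
                          mean_accuracy = maj,
                          model = NULL, binned = NULL, labels = labels,
                          majority_baseline = maj,
                          degenerate = TRUE),
                     class = "ocellar_cv"))
  }
  if (min(counts) < k) {
    # too few minority instances for k strata: shrink the fold count so
    # every fold still sees both classes
    k <- max(2L, as.integer(min(counts)))
    warning("minority class smaller than the fold count for ", class_name,
            "; using k = ", k, call. = FALSE)
  }
  fold <- stratified_folds(labels, k = k, seed = seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    disc_tr <- discretize_params(features[tr, , drop = FALSE], n_bins)
    disc_te <- discretize_params(features[!tr, , drop = FALSE], n_bins,
                                 edges = disc_tr$edges)
    train <- disc_tr$data
    train$class <- labels[tr] + 1L
    model <- learn_bn(train, "class", max_parents = max_parents,
                      max_iter = max_iter)
    pred <- predict(model, disc_te$data)
    acc[f] <- 100 * mean(pred == labels[!tr] + 1L)
  }
  disc_all <- discretize_params(features, n_bins)
  full <- disc_all$data
  full$class <- labels + 1L
  model <- learn_bn(full, "class", max_parents = max_parents,
                    max_iter = max_iter)
  structure(list(class_name = class_name,
                 fold_accuracies = acc,
                 mean_accuracy = mean(acc),
                 model = model,
                 binned = disc_all,
                 labels = labels,
                 majority_baseline = 100 * max(table(labels)) /
                   length(labels)),
            class = "ocellar_cv")
}

#' @export
print.ocellar_cv <- function(x, ...) {
  cat(sprintf("%s: 10-fold CV accuracy %.2f%% (folds %.1f-%.1f, majority %.1f%%)\n",
              x$class_name, x$mean_accuracy, min(x$fold_accuracies),
              max(x$fold_accuracies), x$majority_baseline))
  invisible(x)
}

#' Mutual information between two discrete vectors (nats)
#' @param x,y Integer/factor vectors of equal length.
#' @return Nonnegative scalar.
#' @export
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rank parameters by influence in a learned network
#'
#' Parameters are ordered by their undirected graph distance to the class
#' node; ties are broken by mutual information with the class computed on
#' the (binned) training data.  The leading `top` names are attached as an
#' attribute.
#'
#' @param model An `ocellar_bn`.
#' @param binned_data Data.frame of binned parameters plus the class column
#'   (e.g. the `binned$data` of an [cross_validate()] report with its
#'   labels, or `cv$binned$data` + `cv$labels`).
#' @param labels Class vector aligned with `binned_data` rows.
#' @param top How many leading parameters to flag (default 8).
#' @return Character vector of all parameters in rank order, with
#'   attributes `distance` and `mi`.
#' @export
rank_parameters <- function(model, binned_data, labels, top = 8) {
  if (is.null(model) || is.null(model$nodes))
    return(structure(character(0), distance = numeric(0), mi = numeric(0),
                     top = character(0)))
  params <- setdiff(model$nodes, model$class_name)
  # undirected adjacency including class edges
  adj <- setNames(lapply(model$nodes, function(v) character(0)), model$nodes)
  for (v in names(model$parents)) for (u in model$parents[[v]]) {
    adj[[v]] <- union(adj[[v]], u)
    adj[[u]] <- union(adj[[u]], v)
  }
  dist <- setNames(rep(Inf, length(model$nodes)), model$nodes)
  dist[model$class_name] <- 0
  queue <- model$class_name
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (dist[nb] > dist[cur] + 1) {
      dist[nb] <- dist[cur] + 1
      queue <- c(queue, nb)
    }
  }
  mi <- vapply(params, function(nm)
    mutual_information(binned_data[[nm]], labels), numeric(1))
  ord <- order(dist[params], -mi)
  ranked <- params[ord]
  structure(ranked, distance = dist[params][ord], mi = mi[ord],
            top = ranked[seq_len(min(top, length(ranked)))])
}
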