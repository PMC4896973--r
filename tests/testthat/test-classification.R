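test_that("class labels follow the printed rules (worked coordinates)", {
  df <- data.frame(lambda_CiA = c(-0.20, 0.10, 0.25, 0.05, -0.1, 0),
                   lambda_En = c(0.25, 0.10, 0.30, -0.05, -0.2, 0),
                   converged = TRUE)
  lab <- label_instances(df)
  # (-0.20, +0.25): smaller OC, larger IOC, NF excluded (opposite signs)
  expect_equal(lab$oc_class[1], 0L)
  expect_equal(lab$ioc_class[1], 1L)
  expect_true(is.na(lab$nf_class[1]))
  # (0.10, 0.10): radial ~0.141 < 0.3 -> near
  expect_equal(lab$radial[2], sqrt(0.02), tolerance = 1e-12)
  expect_equal(lab$nf_class[2], 0L)
  # (0.25, 0.30): radial ~0.39 >= 0.3 -> far
  expect_equal(lab$nf_class[3], 1L)
  # lambda_En < 0 excluded from NF regardless of sign agreement
  expect_true(is.na(lab$nf_class[4]))
  expect_true(is.na(lab$nf_class[5]))
  # the origin is near (sign(0) == sign(0))
  expect_equal(lab$nf_class[6], 0L)
  # IOC boundary is >= 0.15
  expect_equal(label_instances(data.frame(lambda_CiA = 0, lambda_En = 0.15,
                                          converged = TRUE))$ioc_class, 1L)
  expect_equal(label_instances(data.frame(lambda_CiA = 0, lambda_En = 0.1499,
                                          converged = TRUE))$ioc_class, 0L)
})

test_that("labels match an independently coded rule set on random coords", {
  set.seed(21)
  df <- data.frame(lambda_CiA = runif(1000, -1, 1),
                   lambda_En = runif(1000, -1, 1))
  lab <- label_instances(df)
  orc <- oracle_labels(df$lambda_CiA, df$lambda_En)
  expect_identical(lab$oc_class, orc$oc)
  expect_identical(lab$ioc_class, orc$ioc)
  expect_identical(lab$nf_class, orc$nf)
  expect_equal(lab$radial, orc$radial)
})

test_that("non-converged instances are dropped before labeling", {
  df <- data.frame(lambda_CiA = c(0.5, NA), lambda_En = c(0.5, NA),
                   converged = c(TRUE, FALSE))
  expect_equal(nrow(label_instances(df)), 1L)
})

test_that("equal-frequency discretization balances bins and freezes edges", {
  set.seed(5)
  x <- data.frame(a = runif(301), b = rnorm(301))
  d <- discretize_params(x, n_bins = 3)
  for (nm in names(x)) {
    counts <- table(d$data[[nm]])
    expect_lte(max(counts) - min(counts), 1)  # rank-based balance
  }
  # uniform values: edges near the population terciles
  expect_equal(as.numeric(d$edges$a), c(1/3, 2/3), tolerance = 0.06)
  # frozen edges applied to new data agree with findInterval semantics
  xn <- data.frame(a = c(0.01, 0.5, 0.99), b = c(-3, 0, 3))
  dn <- discretize_params(xn, edges = d$edges)
  expect_equal(dn$data$a, c(1L, 2L, 3L))
  # constant column collapses to one bin with a warning
  expect_warning(dc <- discretize_params(data.frame(z = rep(2, 50))),
                 "constant")
  expect_equal(unique(dc$data$z), 1L)
})

test_that("BN learner recovers a planted single-parameter signal", {
  ps <- make_planted_classification_set(n = 1200, n_params = 6, seed = 2)
  cv <- suppressWarnings(cross_validate(ps$features, ps$labels,
                                        class_name = "planted", seed = 3))
  expect_gt(cv$mean_accuracy, 95)
  expect_equal(length(cv$fold_accuracies), 10L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  rk <- rank_parameters(cv$model, cv$binned$data, cv$labels)
  expect_equal(rk[1], "x1")
})

test_that("BN accuracy tracks the analytic Bayes rate under label noise", {
  ps <- make_planted_classification_set(n = 2000, n_params = 6, noise = 0.1,
                                        seed = 4)
  expect_equal(ps$bayes_accuracy, 90)
  cv <- suppressWarnings(cross_validate(ps$features, ps$labels, seed = 5))
  expect_lt(abs(cv$mean_accuracy - 90), 3)
})

test_that("class independent of parameters scores at the majority rate", {
  ps <- make_planted_classification_set(n = 1500, n_params = 6, seed = 6)
  set.seed(7)
  shuffled <- sample(ps$labels)
  cv <- suppressWarnings(cross_validate(ps$features, shuffled, seed = 8))
  expect_lt(abs(cv$mean_accuracy - cv$majority_baseline), 3)
})

test_that("learned networks are acyclic with normalized CPTs", {
  ps <- make_planted_classification_set(n = 600, n_params = 5, seed = 9)
  d <- discretize_params(ps$features)
  train <- d$data
  train$class <- ps$labels + 1L
  m <- learn_bn(train, "class")
  # class node has no parents; all parents exist among nodes
  for (v in names(m$parents))
    expect_true(all(m$parents[[v]] %in% m$nodes))
  # acyclicity: topological order exists over parameter-parent edges
  pp <- lapply(m$parents, function(ps_) setdiff(ps_, "class"))
  remaining <- names(pp)
  for (step in seq_along(remaining)) {
    leaves <- remaining[vapply(remaining, function(v)
      !length(intersect(pp[[v]], remaining)), logical(1))]
    expect_gt(length(leaves), 0)
    remaining <- setdiff(remaining, leaves)
    if (!length(remaining)) break
  }
  expect_equal(length(remaining), 0L)
  # every CPT row sums to 1
  for (v in names(m$cpts)) {
    cpt <- m$cpts[[v]]
    nd <- length(dim(cpt))
    sums <- if (nd > 1) apply(cpt, seq(2, nd), sum) else sum(cpt)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  expect_equal(sum(m$class_prior), 1, tolerance = 1e-9)
})

test_that("cross-validation is deterministic under a fixed seed", {
  ps <- make_planted_classification_set(n = 600, n_params = 5, noise = 0.15,
                                        seed = 10)
  cv1 <- suppressWarnings(cross_validate(ps$features, ps$labels, seed = 11))
  cv2 <- suppressWarnings(cross_validate(ps$features, ps$labels, seed = 11))
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
})

test_that("stratified folds keep every class in every fold", {
  y <- rep(c(0, 1), c(80, 40))
  f <- stratified_folds(y, k = 10, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab > 0))
  expect_equal(as.numeric(colSums(tab)), c(80, 40))
  expect_error(stratified_folds(rep(c(0, 1), c(95, 5)), k = 10),
               "stratification")
})

test_that("mutual information is zero for independents, positive for copies", {
  set.seed(12)
  x <- sample(1:3, 4000, replace = TRUE)
  y <- sample(1:2, 4000, replace = TRUE)
  expect_lt(mutual_information(x, y), 0.005)
  expect_gt(mutual_information(x, x), 0.5)
})
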