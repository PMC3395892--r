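# Logistic regression, homology-aware splitting, forward selection.

test_that("train_logreg matches an independent convex-optimizer oracle", {
  set.seed(31)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X %*% c(1, -2, 0.5)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  for (C in c(0.5, 1, 4)) {
    m <- train_logreg(X, y, reg_strength = C)
    obj <- logreg_objective_factory(X, y, C)
    o <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    expect_equal(c(m$intercept, m$weights), o$par, tolerance = 1e-4)
    expect_lte(obj(c(m$intercept, m$weights)), o$value + 1e-8)
  }
})

test_that("train_logreg matches glmnet ridge-logistic at matched penalty", {
  # glmnet objective: (1/n) sum nll + lambda/2 ||w||^2  <=>  C = 1 with
  # lambda = 1/n in the LIBLINEAR parametrization
  set.seed(32)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1, -1, 0, 2)))
  m <- train_logreg(X, y, reg_strength = 1)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1 / n,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(m$weights, as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(m$intercept, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("separable data gets a positive weight and perfect training accuracy", {
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- train_logreg(X, y)
  expect_gt(m$weights, 0)
  p <- predict_proba(m, X)
  expect_equal(as.numeric(p > 0.5), y)
  expect_true(all(p > 0 & p < 1))
})

test_that("symmetric uninformative data gives near-zero weight and intercept", {
  X <- matrix(c(1, -1, 1, -1), ncol = 1)
  y <- c(1, 1, 0, 0)
  m <- train_logreg(X, y)
  expect_equal(m$weights, 0, tolerance = 1e-6)
  expect_equal(m$intercept, 0, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(train_logreg(X, rep(1, 10)), "both classes")
  X[3] <- NA
  expect_error(train_logreg(X, rep(c(0, 1), 5)), "NA")
})

test_that("predict_proba is the logistic of the linear score", {
  m <- structure(list(weights = c(0, 0), intercept = 0, reg_strength = 1),
                 class = "logreg_model")
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(predict_proba(m, X), rep(0.5, 10))
  m2 <- structure(list(weights = c(1, -2), intercept = 0.5, reg_strength = 1),
                  class = "logreg_model")
  x0 <- matrix(c(0.3, 0.1), 1, 2)
  expect_equal(predict_proba(m2, x0),
               1 / (1 + exp(-(0.5 + 0.3 * 1 + 0.1 * -2))))
  # monotone in a positively weighted feature
  xs <- cbind(seq(-3, 3, length.out = 11), 0)
  expect_true(all(diff(predict_proba(m2, xs)) > 0))
  expect_error(predict_proba(m2, matrix(0, 2, 3)), "width")
})

test_that("model JSON serialization round-trips", {
  set.seed(40)
  X <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  m <- train_logreg(X, y)
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(predict_proba(m2, X), predict_proba(m, X))
})

test_that("parameter recovery on data from a known logistic model", {
  set.seed(41)
  n <- 5000
  w_true <- c(2, -1, 0.5, 1.5, -2)
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(X %*% w_true))
  m <- train_logreg(X, y, reg_strength = 1)
  expect_gt(cor(m$weights, w_true), 0.95)
})

test_that("edgeless folds are balanced; components stay atomic", {
  inst <- data.frame(id = sprintf("i%03d", 1:100),
                     protein = sprintf("p%03d", 1:100))
  fa <- assign_folds(inst, NULL, k = 10, seed = 1)
  expect_equal(unname(table(fa$fold_of)), rep(10L, 10), ignore_attr = TRUE)
  expect_setequal(names(fa$fold_of), inst$id)

  # one component holding 30% of the instances
  inst2 <- data.frame(id = sprintf("i%03d", 1:100),
                      protein = c(rep("big", 30), sprintf("p%02d", 1:70)))
  fa2 <- suppressWarnings(assign_folds(inst2, NULL, k = 10, seed = 2))
  big_folds <- unique(fa2$fold_of[1:30])
  expect_length(big_folds, 1)
  expect_gte(sum(fa2$fold_of == big_folds), 30)
})

test_that("no similarity edge ever crosses a fold boundary (random graphs)", {
  set.seed(77)
  for (rep in 1:15) {
    np <- sample(20:60, 1)
    prot <- sprintf("p%02d", 1:np)
    inst <- data.frame(id = sprintf("i%03d", 1:(2 * np)),
                       protein = sample(prot, 2 * np, replace = TRUE))
    ne <- sample(5:40, 1)
    edges <- data.frame(a = sample(prot, ne, replace = TRUE),
                        b = sample(prot, ne, replace = TRUE))
    fa <- suppressWarnings(assign_folds(inst, edges, k = 5, seed = rep))
    fold_of_protein <- tapply(fa$fold_of, inst$protein, function(v) unique(v))
    for (r in seq_len(ne)) {
      pa <- edges$a[r]; pb <- edges$b[r]
      if (pa %in% names(fold_of_protein) && pb %in% names(fold_of_protein)) {
        expect_equal(unname(fold_of_protein[[pa]]),
                     unname(fold_of_protein[[pb]]))
      }
    }
  }
})

test_that("holdout split respects fraction, edges and determinism", {
  inst <- data.frame(id = sprintf("i%04d", 1:1000),
                     protein = sprintf("p%04d", 1:1000))
  sp <- holdout_selection_split(inst, NULL, fraction = 1/5, seed = 3)
  expect_equal(length(sp$selection), 200L)
  expect_equal(length(sp$main), 800L)
  expect_setequal(c(sp$selection, sp$main), inst$id)
  sp2 <- holdout_selection_split(inst, NULL, fraction = 1/5, seed = 3)
  expect_identical(sp, sp2)

  # similarity edges never cross the split
  set.seed(78)
  prot <- sprintf("p%02d", 1:30)
  inst2 <- data.frame(id = sprintf("i%03d", 1:120),
                      protein = sample(prot, 120, replace = TRUE))
  edges <- data.frame(a = sample(prot, 25, replace = TRUE),
                      b = sample(prot, 25, replace = TRUE))
  sp3 <- holdout_selection_split(inst2, edges, fraction = 1/5, seed = 5)
  side <- setNames(inst2$id %in% sp3$selection, inst2$id)
  side_of_protein <- tapply(side, inst2$protein, unique)
  for (r in 1:25) {
    pa <- edges$a[r]; pb <- edges$b[r]
    if (pa %in% names(side_of_protein) && pb %in% names(side_of_protein))
      expect_equal(unname(side_of_protein[[pa]]), unname(side_of_protein[[pb]]))
  }

  # a single giant component makes the split impossible
  giant <- data.frame(id = sprintf("i%02d", 1:10), protein = rep("p1", 10))
  expect_error(holdout_selection_split(giant, NULL), "impossible")
})

test_that("forward selection finds a planted signal and stops on noise", {
  d <- make_planted_dataset(300, 6, signal_feature = 3, d = 2, seed = 51)
  tr <- forward_select(d$X, d$y, attr(d$X, "layout")$name, k = 10, seed = 1)
  expect_s3_class(tr, "selection_trace")
  expect_equal(tr$steps$name[1], "f03")
  expect_true(all(diff(tr$steps$mean_auc) > 0))  # non-decreasing, strictly

  # all-noise candidates: stop quickly near chance level
  d0 <- make_planted_dataset(300, 6, d = 0, seed = 52)
  tr0 <- forward_select(d0$X, d0$y, attr(d0$X, "layout")$name, k = 10, seed = 1)
  expect_lte(nrow(tr0$steps), 2)
  expect_equal(tr0$stopped_reason, "converged")

  # empty candidate list
  tre <- forward_select(d$X, d$y, character(0))
  expect_equal(nrow(tre$steps), 0L)
  expect_equal(tre$stopped_reason, "exhausted")
})

test_that("forward selection is deterministic given a seed", {
  d <- make_planted_dataset(200, 5, d = 1, seed = 53)
  t1 <- forward_select(d$X, d$y, attr(d$X, "layout")$name, seed = 9)
  t2 <- forward_select(d$X, d$y, attr(d$X, "layout")$name, seed = 9)
  expect_identical(t1$steps, t2$steps)
})

test_that("fold rotation covers every instance exactly once as test", {
  inst <- data.frame(id = sprintf("i%03d", 1:95), protein = sprintf("p%03d", 1:95))
  fa <- assign_folds(inst, NULL, k = 10, seed = 6)
  expect_equal(sort(unique(fa$fold_of)), 1:10)
  expect_equal(sum(table(fa$fold_of)), 95L)  # each instance in exactly one fold
})
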