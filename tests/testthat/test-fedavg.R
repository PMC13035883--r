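toy_data <- function(n = 80, p = 4, d = 2, noise = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  w <- matrix(rnorm(p * d), p, d)
  b <- rnorm(d)
  y <- sweep(x %*% w, 2, b, `+`) + noise * matrix(rnorm(n * d), n, d)
  list(data = list(features = x, labels = y), w = w, b = b)
}

zero_model <- function(p, d) {
  structure(list(weights = matrix(0, p, d), bias = rep(0, d)),
            class = "linear_model")
}

test_that("local training: identity at 0 epochs, descent, exact recovery", {
  td <- toy_data()
  m0 <- zero_model(4, 2)
  expect_identical(local_train(m0, td$data, epochs = 0), m0)

  losses <- numeric(20)
  m <- m0
  for (e in 1:20) {
    m <- local_train(m, td$data, epochs = 1, learning_rate = 0.05)
    losses[e] <- biasplit:::mse_loss(m, td$data)
  }
  expect_true(all(diff(losses) <= 1e-12))

  # Noiseless task: gradient descent reaches the least-squares oracle.
  fit <- local_train(m0, td$data, epochs = 5000, learning_rate = 0.1)
  ls <- lm(td$data$labels ~ td$data$features)
  expect_lt(max(abs(fit$weights - coef(ls)[-1, ])), 1e-3)
  expect_lt(max(abs(fit$bias - coef(ls)[1, ])), 1e-3)

  bad <- local_train(m0, td$data, epochs = 0)
  expect_error(local_train(bad, td$data, epochs = 500, learning_rate = 50),
               "diverged")
})

test_that("FedAvg aggregation is the size-weighted parameter mean", {
  td <- toy_data()
  a <- local_train(zero_model(4, 2), td$data, 50, 0.05)
  b <- local_train(zero_model(4, 2), td$data, 10, 0.05)
  same <- fedavg_round(list(a, a), c(3, 5))
  expect_equal(same$weights, a$weights)

  half <- fedavg_round(list(a, b), c(1, 1))
  expect_equal(half$weights, (a$weights + b$weights) / 2)
  expect_equal(half$bias, (a$bias + b$bias) / 2)

  quarter <- fedavg_round(list(a, b), c(3, 1))
  expect_equal(quarter$weights, 0.75 * a$weights + 0.25 * b$weights)

  # Convex hull containment, elementwise.
  lo <- pmin(a$weights, b$weights)
  hi <- pmax(a$weights, b$weights)
  expect_true(all(quarter$weights >= lo - 1e-12 & quarter$weights <= hi + 1e-12))

  expect_error(fedavg_round(list(a, zero_model(3, 2)), c(1, 1)),
               "structurally identical")
  expect_error(fedavg_round(list(a, b), c(1, 0)), "positive")
})

test_that("degenerate federations behave like their centralized counterparts", {
  td <- toy_data(n = 100)
  # Two clients with identical data and a common init: the average equals
  # either client at every round, so the fit matches a single client run.
  both <- run_federation(list(td$data, td$data), rounds = 5, epochs = 4,
                         learning_rate = 0.05, seed = 3, test = td$data,
                         val_fraction = 0)
  one <- run_federation(list(td$data), rounds = 5, epochs = 4,
                        learning_rate = 0.05, seed = 3, test = td$data,
                        val_fraction = 0)
  expect_equal(both$model$weights, one$model$weights, tolerance = 1e-10)

  # A single client is centralized training with the same epoch budget
  # (rounds x epochs consecutive full-batch steps from the same init).
  init <- biasplit:::init_model(4, 2, seed = biasplit:::spawn_seeds(3, 2)[1])
  central <- local_train(init, td$data, epochs = 20, learning_rate = 0.05)
  expect_equal(one$model$weights, central$weights, tolerance = 1e-10)
})

test_that("binned MAE: zero for perfect model, U-shape for mean predictor, decomposition", {
  td <- toy_data(n = 500, noise = 0, seed = 9)
  perfect <- structure(list(weights = td$w, bias = td$b), class = "linear_model")
  rep0 <- binned_mae(perfect, td$data, bins = 4)
  expect_true(all(rep0$mae < 1e-10, na.rm = TRUE))

  # Constant-mean predictor on a symmetric label distribution: MAE grows
  # with |bin center - mean|.
  ym <- colMeans(td$data$labels)
  const <- structure(list(weights = matrix(0, 4, 2), bias = ym),
                     class = "linear_model")
  rep1 <- binned_mae(const, td$data, bins = 6)
  one <- rep1[rep1$label == "y1" & rep1$n > 0, ]
  expect_equal(order(abs(one$bin_center - ym[1])), order(one$mae))

  # Overall MAE is the sample-weighted mean of bin MAEs.
  overall <- overall_mae(const, td$data)
  agg <- sum(one$mae * one$n) / sum(one$n)
  expect_equal(agg, unname(overall[1]), tolerance = 1e-12)
})

test_that("strict splits collapse prediction variance and inflate edge error", {
  co <- generate_anthro_cohort(400, seed = 21)
  task <- make_regression_task(co, seed = 22)
  parts <- holdout_split(co, 0.2, seed = 23)
  test <- biasplit:::task_subset(task, parts$test$sample_id)

  run <- function(split) {
    run_federation(client_datasets(task, split), rounds = 20, epochs = 10,
                   learning_rate = 0.1, seed = 24, test = test,
                   dims = c("weight", "height"))
  }
  iid <- run(split_random(parts$train, 2, seed = 25))
  strict <- run(split_median(parts$train, "weight"))

  vr <- function(fit) {
    var(predict(fit$model, test)[, 1]) / var(test$labels[, 1])
  }
  expect_lt(vr(strict), vr(iid))

  bm <- binned_mae(strict$model, test, bins = 5)
  w <- bm[bm$label == "weight" & bm$n > 0, ]
  edges <- w$mae[c(1, nrow(w))]
  center <- w$mae[ceiling(nrow(w) / 2)]
  expect_gt(mean(edges), center)
})
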