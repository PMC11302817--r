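test_that("the activation trace follows the architecture table row for row", {
  m <- build_cnn(seed = 1)
  x <- matrix(runif(2 * 21 * 66), 1)
  tr <- cnn_shape_trace(m, x)
  expect_equal(tr$stem, c(16L, 21L, 66L))
  expect_equal(tr$conv1, c(16L, 21L, 66L))
  expect_equal(tr$pool1, c(16L, 10L, 33L))
  expect_equal(tr$conv2, c(32L, 10L, 33L))
  expect_equal(tr$pool2, c(32L, 5L, 16L))
  expect_equal(tr$conv3, c(64L, 5L, 16L))
  expect_equal(tr$gap, 64L)
  expect_equal(tr$fc1, 128L)
  expect_equal(tr$out, 5L)
})

test_that("outputs are softmax simplex vectors, even on all-zero input", {
  m <- build_cnn(seed = 2)
  X <- rbind(matrix(0, 1, 2772), matrix(runif(4 * 2772), 4))
  p <- cnn_forward(m, X)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("building twice with one seed gives identical parameters", {
  a <- build_cnn(seed = 11); b <- build_cnn(seed = 11)
  expect_identical(a$params, b$params)
  c <- build_cnn(seed = 12)
  expect_false(identical(a$params$Ws, c$params$Ws))
})

test_that("analytic gradients match central finite differences", {
  # small spatial size keeps the finite-difference loop affordable
  set.seed(4)
  m <- build_cnn(seed = 4, input_dim = c(2L, 8L, 12L))
  X <- matrix(runif(6 * 2 * 8 * 12), 6)
  y <- c(0L, 1L, 2L, 3L, 4L, 1L)
  g <- arcqa:::.cnn_grad(m$params, X, y, 8L, 12L)
  eps <- 1e-3
  for (nm in c("Ws", "W2", "g1", "be3", "Wf1", "bf2", "b1")) {
    th <- m$params[[nm]]
    idx <- sample(length(th), 3)
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- th[i] + eps
      lp <- arcqa:::.cnn_grad(pp, X, y, 8L, 12L)$loss
      pm <- m$params; pm[[nm]][i] <- th[i] - eps
      lm <- arcqa:::.cnn_grad(pm, X, y, 8L, 12L)$loss
      fd <- (lp - lm) / (2 * eps)
      # single-precision forward passes bound the achievable agreement
      expect_lt(abs(g$grads[[nm]][i] - fd),
                max(0.08 * abs(fd), 5e-3),
                label = sprintf("|grad - fd| for %s[%d] (%.4g vs %.4g)",
                                nm, i, g$grads[[nm]][i], fd))
    }
  }
})

test_that("zero learning rate leaves parameters untouched and loss flat", {
  inst <- toy_instances(2)
  m <- build_cnn(seed = 3)
  cfg <- train_config(epochs = 3, batch = length(inst), lr = 0, dropout = 0,
                      seed = 5)
  t <- train_fold(m, inst, cfg)
  for (nm in c("Ws", "W1", "W2", "W3", "Wf1", "Wf2", "g1", "be2"))
    expect_equal(t$params[[nm]], m$params[[nm]], tolerance = 1e-7)
  expect_equal(diff(range(t$loss)), 0, tolerance = 1e-6)
})

test_that("training is reproducible and the loss decreases", {
  inst <- toy_instances(2)
  cfg <- train_config(epochs = 15, batch = 8, seed = 6)
  a <- train_fold(build_cnn(seed = 6), inst, cfg)
  b <- train_fold(build_cnn(seed = 6), inst, cfg)
  expect_identical(a$params, b$params)
  expect_lt(tail(a$loss, 1), a$loss[1])
})

test_that("the network can drive training accuracy to 1 on separable toys", {
  inst <- toy_instances(4)                 # 20 well-separated instances
  cfg <- train_config(epochs = 60, batch = 8, lr = 1e-3, seed = 7)
  m <- train_fold(build_cnn(seed = 7), inst, cfg)
  p <- cnn_forward(m, inst)
  acc <- mean(max.col(p, ties.method = "first") - 1L ==
                arcqa:::instance_labels(inst))
  expect_equal(acc, 1.0)
  expect_error(train_fold(build_cnn(seed = 1), list(), cfg), "empty")
})

test_that("ensemble prediction averages softmax outputs with a stable tie-break", {
  # hand-built ensemble of constant-output models is awkward; check the
  # documented arithmetic directly on the predict path instead
  inst <- toy_instances(1)
  cfg <- train_config(epochs = 2, batch = 5, seed = 8)
  m <- train_fold(build_cnn(seed = 8), inst, cfg)
  ens <- structure(list(models = list(m, m, m, m, m), val_acc = rep(NA, 5),
                        config = cfg), class = "cnn_ensemble")
  single <- cnn_forward(m, inst)
  pr <- predict(ens, inst)
  expect_equal(pr$probs, single, tolerance = 1e-12)
  expect_equal(rowSums(pr$probs), rep(1, length(inst)), tolerance = 1e-6)
  # documented tie-break toward the lowest class index
  fake <- rbind(c(0.3, 0.3, 0.2, 0.1, 0.1), c(0.1, 0.25, 0.2, 0.25, 0.2))
  expect_equal(max.col(fake, ties.method = "first") - 1L, c(0L, 1L))
})

test_that("five-fold cross-validation trains on 4/5 and validates on 1/5", {
  ds <- generate_dataset(sim_config(n_per_class = 20, seed = 13))
  split <- make_split(ds, seed = 13)
  inst <- lapply(ds, normalize_pair)
  ids <- vapply(ds, function(s) s$plan_id, "")
  tr <- augment(inst[ids %in% split$train_ids], 5L, seed = 13)
  fold <- fold_of(tr, split)
  for (k in 1:5) {
    expect_equal(sum(fold == k), length(tr) / 5)
    expect_equal(sum(fold != k), length(tr) * 4 / 5)
  }
  cfg <- train_config(epochs = 2, batch = 32, seed = 13)
  ens <- crossval_train(tr, split, cfg)
  expect_length(ens$models, 5)
  pr <- predict(ens, tr[1:4])
  expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-6)
  ens2 <- crossval_train(tr, split, cfg)
  expect_identical(lapply(ens$models, `[[`, "params"),
                   lapply(ens2$models, `[[`, "params"))
})

test_that("the stated hyperparameter grid enumerates 48 combinations", {
  g <- hp_grids()
  expect_equal(lengths(g), c(epochs = 3L, batch = 4L, lr = 4L))
  expect_equal(prod(lengths(g)), 48)
  expect_true(500L %in% g$epochs && 16L %in% g$batch && 5e-4 %in% g$lr)
  # shipped defaults are the protocol's selected values
  cfg <- train_config()
  expect_equal(cfg$epochs, 500L)
  expect_equal(cfg$batch, 16L)
  expect_equal(cfg$lr, 5e-4)
})

test_that("grid_search returns the argmax config with deterministic tie-breaks", {
  inst <- toy_instances(2)
  # plans must exist in a split for crossval; build a toy split by hand
  pid <- vapply(inst, function(i) i$plan_id, "")
  split <- structure(list(train_ids = pid, test_ids = character(),
                          folds = split(pid, rep(1:5, length.out = length(pid))),
                          seed = 1L), class = "split_plan")
  gs <- grid_search(inst, split,
                    grids = list(epochs = 2L, batch = c(8L, 16L), lr = 1e-3),
                    seed = 9)
  expect_s3_class(gs$best, "train_config")
  expect_equal(nrow(gs$results), 2)
  expect_error(grid_search(inst, split,
                           grids = list(epochs = integer(), batch = 16L,
                                        lr = 1e-3)),
               "empty")
  # exact ties resolve toward fewest epochs, smallest batch, smallest lr
  res <- data.frame(epochs = c(400, 300, 300), batch = c(16, 32, 16),
                    lr = c(1e-4, 1e-4, 5e-4), cv_accuracy = c(0.9, 0.9, 0.9))
  ord <- order(-res$cv_accuracy, res$epochs, res$batch, res$lr)
  expect_equal(ord[1], 3L)
})
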