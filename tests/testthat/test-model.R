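test_that("default architecture chains 32 -> 12 -> 8 -> 4 -> 4096 -> 128 -> 6", {
  spec <- architecture_spec()
  expect_equal(spec$conv1$out_edge, 12L)
  expect_equal(spec$conv2$out_edge, 8L)
  expect_equal(spec$pool$out_edge, 4L)
  expect_equal(spec$flat, 4096L)
  expect_error(architecture_spec(conv1_kernel = 40), "conv1")
  expect_error(architecture_spec(conv2_kernel = 4), "pool")
})

test_that("parameter counts match layer-by-layer arithmetic", {
  m <- build_model()
  expect_identical(count_parameters(m), 804614L)
  by_layer <- count_parameters(m, by_layer = TRUE)
  expect_equal(unname(by_layer),
               c(32 * (9^3 + 1), 64 * (5^3 * 32 + 1),
                 4096 * 128 + 128, 128 * 6 + 6))
  expect_equal(unname(by_layer), c(23360, 256064, 524416, 774))
  m1 <- build_model(architecture_spec(dense1_units = 1L))
  expect_identical(count_parameters(m1), 23360L + 256064L + 4097L + 12L)
})

test_that("forward pass returns a softmax 6-vector per grid", {
  m <- build_model(seed = 5L)
  g <- voxelize(generate_trace(fixture_spec("ring", seed = 2L)),
                voxelizer_config())
  p <- predict_probs(m, g)
  expect_equal(dim(p), c(1L, 6L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # inference is deterministic (dropout off)
  expect_identical(p, predict_probs(m, g))
})

test_that("weight initialization is reproducible from the seed", {
  m1 <- build_model(seed = 42L)
  m2 <- build_model(seed = 42L)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(seed = 43L)
  expect_false(identical(m1$params$W1, m3$params$W1))
})

test_that("weighted cross-entropy matches direct evaluation of the formula", {
  perfect <- diag(6)
  expect_equal(weighted_cross_entropy(perfect, perfect, runif(6, 1, 10)), 0)
  set.seed(8)
  probs <- matrix(rexp(5 * 6), ncol = 6)
  probs <- probs / rowSums(probs)
  labels <- diag(6)[sample(1:6, 5, replace = TRUE), ]
  # uniform weights reduce to the standard categorical cross-entropy
  std_ce <- -sum(labels * log(probs))
  expect_equal(weighted_cross_entropy(probs, labels), std_ce, tolerance = 1e-12)
  # single sample, true class 6, uniform prediction, Table-style weight
  w <- compute_class_weights(c(7096, 12081, 15290, 2875, 1703, 1632))
  loss <- weighted_cross_entropy(matrix(1 / 6, 1, 6), diag(6)[6L, , drop = FALSE], w)
  expect_equal(loss, (15290 / 1632) * log(6), tolerance = 1e-9)  # ~16.787
})

test_that("vanishing predicted probability is clamped with a warning", {
  probs <- matrix(c(1e-12, 1 - 1e-12, 0, 0, 0, 0), 1L)
  labels <- diag(6)[1L, , drop = FALSE]
  expect_warning(loss <- weighted_cross_entropy(probs, labels), "clamping")
  expect_equal(loss, -log(1e-7), tolerance = 1e-9)
  expect_error(weighted_cross_entropy(matrix(1 / 6, 1, 6), matrix(0.5, 1, 6)),
               "one-hot")
})

test_that("the L2 penalty only ever increases the objective", {
  m <- build_model(seed = 2L)
  g <- voxelize(generate_trace(fixture_spec("helix", seed = 1L)),
                voxelizer_config())
  X <- rbind(as.numeric(g$values))
  Y <- diag(6)[2L, , drop = FALSE]
  dims <- enzyvox:::model_dims(m$spec)
  l0 <- enzyvox:::.cnn_backprop_cpp(X, Y, rep(1, 6), m$params, dims,
                                    c(0, 0, 0), 0)$loss
  l1 <- enzyvox:::.cnn_backprop_cpp(X, Y, rep(1, 6), m$params, dims,
                                    c(0, 0, 0), 0.001)$loss
  expect_gte(l0, 0)
  expect_gt(l1, l0)
})

test_that("training with zero epochs returns the initialized model", {
  dir <- withr::local_tempdir()
  samples <- generate_labeled_dataset(2L, dir = dir, seed = 3L,
                                      n_residues = 20L)
  split <- split_dataset(samples, seed = 1L)
  m0 <- build_model(seed = 1L)
  m <- train(m0, split, training_config(epochs = 0L))
  expect_identical(m$params, m0$params)
  expect_equal(nrow(m$history), 0L)
})

test_that("a short training run learns the synthetic families", {
  dir <- withr::local_tempdir()
  split <- synthetic_benchmark_split(n_train = 6L, n_test = 0L,
                                     n_validation = 3L, dir = dir, seed = 2L,
                                     n_residues = 60L)
  m <- build_model(seed = 3L)
  m <- train(m, split, training_config(epochs = 5L, seed = 2L))
  expect_equal(nrow(m$history), 5L)
  expect_true(all(is.finite(m$history$train_loss)))
  # loss trends down and validation beats the 1/6 chance floor
  expect_lt(m$history$train_loss[5L], m$history$train_loss[1L])
  expect_gt(m$history$val_accuracy[5L], 1 / 6)
  expect_true(m$trained)
  expect_identical(count_parameters(m), 804614L)
})

test_that("adapted weighting equals uniform weighting on balanced data", {
  counts <- rep(10L, 6L)
  expect_equal(compute_class_weights(counts), rep(1, 6L))
})

test_that("models round-trip through save_model / load_model", {
  m <- build_model(seed = 9L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$n_parameters, 804614L)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
})
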