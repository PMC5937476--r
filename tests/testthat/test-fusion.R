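test_that("flip weights favor less-transformed copies", {
  expect_equal(flip_weight(flip_code(0, 0, 0)), 1)
  expect_equal(flip_weight(flip_code(1, 1, 1)), 1 / 4)
  expect_equal(flip_weight(flip_code(1, 0, 1)), 1 / 3)
})

test_that("probability fusion sums per-flip probabilities", {
  single <- rbind(c(0.1, 0.5, 0.1, 0.1, 0.1, 0.1))
  expect_equal(fuse_probability(single), 2L)
  rows <- rbind(c(0.6, 0.4, 0, 0, 0, 0), c(0.1, 0.9, 0, 0, 0, 0))
  expect_equal(fuse_probability(rows), 2L)         # 0.7 vs 1.3
  expect_equal(fuse_probability(rows, c(1, 1 / 4)), 1L)  # 0.625 tie -> lowest
  expect_error(fuse_probability(rows[0L, , drop = FALSE]), "no predictions")
  expect_error(fuse_probability(rows, c(1, -1)), "positive")
})

test_that("majority fusion counts weighted votes with deterministic ties", {
  expect_equal(fuse_majority(c(3L, 3L, 5L)), 3L)
  expect_equal(fuse_majority(c(1L, 2L), c(1, 1 / 2)), 1L)
  expect_equal(fuse_majority(rep(4L, 8L)), 4L)
  # vote tie broken by larger summed probability
  probs <- rbind(c(0.9, 0.1, 0, 0, 0, 0), c(0.05, 0.95, 0, 0, 0, 0))
  expect_equal(fuse_majority(c(1L, 2L), c(1, 1), per_flip_probs = probs), 2L)
  # and by lowest index when no probabilities are given
  expect_equal(fuse_majority(c(2L, 5L)), 2L)
  expect_error(fuse_majority(integer(0)), "no predictions")
  expect_error(fuse_majority(c(0L, 1L)), "1..6")
})

test_that("fusion matches a brute-force aggregation oracle", {
  set.seed(31)
  for (rep in 1:120) {
    n <- sample(c(1L, 7L, 8L), 1L)
    probs <- matrix(rexp(n * 6L), ncol = 6L)
    probs <- probs / rowSums(probs)
    coeff <- runif(n, 0.1, 2)
    expect_identical(fuse_probability(probs, coeff),
                     oracle_fuse(probs, coeff, "probability"))
    cls <- max.col(probs, ties.method = "first")
    expect_identical(fuse_majority(cls, coeff, per_flip_probs = probs),
                     oracle_fuse(probs, coeff, "class"))
  }
})

test_that("coefficient rescaling never changes the fused class", {
  set.seed(13)
  for (rep in 1:30) {
    probs <- matrix(rexp(8L * 6L), ncol = 6L)
    probs <- probs / rowSums(probs)
    coeff <- runif(8L, 0.1, 1)
    k <- runif(1L, 0.01, 50)
    expect_identical(fuse_probability(probs, coeff),
                     fuse_probability(probs, k * coeff))
    cls <- max.col(probs, ties.method = "first")
    expect_identical(fuse_majority(cls, coeff, per_flip_probs = probs),
                     fuse_majority(cls, k * coeff, per_flip_probs = probs))
  }
})

test_that("identical per-flip rows reduce every strategy to the single decision", {
  row <- c(0.05, 0.1, 0.4, 0.25, 0.1, 0.1)
  probs <- matrix(rep(row, 8L), ncol = 6L, byrow = TRUE)
  base <- fuse_probability(rbind(row))
  w <- vapply(all_flip_codes(), flip_weight, numeric(1L))
  expect_equal(fuse_probability(probs, rep(1, 8L)), base)
  expect_equal(fuse_probability(probs, w), base)
  expect_equal(fuse_majority(rep(base, 8L), w), base)
})

test_that("predict_final enumerates the configured flip set", {
  m <- build_model(seed = 4L)
  tr <- generate_trace(fixture_spec("ellipsoid", seed = 6L))
  none <- predict_final(m, tr, dec_cfg = decision_config("none"))
  expect_equal(nrow(none$per_flip_probs), 1L)
  expect_equal(none$final_class,
               unname(which.max(none$per_flip_probs[1L, ])))

  fl <- predict_final(m, tr, dec_cfg = decision_config("flips", "probability"))
  expect_equal(nrow(fl$per_flip_probs), 8L)
  codes <- vapply(fl$flip_codes, function(f) paste(unclass(f), collapse = ""),
                  character(1L))
  expect_equal(anyDuplicated(codes), 0L)
  expect_length(codes, 8L)

  strict7 <- predict_final(m, tr, dec_cfg = decision_config(
    "flips", "probability", include_identity = FALSE))
  expect_equal(nrow(strict7$per_flip_probs), 7L)

  # recorded rows re-aggregate to the reported class, for every strategy
  for (strategy in c("flips", "weighted_flips")) for (mode in c("probability", "class")) {
    pr <- predict_final(m, tr, dec_cfg = decision_config(strategy, mode))
    expect_identical(pr$final_class,
                     oracle_fuse(pr$per_flip_probs, pr$coefficients,
                                 if (mode == "probability") "probability"
                                 else "class"))
    expect_true(all(abs(rowSums(pr$per_flip_probs) - 1) < 1e-6))
  }
})

test_that("weighted fusion uses the per-code coefficients", {
  m <- build_model(seed = 4L)
  tr <- generate_trace(fixture_spec("globule", seed = 8L))
  wf <- predict_final(m, tr, dec_cfg = decision_config("weighted_flips"))
  expect_equal(sort(unique(wf$coefficients)), c(1 / 4, 1 / 3, 1 / 2, 1))
})
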