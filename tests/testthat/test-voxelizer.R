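test_that("interpolate_backbone inserts regularly spaced points", {
  coords <- rbind(c(0, 0, 0), c(2, 2, 2))
  expect_equal(interpolate_backbone(coords, 0), coords)
  expect_equal(interpolate_backbone(coords, 1)[2L, ], c(1, 1, 1))
  seg <- rbind(c(0, 0, 0), c(6, 0, 0))
  out <- interpolate_backbone(seg, 5)
  expect_equal(out[2:6, 1L], c(1, 2, 3, 4, 5))  # direct k/(p+1) evaluation
  expect_equal(out[2:6, 2L], rep(0, 5))
  expect_error(interpolate_backbone(seg, -1), "non-negative")
})

test_that("interpolation length and values match the direct formula", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:8, 1L)
    p <- sample(0:6, 1L)
    coords <- matrix(runif(3L * n, -10, 10), ncol = 3L)
    out <- interpolate_backbone(coords, p)
    expect_equal(nrow(out), n + (n - 1L) * p)
    # brute-force reconstruction, point by point
    expected <- coords[1L, , drop = FALSE]
    if (n > 1L) for (i in seq_len(n - 1L)) {
      for (k in seq_len(p))
        expected <- rbind(expected,
                          ((p - k + 1) * coords[i, ] + k * coords[i + 1L, ]) / (p + 1))
      expected <- rbind(expected, coords[i + 1L, ])
    }
    expect_equal(out, expected, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("homothety ratio maps the capture sphere into the grid", {
  expect_identical(homothety_ratio(32, 40), 15 / 40)
  expect_identical(homothety_ratio(64, 40), 31 / 40)
  expect_identical(homothety_ratio(4, 1), 1)
  expect_error(homothety_ratio(2, 40))
  expect_error(homothety_ratio(32, 0))
})

test_that("pca_orient aligns a 1-D point set with the first axis", {
  s <- seq(-4, 4, length.out = 21L)
  line <- cbind(s, s, 0)  # along x = y, z = 0
  expect_warning(out <- pca_orient(line), "rank-deficient")
  v <- apply(out, 2L, stats::var)
  expect_gt(v[1L], 1)
  expect_lt(v[2L], 1e-18)
  expect_lt(v[3L], 1e-18)
})

test_that("pca_orient output covariance is diagonal with sorted variances", {
  set.seed(7)
  for (rep in 1:10) {
    cloud <- matrix(rnorm(3L * 200L), ncol = 3L) %*% diag(c(4, 2, 0.5))
    cloud <- scale(cloud %*% random_rotation(), center = TRUE, scale = FALSE)
    out <- pca_orient(cloud)
    cv <- stats::cov(out)
    off <- abs(cv[upper.tri(cv)])
    expect_lt(max(off), 1e-8 * sum(diag(cv)))
    expect_true(all(diff(diag(cv)) <= 1e-8))
  }
})

test_that("pca_orient recovers generating axis scales of an ellipsoid cloud", {
  set.seed(11)
  cloud <- matrix(rnorm(3L * 4000L), ncol = 3L) %*% diag(c(10, 5, 1))
  cloud <- scale(cloud %*% random_rotation(), center = TRUE, scale = FALSE)
  sds <- apply(pca_orient(cloud), 2L, stats::sd)
  expect_equal(unname(sds), c(10, 5, 1), tolerance = 0.05)
})

test_that("pca_orient is scale-equivariant and errors on tiny inputs", {
  set.seed(3)
  cloud <- scale(matrix(rnorm(60L), ncol = 3L), center = TRUE, scale = FALSE)
  expect_equal(pca_orient(3.5 * cloud), 3.5 * pca_orient(cloud),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pca_orient(cloud[1L, , drop = FALSE]), "at least 2")
  expect_warning(pca_orient(cbind(1:5, 0, 0)), "rank-deficient")
})

test_that("apply_flip reflects the flagged axes and is an involution", {
  x <- rbind(c(1, 2, 3), c(-4, 5, -6))
  expect_equal(apply_flip(x, flip_code(0, 0, 0)), x)
  f <- flip_code(1, 1, 1)
  expect_equal(apply_flip(apply_flip(x, f), f), x)
  expect_equal(apply_flip(rbind(c(1, 2, 3)), flip_code(1, 0, 1)),
               rbind(c(-1, 2, -3)))
})

test_that("flip code construction validates and enumerates correctly", {
  expect_error(flip_code(2, 0, 0), "0 or 1")
  expect_length(all_flip_codes(include_identity = TRUE), 8L)
  expect_length(all_flip_codes(include_identity = FALSE), 7L)
})

test_that("coords_to_grid centers, rounds and clips", {
  g <- coords_to_grid(rbind(c(0, 0, 0)), 32)
  expect_equal(sum(g$values), 1L)
  expect_equal(g$values[17L, 17L, 17L], 1L)  # 0-based voxel (16,16,16)
  g2 <- coords_to_grid(rbind(c(0.1, 0, 0), c(-0.2, 0.1, 0.2)), 32)
  expect_equal(sum(g2$values), 1L)  # closer than half a voxel: merged
  g3 <- suppressWarnings(coords_to_grid(rbind(c(20, 0, 0)), 32))
  expect_equal(sum(g3$values), 0L)  # beyond the grid: discarded
})

test_that("remove_isolated_voxels clears only neighborless voxels", {
  mk <- function(idx) {
    v <- array(0L, dim = c(9L, 9L, 9L))
    v[idx] <- 1L
    voxel_grid(v)
  }
  lone <- mk(rbind(c(5L, 5L, 5L)))
  expect_equal(sum(remove_isolated_voxels(lone, 26L)$values), 0L)
  pair <- mk(rbind(c(5L, 5L, 5L), c(6L, 5L, 5L)))
  expect_equal(remove_isolated_voxels(pair, 26L)$values, pair$values)
  # straight 3-run plus a voxel at Chebyshev distance 2 from its end
  run_plus <- mk(rbind(c(3L, 5L, 5L), c(4L, 5L, 5L), c(5L, 5L, 5L),
                       c(7L, 7L, 5L)))
  out <- remove_isolated_voxels(run_plus, 26L)
  expect_equal(sum(out$values), 3L)
  expect_equal(out$values[7L, 7L, 5L], 0L)
  # under 6-connectivity a diagonal pair is isolated
  diag_pair <- mk(rbind(c(5L, 5L, 5L), c(6L, 6L, 5L)))
  expect_equal(sum(remove_isolated_voxels(diag_pair, 6L)$values), 0L)
  expect_equal(sum(remove_isolated_voxels(diag_pair, 18L)$values), 2L)
})

test_that("remove_isolated_voxels never adds occupancy", {
  set.seed(5)
  for (conn in c(6L, 18L, 26L)) {
    v <- array(as.integer(runif(12^3) < 0.05), dim = c(12L, 12L, 12L))
    g <- voxel_grid(v)
    out <- remove_isolated_voxels(g, conn)
    expect_true(all(out$values <= g$values))
  }
})

test_that("voxelize puts a straight chain through the grid center on axis 1", {
  tr <- generate_trace(fixture_spec("straight", n_residues = 40L,
                                    noise_sd = 0, seed = 1L))
  g <- suppressWarnings(voxelize(tr, voxelizer_config()))  # collinear: rank-deficient frame
  occ <- which(g$values == 1L, arr.ind = TRUE)
  expect_gt(nrow(occ), 5L)
  expect_equal(unique(occ[, 2L]), 17L)  # all in the center y-slice
  expect_equal(unique(occ[, 3L]), 17L)
  expect_equal(sort(occ[, 1L]), min(occ[, 1L]):max(occ[, 1L]))  # contiguous
  expect_true(17L %in% occ[, 1L])
})

test_that("voxelize is deterministic and binary with configured shape", {
  tr <- generate_trace(fixture_spec("helix", seed = 13L))
  cfg <- voxelizer_config()
  g1 <- voxelize(tr, cfg)
  g2 <- voxelize(tr, cfg)
  expect_identical(g1$values, g2$values)
  expect_equal(dim(g1$values), rep(32L, 3L))
  expect_true(all(g1$values %in% c(0L, 1L)))
  expect_gt(sum(g1$values), 0L)
})

test_that("flipped voxelization mirrors the grid through the center plane", {
  tr <- generate_trace(fixture_spec("two_lobe", seed = 21L))
  cfg <- voxelizer_config()
  g0 <- voxelize(tr, cfg, flip_code(0, 0, 0))
  g1 <- voxelize(tr, cfg, flip_code(1, 0, 0))
  # 0-based index i maps to 32 - i, i.e. 1-based row r -> 34 - r
  expect_equal(g1$values[2:32, , ], g0$values[rev(2:32), , ])
})

test_that("voxelization is invariant to rigid pre-rotation of the input", {
  set.seed(17)
  cfg <- voxelizer_config()
  for (fam in c("helix", "two_lobe", "ellipsoid")) {
    tr <- generate_trace(fixture_spec(fam, seed = 31L))
    rot <- random_rotation()
    tr_rot <- backbone_trace(tr$structure_id, tr$residue_index, tr$atom_name,
                             tr$coords %*% rot)
    g <- voxelize(tr, cfg)
    g_rot <- voxelize(tr_rot, cfg)
    mismatch <- sum(g$values != g_rot$values)
    expect_lte(mismatch, max(1L, round(0.01 * sum(g$values))))
  }
})

test_that("occupied voxels stay inside the interior margin for synthetic traces", {
  cfg <- voxelizer_config()
  for (fam in c("straight", "helix", "ring", "globule", "ellipsoid", "two_lobe")) {
    g <- voxelize(generate_trace(fixture_spec(fam, seed = 9L)), cfg)
    occ <- which(g$values == 1L, arr.ind = TRUE) - 1L  # 0-based
    expect_true(all(occ >= 1L & occ <= cfg$l - 2L))
  }
})
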