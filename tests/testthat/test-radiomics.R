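test_that("registry structure: 294 unique names, 91 + 203 split, reconciliation flags", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 294)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(sum(reg$family == "first_order"), 91)
  expect_equal(sum(reg$family != "first_order"), 203)
  expect_equal(sum(reg$reconciliation), 3 * 7)
  expect_equal(unname(table(reg$modality)), rep(42L, 7), ignore_attr = TRUE)
})

test_that("quantization: constant patches, single level, and exact binning", {
  expect_true(all(quantize(array(3.7, c(3, 3, 3)), 32) == 1L))
  expect_true(all(quantize(array(runif(27), c(3, 3, 3)), 1) == 1L))
  expect_equal(as.vector(quantize(c(0, 1, 2, 3), 2)), c(1L, 1L, 2L, 2L))
  # shift invariance
  x <- runif(27)
  expect_identical(quantize(x, 8), quantize(x + 100, 8))
})

test_that("first-order features on hand-computable patches", {
  fo <- first_order_features(array(5, c(3, 3, 3)))
  expect_equal(unname(fo[c("sd", "variance", "entropy", "skewness", "kurtosis")]),
               rep(0, 5))
  expect_equal(unname(fo["uniformity"]), 1)
  expect_equal(unname(fo["rms"]), 5)

  fo <- first_order_features(c(1, 2, 3, 4), n_levels = 32)
  expect_equal(unname(fo["mean"]), 2.5)
  expect_equal(unname(fo["median"]), 2.5)
  expect_equal(unname(fo["min"]), 1)
  expect_equal(unname(fo["max"]), 4)
  expect_equal(unname(fo["variance"]), 1.25)  # population convention
  expect_equal(unname(fo["energy"]), 30)
  expect_equal(unname(fo["rms"]), sqrt(30 / 4))

  # balanced two-level histogram: maximum-entropy 2-bin case
  fo <- first_order_features(c(0, 0, 1, 1), n_levels = 2)
  expect_equal(unname(fo["entropy"]), 1)
  expect_equal(unname(fo["uniformity"]), 0.5)
})

test_that("first-order features are permutation invariant", {
  set.seed(5)
  x <- array(rnorm(64), c(4, 4, 4))
  a <- first_order_features(x)
  b <- first_order_features(array(sample(as.vector(x)), c(4, 4, 4)))
  expect_equal(a, b)
})

test_that("co-occurrence matrix: constant patch, normalization, brute-force toy", {
  q <- quantize(array(1, c(3, 3, 3)), 8)
  P <- glcm_matrix(q, n_levels = 8)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  set.seed(6)
  for (rep in 1:5) {
    q <- array(sample(1:4, 60, TRUE), c(5, 4, 3))
    P <- glcm_matrix(q, n_levels = 4)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
    expect_equal(P, bf_glcm(q, 4, glcm_offsets_3d()), tolerance = 1e-12)
  }

  # 4x4 two-level patch, single (1,0,0) offset, against pair enumeration
  q <- array(rep(c(1L, 2L), 8), c(4, 4, 1))
  off <- matrix(c(1, 0, 0), 1)
  expect_equal(glcm_matrix(q, 2, off), bf_glcm(q, 2, off))

  # offset larger than the patch: zero matrix, flagged
  P <- glcm_matrix(array(1L, c(2, 2, 1)), 2, matrix(c(5, 0, 0), 1))
  expect_equal(sum(P), 0)
  expect_true(isTRUE(attr(P, "empty")))
})

test_that("co-occurrence features: degenerate cases and formula oracle", {
  ng <- 4
  P <- diag(ng) / ng  # all mass on the diagonal, uniform
  f <- glcm_features(P)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["dissimilarity"]), 0)
  expect_equal(unname(f["homogeneity_m"]), 1)
  expect_equal(unname(f["homogeneity_p"]), 1)

  # independence: P = outer product of its own marginals -> IMC1 = 0
  p <- c(.1, .2, .3, .4)
  f <- glcm_features(outer(p, p))
  expect_equal(unname(f["imc1"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["imc2"]), 0, tolerance = 1e-6)

  # toy matrix vs literal transcription of every formula
  set.seed(7)
  M <- matrix(runif(9), 3); M <- (M + t(M)); M <- M / sum(M)
  expect_equal(glcm_features(M), bf_glcm_features(M), tolerance = 1e-12)

  expect_error(glcm_features(matrix(0.3, 2, 2)), "normalized")
})

test_that("run length matrix: single runs, conservation, brute-force toy", {
  q <- array(2L, c(4, 1, 1))
  R <- glrlm_matrix(q, 3, directions = matrix(c(1, 0, 0), 1))
  expect_equal(R[2, 4], 1)
  expect_equal(sum(R), 1)

  set.seed(8)
  for (rep in 1:5) {
    q <- array(sample(1:3, 48, TRUE), c(4, 4, 3))
    dirs <- glcm_offsets_3d()
    R <- glrlm_matrix(q, 3, directions = dirs)
    # voxel conservation: total run length = voxels x directions
    expect_equal(sum(R %*% seq_len(ncol(R))), length(q) * nrow(dirs))
    expect_equal(R, bf_glrlm(q, 3, dirs), ignore_attr = TRUE)
  }
})

test_that("run-length features: closed forms and summation oracle", {
  # all runs of length 1: 4x1 alternating line, single direction
  q <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  f <- glrlm_features(glrlm_matrix(q, 2, directions = matrix(c(1, 0, 0), 1)))
  expect_equal(unname(f["sre"]), 1)
  expect_equal(unname(f["lre"]), 1)
  expect_equal(unname(f["run_percentage"]), 1)

  # one run of length L
  L <- 6
  q <- array(1L, c(L, 1, 1))
  f <- glrlm_features(glrlm_matrix(q, 1, directions = matrix(c(1, 0, 0), 1)))
  expect_equal(unname(f["sre"]), 1 / L^2)
  expect_equal(unname(f["lre"]), L^2)
  expect_equal(unname(f["run_percentage"]), 1 / L)

  # two-level toy matrix against the direct summation oracle
  set.seed(9)
  q <- array(sample(1:2, 36, TRUE), c(6, 3, 2))
  dirs <- glcm_offsets_3d()
  R <- glrlm_matrix(q, 2, directions = dirs)
  expect_equal(glrlm_features(R),
               bf_glrlm_features(unclass(R), length(q), nrow(dirs)),
               tolerance = 1e-12)

  expect_error(glrlm_features(matrix(0, 2, 3), 6, 1), "no runs")
})

test_that("texture features are invariant to adding a constant intensity", {
  set.seed(10)
  x <- array(runif(125), c(5, 5, 5))
  q1 <- quantize(x, 16)
  q2 <- quantize(x + 7.3, 16)
  expect_identical(q1, q2)
})

test_that("voxel-wise table has registry shape and labels", {
  dm <- c(7, 7, 7)
  set.seed(11)
  vols <- setNames(lapply(1:7, function(i) array(runif(prod(dm)), dm)),
                   modalities())
  mask <- array(FALSE, dm); mask[3:5, 3:5, 4] <- TRUE
  lab <- array(0L, dm); lab[4, 4, 4] <- 1L
  tab <- voxelwise_feature_table(vols, mask, window = 3, n_levels = 8,
                                 labels = lab, subject_id = 7)
  expect_equal(nrow(tab), sum(mask))
  expect_equal(ncol(feature_matrix(tab)), 294)
  expect_equal(sum(tab$label), 1)
  expect_true(all(tab$subject == 7))
  expect_true(all(is.finite(feature_matrix(tab))))

  # spatially constant volumes: every row identical
  cvols <- setNames(lapply(1:7, function(i) array(i, dm)), modalities())
  ctab <- voxelwise_feature_table(cvols, mask, window = 3, n_levels = 8)
  fm <- feature_matrix(ctab)
  expect_true(all(apply(fm, 2, function(col) max(col) - min(col)) == 0))

  expect_error(voxelwise_feature_table(vols[1:6], mask, 3, 8), "missing")
  expect_error(voxelwise_feature_table(vols, array(FALSE, dm), 3, 8), "no voxels")
  expect_error(voxelwise_feature_table(vols, mask, window = 4), "window")
})

test_that("bulk extraction agrees with per-patch oracles at interior and edge voxels", {
  dm <- c(6, 6, 6)
  set.seed(12)
  vols <- setNames(lapply(1:7, function(i) array(runif(prod(dm)), dm)),
                   modalities())
  mask <- array(FALSE, dm)
  mask[c(1, 80, 120, 216)] <- TRUE  # corner, interior and face voxels
  tab <- voxelwise_feature_table(vols, mask, window = 3, n_levels = 6)
  fm <- feature_matrix(tab)
  dirs <- glcm_offsets_3d()
  vox <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    for (mi in seq_along(modalities())) {
      m <- modalities()[mi]
      patch <- bf_patch(vols[[m]], vox[v, ], 3)
      q <- bf_quantize(patch, 6)
      expected <- c(bf_first_order(patch, 6),
                    bf_glcm_features(bf_glcm(q, 6, dirs)),
                    bf_glrlm_features(bf_glrlm(q, 6, dirs), length(patch),
                                      nrow(dirs)))
      got <- fm[v, (mi - 1) * 42 + 1:42]
      expect_equal(unname(got), unname(expected), tolerance = 1e-10)
    }
  }
})
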