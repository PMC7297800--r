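test_that("distance transform matches brute force under anisotropic spacing", {
  set.seed(12)
  for (rep in 1:3) {
    dm <- c(7, 6, 5)
    m <- array(runif(prod(dm)) < 0.12, dm)
    if (!any(m)) m[3, 3, 3] <- TRUE
    sp <- c(1, 2, 1.5)
    expect_equal(mask_edt(m, sp), bf_edt(m, sp), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(mask_edt(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("progression ROI is the set difference with the CE lesion", {
  dm <- c(5, 5, 5)
  ce <- array(FALSE, dm)
  prog <- array(FALSE, dm)
  # 30-voxel progression lesion overlapping CE in 12 voxels
  prog[1:30] <- TRUE
  ce[19:40] <- TRUE
  out <- progression_roi(prog, ce)
  expect_equal(which(out), setdiff(which(prog), which(ce)))
  expect_equal(sum(out), 18)

  inside <- array(FALSE, dm); inside[1:10] <- TRUE
  expect_equal(sum(progression_roi(inside, prog)), 0)  # fully inside CE

  disjoint <- array(FALSE, dm); disjoint[100:110] <- TRUE
  expect_identical(progression_roi(disjoint, ce), disjoint)

  expect_error(progression_roi(array(FALSE, c(4, 4, 4)), ce), "dimensions")
})

test_that("single-voxel CE shells match exhaustive distance counting", {
  dm <- c(21, 21, 21)
  ce <- array(FALSE, dm); ce[11, 11, 11] <- TRUE
  brain <- array(TRUE, dm)
  sh <- shell_masks(ce, NULL, brain, spacing = c(1, 1, 1))
  expect_named(sh, c("5", "10", "15", "20"))
  d <- bf_edt(ce, c(1, 1, 1))
  edges <- c(0, 5, 10, 15, 20)
  for (k in 1:4)
    expect_equal(which(sh[[k]]),
                 which(d > edges[k] & d <= edges[k + 1] & !ce))
})

test_that("a band fully claimed by the progression ROI is empty", {
  dm <- c(15, 15, 15)
  ce <- array(FALSE, dm); ce[8, 8, 8] <- TRUE
  brain <- array(TRUE, dm)
  d <- bf_edt(ce, c(1, 1, 1))
  prog <- d > 0 & d <= 5
  sh <- shell_masks(ce, prog, brain, spacing = c(1, 1, 1))
  expect_equal(sum(sh[["5"]]), 0)
  expect_gt(sum(sh[["10"]]), 0)
})

test_that("shells reject degenerate inputs", {
  dm <- c(5, 5, 5)
  brain <- array(TRUE, dm)
  expect_error(shell_masks(array(FALSE, dm), NULL, brain), "empty")
  ce <- array(FALSE, dm); ce[2, 2, 2] <- TRUE
  expect_error(shell_masks(ce, NULL, brain, distances_mm = c(10, 5)))
  expect_error(shell_masks(ce, NULL, brain, distances_mm = c(-5, 10)))
})

test_that("bands partition the 20 mm peritumoral envelope", {
  set.seed(21)
  dm <- c(18, 16, 15)
  sp <- c(1.5, 1, 2)
  ce <- array(FALSE, dm); ce[8:10, 7:9, 7:8] <- TRUE
  brain <- bf_edt(ce, sp) <= 25
  prog <- array(FALSE, dm); prog[11:12, 7:9, 7:8] <- TRUE
  prog <- prog & !ce
  sh <- shell_masks(ce, prog, brain, spacing = sp)
  # pairwise disjoint, and disjoint from CE and progression
  all_idx <- unlist(lapply(sh, which))
  expect_equal(anyDuplicated(all_idx), 0)
  expect_length(intersect(all_idx, which(ce | prog)), 0)
  # union equals the envelope
  d <- bf_edt(ce, sp)
  expect_equal(sort(unname(all_idx)),
               which(d > 0 & d <= 20 & brain & !ce & !prog))
})

test_that("dilating the CE lesion never increases distances", {
  set.seed(22)
  dm <- c(10, 10, 10)
  m <- array(runif(prod(dm)) < 0.05, dm)
  m[5, 5, 5] <- TRUE
  d1 <- mask_edt(m, c(1, 1, 1))
  d2 <- mask_edt(dilate6(m), c(1, 1, 1))
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("NAWM mirrors the abnormal region into the contralateral hemisphere", {
  dm <- c(20, 12, 12)
  brain <- array(TRUE, dm)
  ce <- array(FALSE, dm); ce[3:5, 5:7, 5:7] <- TRUE
  prog <- array(FALSE, dm); prog[6, 5:7, 5:7] <- TRUE
  nw <- nawm_mask(ce, prog, brain, spacing = c(1, 1, 1), midline_axis = 1,
                  envelope_mm = 2)
  # enumeration oracle: flip the region index-wise along axis 1
  env <- bf_edt(ce, c(1, 1, 1)) <= 2
  region <- ce | prog | env
  co <- which(region, arr.ind = TRUE)
  co[, 1] <- dm[1] + 1 - co[, 1]
  mirrored <- array(FALSE, dm); mirrored[co] <- TRUE
  expect_equal(which(nw), which(mirrored & !(ce | prog)))
  # lateral lesion in a symmetric brain: |NAWM| = |mirrored region|
  expect_equal(sum(nw), sum(region))
})

test_that("midline-straddling lesions subtract their own voxels from NAWM", {
  dm <- c(10, 8, 8)
  brain <- array(TRUE, dm)
  ce <- array(FALSE, dm); ce[4:7, 4:5, 4:5] <- TRUE  # straddles the midplane
  prog <- array(FALSE, dm)
  nw <- nawm_mask(ce, prog, brain, spacing = c(1, 1, 1), midline_axis = 1,
                  envelope_mm = 1)
  env <- bf_edt(ce, c(1, 1, 1)) <= 1
  region <- ce | env
  co <- which(region, arr.ind = TRUE)
  co[, 1] <- dm[1] + 1 - co[, 1]
  mirrored <- array(FALSE, dm); mirrored[co] <- TRUE
  expect_equal(which(nw), setdiff(which(mirrored), which(ce)))
})

test_that("NAWM degenerate inputs: empty CE errors, clipped mirror warns", {
  dm <- c(10, 8, 8)
  brain <- array(TRUE, dm)
  expect_error(nawm_mask(array(FALSE, dm), array(FALSE, dm), brain), "empty")
  # asymmetric brain: mirror falls partly outside
  brain2 <- brain; brain2[8:10, , ] <- FALSE
  ce <- array(FALSE, dm); ce[2:3, 4:5, 4:5] <- TRUE
  expect_warning(nawm_mask(ce, array(FALSE, dm), brain2, midline_axis = 1,
                           envelope_mm = 1), "outside")
})

test_that("roi_set assembles consistent regions and serializes them", {
  s <- generate_subject(phantom_params(seed = 13))
  rs <- roi_set(s)
  expect_s3_class(rs, "roi_set")
  expect_equal(sum(rs$progression & rs$ce), 0)
  idx <- unlist(lapply(rs$shells, which))
  expect_equal(anyDuplicated(idx), 0)
  expect_length(intersect(idx, which(rs$ce | rs$progression)), 0)
  expect_length(intersect(which(rs$nawm), which(rs$ce | rs$progression)), 0)
  for (m in c("ce", "progression", "nawm"))
    expect_true(all(which(rs[[m]]) %in% which(rs$brain)))
  dir <- withr::local_tempdir()
  files <- write_roi_set(rs, dir)
  expect_true(all(file.exists(files)))
  bands <- RNifti::readNifti(files["bands"])
  expect_equal(sum(bands == 2), sum(rs$shells[["10"]]))
})
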