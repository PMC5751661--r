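test_that("patch layer tiles the annulus with overlapping circles", {
  m <- make_disk(161, 60)
  res <- contract_border(m, 20)
  ps <- build_patch_layer(res, 10)
  # mid-curve circumference / spacing = 2*pi*50 / 10 ~ 32 patches
  expect_gte(nrow(ps$centers), 30)
  expect_lte(nrow(ps$centers), 34)
  # centers sit on the mid-curve, radius_r inside the original border
  cd <- point_min_dist(ps$centers,
                       res$original$points[-nrow(res$original$points), ])
  expect_true(all(abs(cd - 10) <= 1.5))
  # all patch pixels are annulus pixels
  ann <- which(res$annulus_mask == 1)
  expect_true(all(unlist(ps$patch_pixel_sets) %in% ann))

  expect_error(build_patch_layer(res, 7), "distance_L = 2")
  expect_error(build_patch_layer(res, 10, spacing_factor = 2.5), "overlap")
})

test_that("patch union covers at least 95% of the annulus on random blobs", {
  for (s in 1:10) {
    m <- make_blob(n = 128, R = 40, irr = 0.18, seed = s)
    res <- contract_border(m, 16)
    ps <- build_patch_layer(res, 8)
    expect_gte(patch_coverage(ps, res$annulus_mask), 0.95)
  }
})

test_that("quantization bins the full range uniformly and monotonically", {
  expect_equal(quantize_channel(matrix(100), 2)[1], 0L)
  expect_equal(quantize_channel(matrix(200), 2)[1], 1L)
  expect_equal(unique(as.vector(quantize_channel(matrix(77, 4, 4), 32))),
               quantize_channel(matrix(77), 32)[1])   # constant -> one level
  set.seed(1)
  x <- matrix(runif(400, 0, 255), 20, 20)
  q <- quantize_channel(x, 32)
  expect_true(all(q >= 0 & q <= 31))
  ord <- order(as.vector(x))
  expect_true(all(diff(as.vector(q)[ord]) >= 0))      # monotone
  expect_error(quantize_channel(x, 1), "levels")
})

test_that("co-occurrence counting matches hand enumeration", {
  # 2x2 patch [[0,0],[1,1]], horizontal offset: pairs (0,0) and (1,1)
  q <- rbind(c(0L, 0L), c(1L, 1L))
  g <- compute_glcm(q, matrix(TRUE, 2, 2), offset = c(0L, 1L), levels = 2)
  expect_equal(g$counts, diag(2) * 0.5)
  expect_true(g$normalized)

  # constant patch: all mass at (k, k)
  qc <- matrix(3L, 4, 4)
  gc <- compute_glcm(qc, matrix(TRUE, 4, 4), levels = 8)
  expect_equal(gc$counts[4, 4], 1)
  expect_equal(sum(gc$counts), 1)

  expect_error(compute_glcm(q, matrix(FALSE, 2, 2)), "pairs")
})

test_that("co-occurrence counts equal a brute-force double loop", {
  set.seed(11)
  for (k in 1:20) {
    q <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    msk <- matrix(runif(64) > 0.25, 8, 8)
    off <- if (k %% 2 == 0) c(0L, 1L) else c(1L, 0L)
    if (sum(msk) < 4) msk[] <- TRUE
    got <- compute_glcm(q, msk, offset = off, levels = 8, normalize = FALSE)
    expect_identical(got$counts, brute_glcm_counts(q, msk, off, 8) * 1)
  }
})

test_that("homogeneity evaluates the weighted diagonal sum", {
  expect_equal(glcm_homogeneity(diag(2) * 0.5), 1.0)
  expect_equal(glcm_homogeneity(matrix(0.25, 2, 2)), 0.75)
  expect_error(glcm_homogeneity(matrix(1, 2, 2)), "normalized")

  set.seed(3)
  for (k in 1:20) {
    n <- sample(2:8, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)); a <- a / sum(a)
    h <- glcm_homogeneity(a)
    expect_gt(h, 0); expect_lte(h, 1)
    if (sum(a) - sum(diag(a)) > 1e-9) expect_lt(h, 1)
  }
})

test_that("patch statistics combine texture and color moments", {
  const <- matrix(100, 6, 6)
  expect_equal(unname(patch_statistics(const, matrix(TRUE, 6, 6))),
               c(1, 100, 0))

  two <- matrix(c(0, 255), 6, 6)                       # half 0, half 255
  st <- patch_statistics(two, matrix(TRUE, 6, 6))
  expect_equal(unname(st[2]), 127.5)
  expect_equal(unname(st[3]), 127.5)

  # checkerboard (high frequency) is less homogeneous than a smooth ramp
  chk <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  ramp <- matrix(seq(0, 255, length.out = 8), 8, 8)
  h_chk <- patch_statistics(chk, matrix(TRUE, 8, 8))[1]
  h_ramp <- patch_statistics(ramp, matrix(TRUE, 8, 8))[1]
  expect_lt(h_chk, h_ramp)
})

test_that("feature vectors have the fixed dimensionality and order", {
  les <- generate_lesion(lesion_spec(edge_profile = "abrupt", seed = 21))
  res <- contract_border(les$mask, 20)
  for (cs in c("RGB", "HSV")) {
    fv <- extract_features(les$image, res, 10, cs)
    expect_length(fv$values, 18)
    expect_equal(names(fv$values), feature_names(cs))
  }
  fv <- extract_features(les$image, res, 10, "RGB+HSV")
  expect_length(fv$values, 36)
  # combined = RGB block then HSV block
  expect_equal(names(fv$values)[1:18], feature_names("RGB"))
})

test_that("a uniform lesion has homogeneity 1 and zero stds", {
  sp <- lesion_spec(irregularity = 0, noise_sd = 0, texture_amplitude = 0,
                    edge_profile = "abrupt", seed = 1)
  les <- generate_lesion(sp)
  res <- contract_border(les$mask, 20)
  fv <- extract_features(les$image, res, 10, "RGB")
  v <- fv$values
  expect_true(all(v[grep("homogeneity", names(v))] == 1))
  expect_true(all(v[grep("colstd", names(v))] == 0))
})

test_that("min aggregation never exceeds mean aggregation", {
  co <- generate_cohort(10, 10, seed = 31)
  for (i in seq_along(co$ids)) {
    res <- contract_border(co$masks[[i]], 20)
    v <- extract_features(co$images[[i]], res, 10, "RGB")$values
    for (ch in c("R", "G", "B")) {
      expect_lte(v[paste0(ch, "_min_homogeneity")],
                 v[paste0(ch, "_mean_homogeneity")])
      expect_lte(v[paste0(ch, "_min_colmean")], v[paste0(ch, "_mean_colmean")])
    }
  }
})

test_that("feature extraction is bit-identical across repeated runs", {
  les <- generate_lesion(lesion_spec(edge_profile = "gradual", seed = 8))
  res <- contract_border(les$mask, 20)
  f1 <- extract_features(les$image, res, 10, "RGB+HSV")
  f2 <- extract_features(les$image, contract_border(les$mask, 20), 10,
                         "RGB+HSV")
  expect_identical(f1$values, f2$values)
})
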