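test_that("signed distance init has the right sign, scale and zero level", {
  m <- make_disk(101, 30)
  f <- init_signed_distance(m)
  expect_s3_class(f, "level_set_field")
  expect_equal(f$time, 0)
  expect_lt(abs(f$phi[51, 51] + 30), 0.5 + 1e-9)      # center ~ -R
  expect_gt(f$phi[1, 1], 0)                           # corners outside
  expect_gt(f$phi[1, 101], 0)
  expect_gt(f$phi[101, 1], 0)

  # brute-force oracle: distance to the nearest boundary pixel, 20 pixels
  bnd <- which(brute_boundary(m) == 1, arr.ind = TRUE)
  set.seed(4)
  for (k in 1:20) {
    r <- sample(101, 1); c <- sample(101, 1)
    d <- min(sqrt((bnd[, 1] - r)^2 + (bnd[, 2] - c)^2))
    expect_lt(abs(abs(f$phi[r, c]) - d), 1 + 1e-9)
  }
})

test_that("contraction spec validates its stability bounds", {
  expect_error(contraction_spec(-3), "distance_L")
  expect_error(contraction_spec(10, dt = 0.8), "stability")
  expect_error(contraction_spec(10, dt = 0), "stability")
  sp <- contraction_spec(10)
  expect_equal(sp$velocity, 1)
  expect_equal(sp$reinit_every, 2)
})

test_that("evolving a disk moves the zero level inward by L", {
  m <- make_disk(111, 40)
  f <- init_signed_distance(m)
  expect_identical(evolve(f, 0), f)                   # zero time = identity
  f2 <- evolve(f, contraction_spec(12))
  expect_equal(f2$time, 12)
  rr <- sqrt(rowSums((extract_zero_level_set(f2)[[1]] - 56)^2))
  expect_true(all(abs(rr - 28) <= 1))
})

test_that("the inside region shrinks monotonically during evolution", {
  m <- make_blob(n = 112, R = 36, seed = 2)
  f <- init_signed_distance(m)
  areas <- sum(f$phi < 0)
  for (i in 1:5) {
    f <- evolve(f, contraction_spec(2))
    areas <- c(areas, sum(f$phi < 0))
  }
  expect_true(all(diff(areas) < 0))
})

test_that("zero level extraction recovers circles, loop closure and area", {
  m <- make_disk(101, 30)
  f <- init_signed_distance(m)
  curves <- extract_zero_level_set(f)
  expect_length(curves, 1)
  poly <- curves[[1]]
  expect_gte(nrow(poly), 8)
  expect_equal(poly[1, ], poly[nrow(poly), ])
  rr <- sqrt(rowSums((poly - 51)^2))
  expect_true(all(abs(rr - 30) <= 0.5 + 1e-9))
  # shoelace area vs pixel count, within one perimeter
  a <- abs(polygon_area(poly))
  expect_lt(abs(a - sum(f$phi < 0)), polyline_length(poly))
})

test_that("time-stepped contraction matches the distance-transform offset", {
  for (s in 1:3) {
    m <- make_blob(n = 128, R = 40, irr = 0.22, seed = s)
    f0 <- init_signed_distance(m)
    f <- evolve(f0, contraction_spec(10))
    lsp <- do.call(rbind, lapply(extract_zero_level_set(f), densify))
    oracle <- do.call(rbind,
                      lapply(zero_level_curves(f0$phi, level = -10), densify))
    expect_lt(hausdorff_distance(lsp, oracle), 1.5)
  }
})

test_that("the pde and distance methods of contract_border agree", {
  for (s in c(4, 9)) {
    m <- make_blob(n = 128, R = 40, seed = s)
    r1 <- contract_border(m, 10, method = "pde")
    r2 <- contract_border(m, 10, method = "distance")
    a <- do.call(rbind, lapply(r1$contracted, densify))
    b <- do.call(rbind, lapply(r2$contracted, densify))
    expect_lt(hausdorff_distance(a, b), 1)
    # annulus masks nearly coincide
    expect_lt(mean(r1$annulus_mask != r2$annulus_mask), 0.02)
  }
})

test_that("contract_border yields the analytic annulus and distance band", {
  m <- make_disk(121, 50)
  res <- contract_border(m, 20)
  expect_s3_class(res, "contraction_result")
  a <- sum(res$annulus_mask)
  expect_lt(abs(a - pi * (50^2 - 30^2)) / (pi * (50^2 - 30^2)), 0.05)

  m <- make_blob(n = 128, R = 40, seed = 9)
  res <- contract_border(m, 10, method = "pde")
  vd <- point_min_dist(do.call(rbind, res$contracted),
                       res$original$points[-nrow(res$original$points), ])
  expect_gte(min(vd), 8.5)
  expect_lte(max(vd), 11.5)
  # contracted region lies inside the original mask
  ins <- res$field_final$phi < 0
  expect_true(all(m[ins] == 1))
})

test_that("contracting twice approximates one contraction by the sum", {
  m <- make_blob(n = 128, R = 42, seed = 6)
  res1 <- contract_border(m, 6)
  mask2 <- matrix(0L, nrow(m), ncol(m))
  mask2[res1$field_final$phi < 0] <- 1L
  res2 <- contract_border(mask2, 6)
  resd <- contract_border(m, 12)
  a <- do.call(rbind, lapply(res2$contracted, densify))
  b <- do.call(rbind, lapply(resd$contracted, densify))
  expect_lt(hausdorff_distance(a, b), 1.5)
})

test_that("over-contraction errors name the maximal feasible distance", {
  m <- make_disk(61, 15)
  err <- tryCatch(contract_border(m, 20), error = function(e) e)
  expect_match(conditionMessage(err), "over-contraction")
  expect_match(conditionMessage(err), "at most")
  maxL <- as.numeric(sub(".*at most ([0-9.]+) px.*", "\\1",
                         conditionMessage(err)))
  expect_lt(abs(maxL - 15), 1.5)
  expect_error(contract_border(m, 10, dt = 0.9, method = "pde"), "stability")
})

test_that("naive normal offset matches the level set on convex shapes only", {
  # disk: normals never collide, both methods give the circle R - L
  m <- make_disk(121, 45)
  ch <- trace_chain_code(m)
  off <- naive_normal_offset(ch, 15)
  rr <- sqrt(rowSums((off - 61)^2))
  expect_true(all(abs(rr - 30) <= 1.5))
  expect_true(polyline_is_simple(off))
  lsp <- contract_border(m, 15, method = "pde")$contracted[[1]]
  expect_lt(hausdorff_distance(densify(off), densify(lsp)), 1.5)

  # deep concavities (curvature radius < L): naive self-intersects, the
  # entropy-satisfying contraction stays simple
  s <- make_star()
  ch <- trace_chain_code(s)
  expect_false(polyline_is_simple(naive_normal_offset(ch, 12)))
  res <- contract_border(s, 12, method = "pde")
  expect_true(all(vapply(res$contracted, polyline_is_simple, logical(1))))
})
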