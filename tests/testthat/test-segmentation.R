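test_that("to_grayscale handles 1- and 3-channel input and rejects others", {
  v <- matrix(100, 4, 4)
  rgb <- array(100, dim = c(4, 4, 3))
  expect_equal(unclass(to_grayscale(rgb))[1, 1], 100)
  expect_true(all(unclass(to_grayscale(array(0, c(3, 3, 3)))) == 0))
  # luminance weighting on known channel values
  arr <- array(0, dim = c(3, 3, 3))
  arr[, , 1] <- 200; arr[, , 2] <- 100; arr[, , 3] <- 50
  expected <- 0.299 * 200 + 0.587 * 100 + 0.114 * 50
  expect_equal(unclass(to_grayscale(arr))[2, 2], expected)
  expect_identical(unclass(to_grayscale(v))[1, 1], 100)
  expect_error(to_grayscale(array(1, c(3, 3, 2))), "channel")
})

test_that("median_smooth removes isolated speckle and is identity at k = 1", {
  g <- matrix(10, 9, 9)
  expect_identical(median_smooth(g, 1L), g)
  g[5, 5] <- 250
  sm <- median_smooth(gray_image(g), 3L)
  expect_equal(unclass(sm)[5, 5], 10)    # 9-value median is the dark level
  const <- gray_image(matrix(42, 6, 6))
  expect_true(all(unclass(median_smooth(const, 5L)) == 42))
  expect_error(median_smooth(g, 2L), "odd")
})

test_that("invert_image is the 255-complement involution", {
  g <- gray_image(matrix(c(0, 128, 255, 40), 2, 2))
  inv <- invert_image(g)
  expect_equal(sort(as.vector(unclass(inv))), c(0, 127, 215, 255))
  expect_equal(unclass(invert_image(inv)), unclass(g))
})

test_that("Otsu separates a two-level image and errors on constant input", {
  g <- matrix(0, 10, 10)
  g[, 6:10] <- 255
  res <- threshold_otsu(g)
  expect_identical(raw_logical(res$mask), g > 127)
  expect_true(res$threshold >= 0 && res$threshold < 255)
  expect_error(threshold_otsu(matrix(7, 5, 5)), "degenerate")
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  set.seed(11)
  for (i in 1:25) {
    counts <- random_bimodal_hist(w_hi = runif(1, 0.2, 0.8))
    expect_identical(rootpheno:::otsu_from_hist(counts), brute_otsu(counts))
  }
})

test_that("triangle threshold matches the geometric oracle and symmetry", {
  set.seed(12)
  for (i in 1:25) {
    counts <- random_skewed_hist()
    expect_identical(rootpheno:::triangle_from_hist(counts),
                     brute_triangle(counts))
  }
  # two-level image separates the levels
  g <- matrix(20, 8, 8); g[, 5:8] <- 240
  t2 <- threshold_triangle(g)$threshold
  expect_true(t2 >= 20 && t2 < 240)
  # mirrored histogram maps the threshold to 255 - t within one bin
  set.seed(13)
  v <- pmin(pmax(round(c(rnorm(5000, 40, 10), rnorm(400, 180, 15))), 0), 255)
  g1 <- matrix(v[1:5304][seq_len(5304)], 52, 102)
  t1 <- threshold_triangle(g1)$threshold
  tm <- threshold_triangle(255 - g1)$threshold
  expect_lte(abs((255 - t1) - tm), 1)
})

test_that("adaptive thresholding follows the local-contrast contract", {
  # constant image with positive offset: nothing exceeds its neighbourhood
  expect_equal(sum(threshold_adaptive(matrix(80, 12, 12), "mean",
                                      3L, offset_c = 2)), 0)
  # step edge, mean mode, block 3, offset 0: foreground hugs the bright
  # (root) side of the edge, where pixels exceed the straddling local mean
  g <- matrix(0, 8, 8); g[, 5:8] <- 210
  m <- threshold_adaptive(g, "mean", 3L, offset_c = 0)
  # column 5 mean straddles the edge (mean 140 < 210) -> foreground
  expect_true(all(m[2:7, 5]))
  # deep background far from the edge is not foreground
  expect_true(all(!m[, 1:3]))
  # gaussian with large sigma approaches mean mode on a smooth ramp
  ramp <- matrix(rep(seq(0, 200, length.out = 20), each = 20), 20, 20)
  lm_box <- rootpheno:::cpp_local_mean(ramp, 9L, FALSE, 0)
  lm_g <- rootpheno:::cpp_local_mean(ramp, 9L, TRUE, 50)
  expect_lt(max(abs(lm_box - lm_g)), 1)
  expect_error(threshold_adaptive(g, "mean", 4L), "odd")
})

test_that("particle clearance removes exactly the small components", {
  m <- matrix(FALSE, 40, 40)
  m[2:4, 2] <- TRUE                 # size 3
  m[10:14, 10:19] <- TRUE           # size 50
  m[25:39, 5:38] <- TRUE            # size 510
  msk <- binary_mask(m, "manual")
  out <- remove_small_components(msk, min_area = 10L)
  expect_equal(sum(out), 50 + 510)
  expect_equal(count_components(out), 2L)
  # identity at 0, empty when the floor exceeds everything
  expect_identical(raw_logical(remove_small_components(msk, 0L)),
                   raw_logical(msk))
  expect_equal(sum(remove_small_components(msk, 1000L)), 0)
})

test_that("particle clearance is idempotent and never adds foreground", {
  set.seed(14)
  for (i in 1:10) {
    m <- matrix(runif(900) < 0.25, 30, 30)
    a <- remove_small_components(binary_mask(m, "manual"), 5L)
    b <- remove_small_components(a, 5L)
    expect_identical(raw_logical(a), raw_logical(b))
    expect_lte(sum(a), sum(m))
    expect_true(all(!(raw_logical(a) & !m)))   # subset of the input
  }
})

test_that("manual thresholds on a root-bright image are nested", {
  # qualitative threshold-level behaviour: a lower cutoff keeps at least
  # the foreground of any higher cutoff (erase vs merge extremes)
  ph <- rootpheno:::single_wire_phantom(5, 80, noise_sd = 8, seed = 3)
  inv <- 255 - unclass(ph$image)
  prev <- NULL
  for (t in c(1, 60, 170, 254)) {
    fg <- inv > t
    if (!is.null(prev)) expect_true(all(fg <= prev))
    prev <- fg
  }
})

test_that("threshold outputs are exact binary partitions", {
  ph <- rootpheno:::single_wire_phantom(9, 100, noise_sd = 5, seed = 5)
  inv <- invert_image(ph$image)
  for (mk in list(threshold_otsu(inv)$mask, threshold_triangle(inv)$mask,
                  threshold_adaptive(inv, "mean"),
                  threshold_adaptive(inv, "gaussian"))) {
    expect_type(mk, "logical")
    expect_identical(dim(mk), dim(unclass(ph$image)))
    expect_false(anyNA(mk))
    expect_equal(sum(mk) + sum(!mk), length(mk))
  }
})
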