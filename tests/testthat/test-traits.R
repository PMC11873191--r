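ps400 <- scale_from_dpi(400)

test_that("distance transform is the exact Euclidean distance", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  expect_equal(unclass(distance_transform(m))[5, 5], 1)  # adjacent background
  # 9-px ribbon spanning the full width: centre row is 5 from background
  rib <- matrix(FALSE, 19, 19)
  rib[6:14, ] <- TRUE
  expect_equal(unclass(distance_transform(rib))[10, 10], 5)
  # diagonal nearest background at offset (3, 4) -> 5 (Pythagoras)
  blk <- matrix(TRUE, 10, 10)
  blk[1, 1] <- FALSE                     # single background pixel
  d <- unclass(distance_transform(blk))
  expect_equal(d[4, 5], 5)
  expect_equal(d[5, 4], 5)
  expect_equal(unclass(distance_transform(matrix(c(TRUE, FALSE), 2, 2)))[1, 1],
               1)
})

test_that("distance transform pads an all-foreground mask and is Lipschitz", {
  expect_message(d <- distance_transform(matrix(TRUE, 7, 7)), "ring")
  expect_equal(unclass(d)[4, 4], 4)   # centre of a 7x7 with implicit ring
  set.seed(31)
  m <- matrix(runif(1600) < 0.6, 40, 40)
  dv <- unclass(distance_transform(m))
  expect_true(all(dv[!m] == 0))
  expect_true(all(dv[m] > 0))
  # 1-Lipschitz across orthogonal neighbours
  expect_true(all(abs(diff(dv)) <= 1 + 1e-12))
  expect_true(all(abs(t(diff(t(dv)))) <= 1 + 1e-12))
})

test_that("total_root_length applies the diagonal sqrt(2) rule per edge", {
  unit <- root_scale(1)
  d2 <- matrix(FALSE, 4, 4); d2[2, 2] <- TRUE; d2[3, 3] <- TRUE
  expect_equal(total_root_length(d2, unit), sqrt(2))
  # horizontal chain of n pixels -> n - 1
  h <- matrix(FALSE, 3, 12); h[2, 2:11] <- TRUE
  expect_equal(total_root_length(h, unit), 9)
  # pure 45-degree staircase -> Euclidean endpoint distance
  st <- matrix(FALSE, 14, 14)
  for (k in 1:10) st[k + 1, k + 1] <- TRUE
  expect_equal(total_root_length(st, unit), 9 * sqrt(2))
  # L-corner: the diagonal closing the triangle is suppressed
  l3 <- matrix(FALSE, 4, 4); l3[2, 2] <- TRUE; l3[2, 3] <- TRUE
  l3[3, 3] <- TRUE
  expect_equal(total_root_length(l3, unit), 2)
  expect_equal(total_root_length(matrix(FALSE, 5, 5), unit), 0)
})

test_that("TRL equals the polyline-through-centres oracle on random chains", {
  set.seed(32)
  unit <- root_scale(1)
  for (i in 1:25) {
    chain <- random_chain(n_steps = sample(10:60, 1))
    m <- chain_to_matrix(chain, max(chain[, 1]) + 2L, max(chain[, 2]) + 2L)
    expect_equal(total_root_length(m, unit), polyline_length(chain),
                 tolerance = 1e-9)
  }
})

test_that("the per-pixel length rule counts diagonal-only pixels as sqrt(2)", {
  unit <- root_scale(1)
  h <- matrix(FALSE, 3, 12); h[2, 2:11] <- TRUE
  expect_equal(total_root_length(h, unit, rule = "pixels"), 10)
  st <- matrix(FALSE, 14, 14)
  for (k in 1:10) st[k + 1, k + 1] <- TRUE
  expect_equal(total_root_length(st, unit, rule = "pixels"), 10 * sqrt(2))
})

test_that("radii_along_skeleton maps DT values through the pixel size", {
  rib <- matrix(FALSE, 19, 40)
  rib[6:14, ] <- TRUE
  dm <- distance_transform(rib)
  sk <- matrix(FALSE, 19, 40)
  sk[10, 6:35] <- TRUE        # centre row, away from the ends
  r <- radii_along_skeleton(sk, dm, root_scale(0.0063))
  expect_length(r, 30)
  expect_true(all(r == 5 * 0.0063))    # DT 5 px * 0.0063 cm = 0.0315 cm
  expect_equal(r[1], 0.0315)
  expect_length(radii_along_skeleton(matrix(FALSE, 19, 40), dm,
                                     ps400), 0)
  # skeleton pixel outside the mask is an internal error
  bad <- sk; bad[1, 1] <- TRUE
  expect_error(radii_along_skeleton(bad, dm, ps400), "consistency")
})

test_that("trait aggregators implement the per-pixel cylinder sums", {
  expect_equal(average_diameter(rep(0.02, 7)), 0.04)
  expect_equal(average_diameter(c(0.01, 0.02)), 0.03)
  expect_error(average_diameter(numeric(0)), "undefined")

  s <- root_scale(0.0063)
  expect_equal(surface_area(0.01, s), 0.0063 * 2 * pi * 0.01)
  expect_equal(surface_area(0.01, s), 3.958e-4, tolerance = 1e-3)
  expect_equal(root_volume(0.01, s), 0.0063 * pi * 0.01^2)
  expect_equal(root_volume(0.01, s), 1.979e-6, tolerance = 1e-3)
  r <- c(0.01, 0.03, 0.02)
  expect_equal(surface_area(2 * r, s), 2 * surface_area(r, s))
  expect_equal(root_volume(3 * r, s), 9 * root_volume(r, s))
  expect_message(expect_equal(surface_area(numeric(0), s), 0), "empty")
  expect_message(expect_equal(root_volume(numeric(0), s), 0), "empty")

  # bit-consistency with the radius list (the only asserted identity)
  expect_identical(surface_area(r, s), s$pixel_size * sum(2 * pi * r))
  expect_identical(root_volume(r, s), s$pixel_size * sum(pi * r^2))
})

test_that("projected_area is foreground count times pixel area", {
  s <- root_scale(0.01)
  expect_equal(projected_area(matrix(FALSE, 5, 5), s), 0)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(projected_area(m, s), 100 * 1e-4)
  rect <- matrix(TRUE, 7, 13)
  expect_equal(projected_area(rect, s), 7 * 13 * 0.01^2)
})

test_that("estimated traits follow the projected-area cylinder model", {
  est <- estimated_traits(pa = 1, trl = 10)
  expect_equal(est$ad_est, 0.1)
  expect_equal(est$sa_est, pi)
  expect_equal(est$sa_est, 3.141, tolerance = 2e-4)
  expect_equal(est$rv_est, pi * 0.05^2 * 10)
  expect_equal(est$rv_est, 0.0785, tolerance = 1e-3)
  expect_error(estimated_traits(1, 0), "TRL")
})

test_that("analyze_root recovers wire phantoms within the method's physics", {
  # r = DT * ps makes the measured diameter (w + 1) px for a w-px stroke,
  # hence SA scales by (w+1)/w and RV by ((w+1)/w)^2 against the cylinder
  s <- ps400
  for (w in c(5, 9)) {
    ph <- rootpheno:::single_wire_phantom(w, 300, noise_sd = 0)
    tr <- analyze_root(ph$image, scale = s)
    truth <- ph$truth[[1]]
    expect_lt(abs(tr$trl - truth$length_cm),
              max(0.03 * truth$length_cm, w * s$pixel_size))
    expect_lt(abs(tr$ad - truth$diameter_cm), 1.5 * s$pixel_size)
    bias <- (w + 1) / w
    expect_equal(tr$sa, truth$sa_cm2 * bias, tolerance = 0.04)
    expect_equal(tr$rv, truth$volume_cm3 * bias^2, tolerance = 0.06)
    expect_equal(tr$projected_area, truth$pa_cm2, tolerance = 0.05)
  }
})

test_that("blank scans yield zero traits with a warning", {
  blank <- gray_image(matrix(235, 40, 40))
  expect_warning(tr <- analyze_root(blank, scale = ps400), "blank")
  expect_equal(tr$trl, 0)
  expect_equal(tr$sa, 0)
  expect_equal(tr$n_skeleton_pixels, 0L)
  # noisy but rootless scan: speckle is cleared, traits are zero
  set.seed(33)
  noise <- gray_image(pmin(pmax(round(235 + rnorm(1600, 0, 4)), 0), 255) |>
                        matrix(40, 40))
  tr2 <- suppressWarnings(analyze_root(noise, scale = ps400))
  expect_equal(tr2$trl, 0)
})

test_that("forcing a single method overrides the default pairing", {
  ph <- rootpheno:::single_wire_phantom(9, 120, noise_sd = 0)
  tr_auto <- analyze_root(ph$image, scale = ps400)
  expect_identical(tr_auto$method_trl, "triangle")
  expect_identical(tr_auto$method_dt, "otsu")
  tr_otsu <- analyze_root(ph$image, config = seg_config(method = "otsu"),
                          scale = ps400)
  expect_identical(tr_otsu$method_trl, "otsu")
  expect_identical(tr_otsu$method_dt, "otsu")
})

test_that("DT traits are invariant under rotation and mirroring", {
  ph <- rootpheno:::single_wire_phantom(9, 150, noise_sd = 0)
  img <- unclass(ph$image)
  tr0 <- analyze_root(gray_image(img), scale = ps400)
  tr90 <- analyze_root(gray_image(rotate90(img)), scale = ps400)
  trm <- analyze_root(gray_image(img[, ncol(img):1]), scale = ps400)
  expect_identical(tr0$sa, tr90$sa)
  expect_identical(tr0$rv, tr90$rv)
  expect_identical(tr0$ad, tr90$ad)
  expect_identical(tr0$trl, tr90$trl)       # TRL exact under 90 degrees
  expect_identical(tr0$sa, trm$sa)
  expect_identical(tr0$rv, trm$rv)
})

test_that("adding a disjoint fragment never decreases the sum traits", {
  s <- ps400
  base <- matrix(FALSE, 60, 60)
  base[10:14, 5:50] <- TRUE
  frag <- matrix(FALSE, 60, 60)
  frag[40:44, 10:30] <- TRUE
  both <- base | frag
  tr_of <- function(m) {
    sk <- thin(m)
    dm <- distance_transform(m)
    r <- radii_along_skeleton(sk, dm, s)
    c(trl = total_root_length(sk, s), sa = surface_area(r, s),
      rv = root_volume(r, s), pa = projected_area(m, s))
  }
  a <- tr_of(base); b <- tr_of(both)
  expect_true(all(b >= a))
})
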