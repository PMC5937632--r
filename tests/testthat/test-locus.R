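test_that("locus points lie on a line parallel to the lightness axis", {
  expect_equal(locus_point(achromatic_locus(0, 0), 50), c(L = 50, a = 0, b = 0))
  loc <- achromatic_locus(-5, -20)
  expect_equal(locus_point(loc, 25), c(L = 25, a = -5, b = -20))
  expect_equal(locus_point(loc, 80), c(L = 80, a = -5, b = -20))
})

test_that("a neutral region yields a neutral locus at any L_base", {
  img <- lab_image(matrix(c(20, 40, 60, 80), 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                   masks = list(body = matrix(TRUE, 2, 2)))
  for (lb in c(10, 25, 60)) {
    loc <- estimate_locus_from_region(img, "body", L_base = lb)
    expect_equal(c(loc$a0, loc$b0), c(0, 0), tolerance = 1e-9)
  }
})

test_that("a single-chromaticity region estimates the locus predicted by scalar conversion", {
  lab0 <- c(55, 12, -35)
  img <- lab_image(matrix(lab0[1], 3, 3), matrix(lab0[2], 3, 3), matrix(lab0[3], 3, 3),
                   masks = list(body = matrix(TRUE, 3, 3)))
  loc <- estimate_locus_from_region(img, "body", L_base = 25)
  # oracle: chromaticity of lab0 re-rendered at the luminance of L* = 25
  xyz <- oracle_lab_to_xyz(lab0)
  xy <- xyz[1:2] / sum(xyz)
  Yb <- 100 * oracle_f_inv((25 + 16) / 116)
  lab_b <- oracle_xyz_to_lab(c(xy[1] / xy[2] * Yb, Yb, (1 - sum(xy)) / xy[2] * Yb))
  expect_equal(c(loc$a0, loc$b0), lab_b[2:3], tolerance = 1e-9)
})

test_that("the chromaticity mean is invariant to the region's luminance", {
  xyz0 <- c(25, 22, 40)
  dim_px <- xyz_to_lab_d65(rbind(xyz0 * 0.4, xyz0 * 0.5))
  bright_px <- xyz_to_lab_d65(rbind(xyz0 * 2, xyz0 * 3))
  mk <- list(body = matrix(TRUE, 1, 2))
  img_dim <- lab_image(rbind(dim_px[, 1]), rbind(dim_px[, 2]), rbind(dim_px[, 3]), mk)
  img_bright <- lab_image(rbind(bright_px[, 1]), rbind(bright_px[, 2]), rbind(bright_px[, 3]), mk)
  l1 <- estimate_locus_from_region(img_dim, "body", 25)
  l2 <- estimate_locus_from_region(img_bright, "body", 25)
  expect_equal(c(l1$a0, l1$b0), c(l2$a0, l2$b0), tolerance = 1e-9)
})

test_that("empty or zero-luminance regions are rejected", {
  img <- lab_image(matrix(10, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                   masks = list(body = matrix(FALSE, 2, 2)))
  expect_error(estimate_locus_from_region(img, "body"), "empty")
  img0 <- lab_image(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                    masks = list(body = matrix(TRUE, 2, 2)))
  expect_error(estimate_locus_from_region(img0, "body"), "zero-luminance")
})

test_that("a neutral locus gives unit coefficients at every lightness", {
  loc <- achromatic_locus(0, 0)
  k <- coefficients_at_lightness(loc, seq(5, 95, by = 10))
  expect_equal(unname(k), matrix(1, 10, 3), tolerance = 1e-12)
})

test_that("coefficients differ across lightness and match the scalar oracle", {
  loc <- achromatic_locus(-5, -20)
  for (L in c(25, 75)) {
    k <- coefficients_at_lightness(loc, L)
    k_oracle <- oracle_xyz_to_lms(oracle_lab_to_xyz(c(L, 0, 0))) /
      oracle_xyz_to_lms(oracle_lab_to_xyz(c(L, -5, -20)))
    expect_equal(unname(k), k_oracle, tolerance = 1e-9)
  }
  expect_gt(max(abs(coefficients_at_lightness(loc, 25) -
                    coefficients_at_lightness(loc, 75))), 1e-3)
})

test_that("coefficients null the locus point at its own lightness (property over a grid)", {
  withr::with_seed(7, {
    for (rep in 1:8) {
      # this offset box keeps the locus inside the cone-response gamut down
      # to L* = 5 (yellowish offsets turn non-physical at dark lightness)
      a0 <- runif(1, -20, 20); b0 <- runif(1, -20, 5)
      loc <- achromatic_locus(a0, b0)
      for (L in seq(5, 95, by = 10)) {
        k <- coefficients_at_lightness(loc, L)
        lms <- xyz_to_lms(lab_d65_to_xyz(c(L, a0, b0))) * k
        out <- xyz_to_lab_d65(lms_to_xyz(lms))
        expect_equal(unname(out[2:3]), c(0, 0), tolerance = 1e-9)
      }
    }
  })
})

test_that("coefficients vary continuously and monotonically in lightness", {
  loc <- achromatic_locus(-8, -24)
  L <- seq(10, 95, by = 2.5)
  k <- coefficients_at_lightness(loc, L)
  expect_true(all(abs(diff(k)) < 0.2))          # no jumps
  for (j in 1:3) {
    d <- diff(k[, j])
    expect_true(all(d > 0) || all(d < 0))       # single-signed slope
  }
})

test_that("the locus and the illuminant-chromaticity locus agree at L_base", {
  # the two loci cross at L_base: the illuminant-chromaticity point rendered
  # at L_base *is* the locus point there, so its coefficients coincide
  lab0 <- c(60, 5, -30)
  img <- lab_image(matrix(lab0[1], 2, 2), matrix(lab0[2], 2, 2), matrix(lab0[3], 2, 2),
                   masks = list(body = matrix(TRUE, 2, 2)))
  loc <- estimate_locus_from_region(img, "body", 25)
  xyz <- oracle_lab_to_xyz(lab0)
  xy <- xyz[1:2] / sum(xyz)
  Yb <- 100 * oracle_f_inv((25 + 16) / 116)
  ill_pt <- oracle_xyz_to_lab(c(xy[1] / xy[2] * Yb, Yb, (1 - sum(xy)) / xy[2] * Yb))
  k_ill <- oracle_xyz_to_lms(oracle_lab_to_xyz(c(25, 0, 0))) /
    oracle_xyz_to_lms(oracle_lab_to_xyz(ill_pt))
  expect_equal(unname(coefficients_at_lightness(loc, 25)), k_ill, tolerance = 1e-9)
})

test_that("lightness below the floor is clamped with a warning", {
  loc <- achromatic_locus(-5, -10)
  expect_warning(k <- coefficients_at_lightness(loc, 0.2), "clamped")
  expect_equal(unname(k), unname(coefficients_at_lightness(loc, 1)))
})

test_that("the interpolating lookup table stays within 1e-3 delta E of exact coefficients", {
  loc <- achromatic_locus(-10, -30)
  lut <- coefficients_lut(loc, L_range = c(5, 100))  # gamut-valid range for this locus
  withr::with_seed(5, {
    L <- runif(200, 5, 99)
    k_lut <- lut(L)
    k_exact <- coefficients_at_lightness(loc, L)
    # propagate through the transform of the locus point and compare in Lab
    for (i in seq(1, 200, by = 10)) {
      lms <- xyz_to_lms(lab_d65_to_xyz(c(L[i], -10, -30)))
      lab_lut <- xyz_to_lab_d65(lms_to_xyz(lms * k_lut[i, ]))
      lab_ex <- xyz_to_lab_d65(lms_to_xyz(lms * k_exact[i, ]))
      expect_lt(delta_e_lab(lab_lut, lab_ex), 1e-3)
    }
  })
})
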