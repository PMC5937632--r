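test_that("a uniform image fills exactly one histogram cell", {
  img <- lab_image(matrix(40, 4, 4), matrix(3.1, 4, 4), matrix(-7.2, 4, 4))
  h <- histogram2d(img, "ab")
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(sum(h$counts), 16L)
})

test_that("a two-color image straddling a bin edge fills two cells that conserve pixels", {
  img <- lab_image(matrix(50, 2, 2), matrix(c(2.4, 2.4, 2.6, 2.6), 2, 2),
                   matrix(0, 2, 2))
  h <- histogram2d(img, "ab", bin_size = 2.5)
  expect_equal(sum(h$counts > 0), 2L)
  expect_equal(sum(h$counts), 4L)
})

test_that("binning equals a brute-force per-pixel loop on random images", {
  withr::with_seed(97, {
    for (rep in 1:3) {
      img <- random_lab_image(25, 40, seed = 300 + rep)  # 1,000 pixels
      for (plane in c("ab", "bL")) {
        h <- histogram2d(img, plane)
        px <- cbind(as.vector(img$L), as.vector(img$a), as.vector(img$b))
        xy <- if (plane == "ab") px[, c(2, 3)] else px[, c(3, 1)]
        expect_identical(h$counts, oracle_hist2d(xy, 2.5))
        expect_equal(sum(h$counts), 1000L)
      }
    }
  })
})

test_that("excluded pixels are omitted from the histogram", {
  img <- random_lab_image(10, 10, seed = 5)
  excl <- matrix(FALSE, 10, 10); excl[1:3, ] <- TRUE
  h <- histogram2d(img, "ab", exclude = excl)
  expect_equal(sum(h$counts), 70L)
})

test_that("modal points find two well-separated blobs, heavier first", {
  # blob 1: 30 px at (b, L) = (0, 20); blob 2: 20 px at (0, 70)
  L <- matrix(c(rep(20, 30), rep(70, 20)), 1)
  img <- lab_image(L, matrix(0, 1, 50), matrix(0, 1, 50))
  mp <- modal_points(histogram2d(img, "bL"))
  expect_equal(mp$mode1, c(1.25, 21.25))
  expect_equal(mp$mode2, c(1.25, 71.25))
  expect_gte(mp$pop1, mp$pop2)
  ct <- contrast_bl(img)
  expect_equal(ct$distance, 50)
  expect_equal(ct$nonzero_cells, 2L)
})

test_that("a single broad blob is rejected as unimodal", {
  withr::with_seed(13, {
    img <- lab_image(matrix(rnorm(100, 50, 1), 10, 10),
                     matrix(rnorm(100, 0, 1), 10, 10),
                     matrix(rnorm(100, 0, 1), 10, 10))
  })
  expect_error(modal_points(histogram2d(img, "bL")), "unimodal")
})

test_that("the b*-L* contrast is preserved under an identity transform", {
  f <- study_fixture()
  img <- f$scene$image
  out <- simulate_appearance(img, illuminant_estimate(0, 0), appearance_config())
  c1 <- contrast_bl(img, exclude = "background")
  c2 <- contrast_bl(out, exclude = "background")
  expect_equal(c2$distance, c1$distance)
  expect_equal(c2$nonzero_cells, c1$nonzero_cells)
})

test_that("3D modal points recover the generating surface clusters of a scene", {
  sc <- scene_spec(noise_sd = 0.5)
  scn <- render_scene(sc, illuminant_estimate(0, 0))  # neutral: image = surfaces
  mp <- part_modes_lab(scn$image, exclude = "background")
  # within one bin (2.5) of the generating colors (surface + intensity
  # offset in L*) per coordinate
  off <- c(sc$intensity_offset, 0, 0)
  expect_true(all(abs(mp["body", ] - (sc$body_color + off)) <= 2.5))
  expect_true(all(abs(mp["lace", ] - (sc$lace_color + off)) <= 2.5))
})

test_that("matches convert through display primaries, with an sRGB fallback warning", {
  rec <- list(R = 1, G = 1, B = 1)
  expect_warning(lab <- match_to_lab(rec), "sRGB")
  expect_equal(unname(lab), c(100, 0, 0), tolerance = 1e-9)
  expect_equal(unname(match_to_lab(rec, "srgb")), c(100, 0, 0), tolerance = 1e-9)
  # linear wide-gamut display metadata round trip
  prim <- list(matrix = diag(c(200, 200, 400)), gamma = 1)
  lab0 <- c(40, 10, -30)
  xyz <- lab_d65_to_xyz(lab0)
  rec2 <- list(R = xyz[1] / 200, G = xyz[2] / 200, B = xyz[3] / 400)
  expect_equal(unname(match_to_lab(rec2, prim)), lab0, tolerance = 1e-9)
  # scalar-oracle agreement for an arbitrary sRGB record
  rec3 <- list(R = 0.3, G = 0.55, B = 0.8)
  expect_equal(unname(match_to_lab(rec3, "srgb")),
               oracle_xyz_to_lab(oracle_srgb_to_xyz(c(0.3, 0.55, 0.8))),
               tolerance = 1e-9)
  # explicit appearance-space fields take precedence
  expect_equal(unname(match_to_lab(list(L = 12, a = -80, b = 4))), c(12, -80, 4))
})

test_that("matches placed exactly at a render's modal points select that render", {
  f <- study_fixture()
  for (lb in c("A-1", "D-4", "F-6")) {
    m <- make_synthetic_matches(f$renders, lb, jitter_de = 0, n_subjects = 1)
    sel <- find_optimal_variant(f$renders, m, m$type[1], modes = f$modes)
    expect_equal(sel, lb)
  }
})

test_that("ties are broken by grid order", {
  f <- study_fixture()
  img <- f$scene$image
  same <- lapply(1:4, function(i) img)
  names(same) <- c("A-1", "B-1", "A-2", "B-2")
  m <- data.frame(subject_id = 1, part = c("body", "lace"),
                  R = NA, G = NA, B = NA,
                  L = c(50, 20), a = c(0, 0), b = c(-20, 10),
                  type = "white/gold")
  expect_equal(find_optimal_variant(same, m, "white/gold"), "A-1")
})

test_that("the optimal variant has the smallest achromatic residual by construction", {
  f <- study_fixture()
  m <- make_synthetic_matches(f$renders, "C-3", jitter_de = 6, n_subjects = 3, seed = 9)
  rr <- residual_report(f$renders, m, n_boot = 200, seed = 4)
  R <- rr$residual_matrices$achromatic
  for (s in seq_len(nrow(R))) {
    opt_label <- rr$per_subject$optimal[s]
    expect_equal(R[s, opt_label], min(R[s, ]))
  }
})

test_that("hand-placed matches give hand-computable residuals", {
  f <- study_fixture()
  modes_d4 <- f$modes[["D-4"]]
  # white/gold subject: body match 3 units above the body mode in L*,
  # lace match 4 units off in b* -> residuals exactly 3 and 4
  m <- data.frame(subject_id = c(1, 1, 2, 2),
                  part = c("body", "lace", "body", "lace"),
                  R = NA, G = NA, B = NA,
                  L = c(modes_d4["body", 1] + 3, modes_d4["lace", 1],
                        f$modes[["B-2"]]["body", 1], f$modes[["B-2"]]["lace", 1]),
                  a = c(modes_d4["body", 2], modes_d4["lace", 2],
                        f$modes[["B-2"]]["body", 2], f$modes[["B-2"]]["lace", 2] + 5),
                  b = c(modes_d4["body", 3], modes_d4["lace", 3] + 4,
                        f$modes[["B-2"]]["body", 3], f$modes[["B-2"]]["lace", 3]),
                  type = "white/gold")
  rr <- residual_report(f$renders, m, n_boot = 200, seed = 4)
  ps <- rr$per_subject
  expect_equal(ps$optimal, c("D-4", "B-2"))
  expect_equal(ps$achromatic_de, c(3, 0), tolerance = 1e-9)
  expect_equal(ps$chromatic_de, c(4, 5), tolerance = 1e-9)
  expect_equal(rr$stats$chromatic_mean[rr$stats$group == "all"], 4.5)
  expect_equal(rr$stats$chromatic_sem[rr$stats$group == "all"],
               sd(c(4, 5)) / sqrt(2))
})

test_that("the residual report is deterministic under a fixed seed", {
  f <- study_fixture()
  m <- make_synthetic_matches(f$renders, "E-5", jitter_de = 3, n_subjects = 4, seed = 2)
  r1 <- residual_report(f$renders, m, n_boot = 500, seed = 77)
  r2 <- residual_report(f$renders, m, n_boot = 500, seed = 77)
  expect_identical(r1$bootstrap, r2$bootstrap)
  expect_identical(r1$per_subject, r2$per_subject)
  expect_warning(residual_report(f$renders, m, n_boot = 50, seed = 1), "unreliable")
})

test_that("the bootstrap reference cannot beat the optimal selection on the achromatic part", {
  f <- study_fixture()
  m <- make_synthetic_matches(f$renders, "B-6", jitter_de = 3, n_subjects = 5, seed = 31)
  rr <- residual_report(f$renders, m, n_boot = 1000, seed = 8)
  opt_ach <- rr$stats$achromatic_mean[rr$stats$group == "all"]
  expect_gte(rr$bootstrap$achromatic_mean, opt_ach)
  expect_lte(rr$bootstrap$achromatic_ci[1], rr$bootstrap$achromatic_mean)
  expect_lte(rr$bootstrap$chromatic_ci[1], rr$bootstrap$chromatic_mean)
  expect_lte(rr$bootstrap$chromatic_mean, rr$bootstrap$chromatic_ci[2])
})

test_that("matching CSVs round-trip with primaries sidecar", {
  f <- study_fixture()
  m <- make_synthetic_matches(f$renders, "D-4", jitter_de = 2, n_subjects = 2, seed = 3)
  path <- file.path(tempdir(), "matches.csv")
  utils::write.csv(m[, c("subject_id", "part", "R", "G", "B", "type")], path,
                   row.names = FALSE)
  prim <- attr(m, "primaries")
  jsonlite::write_json(list(matrix = as.vector(t(prim$matrix)), gamma = prim$gamma),
                       file.path(tempdir(), "matches.json"), auto_unbox = TRUE)
  back <- read_matches_csv(path)
  expect_equal(nrow(back), 4L)
  expect_equal(attr(back, "primaries")$matrix, prim$matrix)
  lab_back <- match_to_lab(back[1, ], attr(back, "primaries"))
  # the CSV record is the gamut-clipped display encoding of the match
  expect_equal(unname(lab_back),
               unname(xyz_to_lab_d65(pmax(lab_d65_to_xyz(attr(m, "lab")[1, ]), 0))),
               tolerance = 1e-6)
})
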