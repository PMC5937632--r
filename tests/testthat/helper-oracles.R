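# Independent scalar oracles: formula-by-formula, loop-based implementations
# of the colorimetric standards, written separately from the package's
# vectorized code paths so the two can be compared.

oracle_srgb_matrix <- local({
  # linear RGB -> XYZ from the sRGB primary chromaticities, D65 white
  prim <- list(r = c(0.64, 0.33), g = c(0.30, 0.60), b = c(0.15, 0.06))
  white <- c(0.95047, 1, 1.08883)
  P <- matrix(0, 3, 3)
  for (j in 1:3) {
    xy <- prim[[j]]
    P[, j] <- c(xy[1] / xy[2], 1, (1 - xy[1] - xy[2]) / xy[2])
  }
  P %*% diag(as.vector(solve(P) %*% white))
})

oracle_srgb_to_xyz <- function(rgb) {
  lin <- numeric(3)
  for (i in 1:3) {
    u <- rgb[i]
    lin[i] <- if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  out <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) s <- s + oracle_srgb_matrix[i, j] * lin[j]
    out[i] <- 100 * s
  }
  out
}

oracle_f <- function(t) {
  d <- 6 / 29
  if (t > d^3) t^(1 / 3) else t / (3 * d^2) + 4 / 29
}

oracle_f_inv <- function(u) {
  d <- 6 / 29
  if (u > d) u^3 else 3 * d^2 * (u - 4 / 29)
}

oracle_xyz_to_lab <- function(xyz) {
  wn <- c(95.047, 100, 108.883)
  fx <- oracle_f(xyz[1] / wn[1])
  fy <- oracle_f(xyz[2] / wn[2])
  fz <- oracle_f(xyz[3] / wn[3])
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

oracle_lab_to_xyz <- function(lab) {
  wn <- c(95.047, 100, 108.883)
  fy <- (lab[1] + 16) / 116
  fx <- fy + lab[2] / 500
  fz <- fy - lab[3] / 200
  c(wn[1] * oracle_f_inv(fx), wn[2] * oracle_f_inv(fy), wn[3] * oracle_f_inv(fz))
}

oracle_hpe <- rbind(c(0.38971, 0.68898, -0.07868),
                    c(-0.22981, 1.18340, 0.04641),
                    c(0, 0, 1))
oracle_hpe_white <- as.vector(oracle_hpe %*% c(95.047, 100, 108.883))

oracle_xyz_to_lms <- function(xyz) {
  out <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) s <- s + oracle_hpe[i, j] * xyz[j]
    out[i] <- s / oracle_hpe_white[i]
  }
  out
}

oracle_lms_to_xyz <- function(lms) {
  m <- solve(oracle_hpe / oracle_hpe_white)
  out <- numeric(3)
  for (i in 1:3) {
    s <- 0
    for (j in 1:3) s <- s + m[i, j] * lms[j]
    out[i] <- s
  }
  out
}

# Per-pixel scalar oracle for the iso-lightness chromatic shift (Step 2).
oracle_chromatic_shift <- function(lab, a0, b0) {
  L <- max(lab[1], 1)
  k <- oracle_xyz_to_lms(oracle_lab_to_xyz(c(L, 0, 0))) /
    oracle_xyz_to_lms(oracle_lab_to_xyz(c(L, a0, b0)))
  lms <- oracle_xyz_to_lms(oracle_lab_to_xyz(lab)) * k
  xyz <- oracle_lms_to_xyz(lms)
  xyz[xyz < 0] <- 0
  out <- oracle_xyz_to_lab(xyz)
  out[1] <- lab[1]
  out
}

# Brute-force 2D binning loop.
oracle_hist2d <- function(xy, bin_size, origin = 0) {
  ix <- integer(nrow(xy)); iy <- integer(nrow(xy))
  for (i in seq_len(nrow(xy))) {
    ix[i] <- floor((xy[i, 1] - origin) / bin_size)
    iy[i] <- floor((xy[i, 2] - origin) / bin_size)
  }
  xr <- range(ix); yr <- range(iy)
  counts <- matrix(0L, xr[2] - xr[1] + 1L, yr[2] - yr[1] + 1L)
  for (i in seq_len(nrow(xy))) {
    counts[ix[i] - xr[1] + 1L, iy[i] - yr[1] + 1L] <-
      counts[ix[i] - xr[1] + 1L, iy[i] - yr[1] + 1L] + 1L
  }
  counts
}

# Random in-gamut Lab image.
random_lab_image <- function(h, w, seed, L_range = c(5, 95), ab_range = c(-30, 30)) {
  withr::with_seed(seed, {
    lab_image(matrix(runif(h * w, L_range[1], L_range[2]), h, w),
              matrix(runif(h * w, ab_range[1], ab_range[2]), h, w),
              matrix(runif(h * w, ab_range[1], ab_range[2]), h, w))
  })
}

# The synthetic study fixture shared by the evaluation tests: the default
# dress-like scene rendered under the white/gold-extreme illuminant, with the
# default 7 x 7 variant grid.
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ep <- default_grid_endpoints()
      scn <- render_scene(scene_spec(), ep$wg)
      grid <- make_variant_grid(ep$wg, ep$bb, 7)
      renders <- render_grid(scn$image, grid, appearance_config())
      cache <<- list(scene = scn, grid = grid, renders = renders,
                     modes = achrosim:::variant_part_modes(renders))
    }
    cache
  }
})
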