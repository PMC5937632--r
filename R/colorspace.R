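# Colorimetric conversions: sRGB <-> XYZ <-> CIELAB(D65) and XYZ <-> LMS.
#
# All conversions work on the scale where the D65 reference white has
# Y = 100 (the appearance space is CIELAB normalized to D65 at 100 cd/m^2).
# Inputs may be a single color (length-3 vector) or an n x 3 matrix with one
# color per row; the output mirrors the input shape.

# D65 reference white, tristimulus on the Y = 100 scale.
WHITE_D65 <- c(X = 95.047, Y = 100, Z = 108.883)

# sRGB primaries (IEC 61966-2-1 chromaticities). The linear-RGB -> XYZ matrix
# is derived from these so that RGB (1,1,1) maps *exactly* onto WHITE_D65,
# keeping the encoding consistent with the Lab normalization above.
.srgb_matrix <- local({
  xy <- rbind(r = c(0.64, 0.33), g = c(0.30, 0.60), b = c(0.15, 0.06))
  P <- apply(xy, 1L, function(p) c(p[1] / p[2], 1, (1 - p[1] - p[2]) / p[2]))
  s <- solve(P, WHITE_D65 / 100)
  P %*% diag(s)   # columns: r, g, b contributions; white sums to D65/100
})
.srgb_matrix_inv <- solve(.srgb_matrix)

# Hunt-Pointer-Estevez cone matrix, row-normalized so that the D65 white has
# cone excitations (1, 1, 1); the classic von Kries substrate.
.hpe <- rbind(c(0.38971, 0.68898, -0.07868),
              c(-0.22981, 1.18340, 0.04641),
              c(0, 0, 1))
.lms_matrix <- .hpe / as.vector(.hpe %*% WHITE_D65)
.lms_matrix_inv <- solve(.lms_matrix)

# CIELAB linear-segment constant.
.lab_delta <- 6 / 29

.as_color_matrix <- function(x, name) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop(sprintf("'%s' must be a length-3 vector or an n x 3 matrix", name),
           call. = FALSE)
    }
    matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) {
      stop(sprintf("'%s' must have 3 columns", name), call. = FALSE)
    }
    storage.mode(x) <- "double"
    x
  }
}

.restore_shape <- function(out, template) {
  if (is.null(dim(template))) drop(out) else out
}

#' Convert nonlinear sRGB to XYZ tristimulus values
#'
#' Applies the IEC 61966-2-1 piecewise gamma decoding followed by the fixed
#' linear-RGB to XYZ primary matrix. The matrix is derived from the sRGB
#' primary chromaticities with the D65 white fixed at (95.047, 100, 108.883),
#' so (1, 1, 1) maps exactly onto the reference white.
#'
#' @param rgb length-3 vector or n x 3 matrix of sRGB components in [0, 1].
#' @return XYZ values (same shape as input) on the Y = 100 scale.
#' @export
srgb_to_xyz <- function(rgb) {
  m <- .as_color_matrix(rgb, "rgb")
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("sRGB components must lie in [0, 1]", call. = FALSE)
  }
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  out <- lin %*% t(.srgb_matrix) * 100
  colnames(out) <- c("X", "Y", "Z")
  .restore_shape(out, rgb)
}

#' Convert XYZ tristimulus values to nonlinear sRGB
#'
#' Inverse of [srgb_to_xyz()]. Out-of-gamut components are clipped to [0, 1];
#' the number of clipped components is attached as attribute `"n_clipped"`.
#'
#' @param xyz XYZ on the Y = 100 scale (length-3 vector or n x 3 matrix).
#' @return sRGB components in [0, 1], with attribute `n_clipped`.
#' @export
xyz_to_srgb <- function(xyz) {
  m <- .as_color_matrix(xyz, "xyz")
  lin <- (m / 100) %*% t(.srgb_matrix_inv)
  n_clip <- sum(lin < 0 | lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  out <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- c("R", "G", "B")
  out <- .restore_shape(out, xyz)
  attr(out, "n_clipped") <- n_clip
  out
}

.lab_f <- function(t) {
  ifelse(t > .lab_delta^3, t^(1 / 3), t / (3 * .lab_delta^2) + 4 / 29)
}

.lab_f_inv <- function(u) {
  ifelse(u > .lab_delta, u^3, 3 * .lab_delta^2 * (u - 4 / 29))
}

#' Convert XYZ to CIELAB normalized to D65
#'
#' Standard CIE 1976 L*a*b* with the (6/29) linear-segment formulation and the
#' white normalization fixed to D65 at Y = 100. This space is used for all
#' appearance computations regardless of the scene illuminant.
#'
#' @param xyz XYZ on the Y = 100 scale; all components must be non-negative.
#' @return Lab values, same shape as input.
#' @export
xyz_to_lab_d65 <- function(xyz) {
  m <- .as_color_matrix(xyz, "xyz")
  if (anyNA(m) || any(m < 0)) {
    stop("tristimulus values must be finite and non-negative", call. = FALSE)
  }
  fx <- .lab_f(m[, 1] / WHITE_D65[1])
  fy <- .lab_f(m[, 2] / WHITE_D65[2])
  fz <- .lab_f(m[, 3] / WHITE_D65[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  .restore_shape(out, xyz)
}

#' Convert CIELAB (D65-normalized) to XYZ
#'
#' Exact closed-form inverse of [xyz_to_lab_d65()] on its range. Accepts any
#' finite (L, a, b); lightness values produced by shifts may exceed the
#' nominal 0-100 range and are inverted with the same formulas.
#'
#' @param lab Lab values (length-3 vector or n x 3 matrix).
#' @return XYZ on the Y = 100 scale, same shape as input.
#' @export
lab_d65_to_xyz <- function(lab) {
  m <- .as_color_matrix(lab, "lab")
  if (anyNA(m) || any(!is.finite(m))) {
    stop("Lab values must be finite", call. = FALSE)
  }
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  out <- cbind(X = WHITE_D65[1] * .lab_f_inv(fx),
               Y = WHITE_D65[2] * .lab_f_inv(fy),
               Z = WHITE_D65[3] * .lab_f_inv(fz))
  .restore_shape(out, lab)
}

#' Convert XYZ to cone excitations (LMS)
#'
#' Linear map through the Hunt-Pointer-Estevez matrix row-normalized to D65,
#' so the reference white has cone excitations (1, 1, 1). This is the space in
#' which von Kries gains act.
#'
#' @param xyz XYZ on the Y = 100 scale.
#' @return LMS values, same shape as input.
#' @export
xyz_to_lms <- function(xyz) {
  m <- .as_color_matrix(xyz, "xyz")
  out <- m %*% t(.lms_matrix)
  colnames(out) <- c("Lc", "Mc", "Sc")
  .restore_shape(out, xyz)
}

#' Convert cone excitations (LMS) back to XYZ
#'
#' Exact inverse of [xyz_to_lms()].
#'
#' @param lms LMS values (length-3 vector or n x 3 matrix).
#' @return XYZ on the Y = 100 scale, same shape as input.
#' @export
lms_to_xyz <- function(lms) {
  m <- .as_color_matrix(lms, "lms")
  out <- m %*% t(.lms_matrix_inv)
  colnames(out) <- c("X", "Y", "Z")
  .restore_shape(out, lms)
}

#' Euclidean color difference in CIELAB
#'
#' Plain Euclidean distance in (L*, a*, b*) -- the residual-error metric used
#' throughout the evaluation machinery. No CIEDE2000-style weighting.
#'
#' @param p,q Lab values (length-3 vectors or n x 3 matrices, recycled rowwise
#'   if one side is a single color).
#' @return non-negative scalar or vector of distances.
#' @export
delta_e_lab <- function(p, q) {
  pm <- .as_color_matrix(p, "p")
  qm <- .as_color_matrix(q, "q")
  if (nrow(pm) == 1L && nrow(qm) > 1L) pm <- pm[rep(1L, nrow(qm)), , drop = FALSE]
  if (nrow(qm) == 1L && nrow(pm) > 1L) qm <- qm[rep(1L, nrow(pm)), , drop = FALSE]
  d <- sqrt(rowSums((pm - qm)^2))
  if (is.null(dim(p)) && is.null(dim(q))) unname(d[1]) else unname(d)
}

#' Convert sRGB directly to CIELAB (D65)
#'
#' Convenience composition of [srgb_to_xyz()] and [xyz_to_lab_d65()].
#'
#' @inheritParams srgb_to_xyz
#' @return Lab values, same shape as input.
#' @export
srgb_to_lab_d65 <- function(rgb) xyz_to_lab_d65(srgb_to_xyz(rgb))

#' Convert CIELAB (D65) directly to sRGB
#'
#' Convenience composition of [lab_d65_to_xyz()] and [xyz_to_srgb()]; carries
#' the `n_clipped` attribute of the gamut clip.
#'
#' @inheritParams lab_d65_to_xyz
#' @return sRGB components in [0, 1].
#' @export
lab_d65_to_srgb <- function(lab) xyz_to_srgb(lab_d65_to_xyz(lab))
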