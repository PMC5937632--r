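# Step 1: the achromatic-point locus and the lightness-dependent von Kries
# coefficients derived from it.
#
# The locus of achromatic points under a chromatic illuminant is approximated
# as a straight line parallel to the lightness axis of D65-normalized CIELAB:
# every lightness L has its achromatic point at (L, a0, b0). The line crosses
# the (oblique) illuminant-chromaticity locus at L = L_base.

# Below this lightness the Lab -> XYZ inversion is numerically degenerate;
# coefficients for darker pixels reuse the L_MIN values.
L_MIN <- 1

#' Construct an achromatic-point locus
#'
#' @param a0,b0 constant chromatic offset of the locus from the lightness axis.
#' @param L_base lightness at which the locus crosses the illuminant-
#'   chromaticity locus (default 25).
#' @return object of class `achromatic_locus`.
#' @export
achromatic_locus <- function(a0, b0, L_base = 25) {
  stopifnot(is.finite(a0), is.finite(b0), is.finite(L_base))
  if (L_base <= 0 || L_base > 100) {
    stop("L_base must lie in (0, 100]", call. = FALSE)
  }
  structure(list(a0 = unname(a0), b0 = unname(b0), L_base = unname(L_base)),
            class = "achromatic_locus")
}

#' @export
print.achromatic_locus <- function(x, ...) {
  cat(sprintf("<achromatic_locus> offset (a0*, b0*) = (%.3f, %.3f), L*_base = %g\n",
              x$a0, x$b0, x$L_base))
  invisible(x)
}

#' Point on the achromatic locus at a given lightness
#'
#' The parallel-line approximation: the achromatic point at lightness L is
#' simply (L, a0, b0).
#'
#' @param locus an [achromatic_locus()].
#' @param L lightness value(s), > 0.
#' @return Lab triplet (or n x 3 matrix for vector `L`).
#' @export
locus_point <- function(locus, L) {
  stopifnot(inherits(locus, "achromatic_locus"), all(L > 0))
  out <- cbind(L = L, a = rep(locus$a0, length(L)), b = rep(locus$b0, length(L)))
  if (length(L) == 1L) drop(out) else out
}

#' Estimate the achromatic locus from an image region
#'
#' The region's mean CIE xy chromaticity (luminance-free, so bright and dim
#' renderings of the same surface agree) is re-rendered at the luminance
#' corresponding to L* = L_base and converted to Lab; its (a*, b*) become the
#' locus offset. Alternatively (`method = "ab"`), the region's mean (a*, b*)
#' is used directly.
#'
#' @param image a [lab_image()].
#' @param region mask name or logical matrix.
#' @param L_base lightness of the crossing point (default 25).
#' @param method `"xy"` (default; mean chromaticity re-rendered at L_base) or
#'   `"ab"` (mean a*b* of the region's pixels).
#' @return an [achromatic_locus()].
#' @export
estimate_locus_from_region <- function(image, region, L_base = 25,
                                       method = c("xy", "ab")) {
  method <- match.arg(method)
  mask <- resolve_mask(image, region)
  if (!any(mask)) stop("region mask is empty", call. = FALSE)
  px <- lab_pixels(image)[as.vector(mask), , drop = FALSE]
  if (method == "ab") {
    return(achromatic_locus(mean(px[, 2]), mean(px[, 3]), L_base))
  }
  xyz <- lab_d65_to_xyz(px)
  s <- rowSums(xyz)
  keep <- xyz[, 2] > 0 & s > 0
  if (!any(keep)) stop("region contains only zero-luminance pixels", call. = FALSE)
  x <- mean(xyz[keep, 1] / s[keep])
  y <- mean(xyz[keep, 2] / s[keep])
  Y_base <- 100 * .lab_f_inv((L_base + 16) / 116)
  xyz_base <- c(x / y * Y_base, Y_base, (1 - x - y) / y * Y_base)
  lab <- xyz_to_lab_d65(xyz_base)
  achromatic_locus(lab[2], lab[3], L_base)
}

#' Lightness-dependent von Kries coefficients
#'
#' For each lightness L, the gains that map the cone excitations of the locus
#' point (L, a0, b0) onto those of the neutral axis point (L, 0, 0):
#' k = LMS(L, 0, 0) / LMS(L, a0, b0), componentwise. Applying k to the locus
#' point and restoring its lightness yields exactly (L, 0, 0) -- the defining
#' nulling property. Lightness below `L_MIN` (= 1) is clamped with a warning.
#'
#' @param locus an [achromatic_locus()].
#' @param L lightness value(s).
#' @return for scalar `L` a named gain triplet (kL, kM, kS); for vector `L` an
#'   n x 3 matrix of gains.
#' @export
coefficients_at_lightness <- function(locus, L) {
  stopifnot(inherits(locus, "achromatic_locus"), all(is.finite(L)))
  if (any(L < L_MIN)) {
    warning(sprintf("%d lightness value(s) below %g clamped for coefficient computation",
                    sum(L < L_MIN), L_MIN))
    L <- pmax(L, L_MIN)
  }
  n <- length(L)
  lms_neutral <- xyz_to_lms(lab_d65_to_xyz(cbind(L, 0, 0)))
  lms_locus <- xyz_to_lms(lab_d65_to_xyz(cbind(L, locus$a0, locus$b0)))
  if (n == 1L) {
    lms_neutral <- rbind(lms_neutral); lms_locus <- rbind(lms_locus)
  }
  if (any(lms_locus <= 0)) {
    stop("locus point has non-positive cone response (locus outside the spectral gamut)",
         call. = FALSE)
  }
  k <- lms_neutral / lms_locus
  colnames(k) <- c("kL", "kM", "kS")
  if (n == 1L) drop(k) else k
}

#' Tabulated von Kries coefficients with linear interpolation
#'
#' Builds a lookup table of [coefficients_at_lightness()] and returns a
#' function interpolating it linearly; a speed convenience whose
#' approximation error stays below 1e-3 Delta-E for the default 512 levels
#' even for strongly chromatic loci. The locus must stay inside the
#' cone-response gamut over `L_range`.
#'
#' @param locus an [achromatic_locus()].
#' @param levels number of table rows (default 512).
#' @param L_range lightness range covered (default c(1, 100)).
#' @return function mapping a lightness vector to an n x 3 gain matrix.
#' @export
coefficients_lut <- function(locus, levels = 512L, L_range = c(L_MIN, 100)) {
  grid <- seq(L_range[1], L_range[2], length.out = levels)
  tab <- coefficients_at_lightness(locus, grid)
  function(L) {
    L <- pmin(pmax(L, L_range[1]), L_range[2])
    cbind(kL = stats::approx(grid, tab[, 1], L)$y,
          kM = stats::approx(grid, tab[, 2], L)$y,
          kS = stats::approx(grid, tab[, 3], L)$y)
  }
}
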