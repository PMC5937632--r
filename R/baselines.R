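# Lightness-invariant von Kries baseline: one gain triplet, derived at a
# single reference lightness, applied to every pixel. This is the coefficient
# policy shared by the classic appearance-model family (CIECAM02, RLAB use a
# single set of von Kries coefficients); comparing it against the proposed
# lightness-dependent policy isolates the effect of the coefficient rule.

#' Flat (lightness-invariant) von Kries transform
#'
#' Derives the von Kries gains once, at `reference_L` on the given locus, and
#' applies that single triplet to every pixel regardless of its own L*. The
#' iso-lightness constraint (L* restored after the cone-space scaling) is
#' enforced exactly as in [apply_chromatic_shift()], so any output difference
#' is attributable to the coefficient policy alone. At pixels with
#' L* = reference_L the two policies agree exactly.
#'
#' @param image a [lab_image()].
#' @param locus an [achromatic_locus()].
#' @param reference_L lightness at which the single gain triplet is derived
#'   (default: the locus's L_base, i.e. 25; appearance models more commonly
#'   normalize at white, `reference_L = 100`).
#' @param exclude optional mask of pixels to pass through unchanged.
#' @return transformed [lab_image()]; attribute `"coefficients"` holds the
#'   gain triplet used.
#' @export
flat_von_kries <- function(image, locus, reference_L = locus$L_base,
                           exclude = NULL) {
  stopifnot(inherits(image, "lab_image"), inherits(locus, "achromatic_locus"))
  if (reference_L <= 0 || reference_L > 100) {
    stop("reference_L must lie in (0, 100]", call. = FALSE)
  }
  k <- coefficients_at_lightness(locus, reference_L)
  if (locus$a0 == 0 && locus$b0 == 0) {
    out <- image
    attr(out, "coefficients") <- k
    return(out)
  }
  excl <- resolve_mask(image, exclude, allow_null = TRUE)
  px <- lab_pixels(image)
  sel <- if (is.null(excl)) rep(TRUE, nrow(px)) else !as.vector(excl)
  p <- px[sel, , drop = FALSE]
  lms <- xyz_to_lms(lab_d65_to_xyz(p))
  lms <- sweep(lms, 2L, k, `*`)
  out <- xyz_to_lab_d65(pmax(lms_to_xyz(lms), 0))
  if (is.null(dim(out))) out <- rbind(out)
  out[, 1] <- p[, 1]
  px[sel, ] <- out
  res <- lab_from_pixels(px, image)
  attr(res, "coefficients") <- k
  res
}
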