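# Steps 2 and 3 of the appearance simulation:
#   Step 2 -- iso-lightness chromatic shift: per pixel, von Kries gains derived
#             at that pixel's own L* null the achromatic locus onto the
#             lightness axis; the pixel's L* is then restored exactly.
#   Step 3 -- a single additive L* shift anchoring a region's mean lightness
#             to a target (e.g. body appears white, or lace appears black).

#' Appearance-simulation configuration
#'
#' @param L_base lightness at which the achromatic locus crosses the
#'   illuminant-chromaticity locus (default 25).
#' @param anchor_region mask name whose mean L* is driven to the anchor target
#'   in Step 3 (default "body").
#' @param anchor_target_L default lightness target for Step 3 when the
#'   illuminant estimate does not carry one; `NA` disables the lightness shift.
#' @param exclude_background if `TRUE` (default), pixels in the `background`
#'   mask pass through both steps unchanged (the high-intensity background is
#'   not part of the appearance simulation).
#' @param background_region name of the background mask (default "background").
#' @return object of class `appearance_config`.
#' @export
appearance_config <- function(L_base = 25, anchor_region = "body",
                              anchor_target_L = NA_real_,
                              exclude_background = TRUE,
                              background_region = "background") {
  if (!is.na(anchor_target_L) && (anchor_target_L < 0 || anchor_target_L > 100)) {
    stop("anchor_target_L must lie in [0, 100]", call. = FALSE)
  }
  structure(list(L_base = L_base, anchor_region = anchor_region,
                 anchor_target_L = anchor_target_L,
                 exclude_background = exclude_background,
                 background_region = background_region),
            class = "appearance_config")
}

.background_mask <- function(image, config) {
  if (!config$exclude_background) return(NULL)
  if (is.na(match(config$background_region, names(image$masks)))) return(NULL)
  image$masks[[config$background_region]]
}

#' Apply the iso-lightness chromatic shift (Step 2)
#'
#' Each pixel is taken to cone space, scaled by the von Kries coefficients
#' derived for its own lightness from the achromatic locus, taken back to Lab,
#' and its original L* restored exactly (the iso-lightness constraint). A
#' pixel lying on the locus maps onto the neutral axis.
#'
#' @param image a [lab_image()].
#' @param locus an [achromatic_locus()].
#' @param exclude optional mask (name or logical matrix) of pixels to pass
#'   through unchanged, typically the bright background.
#' @return transformed [lab_image()]; the L* channel is bit-identical to the
#'   input.
#' @export
apply_chromatic_shift <- function(image, locus, exclude = NULL) {
  stopifnot(inherits(image, "lab_image"), inherits(locus, "achromatic_locus"))
  if (locus$a0 == 0 && locus$b0 == 0) return(image)  # identity illuminant
  excl <- resolve_mask(image, exclude, allow_null = TRUE)
  px <- lab_pixels(image)
  sel <- if (is.null(excl)) rep(TRUE, nrow(px)) else !as.vector(excl)
  p <- px[sel, , drop = FALSE]
  k <- coefficients_at_lightness(locus, p[, 1])
  if (is.null(dim(k))) k <- rbind(k)
  lms <- xyz_to_lms(lab_d65_to_xyz(p)) * k
  out <- xyz_to_lab_d65(pmax(lms_to_xyz(lms), 0))
  if (is.null(dim(out))) out <- rbind(out)
  out[, 1] <- p[, 1]  # restore L* exactly
  px[sel, ] <- out
  lab_from_pixels(px, image)
}

#' Apply the anchored lightness shift (Step 3)
#'
#' Computes Delta-L = target_L - mean(L* over the anchor region) and adds it
#' to every pixel's L* (optionally excluding the background), then clamps to
#' [0, 100]. Chromatic coordinates are untouched. The applied shift and the
#' clip count are attached as attributes `"delta_L"` and `"n_clipped"`.
#'
#' @param image a [lab_image()].
#' @param region anchor mask (name or logical matrix); must be non-empty.
#' @param target_L lightness the anchor region's mean is driven to.
#' @param exclude optional mask of pixels left unshifted.
#' @return shifted [lab_image()] with attributes `delta_L`, `n_clipped`.
#' @export
apply_lightness_shift <- function(image, region, target_L, exclude = NULL) {
  stopifnot(inherits(image, "lab_image"), is.finite(target_L))
  mask <- resolve_mask(image, region)
  if (!any(mask)) stop("anchor region is empty", call. = FALSE)
  excl <- resolve_mask(image, exclude, allow_null = TRUE)
  delta <- target_L - mean(image$L[mask])
  L <- image$L
  sel <- if (is.null(excl)) rep(TRUE, length(L)) else !as.vector(excl)
  shifted <- L
  shifted[sel] <- L[sel] + delta
  n_clip <- sum(shifted[sel] < 0 | shifted[sel] > 100)
  shifted[sel] <- pmin(pmax(shifted[sel], 0), 100)
  out <- lab_image(shifted, image$a, image$b, masks = image$masks)
  attr(out, "delta_L") <- delta
  attr(out, "n_clipped") <- n_clip
  out
}

#' Simulate color appearance under an assumed illuminant (Steps 1-3)
#'
#' Full pipeline: the illuminant estimate's locus offset defines the
#' achromatic locus (Step 1 output), the iso-lightness chromatic shift aligns
#' it with the lightness axis (Step 2), and the anchored lightness shift
#' adjusts intensity (Step 3). Deterministic; a provenance record (locus,
#' applied Delta-L, clip count) is attached as attribute `"provenance"`.
#'
#' @param image a [lab_image()] with the masks named in `config`.
#' @param estimate an [illuminant_estimate()]; its `anchor_target_L` (if not
#'   `NA`) overrides the config default. `NA` in both disables Step 3.
#' @param config an [appearance_config()].
#' @return simulated [lab_image()] with attribute `provenance`.
#' @export
simulate_appearance <- function(image, estimate, config = appearance_config()) {
  stopifnot(inherits(image, "lab_image"), inherits(estimate, "illuminant_estimate"),
            inherits(config, "appearance_config"))
  bg <- .background_mask(image, config)
  locus <- achromatic_locus(estimate$a0, estimate$b0, config$L_base)
  out <- apply_chromatic_shift(image, locus, exclude = bg)
  target <- if (!is.na(estimate$anchor_target_L)) estimate$anchor_target_L else config$anchor_target_L
  delta_L <- 0
  n_clip <- 0L
  if (!is.na(target)) {
    out <- apply_lightness_shift(out, config$anchor_region, target, exclude = bg)
    delta_L <- attr(out, "delta_L")
    n_clip <- attr(out, "n_clipped")
  }
  attr(out, "provenance") <- list(locus = locus, delta_L = delta_L,
                                  n_clipped = n_clip,
                                  anchor_target_L = target,
                                  label = estimate$label)
  out
}
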