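# Synthetic dress-like scenes: a large "body" region, narrow "lace" stripes,
# and a bright background frame, rendered under a parameterized chromatic
# illuminant of variable intensity, plus simulated subject matches. The
# renderer is the exact inverse of the appearance transform (inverse von
# Kries at each pixel's rendered lightness, iso-lightness), which is the
# module's core guarantee: rendering a scene and simulating it back with the
# true parameters recovers the surfaces.

#' Specify a synthetic two-part scene
#'
#' Surfaces are specified colorimetrically, as Lab under a neutral (D65)
#' illuminant. Defaults mimic the dress's bimodal structure: a bluish body
#' (b* ~ -20) and a darker yellowish lace (b* ~ +15); they are pure fixtures,
#' not claims about the real photograph.
#'
#' @param size pixel dimensions c(height, width).
#' @param body_color,lace_color surface Lab triplets under neutral light.
#' @param stripe_period,stripe_width lace geometry: every `stripe_period`-th
#'   row band of `stripe_width` rows inside the dress area is lace.
#' @param border width in pixels of the bright background frame.
#' @param background_L lightness of the high-intensity background.
#' @param noise_sd per-channel Gaussian pixel noise, in Lab units.
#' @param intensity_offset additive L* offset imposed by the illuminant's
#'   intensity on the dress surfaces (negative = dim illuminant).
#' @param seed integer seed for the pixel noise.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(64L, 64L),
                       body_color = c(48, -2, -20),
                       lace_color = c(34, 2, 15),
                       stripe_period = 8L, stripe_width = 2L,
                       border = 6L, background_L = 96,
                       noise_sd = 0.8, intensity_offset = -10,
                       seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 8L), noise_sd >= 0,
            stripe_width < stripe_period, border >= 1L)
  structure(list(size = as.integer(size), body_color = body_color,
                 lace_color = lace_color,
                 stripe_period = as.integer(stripe_period),
                 stripe_width = as.integer(stripe_width),
                 border = as.integer(border), background_L = background_L,
                 noise_sd = noise_sd, intensity_offset = intensity_offset,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Region masks for a spec: background frame, lace stripe bands, body rest.
scene_masks <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]; bd <- spec$border
  background <- matrix(FALSE, h, w)
  background[c(seq_len(bd), h - seq_len(bd) + 1L), ] <- TRUE
  background[, c(seq_len(bd), w - seq_len(bd) + 1L)] <- TRUE
  inner_rows <- (bd + 1L):(h - bd)
  lace <- matrix(FALSE, h, w)
  stripe_rows <- inner_rows[((inner_rows - bd - 1L) %% spec$stripe_period) < spec$stripe_width]
  lace[stripe_rows, (bd + 1L):(w - bd)] <- TRUE
  body <- !background & !lace
  if (!any(lace) || !any(body)) stop("degenerate scene geometry", call. = FALSE)
  list(body = body, lace = lace, background = background)
}

#' Render a synthetic scene under an illuminant
#'
#' Builds the surface image from the spec, imposes the illuminant's intensity
#' (additive L* offset on the dress surfaces; the background is pinned at its
#' own high lightness) and its chromatic bias (inverse von Kries at each
#' pixel's rendered lightness, iso-lightness -- the exact inverse of
#' [apply_chromatic_shift()]), then adds per-channel Gaussian noise.
#' Deterministic under the spec's seed.
#'
#' The returned ground truth records what an appearance simulation needs for
#' exact recovery: the locus offset and, per region, the mean *surface*
#' lightness, which is the anchor target that undoes the intensity offset.
#'
#' @param spec a [scene_spec()].
#' @param illuminant an [illuminant_estimate()]; its (a0, b0) is the
#'   illuminant's chromatic bias as a locus offset.
#' @return object of class `rendered_scene`: `image` (a [lab_image()] with
#'   body/lace/background masks), `truth` (list: `a0`, `b0`,
#'   `anchor_mean_L` named by region, `intensity_offset`), `spec`,
#'   `illuminant`.
#' @export
render_scene <- function(spec, illuminant) {
  stopifnot(inherits(spec, "scene_spec"), inherits(illuminant, "illuminant_estimate"))
  masks <- scene_masks(spec)
  h <- spec$size[1]; w <- spec$size[2]
  L <- matrix(NA_real_, h, w); a <- L; b <- L
  set_region <- function(ch, mask, val) { ch[mask] <- val; ch }
  L <- set_region(L, masks$body, spec$body_color[1])
  a <- set_region(a, masks$body, spec$body_color[2])
  b <- set_region(b, masks$body, spec$body_color[3])
  L <- set_region(L, masks$lace, spec$lace_color[1])
  a <- set_region(a, masks$lace, spec$lace_color[2])
  b <- set_region(b, masks$lace, spec$lace_color[3])
  L <- set_region(L, masks$background, spec$background_L)
  a <- set_region(a, masks$background, 0)
  b <- set_region(b, masks$background, 0)

  anchor_mean_L <- c(body = mean(L[masks$body]), lace = mean(L[masks$lace]))

  dress <- masks$body | masks$lace
  L[dress] <- L[dress] + spec$intensity_offset
  if (any(L <= 0)) {
    stop("intensity offset drives surface lightness to or below zero", call. = FALSE)
  }

  px <- cbind(as.vector(L), as.vector(a), as.vector(b))
  Lk <- pmax(px[, 1], L_MIN)
  lms_neutral <- xyz_to_lms(lab_d65_to_xyz(cbind(Lk, 0, 0)))
  lms_locus <- xyz_to_lms(lab_d65_to_xyz(cbind(Lk, illuminant$a0, illuminant$b0)))
  bad_regions <- function(bad_px) {
    unique(unlist(lapply(names(masks), function(nm) {
      if (any(bad_px[as.vector(masks[[nm]])])) nm
    })))
  }
  if (any(lms_locus <= 0)) {
    stop("surfaces fall outside the representable gamut under this illuminant: ",
         paste(bad_regions(rowSums(lms_locus <= 0) > 0), collapse = ", "),
         call. = FALSE)
  }
  k <- lms_neutral / lms_locus
  lms <- xyz_to_lms(lab_d65_to_xyz(px)) / k   # inverse von Kries
  xyz <- lms_to_xyz(lms)
  if (any(xyz < 0)) {
    stop("surfaces fall outside the representable gamut under this illuminant: ",
         paste(bad_regions(rowSums(xyz < 0) > 0), collapse = ", "),
         call. = FALSE)
  }
  lab <- xyz_to_lab_d65(xyz)
  lab[, 1] <- px[, 1]  # iso-lightness, mirroring the forward transform

  lab <- withr::with_seed(spec$seed, {
    lab + matrix(stats::rnorm(length(lab), 0, spec$noise_sd), nrow(lab), 3L)
  })

  img <- lab_image(matrix(lab[, 1], h, w), matrix(lab[, 2], h, w),
                   matrix(lab[, 3], h, w), masks = masks)
  structure(list(image = img,
                 truth = list(a0 = illuminant$a0, b0 = illuminant$b0,
                              anchor_mean_L = anchor_mean_L,
                              intensity_offset = spec$intensity_offset),
                 spec = spec, illuminant = illuminant),
            class = "rendered_scene")
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("<rendered_scene> %d x %d, illuminant (a0*, b0*) = (%.2f, %.2f), offset %.1f L*\n",
              x$spec$size[1], x$spec$size[2], x$truth$a0, x$truth$b0,
              x$truth$intensity_offset))
  invisible(x)
}

#' The illuminant estimate that exactly inverts a rendered scene
#'
#' Convenience accessor: pairs the scene's true locus offset with the anchor
#' target that undoes the intensity offset for the given anchor region.
#'
#' @param scene a [render_scene()] result.
#' @param anchor_region `"body"` or `"lace"`.
#' @return an [illuminant_estimate()].
#' @export
true_estimate <- function(scene, anchor_region = "body") {
  stopifnot(inherits(scene, "rendered_scene"))
  illuminant_estimate(scene$truth$a0, scene$truth$b0,
                      anchor_target_L = scene$truth$anchor_mean_L[[anchor_region]],
                      label = "truth")
}

# Virtual wide-gamut linear display used to record synthetic matches; sRGB
# cannot hold the strongly blue renders of the off-diagonal grid corners.
wide_gamut_primaries <- function() {
  list(matrix = diag(c(200, 200, 400)), gamma = 1)
}

# Expected norm of a 3D isotropic Gaussian with unit per-axis sd.
.chi3_mean <- sqrt(2) * gamma(2) / gamma(1.5)

#' Simulate subject color matches for a rendered variant
#'
#' Places each simulated subject's body and lace matches at the labeled
#' render's modal Lab points ([modal_points_lab()], with the brighter mode
#' taken as the body),
#' adds isotropic Lab jitter with expected magnitude `jitter_de`, and records
#' the matches both directly in the appearance space (`L`, `a`, `b` columns:
#' dark extreme variants have appearance coordinates no physical display can
#' reproduce, so an RGB encoding alone would be lossy) and as RGB on a
#' wide-gamut linear virtual display (metadata in the `"primaries"`
#' attribute; out-of-gamut components clipped, count in `"n_clipped"`).
#' The phenomenal type is assigned
#' from the variant's side of the grid diagonal: cells nearer the A-1 corner
#' (column index + row index <= n + 1) report white/gold, the rest
#' blue/black.
#'
#' @param renders [render_grid()] output (must carry the `"grid"` attribute).
#' @param variant_label label of the generating variant, e.g. `"B-3"`.
#' @param jitter_de expected Delta-E magnitude of the match jitter.
#' @param n_subjects number of simulated subjects.
#' @param seed integer seed.
#' @param bin_size,min_sep modal-point parameters.
#' @return data frame of match records (`subject_id`, `part`, `R`, `G`, `B`,
#'   `type`) with attributes `primaries` and `lab` (the jittered Lab values).
#' @export
make_synthetic_matches <- function(renders, variant_label, jitter_de = 0,
                                   n_subjects = 1L, seed = 1L,
                                   bin_size = 2.5, min_sep = 4) {
  grid <- attr(renders, "grid")
  if (is.null(grid)) stop("renders must carry a 'grid' attribute", call. = FALSE)
  if (is.na(match(variant_label, names(renders)))) {
    stop("no render labeled '", variant_label, "'", call. = FALSE)
  }
  idx <- grid_label_index(variant_label)
  type <- if (sum(idx) <= grid$n_color + 1L) "white/gold" else "blue/black"
  base <- part_modes_lab(renders[[variant_label]], exclude = "background",
                         bin_size = bin_size, min_sep = min_sep)
  sd_axis <- jitter_de / .chi3_mean
  prim <- wide_gamut_primaries()
  lab_all <- withr::with_seed(seed, {
    jit <- matrix(stats::rnorm(n_subjects * 2L * 3L, 0, sd_axis), n_subjects * 2L, 3L)
    base[rep(c("body", "lace"), n_subjects), , drop = FALSE] + jit
  })
  xyz <- lab_d65_to_xyz(lab_all)
  lin <- xyz %*% t(solve(prim$matrix))
  n_clip <- sum(lin < 0 | lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  out <- data.frame(
    subject_id = rep(seq_len(n_subjects), each = 2L),
    part = rep(c("body", "lace"), n_subjects),
    R = lin[, 1], G = lin[, 2], B = lin[, 3],
    L = lab_all[, 1], a = lab_all[, 2], b = lab_all[, 3],
    type = type, stringsAsFactors = FALSE)
  attr(out, "primaries") <- prim
  attr(out, "lab") <- lab_all
  attr(out, "n_clipped") <- n_clip
  out
}
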