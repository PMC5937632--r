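# Evaluation machinery: 2.5-step chromaticity histograms, modal points,
# b*-L* contrast, conversion of subject matches, optimal-variant selection,
# and residual Delta-E statistics with a bootstrap reference distribution.

#' 2D chromaticity histogram of a Lab image
#'
#' Bins the image's pixels in either the (a*, b*) plane or the (b*, L*)
#' plane with half-open square bins `[edge, edge + bin_size)` anchored at
#' `origin`. Counts conserve the number of included pixels.
#'
#' @param image a [lab_image()].
#' @param plane `"ab"` (x = a*, y = b*) or `"bL"` (x = b*, y = L*).
#' @param bin_size bin width in Lab units (default 2.5).
#' @param origin bin-edge anchor (default 0).
#' @param exclude optional mask (name or logical matrix) of pixels to omit,
#'   typically the background.
#' @return object of class `histogram2d`: fields `plane`, `bin_size`,
#'   `origin`, `counts` (matrix, rows = x bins), `x_centers`, `y_centers`,
#'   `n_pixels`.
#' @export
histogram2d <- function(image, plane = c("ab", "bL"), bin_size = 2.5,
                        origin = 0, exclude = NULL) {
  stopifnot(inherits(image, "lab_image"))
  plane <- match.arg(plane)
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  excl <- resolve_mask(image, exclude, allow_null = TRUE)
  px <- lab_pixels(image)
  if (!is.null(excl)) px <- px[!as.vector(excl), , drop = FALSE]
  if (nrow(px) == 0L) stop("no pixels left to histogram", call. = FALSE)
  xy <- if (plane == "ab") px[, c(2, 3)] else px[, c(3, 1)]
  ix <- floor((xy[, 1] - origin) / bin_size)
  iy <- floor((xy[, 2] - origin) / bin_size)
  xr <- range(ix); yr <- range(iy)
  counts <- matrix(0L, xr[2] - xr[1] + 1L, yr[2] - yr[1] + 1L)
  tab <- table(factor(ix - xr[1] + 1L, levels = seq_len(nrow(counts))),
               factor(iy - yr[1] + 1L, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  structure(list(plane = plane, bin_size = bin_size, origin = origin,
                 counts = counts,
                 x_centers = (seq(xr[1], xr[2]) + 0.5) * bin_size + origin,
                 y_centers = (seq(yr[1], yr[2]) + 0.5) * bin_size + origin,
                 n_pixels = nrow(px)),
            class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("<histogram2d> plane %s, bin %.2f, %d x %d cells, %d pixels, %d nonzero\n",
              x$plane, x$bin_size, nrow(x$counts), ncol(x$counts), x$n_pixels,
              sum(x$counts > 0)))
  invisible(x)
}

#' Two dominant modal points of a 2D histogram
#'
#' The first mode is the globally most populated cell; the second is the most
#' populated cell at least `min_sep` bins (Euclidean, in bin units) away from
#' the first, so that one broad blob cannot yield two modes. Modes are
#' reported at cell centers.
#'
#' @param hist a [histogram2d()] result.
#' @param min_sep minimum mutual separation in bins (default 4).
#' @return object of class `modal_pair`: `mode1`, `mode2` (cell-center
#'   coordinates), `pop1 >= pop2` (cell populations).
#' @export
modal_points <- function(hist, min_sep = 4) {
  stopifnot(inherits(hist, "histogram2d"))
  cts <- hist$counts
  if (sum(cts > 0) < 2L) {
    stop("histogram needs at least two non-empty cells", call. = FALSE)
  }
  i1 <- which.max(cts)  # column-major first occurrence breaks ties
  r1 <- (i1 - 1L) %% nrow(cts) + 1L
  c1 <- (i1 - 1L) %/% nrow(cts) + 1L
  rows <- row(cts); cols <- col(cts)
  dist_bins <- sqrt((rows - r1)^2 + (cols - c1)^2)
  cand <- cts
  cand[dist_bins < min_sep | cts == 0L] <- -1L
  if (all(cand < 0L)) {
    stop(sprintf(paste("histogram is unimodal after the %g-bin separation filter;",
                       "dominant cell at (%.2f, %.2f) with %d pixels"),
                 min_sep, hist$x_centers[r1], hist$y_centers[c1], cts[r1, c1]),
         call. = FALSE)
  }
  i2 <- which.max(cand)
  r2 <- (i2 - 1L) %% nrow(cts) + 1L
  c2 <- (i2 - 1L) %/% nrow(cts) + 1L
  structure(list(mode1 = c(hist$x_centers[r1], hist$y_centers[c1]),
                 mode2 = c(hist$x_centers[r2], hist$y_centers[c2]),
                 pop1 = cts[r1, c1], pop2 = cts[r2, c2]),
            class = "modal_pair")
}

#' Modal-point contrast in the (b*, L*) plane
#'
#' Chromatic contrast of an image defined as the Euclidean distance between
#' the two modal points (dress-body and lace populations) of its (b*, L*)
#' histogram, together with the number of nonzero histogram cells (the gamut
#' footprint).
#'
#' @param image a [lab_image()].
#' @param exclude optional mask of pixels to omit (typically background).
#' @param bin_size histogram bin width (default 2.5).
#' @param min_sep modal separation filter in bins (default 4).
#' @return list with `distance`, `nonzero_cells`, and the `modal_pair`.
#' @export
contrast_bl <- function(image, exclude = NULL, bin_size = 2.5, min_sep = 4) {
  h <- histogram2d(image, plane = "bL", bin_size = bin_size, exclude = exclude)
  mp <- modal_points(h, min_sep = min_sep)
  list(distance = sqrt(sum((mp$mode1 - mp$mode2)^2)),
       nonzero_cells = sum(h$counts > 0),
       modes = mp)
}

#' Two dominant modal points in full (L*, a*, b*)
#'
#' Three-dimensional analogue of [modal_points()]: pixels are binned in
#' (L*, a*, b*) with the same cube side (default 2.5) and the two dominant
#' well-separated cells are returned as Lab cell centers. The heavier mode
#' corresponds to the larger image population (the dress body in a two-part
#' scene) and the second to the lace. Variant selection uses these, since
#' proximity in Delta-E needs all three coordinates.
#'
#' @param image a [lab_image()].
#' @param exclude optional mask of pixels to omit.
#' @param bin_size bin side in Lab units (default 2.5).
#' @param min_sep minimum mode separation in bins (default 4).
#' @param origin bin-edge anchor (default 0).
#' @return list with Lab triplets `mode1`, `mode2` and populations
#'   `pop1 >= pop2`.
#' @export
modal_points_lab <- function(image, exclude = NULL, bin_size = 2.5,
                             min_sep = 4, origin = 0) {
  stopifnot(inherits(image, "lab_image"))
  excl <- resolve_mask(image, exclude, allow_null = TRUE)
  px <- lab_pixels(image)
  if (!is.null(excl)) px <- px[!as.vector(excl), , drop = FALSE]
  if (nrow(px) == 0L) stop("no pixels left to bin", call. = FALSE)
  idx <- floor((px - origin) / bin_size)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  tab <- sort(table(key), decreasing = TRUE)
  if (length(tab) < 2L) stop("fewer than two occupied cells", call. = FALSE)
  cells <- do.call(rbind, lapply(strsplit(names(tab), ",", fixed = TRUE), as.numeric))
  d1 <- sqrt(rowSums(sweep(cells, 2L, cells[1L, ])^2))
  far <- which(d1 >= min_sep)
  if (!length(far)) {
    stop(sprintf("distribution is unimodal after the %g-bin separation filter", min_sep),
         call. = FALSE)
  }
  i2 <- far[1L]  # tab is sorted by population, so the first far cell is the max
  center <- function(i) (cells[i, ] + 0.5) * bin_size + origin
  m1 <- center(1L); m2 <- center(i2)
  names(m1) <- names(m2) <- c("L", "a", "b")
  list(mode1 = m1, mode2 = m2,
       pop1 = as.integer(tab[1L]), pop2 = as.integer(tab[i2]))
}

#' Convert a subject's matched color to CIELAB (D65)
#'
#' RGB components are decoded with the display-primaries metadata (a linear
#' RGB -> XYZ matrix on the Y = 100 scale plus a gamma exponent, or the
#' string `"srgb"` for the piecewise sRGB decoding) and converted to Lab
#' normalized to D65. When no primaries are supplied the sRGB standard is
#' assumed, with a warning.
#'
#' If the record carries explicit `L`, `a`, `b` fields (a match already
#' expressed in the appearance space, as the synthetic observer's records
#' are), those are returned directly: simulated appearance coordinates of
#' extreme variants can lie outside every physical display gamut, where an
#' RGB encoding would be lossy.
#'
#' @param rec a match record: list or one-row data frame with fields
#'   `R`, `G`, `B` in [0, 1], or `L`, `a`, `b` in the appearance space.
#' @param primaries `NULL` (assume sRGB, warn), the string `"srgb"`, or a
#'   list with `matrix` (3 x 3 linear RGB -> XYZ, Y = 100 scale) and `gamma`
#'   (decoding exponent, 1 = linear).
#' @return Lab triplet.
#' @export
match_to_lab <- function(rec, primaries = NULL) {
  lab <- suppressWarnings(as.numeric(c(rec$L, rec$a, rec$b)))
  if (length(lab) == 3L && !anyNA(lab)) {
    return(c(L = lab[1], a = lab[2], b = lab[3]))
  }
  rgb <- as.numeric(c(rec$R, rec$G, rec$B))
  if (length(rgb) != 3L || anyNA(rgb)) {
    stop("record must carry numeric R, G, B", call. = FALSE)
  }
  if (is.null(primaries)) {
    warning("no display primaries supplied; assuming sRGB")
    primaries <- "srgb"
  }
  if (identical(primaries, "srgb")) {
    return(srgb_to_lab_d65(rgb))
  }
  lin <- if (primaries$gamma == 1) rgb else rgb^primaries$gamma
  xyz_to_lab_d65(as.vector(primaries$matrix %*% lin))
}

# Achromatic part: the region each phenomenal type anchors (body appears
# white for white/gold observers, lace appears black for blue/black ones);
# the remaining, chromatic-looking part carries the residual of interest.
achromatic_part <- function(type) {
  switch(type,
         "white/gold" = "body",
         "blue/black" = "lace",
         stop("phenomenal type must be 'white/gold' or 'blue/black'", call. = FALSE))
}

chromatic_part <- function(type) {
  if (achromatic_part(type) == "body") "lace" else "body"
}

#' Modal Lab points of the two scene parts
#'
#' Extracts the two dominant modes with [modal_points_lab()] and assigns them
#' to body/lace by lightness: the dress body sits above the lace in L* under
#' any anchoring (white/gold renders a white body over gold lace, blue/black
#' a mid-blue body over black lace). Raw peak-cell population would be
#' unstable for this purpose: a transform can spread the larger cluster over
#' more cells than the smaller one.
#'
#' @inheritParams modal_points_lab
#' @param exclude mask (name or logical matrix) of pixels to omit; a mask
#'   name absent from the image is ignored.
#' @return 2 x 3 matrix with rows `body`, `lace` and columns `L`, `a`, `b`.
#' @export
part_modes_lab <- function(image, exclude = "background",
                           bin_size = 2.5, min_sep = 4) {
  excl <- if (is.character(exclude) &&
              is.na(match(exclude, names(image$masks)))) NULL else exclude
  mp <- modal_points_lab(image, exclude = excl, bin_size = bin_size,
                         min_sep = min_sep)
  if (mp$mode1[["L"]] >= mp$mode2[["L"]]) {
    rbind(body = mp$mode1, lace = mp$mode2)
  } else {
    rbind(body = mp$mode2, lace = mp$mode1)
  }
}

# part_modes_lab for every render, as a list of 2 x 3 matrices.
variant_part_modes <- function(renders, exclude = "background",
                               bin_size = 2.5, min_sep = 4) {
  lapply(renders, part_modes_lab, exclude = exclude, bin_size = bin_size,
         min_sep = min_sep)
}

#' Select the grid variant closest to a subject's matches
#'
#' For each rendered variant the Delta-E between the subject's
#' achromatic-part match (dress body for a white/gold observer, lace for a
#' blue/black observer) and that render's corresponding modal point is
#' computed; the variant with the smallest distance wins. Ties are broken by
#' row-major grid order. A render whose modes cannot be resolved is skipped
#' with a warning.
#'
#' @param renders named list of rendered variants ([render_grid()] output).
#' @param rec_pair the subject's two match records: data frame with one row
#'   per `part` (`"body"`, `"lace"`) and columns `R`, `G`, `B`.
#' @param type the subject's phenomenal type, `"white/gold"` or
#'   `"blue/black"`.
#' @param primaries display metadata for [match_to_lab()]; defaults to the
#'   `"primaries"` attribute of `rec_pair`, else sRGB.
#' @param modes optional precomputed part modes (internal reuse).
#' @param bin_size,min_sep passed to the modal-point extraction.
#' @return the winning variant's label (character).
#' @export
find_optimal_variant <- function(renders, rec_pair, type,
                                 primaries = attr(rec_pair, "primaries"),
                                 modes = NULL, bin_size = 2.5, min_sep = 4) {
  part <- achromatic_part(type)
  rec <- rec_pair[rec_pair$part == part, , drop = FALSE]
  if (nrow(rec) != 1L) {
    stop(sprintf("rec_pair must contain exactly one '%s' record", part), call. = FALSE)
  }
  target <- match_to_lab(rec[1, ], primaries = primaries)
  if (is.null(modes)) {
    modes <- lapply(seq_along(renders), function(i) {
      tryCatch(part_modes_lab(renders[[i]], bin_size = bin_size,
                              min_sep = min_sep),
               error = function(e) {
                 warning(sprintf("skipping render '%s': %s",
                                 names(renders)[i], conditionMessage(e)))
                 NULL
               })
    })
    names(modes) <- names(renders)
  }
  de <- vapply(modes, function(m) {
    if (is.null(m)) return(Inf)
    delta_e_lab(target, m[part, ])
  }, 0)
  if (all(!is.finite(de))) stop("no render had resolvable modes", call. = FALSE)
  names(renders)[which.min(de)]  # which.min takes the first minimum: grid order
}

#' Residual Delta-E report with a bootstrap reference distribution
#'
#' For every subject the optimal variant is selected on the achromatic part
#' (as in [find_optimal_variant()]); the residual Delta-E of the remaining,
#' chromatic part at that variant is the model's figure of merit. Reported:
#' per-subject residuals, mean +/- SEM overall and by phenomenal type (for
#' both parts), and a reference distribution obtained by drawing a uniformly
#' random variant per subject and averaging the chromatic-part residual,
#' repeated `n_boot` times (percentile 95% CI). Deterministic under `seed`.
#'
#' @param renders named list of rendered variants ([render_grid()] output).
#' @param matches data frame of match records: columns `subject_id`, `part`
#'   (`"body"`/`"lace"`), `R`, `G`, `B`, `type`; one row per subject per part.
#' @param n_boot bootstrap iterations (default 10000; < 100 warns).
#' @param seed integer seed for the bootstrap draws.
#' @param primaries display metadata (default: `attr(matches, "primaries")`).
#' @param bin_size,min_sep modal-point parameters.
#' @return object of class `residual_report`: `per_subject` data frame,
#'   `stats` data frame (group means +/- SEM), `bootstrap` list (chromatic and
#'   achromatic reference mean, 95% percentile CI, draws summary).
#' @export
residual_report <- function(renders, matches, n_boot = 10000L, seed = 1L,
                            primaries = attr(matches, "primaries"),
                            bin_size = 2.5, min_sep = 4) {
  stopifnot(is.data.frame(matches),
            all(c("subject_id", "part", "R", "G", "B", "type") %in% names(matches)))
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) warning("n_boot < 100 gives an unreliable reference distribution")
  subjects <- unique(matches$subject_id)
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  modes <- variant_part_modes(renders, bin_size = bin_size, min_sep = min_sep)
  labels <- names(renders)
  V <- length(renders); S <- length(subjects)

  R_ach <- matrix(NA_real_, S, V, dimnames = list(subjects, labels))
  R_chr <- R_ach
  types <- character(S)
  for (s in seq_len(S)) {
    recs <- matches[matches$subject_id == subjects[s], , drop = FALSE]
    types[s] <- recs$type[1]
    ap <- achromatic_part(types[s]); cp <- chromatic_part(types[s])
    lab_ach <- match_to_lab(recs[recs$part == ap, ][1, ], primaries = primaries)
    lab_chr <- match_to_lab(recs[recs$part == cp, ][1, ], primaries = primaries)
    for (v in seq_len(V)) {
      R_ach[s, v] <- delta_e_lab(lab_ach, modes[[v]][ap, ])
      R_chr[s, v] <- delta_e_lab(lab_chr, modes[[v]][cp, ])
    }
  }
  opt <- apply(R_ach, 1L, which.min)  # first minimum: row-major grid order
  per_subject <- data.frame(
    subject_id = subjects, type = types, optimal = labels[opt],
    achromatic_de = R_ach[cbind(seq_len(S), opt)],
    chromatic_de = R_chr[cbind(seq_len(S), opt)],
    row.names = NULL)

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  grp <- function(sel, name) {
    data.frame(group = name, n = sum(sel),
               chromatic_mean = mean(per_subject$chromatic_de[sel]),
               chromatic_sem = sem(per_subject$chromatic_de[sel]),
               achromatic_mean = mean(per_subject$achromatic_de[sel]),
               achromatic_sem = sem(per_subject$achromatic_de[sel]))
  }
  stats_df <- rbind(
    grp(rep(TRUE, S), "all"),
    if (any(types == "blue/black")) grp(types == "blue/black", "blue/black"),
    if (any(types == "white/gold")) grp(types == "white/gold", "white/gold"))

  boot <- withr::with_seed(seed, {
    draws <- matrix(sample.int(V, n_boot * S, replace = TRUE), n_boot, S)
    chr <- matrix(R_chr[cbind(rep(seq_len(S), each = n_boot), as.vector(draws))],
                  n_boot, S)
    ach <- matrix(R_ach[cbind(rep(seq_len(S), each = n_boot), as.vector(draws))],
                  n_boot, S)
    list(chr = rowMeans(chr), ach = rowMeans(ach))
  })
  ci <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  structure(list(
    per_subject = per_subject,
    stats = stats_df,
    bootstrap = list(
      n_boot = n_boot, seed = seed,
      chromatic_mean = mean(boot$chr), chromatic_ci = ci(boot$chr),
      achromatic_mean = mean(boot$ach), achromatic_ci = ci(boot$ach)),
    residual_matrices = list(achromatic = R_ach, chromatic = R_chr)),
    class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("<residual_report>\n")
  s <- x$stats
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s (n=%2d): chromatic %6.2f +/- %.2f   achromatic %6.2f +/- %.2f\n",
                s$group[i], s$n[i], s$chromatic_mean[i], s$chromatic_sem[i],
                s$achromatic_mean[i], s$achromatic_sem[i]))
  }
  b <- x$bootstrap
  cat(sprintf("  bootstrap reference (n_boot=%d): chromatic mean %.2f, 95%% CI [%.2f, %.2f]\n",
              b$n_boot, b$chromatic_mean, b$chromatic_ci[1], b$chromatic_ci[2]))
  invisible(x)
}

#' Read a color-matching CSV
#'
#' Expected columns: `subject_id`, `part` (`body`/`lace`), `R`, `G`, `B`
#' (components in [0, 1]), `type` (`white/gold`/`blue/black`). An optional
#' JSON sidecar (same path with `.json` extension) supplies the display
#' primaries as `{"matrix": [...9 numbers, row-major...], "gamma": g}`.
#'
#' @param path CSV file path.
#' @return data frame of records, with a `"primaries"` attribute when a
#'   sidecar is present.
#' @export
read_matches_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "part", "R", "G", "B", "type")
  if (!all(need %in% names(df))) {
    stop("matching CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "primaries") <- list(
      matrix = matrix(as.numeric(meta$matrix), 3, 3, byrow = TRUE),
      gamma = as.numeric(meta$gamma))
  }
  df
}
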