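# LabImage: the model's working representation -- per-pixel (L*, a*, b*) in
# the D65-normalized appearance space, plus optional named region masks
# (body / lace / background).

#' Construct a Lab image
#'
#' @param L,a,b numeric matrices of identical dimension holding the per-pixel
#'   CIELAB (D65-normalized) channels.
#' @param masks optional named list of logical matrices (same dimension as the
#'   channels) marking regions such as `body`, `lace`, `background`. Masks
#'   must be pairwise disjoint.
#' @return object of class `lab_image`.
#' @export
lab_image <- function(L, a, b, masks = list()) {
  L <- as.matrix(L); a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(L)) || !all(dim(b) == dim(L))) {
    stop("L, a, b must have identical dimensions", call. = FALSE)
  }
  if (length(L) == 0L) stop("image must contain at least one pixel", call. = FALSE)
  if (length(masks)) {
    if (is.null(names(masks)) || any(!nzchar(names(masks)))) {
      stop("masks must be a named list", call. = FALSE)
    }
    masks <- lapply(masks, function(m) {
      m <- as.matrix(m)
      if (!all(dim(m) == dim(L))) stop("mask dimensions must match the image", call. = FALSE)
      storage.mode(m) <- "logical"
      m
    })
    tot <- Reduce(`+`, masks)
    if (any(tot > 1L)) stop("masks must be disjoint", call. = FALSE)
  }
  structure(list(L = L, a = a, b = b, masks = masks), class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image> %d x %d pixels\n", nrow(x$L), ncol(x$L)))
  cat(sprintf("  L* range: [%.2f, %.2f]   a*: [%.2f, %.2f]   b*: [%.2f, %.2f]\n",
              min(x$L), max(x$L), min(x$a), max(x$a), min(x$b), max(x$b)))
  if (length(x$masks)) {
    cat("  masks:", paste(sprintf("%s (%d px)", names(x$masks),
                                  vapply(x$masks, sum, 0L)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.lab_image <- function(x) dim(x$L)

# Flatten the Lab channels to an n x 3 matrix (pixel order = column-major,
# matching matrix storage so round trips are positionally exact).
lab_pixels <- function(image) {
  cbind(L = as.vector(image$L), a = as.vector(image$a), b = as.vector(image$b))
}

# Rebuild a lab_image from an n x 3 pixel matrix using `template` for shape
# and masks.
lab_from_pixels <- function(px, template) {
  d <- dim(template$L)
  lab_image(matrix(px[, 1], d[1], d[2]), matrix(px[, 2], d[1], d[2]),
            matrix(px[, 3], d[1], d[2]), masks = template$masks)
}

# Resolve a region argument: a mask name, a logical matrix, or NULL.
resolve_mask <- function(image, region, allow_null = FALSE) {
  if (is.null(region)) {
    if (allow_null) return(NULL)
    stop("a region mask is required", call. = FALSE)
  }
  if (is.character(region)) {
    if (length(region) != 1L || is.na(match(region, names(image$masks)))) {
      stop(sprintf("image has no mask named '%s'", region), call. = FALSE)
    }
    return(image$masks[[region]])
  }
  m <- as.matrix(region)
  if (!all(dim(m) == dim(image$L))) {
    stop("mask dimensions must match the image", call. = FALSE)
  }
  storage.mode(m) <- "logical"
  m
}

#' Read an sRGB raster image into a Lab image
#'
#' Reads a PNG or TIFF (8- or 16-bit; chosen by file extension), assumes sRGB
#' encoding, and converts each pixel to CIELAB normalized to D65. An alpha
#' channel, if present, is dropped.
#'
#' @param path image file path (`.png`, `.tif`/`.tiff`).
#' @param masks optional named list of mask file paths read with [read_mask()].
#' @return a [lab_image()].
#' @export
read_image_lab <- function(path, masks = list()) {
  arr <- .read_raster(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  rgb <- cbind(as.vector(arr[, , 1]), as.vector(arr[, , 2]), as.vector(arr[, , 3]))
  lab <- srgb_to_lab_d65(rgb)
  d <- dim(arr)[1:2]
  mk <- lapply(masks, read_mask)
  lab_image(matrix(lab[, 1], d[1], d[2]), matrix(lab[, 2], d[1], d[2]),
            matrix(lab[, 3], d[1], d[2]), masks = mk)
}

#' Write a Lab image as an sRGB raster
#'
#' Converts to sRGB (clipping out-of-gamut values to [0, 1]) and writes a PNG
#' or a TIFF; 16-bit output is available for TIFF. The number of clipped
#' components is reported via a message and returned invisibly.
#'
#' @param image a [lab_image()].
#' @param path output path; format chosen by extension.
#' @param bits bit depth for TIFF output (8 or 16).
#' @return invisibly, the clipped-component count.
#' @export
write_image_srgb <- function(image, path, bits = 8L) {
  rgb <- lab_d65_to_srgb(lab_pixels(image))
  n_clip <- attr(rgb, "n_clipped")
  d <- dim(image$L)
  arr <- array(c(rgb[, 1], rgb[, 2], rgb[, 3]), c(d[1], d[2], 3L))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (n_clip > 0) message(n_clip, " color components clipped to the sRGB gamut")
  invisible(n_clip)
}

#' Read a region mask
#'
#' A mask is a single-channel PNG/TIFF where any nonzero pixel is inside the
#' region.
#'
#' @param path mask image path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  arr <- .read_raster(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0
}

#' Write a region mask as a PNG
#'
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
    if (is.list(arr)) arr <- arr[[1]]
    arr
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
}
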