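#' Grayscale image objects
#'
#' A `gray_image` is a numeric matrix of per-pixel grey levels with a `scale`
#' attribute: `"8bit"` for integer intensities in \[0, 255\] (the working
#' scale of the whole pipeline) or `"unit"` for normalized reals in \[0, 1\].
#' The coordinate convention is row-major with origin at the top-left;
#' `x[i, j]` is the pixel in (0-based) row `i - 1`, column `j - 1`.
#'
#' @param x numeric matrix of intensities.
#' @param scale `"8bit"` or `"unit"`.
#' @return A `gray_image` object (a classed matrix).
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
gray_image <- function(x, scale = c("8bit", "unit")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(x)) stop("image contains NA intensities", call. = FALSE)
  hi <- if (scale == "8bit") 255 else 1
  if (min(x) < 0 || max(x) > hi) {
    stop(sprintf("intensities outside [0, %s] for scale '%s'", hi, scale),
         call. = FALSE)
  }
  if (scale == "8bit" && any(x != round(x))) {
    stop("8-bit images must have integer intensities", call. = FALSE)
  }
  structure(x, scale = scale, class = c("gray_image", class(matrix())))
}

#' Binary microaneurysm mask objects
#'
#' A `mask_image` is an integer matrix of per-pixel class labels: 0 for
#' background (including vessels) and 1 for microaneurysm. A mask is always
#' paired with a grayscale frame of identical height and width.
#'
#' @param x numeric matrix whose values are all 0 or 1.
#' @return A `mask_image` object.
#' @export
mask_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("mask must have height >= 1 and width >= 1", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(x)), c(0, 1))
  if (length(bad) > 0) {
    stop(sprintf("mask labels must be 0 or 1; found: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  structure(x, class = c("mask_image", class(matrix())))
}

#' Per-pixel class probability maps
#'
#' A `prob_map` is an H x W x 2 array of class probabilities over
#' {background, microaneurysm}; each pixel's probabilities sum to 1
#' (within 1e-6).
#'
#' @param x numeric H x W x 2 array.
#' @return A `prob_map` object.
#' @export
prob_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 2L) {
    stop("`x` must be an H x W x 2 array", call. = FALSE)
  }
  if (min(x) < 0) stop("probabilities must be nonnegative", call. = FALSE)
  s <- x[, , 1] + x[, , 2]
  if (max(abs(s - 1)) > 1e-6) {
    stop("per-pixel probabilities must sum to 1 (tolerance 1e-6)",
         call. = FALSE)
  }
  structure(x, class = c("prob_map", class(array(0, c(1, 1, 1)))))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, scale %s, range [%s, %s]>\n",
              nrow(x), ncol(x), attr(x, "scale"), min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

#' @export
as.matrix.mask_image <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image %d x %d, %d positive pixel(s) (%.3f%%)>\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

# Stop unless a mask/image (or any two rasters) share height and width.
check_same_dim <- function(a, b, what = "images") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (any(da != db)) {
    stop(sprintf("dimension mismatch between %s: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]), call. = FALSE)
  }
  invisible(TRUE)
}

# round half away from zero, the package-wide rounding convention
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported raster format '.%s' (PNG or TIFF expected): %s",
                 ext, path), call. = FALSE)
  )
  if (length(arr) == 0) stop(sprintf("zero-sized raster: %s", path), call. = FALSE)
  # collapse RGB(A) to luminance; drop alpha
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (!is.matrix(arr)) arr <- matrix(arr, nrow = NROW(arr))
  arr
}

#' Read a grayscale FFA image
#'
#' Reads a PNG or TIFF raster as an 8-bit `gray_image`. RGB inputs are
#' converted to luminance (0.299 R + 0.587 G + 0.114 B); an alpha channel is
#' discarded. 16-bit TIFF intensities are linearly rescaled onto 0–255.
#'
#' @param path path to a PNG or TIFF file.
#' @return An 8-bit [gray_image].
#' @seealso [write_gray_image()], [read_mask()]
#' @export
read_gray_image <- function(path) {
  arr <- read_raster(path)
  # readers return [0,1]; map back to the 8-bit scale
  gray_image(matrix(round_half_away(arr * 255), nrow(arr), ncol(arr)))
}

#' Read a binary microaneurysm mask
#'
#' Accepts rasters whose distinct values are a subset of {0, 1} or {0, 255}
#' (on the 8-bit scale); {0, 255} is mapped to {0, 1}. Any other value set is
#' rejected with an error naming the offending values.
#'
#' @param path path to a PNG or TIFF file.
#' @return A [mask_image].
#' @export
read_mask <- function(path) {
  arr <- read_raster(path)
  v <- round_half_away(arr * 255)
  vals <- sort(unique(as.vector(v)))
  if (all(vals %in% c(0, 1))) {
    lab <- v
  } else if (all(vals %in% c(0, 255))) {
    lab <- v / 255
  } else {
    stop(sprintf(
      "mask values must be a subset of {0,1} or {0,255}; found: %s (%s)",
      paste(utils::head(vals, 6), collapse = ", "), path), call. = FALSE)
  }
  mask_image(matrix(lab, nrow(v), ncol(v)))
}

#' Write a grayscale image as lossless 8-bit PNG
#'
#' 8-bit images round-trip bit-exactly through [read_gray_image()].
#' Normalized (`"unit"`) images are rescaled to 0–255 with
#' round-half-away-from-zero before writing.
#'
#' @param img a [gray_image].
#' @param path output path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  v <- if (identical(attr(img, "scale"), "unit")) {
    round_half_away(unclass(img) * 255)
  } else {
    unclass(img)
  }
  png::writePNG(matrix(v / 255, nrow(img), ncol(img)), target = path)
  invisible(path)
}

#' Write a binary mask as a {0, 255} PNG
#'
#' Masks are stored with positives at 255 for viewability; [read_mask()]
#' restores in-memory {0, 1} labels.
#'
#' @param mask a [mask_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_image"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}
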