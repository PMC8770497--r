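#' Histogram-stretch configuration
#'
#' Target grey-level range for linear contrast stretching. Defaults map the
#' observed intensity range of each frame onto the full 8-bit range.
#'
#' @param g_min target minimum grey level (integer, default 0).
#' @param g_max target maximum grey level (integer, default 255).
#' @return A `stretch_config` object.
#' @export
stretch_config <- function(g_min = 0L, g_max = 255L) {
  g_min <- as.integer(g_min); g_max <- as.integer(g_max)
  if (is.na(g_min) || is.na(g_max) || g_min < 0L || g_max > 255L || g_min >= g_max) {
    stop("require 0 <= g_min < g_max <= 255", call. = FALSE)
  }
  structure(list(g_min = g_min, g_max = g_max), class = "stretch_config")
}

#' Gaussian-filter configuration
#'
#' @param sigma kernel standard deviation in pixels (positive). Default 1.
#' @param kernel_size odd side length of the square kernel; default
#'   `2 * ceiling(3 * sigma) + 1` (about 3-sigma support).
#' @return A `gaussian_config` object.
#' @export
gaussian_config <- function(sigma = 1, kernel_size = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  if (is.null(kernel_size)) kernel_size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  kernel_size <- as.integer(kernel_size)
  if (is.na(kernel_size) || kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop("`kernel_size` must be an odd positive integer", call. = FALSE)
  }
  structure(list(sigma = sigma, kernel_size = kernel_size),
            class = "gaussian_config")
}

# Degenerate-input condition raised on constant frames so batch callers can
# pass the frame through instead of aborting a run.
stop_degenerate <- function(msg) {
  stop(structure(class = c("mafcdn_degenerate_input", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Linear histogram stretching
#'
#' Maps each pixel `I` to `(g_max - g_min) / (I_max - I_min) * (I - I_min) +
#' g_min`, where `I_min`/`I_max` are the observed minimum and maximum of the
#' frame, then rounds half away from zero and clips to `[g_min, g_max]`. The
#' mapping is monotone and hits both endpoints of the target range.
#'
#' @param img an 8-bit [gray_image] with at least two distinct intensities.
#' @param cfg a [stretch_config()].
#' @return The stretched 8-bit [gray_image].
#' @examples
#' img <- gray_image(matrix(c(50, 100, 150, 50), 2, 2))
#' histogram_stretch(img, stretch_config())
#' @export
histogram_stretch <- function(img, cfg = stretch_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "stretch_config"))
  x <- unclass(img)
  i_min <- min(x); i_max <- max(x)
  if (i_max == i_min) {
    stop_degenerate(sprintf(
      "constant image (all pixels %s): histogram stretch undefined", i_min))
  }
  # multiply before dividing so exact half-way values (e.g. 127.5) are hit
  y <- (cfg$g_max - cfg$g_min) * (x - i_min) / (i_max - i_min) + cfg$g_min
  y <- pmin(pmax(round_half_away(y), cfg$g_min), cfg$g_max)
  gray_image(matrix(y, nrow(x), ncol(x)))
}

#' Gaussian kernel table
#'
#' Discrete isotropic Gaussian weights `exp(-(x^2 + y^2) / (2 sigma^2))` on
#' the integer offset grid `[-(l-1)/2, (l-1)/2]^2`, normalized to sum exactly
#' to 1. The continuous normalization prefactor cancels under this discrete
#' renormalization.
#'
#' @param cfg a [gaussian_config()].
#' @return An `l x l` numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(cfg = gaussian_config()) {
  stopifnot(inherits(cfg, "gaussian_config"))
  r <- (cfg$kernel_size - 1L) / 2L
  off <- seq(-r, r)
  k <- exp(-outer(off^2, off^2, "+") / (2 * cfg$sigma^2))
  k / sum(k)
}

#' Gaussian filtering with reflect padding
#'
#' Convolves the frame with [gaussian_kernel()] using mirror padding (the
#' edge pixel is not repeated), then rounds half away from zero and clips to
#' \[0, 255\]. Constant frames are fixed points; the intensity range never
#' widens beyond one grey level of rounding.
#'
#' @param img an 8-bit [gray_image].
#' @param cfg a [gaussian_config()].
#' @return The filtered 8-bit [gray_image].
#' @export
gaussian_filter <- function(img, cfg = gaussian_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "gaussian_config"))
  y <- conv2d_reflect(unclass(img) * 1.0, gaussian_kernel(cfg))
  y <- pmin(pmax(round_half_away(y), 0), 255)
  gray_image(matrix(y, nrow(img), ncol(img)))
}

#' Two-stage FFA preprocessing
#'
#' Contrast enhancement by [histogram_stretch()] followed by noise reduction
#' with [gaussian_filter()], in that order.
#'
#' @param img an 8-bit [gray_image].
#' @param stretch a [stretch_config()].
#' @param gaussian a [gaussian_config()].
#' @return The preprocessed 8-bit [gray_image].
#' @export
preprocess_image <- function(img, stretch = stretch_config(),
                             gaussian = gaussian_config()) {
  gaussian_filter(histogram_stretch(img, stretch), gaussian)
}

#' Preprocess a directory of images
#'
#' Applies [preprocess_image()] to every PNG/TIFF in `in_dir`, writing PNGs
#' with the same base names to `out_dir`. Constant (blank) frames cannot be
#' stretched; they are passed through unchanged with a message rather than
#' aborting the batch.
#'
#' @param in_dir,out_dir input and output directories (`out_dir` is created).
#' @param stretch,gaussian stage configurations.
#' @return Invisibly, a data frame with one row per file and a `passthrough`
#'   flag for degenerate frames.
#' @export
preprocess_dir <- function(in_dir, out_dir, stretch = stretch_config(),
                           gaussian = gaussian_config()) {
  files <- list.files(in_dir, pattern = "\\.(png|tiff?)$", ignore.case = TRUE)
  if (length(files) == 0) stop(sprintf("no PNG/TIFF files in %s", in_dir), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame(file = files, passthrough = FALSE)
  for (i in seq_along(files)) {
    img <- read_gray_image(file.path(in_dir, files[i]))
    out <- tryCatch(preprocess_image(img, stretch, gaussian),
                    mafcdn_degenerate_input = function(e) {
                      message(sprintf("pass-through (constant frame): %s", files[i]))
                      log$passthrough[i] <<- TRUE
                      img
                    })
    out_name <- paste0(tools::file_path_sans_ext(files[i]), ".png")
    write_gray_image(out, file.path(out_dir, out_name))
  }
  invisible(log)
}
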