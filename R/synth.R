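#' Synthetic FFA scene configuration
#'
#' Parameters of the synthetic fundus-fluorescein-angiography generator:
#' a dark background with a smooth low-frequency illumination field, bright
#' curvilinear vessels, and a handful of tiny bright microaneurysm discs
#' placed preferentially near vessels — reproducing the statistical structure
#' the detector faces (low lesion/vessel contrast, extreme class imbalance)
#' without any clinical data.
#'
#' @param height,width frame size in pixels (desk-scale default 128 x 128;
#'   use 768 x 868 to mimic full angiography frames).
#' @param n_vessels number of vessel strokes.
#' @param vessel_width_range numeric length-2, stroke width range in pixels.
#' @param vessel_intensity vessel grey level.
#' @param n_mas microaneurysms per frame.
#' @param ma_radius_range numeric length-2, MA disc radius range in pixels.
#' @param ma_peak_intensity grey level at an MA centre; must exceed the
#'   background level.
#' @param background_level base background grey level.
#' @param illumination_amplitude amplitude (grey levels) of the smooth
#'   low-frequency illumination field; 0 disables it.
#' @param noise_sigma additive Gaussian pixel noise, in grey levels.
#' @param contrast_compression factor in (0, 1\] pulling all intensities
#'   toward mid-grey (128); 1 = no compression, smaller = lower contrast.
#' @param seed integer seed; fully determines every pixel.
#' @return A `scene_config` object.
#' @seealso [scene_preset()], [generate_sample()], [generate_dataset()]
#' @export
scene_config <- function(height = 128L, width = 128L,
                         n_vessels = 3L, vessel_width_range = c(2, 5),
                         vessel_intensity = 140,
                         n_mas = 6L, ma_radius_range = c(1.5, 3),
                         ma_peak_intensity = 230,
                         background_level = 30,
                         illumination_amplitude = 8,
                         noise_sigma = 4,
                         contrast_compression = 1,
                         seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_vessels = as.integer(n_vessels),
              vessel_width_range = as.numeric(vessel_width_range),
              vessel_intensity = vessel_intensity,
              n_mas = as.integer(n_mas),
              ma_radius_range = as.numeric(ma_radius_range),
              ma_peak_intensity = ma_peak_intensity,
              background_level = background_level,
              illumination_amplitude = illumination_amplitude,
              noise_sigma = noise_sigma,
              contrast_compression = contrast_compression,
              seed = as.integer(seed))
  if (cfg$height < 8L || cfg$width < 8L) stop("frame too small", call. = FALSE)
  ints <- c(cfg$vessel_intensity, cfg$ma_peak_intensity, cfg$background_level)
  if (any(ints < 0 | ints > 255)) stop("intensities must be in [0, 255]", call. = FALSE)
  if (cfg$ma_peak_intensity <= cfg$background_level) {
    stop("ma_peak_intensity must exceed background_level", call. = FALSE)
  }
  if (cfg$contrast_compression <= 0 || cfg$contrast_compression > 1) {
    stop("contrast_compression must be in (0, 1]", call. = FALSE)
  }
  if (any(diff(cfg$ma_radius_range) < 0) || any(cfg$ma_radius_range <= 0)) {
    stop("ma_radius_range must be positive and non-decreasing", call. = FALSE)
  }
  structure(cfg, class = "scene_config")
}

#' Difficulty presets for the synthetic generator
#'
#' `"easy"`: bright high-contrast lesions, light noise, no contrast
#' compression — for smoke tests. `"hard"`: contrast compression 0.4, noise
#' sigma 8, lesions barely brighter than vessels — for ablation
#' demonstrations where preprocessing and the focal loss earn their keep.
#'
#' @param name `"easy"` or `"hard"`.
#' @param ... overrides passed on to [scene_config()].
#' @return A [scene_config()].
#' @export
scene_preset <- function(name = c("easy", "hard"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    easy = list(ma_peak_intensity = 255, vessel_intensity = 120,
                background_level = 25, noise_sigma = 2,
                illumination_amplitude = 5, contrast_compression = 1),
    hard = list(ma_peak_intensity = 200, vessel_intensity = 150,
                background_level = 40, noise_sigma = 8,
                illumination_amplitude = 10, contrast_compression = 0.4)
  )
  do.call(scene_config, utils::modifyList(base, list(...)))
}

# bilinear upsample of a coarse grid to H x W (illumination field)
bilinear_field <- function(grid, H, W) {
  gh <- nrow(grid); gw <- ncol(grid)
  ys <- seq(1, gh, length.out = H)
  xs <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(ys), gh - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), gw - 1L); fx <- xs - x0
  a <- grid[cbind(rep(y0, W), rep(x0, each = H))]
  b <- grid[cbind(rep(y0 + 1, W), rep(x0, each = H))]
  c_ <- grid[cbind(rep(y0, W), rep(x0 + 1, each = H))]
  d <- grid[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
  fyr <- rep(fy, W); fxr <- rep(fx, each = H)
  v <- a * (1 - fyr) * (1 - fxr) + b * fyr * (1 - fxr) +
    c_ * (1 - fyr) * fxr + d * fyr * fxr
  matrix(v, H, W)
}

# stamp a filled disc of `value` (or a radial profile) into img around
# (r0, c0) (1-based); returns the modified matrix
stamp_disc <- function(img, r0, c0, radius, value_fun) {
  H <- nrow(img); W <- ncol(img)
  rr <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
  for (i in rr) {
    dy2 <- (i - r0)^2
    for (j in cc) {
      d <- sqrt(dy2 + (j - c0)^2)
      if (d <= radius) img[i, j] <- max(img[i, j], value_fun(d))
    }
  }
  img
}

#' Generate one synthetic FFA frame with ground truth
#'
#' Deterministic given `cfg$seed`: background plus smooth illumination,
#' random curvilinear vessel strokes, microaneurysms as radially decaying
#' bright discs placed preferentially within 10 pixels of a vessel, additive
#' Gaussian noise, then global contrast compression toward mid-grey and
#' clipping to \[0, 255\]. The mask marks exactly the MA discs (a pixel is
#' inside a disc iff its centre lies within the Euclidean radius); vessels
#' are background class.
#'
#' @param cfg a [scene_config()].
#' @return A `synthetic_sample`: list with `image` ([gray_image]), `mask`
#'   ([mask_image]) and `ma_centers` (data frame of 0-based `row`, `col`,
#'   `radius`).
#' @examples
#' s <- generate_sample(scene_preset("easy", height = 64, width = 64, seed = 7))
#' s$image
#' s$mask
#' @export
generate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, generate_sample_impl(cfg))
}

generate_sample_impl <- function(cfg) {
  H <- cfg$height; W <- cfg$width
  img <- matrix(cfg$background_level, H, W)
  if (cfg$illumination_amplitude > 0) {
    grid <- matrix(stats::runif(16, -1, 1), 4, 4) * cfg$illumination_amplitude
    img <- img + bilinear_field(grid, H, W)
  }
  # vessels: smooth random walks stamped as discs of half-width
  vessel_px <- NULL
  if (cfg$n_vessels > 0) {
    vmask <- matrix(FALSE, H, W)
    for (v in seq_len(cfg$n_vessels)) {
      wdt <- stats::runif(1, cfg$vessel_width_range[1], cfg$vessel_width_range[2])
      side <- sample.int(4L, 1L)
      pos <- switch(side,
        c(1, stats::runif(1, 1, W)), c(H, stats::runif(1, 1, W)),
        c(stats::runif(1, 1, H), 1), c(stats::runif(1, 1, H), W))
      ang <- switch(side, pi / 2, -pi / 2, 0, pi) + stats::rnorm(1, 0, 0.4)
      for (s in seq_len(4L * max(H, W))) {
        pos <- pos + c(sin(ang), cos(ang))
        ang <- ang + stats::rnorm(1, 0, 0.08)
        if (pos[1] < 1 || pos[1] > H || pos[2] < 1 || pos[2] > W) break
        img <- stamp_disc(img, pos[1], pos[2], wdt / 2,
                          function(d) cfg$vessel_intensity)
        vmask[round(pos[1]), round(pos[2])] <- TRUE
      }
    }
    vessel_px <- which(vmask, arr.ind = TRUE)
  }
  # microaneurysms: bright discs, peak at centre decaying to half at the rim
  mask <- matrix(0L, H, W)
  centers <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (cfg$n_mas > 0) {
    for (m in seq_len(cfg$n_mas)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        radius <- stats::runif(1, cfg$ma_radius_range[1], cfg$ma_radius_range[2])
        if (!is.null(vessel_px) && nrow(vessel_px) > 0 && stats::runif(1) < 0.9) {
          vp <- vessel_px[sample.int(nrow(vessel_px), 1L), ]
          ctr <- vp + stats::runif(2, -10, 10)
        } else {
          ctr <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
        }
        pad <- ceiling(radius)
        if (ctr[1] < 1 + pad || ctr[1] > H - pad ||
            ctr[2] < 1 + pad || ctr[2] > W - pad) next
        if (nrow(centers) > 0) {
          dd <- sqrt((centers$row + 1 - ctr[1])^2 + (centers$col + 1 - ctr[2])^2)
          if (any(dd <= centers$radius + radius + 1)) next
        }
        peak <- cfg$ma_peak_intensity
        img <- stamp_disc(img, ctr[1], ctr[2], radius,
                          function(d) peak * (1 - 0.5 * (d / radius)^2))
        mask <- stamp_disc(mask, ctr[1], ctr[2], radius, function(d) 1L)
        centers <- rbind(centers, data.frame(row = ctr[1] - 1, col = ctr[2] - 1,
                                             radius = radius))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf("could not place microaneurysm %d without overlap", m),
             call. = FALSE)
      }
    }
  }
  if (cfg$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, cfg$noise_sigma), H, W)
  }
  img <- 128 + cfg$contrast_compression * (img - 128)
  img <- pmin(pmax(round_half_away(img), 0), 255)
  structure(list(image = gray_image(img), mask = mask_image(mask),
                 ma_centers = centers, config = cfg),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample %dx%d, %d MA(s), %d positive pixel(s)>\n",
              nrow(x$image), ncol(x$image), nrow(x$ma_centers), sum(x$mask)))
  invisible(x)
}

#' Generate a train/val/test dataset of synthetic FFA frames
#'
#' Writes paired PNGs (`NNN_img.png`, `NNN_mask.png`) under `train/`, `val/`
#' and `test/` subdirectories of `out_dir`, with disjoint per-sample seeds
#' drawn from the master seed, and a JSON manifest recording the scene
#' configuration and every per-sample seed — regenerating from those seeds
#' reproduces the dataset bit-identically.
#'
#' @param cfg a [scene_config()]; its `seed` is the master seed.
#' @param n_train,n_val,n_test split sizes (an 8:1:1 split mirrors common
#'   practice for this task).
#' @param out_dir output directory (created).
#' @return Invisibly, the manifest as a list.
#' @export
generate_dataset <- function(cfg, n_train, n_val, n_test, out_dir) {
  stopifnot(inherits(cfg, "scene_config"))
  n <- c(train = n_train, val = n_val, test = n_test)
  if (any(n < 0) || sum(n) == 0) {
    stop("split sizes must be >= 0 with at least one > 0", call. = FALSE)
  }
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, sum(n)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  k <- 0L
  for (split in names(n)) {
    sdir <- file.path(out_dir, split)
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(n[[split]])) {
      k <- k + 1L
      scfg <- cfg; scfg$seed <- seeds[k]
      s <- generate_sample(scfg)
      img_file <- file.path(split, sprintf("%03d_img.png", i))
      mask_file <- file.path(split, sprintf("%03d_mask.png", i))
      write_gray_image(s$image, file.path(out_dir, img_file))
      write_mask(s$mask, file.path(out_dir, mask_file))
      entries[[k]] <- list(split = split, image = img_file, mask = mask_file,
                           seed = seeds[k])
    }
  }
  manifest <- list(config = unclass(cfg), master_seed = cfg$seed,
                   counts = as.list(n), samples = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
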