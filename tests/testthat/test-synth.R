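test_that("generation is bit-identical under the same seed", {
  cfg <- scene_preset("easy", height = 64, width = 64, seed = 77)
  a <- generate_sample(cfg)
  b <- generate_sample(cfg)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(unclass(a$mask), unclass(b$mask))
  expect_identical(a$ma_centers, b$ma_centers)
  # a different seed changes the scene
  c <- generate_sample(scene_preset("easy", height = 64, width = 64, seed = 78))
  expect_false(identical(unclass(a$image), unclass(c$image)))
})

test_that("an empty scene is a constant frame with an all-zero mask", {
  cfg <- scene_config(height = 32, width = 32, n_mas = 0, n_vessels = 0,
                      noise_sigma = 0, contrast_compression = 1,
                      illumination_amplitude = 0, background_level = 30)
  s <- generate_sample(cfg)
  expect_true(all(s$image == 30))
  expect_equal(sum(s$mask), 0)
  expect_equal(nrow(s$ma_centers), 0)
})

test_that("masks mark exactly the listed discs, fully inside the frame", {
  cfg <- scene_config(height = 128, width = 128, n_mas = 5,
                      ma_radius_range = c(2, 3), n_vessels = 2,
                      noise_sigma = 0, seed = 55)
  s <- generate_sample(cfg)
  comp <- disc_components(unclass(s$mask))
  expect_equal(length(comp), 5)
  # disc areas for radii 2-3 under centre-in-radius rasterization
  expect_true(all(vapply(comp, length, integer(1)) >= 9))
  expect_true(all(vapply(comp, length, integer(1)) <= 29))
  # mask pixel 1 iff within some listed disc (0-based centres)
  want <- matrix(0L, 128, 128)
  for (k in seq_len(nrow(s$ma_centers))) {
    ctr <- s$ma_centers[k, ]
    expect_gte(ctr$row - ctr$radius, 0)
    expect_lte(ctr$row + ctr$radius, 127)
    expect_gte(ctr$col - ctr$radius, 0)
    expect_lte(ctr$col + ctr$radius, 127)
    for (i in 1:128) for (j in 1:128) {
      if ((i - 1 - ctr$row)^2 + (j - 1 - ctr$col)^2 <= ctr$radius^2) {
        want[i, j] <- 1L
      }
    }
  }
  expect_identical(unclass(s$mask), want)
})

test_that("the default scene is heavily imbalanced toward background", {
  fracs <- vapply(1:50, function(s) {
    mean(generate_sample(scene_config(seed = 1000 + s))$mask)
  }, numeric(1))
  expect_lt(mean(fracs), 0.01)   # under 1% lesion pixels on average
})

test_that("contrast compression monotonically reduces lesion contrast", {
  peak_contrast <- function(cc) {
    vals <- vapply(1:8, function(s) {
      smp <- generate_sample(scene_config(contrast_compression = cc,
                                          noise_sigma = 0, seed = 300 + s))
      img <- unclass(smp$image)
      mean(vapply(seq_len(nrow(smp$ma_centers)), function(k) {
        r0 <- smp$ma_centers$row[k] + 1; c0 <- smp$ma_centers$col[k] + 1
        img[round(r0), round(c0)] - mean(img[smp$mask == 0])
      }, numeric(1)))
    }, numeric(1))
    mean(vals)
  }
  cs <- vapply(c(1, 0.7, 0.4), peak_contrast, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("datasets follow the split protocol and regenerate identically", {
  dir <- withr::local_tempdir()
  cfg <- scene_preset("easy", height = 32, width = 32, n_mas = 2,
                      n_vessels = 1, seed = 21)
  man <- generate_dataset(cfg, 8, 1, 1, dir)
  expect_length(list.files(file.path(dir, "train"), pattern = "_img"), 8)
  expect_length(list.files(file.path(dir, "val"), pattern = "_img"), 1)
  expect_length(list.files(file.path(dir, "test"), pattern = "_img"), 1)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # per-sample seeds are disjoint and regenerate the exact pixels
  seeds <- vapply(man$samples, `[[`, integer(1), "seed")
  expect_equal(anyDuplicated(seeds), 0)
  for (k in c(1, 10)) {
    scfg <- cfg; scfg$seed <- seeds[k]
    s <- generate_sample(scfg)
    on_disk <- read_gray_image(file.path(dir, man$samples[[k]]$image))
    expect_identical(unclass(on_disk), unclass(s$image) * 1.0 + 0)
  }
  # single-split call writes only that split
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, 0, 0, 1, dir2)
  expect_length(list.files(file.path(dir2, "test"), pattern = "_img"), 1)
  expect_length(list.files(file.path(dir2, "train")), 0)
  expect_error(generate_dataset(cfg, 0, 0, 0, withr::local_tempdir()),
               "at least one")
})

test_that("scene configuration rejects inconsistent intensity settings", {
  expect_error(scene_config(ma_peak_intensity = 20, background_level = 30),
               "exceed")
  expect_error(scene_config(contrast_compression = 0), "0, 1")
  expect_error(scene_config(ma_radius_range = c(3, 2)), "non-decreasing")
})
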