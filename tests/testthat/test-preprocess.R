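test_that("histogram stretching matches the linear map with rounding", {
  img <- gray_image(matrix(c(50, 100, 150, 50), 2, 2))
  out <- histogram_stretch(img, stretch_config(0, 255))
  # 100 maps to 127.5, which rounds half away from zero to 128
  expect_equal(sort(unique(as.vector(out))), c(0, 128, 255))
  # full-range input with default targets is the identity
  full <- gray_image(matrix(c(0, 255, 17, 203), 2, 2))
  expect_equal(unclass(histogram_stretch(full)), unclass(full) * 1.0)
  # constant frame: degenerate-input error (zero denominator)
  expect_error(histogram_stretch(gray_image(matrix(7, 3, 3))),
               class = "mafcdn_degenerate_input")
})

test_that("stretching is monotone and hits both endpoints", {
  set.seed(21)
  for (rep in 1:20) {
    img <- random_gray(sample(2:20, 1), sample(2:20, 1))
    if (min(img) == max(img)) next
    cfg <- stretch_config(sample(0:100, 1), sample(150:255, 1))
    out <- histogram_stretch(img, cfg)
    expect_equal(min(out), cfg$g_min)
    expect_equal(max(out), cfg$g_max)
    # order preservation: i <= j in input implies out_i <= out_j
    o <- order(as.vector(unclass(img)))
    expect_true(all(diff(as.vector(unclass(out))[o]) >= 0))
  }
})

test_that("the Gaussian kernel matches direct evaluation of the exponential", {
  k <- gaussian_kernel(gaussian_config(sigma = 1, kernel_size = 3))
  raw <- matrix(c(exp(-1), exp(-0.5), exp(-1),
                  exp(-0.5), 1, exp(-0.5),
                  exp(-1), exp(-0.5), exp(-1)), 3, 3)
  expect_equal(k, raw / sum(raw), tolerance = 1e-15)
  expect_equal(sum(k), 1, tolerance = 1e-15)
  expect_equal(k, t(k))                         # 4-fold symmetry
  expect_equal(k, k[3:1, ])
  # flat limit at large sigma
  flat <- gaussian_kernel(gaussian_config(sigma = 1e6, kernel_size = 3))
  expect_equal(as.vector(flat), rep(1 / 9, 9), tolerance = 1e-9)
  # one-element kernel normalizes to 1
  expect_equal(gaussian_kernel(gaussian_config(0.5, 1)), matrix(1, 1, 1))
  expect_error(gaussian_config(sigma = 1, kernel_size = 4), "odd")
  expect_error(gaussian_config(sigma = 0), "positive")
})

test_that("Gaussian filtering reproduces the kernel on an impulse and fixes constants", {
  imp <- matrix(0, 9, 9); imp[5, 5] <- 255
  out <- gaussian_filter(gray_image(imp), gaussian_config(1, 3))
  k <- gaussian_kernel(gaussian_config(1, 3))
  expect_equal(unclass(out)[4:6, 4:6],
               sign(k * 255) * floor(abs(k * 255) + 0.5))
  expect_true(all(unclass(out)[-(4:6), ] == 0))
  # constant image is a fixed point (kernel sums to 1)
  const <- gray_image(matrix(100, 8, 8))
  expect_equal(as.matrix(gaussian_filter(const, gaussian_config(2))),
               matrix(100, 8, 8))
  # identity kernel
  img <- random_gray(6, 6)
  expect_equal(unclass(gaussian_filter(img, gaussian_config(0.001, 1))),
               unclass(img) * 1.0)
})

test_that("filtering matches the nested-loop reflect-padding oracle exactly", {
  set.seed(31)
  for (rep in 1:12) {
    h <- sample(1:16, 1); w <- sample(1:16, 1)
    img <- random_gray(h, w)
    cfg <- gaussian_config(sigma = stats::runif(1, 0.5, 2),
                           kernel_size = sample(c(1, 3, 5), 1))
    got <- gaussian_filter(img, cfg)
    want <- oracle_conv_reflect(unclass(img) * 1.0, gaussian_kernel(cfg))
    want <- pmin(pmax(sign(want) * floor(abs(want) + 0.5), 0), 255)
    expect_equal(as.matrix(got), want, info = sprintf("%dx%d rep %d", h, w, rep))
  }
})

test_that("filtering preserves the mean and never widens the range", {
  set.seed(41)
  for (rep in 1:10) {
    img <- random_gray(24, 24)
    out <- gaussian_filter(img, gaussian_config(stats::runif(1, 0.5, 1.2)))
    # mean preserved up to rounding and mild border mirroring
    expect_lt(abs(mean(out) - mean(img)), 2)
    expect_gte(min(out), min(img) - 1)
    expect_lte(max(out), max(img) + 1)
  }
})

test_that("the pipeline is stretch-then-filter and propagates degeneracy", {
  img <- random_gray(8, 8)
  if (min(img) == max(img)) img[1, 1] <- (img[1, 1] + 1) %% 256
  staged <- gaussian_filter(histogram_stretch(img, stretch_config()),
                            gaussian_config(1, 3))
  expect_equal(unclass(preprocess_image(img, stretch_config(),
                                        gaussian_config(1, 3))),
               unclass(staged))
  expect_error(preprocess_image(gray_image(matrix(9, 4, 4))),
               class = "mafcdn_degenerate_input")
})

test_that("directory preprocessing passes constant frames through with a note", {
  ind <- withr::local_tempdir(); outd <- withr::local_tempdir()
  write_gray_image(random_gray(8, 8), file.path(ind, "a.png"))
  write_gray_image(gray_image(matrix(50, 8, 8)), file.path(ind, "blank.png"))
  expect_message(log <- preprocess_dir(ind, outd), "pass-through")
  expect_setequal(list.files(outd), c("a.png", "blank.png"))
  expect_true(log$passthrough[log$file == "blank.png"])
  expect_false(log$passthrough[log$file == "a.png"])
  expect_true(all(read_gray_image(file.path(outd, "blank.png")) == 50))
})
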