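test_that("training runs, logs per epoch, and checkpoints round-trip", {
  data_dir <- withr::local_tempdir()
  make_micro_dataset(data_dir)
  out_dir <- withr::local_tempdir()
  fit <- fcdn_train(data_dir, micro_run_config(), out_dir = out_dir)
  expect_s3_class(fit, "fcdn_fit")
  expect_equal(nrow(fit$log), 2)
  expect_named(fit$log, c("epoch", "lr", "train_loss", "val_miou"))
  expect_true(all(file.exists(file.path(out_dir,
    c("epochs.csv", "run_config.json", "checkpoint.rds",
      "checkpoint_final.rds")))))
  # a restored checkpoint reproduces the validation MIoU of the fit
  ck <- load_checkpoint(file.path(out_dir, "checkpoint.rds"))
  val <- mafcdn:::load_split(data_dir, "val")
  miou <- mean(vapply(val, function(p) {
    pred <- predict(ck, p$image)
    compute_metrics(confusion_table(pred, p$mask))$MIoU
  }, numeric(1)))
  expect_equal(miou, fit$best_val_miou, tolerance = 1e-6)
})

test_that("identical config and data give identical runs", {
  data_dir <- withr::local_tempdir()
  make_micro_dataset(data_dir)
  f1 <- fcdn_train(data_dir, micro_run_config(epochs = 1))
  f2 <- fcdn_train(data_dir, micro_run_config(epochs = 1))
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_identical(f1$log$val_miou, f2$log$val_miou)
  # and a different seed gives a different epoch-1 loss
  f3 <- fcdn_train(data_dir, micro_run_config(epochs = 1, seed = 10))
  expect_false(identical(f1$log$train_loss, f3$log$train_loss))
})

test_that("training validates its inputs", {
  data_dir <- withr::local_tempdir()
  make_micro_dataset(data_dir, n_train = 2, n_val = 1, n_test = 0)
  expect_error(run_config(epochs = 0), "epochs")
  empty <- withr::local_tempdir()
  expect_error(fcdn_train(empty, micro_run_config()), "empty split")
  # orphaned image file is named in the error
  file.remove(file.path(data_dir, "train", "001_mask.png"))
  expect_error(fcdn_train(data_dir, micro_run_config()), "001_img")
})

test_that("prediction writes aligned binary masks deterministically", {
  data_dir <- withr::local_tempdir()
  make_micro_dataset(data_dir)
  fit <- fcdn_train(data_dir, micro_run_config())
  p1 <- withr::local_tempdir(); p2 <- withr::local_tempdir()
  predict_masks(fit, file.path(data_dir, "test"), p1)
  predict_masks(fit, file.path(data_dir, "test"), p2)
  files <- list.files(p1)
  expect_length(files, 4)
  for (f in files) {
    m <- png::readPNG(file.path(p1, f))
    expect_true(all(m %in% c(0, 1)))            # {0, 255} on the 8-bit scale
    expect_equal(dim(m), c(32, 32))
    expect_identical(m, png::readPNG(file.path(p2, f)))
  }
  # probability output is a valid map of the input size
  img <- read_gray_image(file.path(data_dir, "test", "001_img.png"))
  pm <- predict(fit, img, type = "prob")
  expect_s3_class(pm, "prob_map")
  expect_equal(dim(pm)[1:2], dim(img))
  # a constant frame passes through preprocessing and still predicts
  expect_message(msk <- predict(fit, gray_image(matrix(40, 32, 32))),
                 "pass-through")
  expect_s3_class(msk, "mask_image")
  # frames not divisible by the stride are reflect-padded then cropped back
  odd <- gray_image(matrix(sample(0:255, 33 * 35, TRUE), 33, 35))
  expect_equal(dim(predict(fit, odd)), c(33L, 35L))
})

test_that("directory evaluation matches hand-computed reports", {
  pd <- withr::local_tempdir(); td <- withr::local_tempdir()
  # self-comparison: everything is exactly 1
  set.seed(3)
  m <- mask_image(matrix(stats::rbinom(64, 1, 0.2), 8, 8))
  write_mask(m, file.path(pd, "a_mask.png"))
  write_mask(m, file.path(td, "a_mask.png"))
  ev <- evaluate_masks(pd, td)
  expect_true(all(ev$summary$mean == 1))
  expect_true(all(ev$summary$sd == 0))
  # the worked 2x2 table, reconstructed from pixels
  pred <- matrix(0, 10, 10); pred[1, 1:5] <- 1; pred[2, 1:2] <- 1
  truth <- matrix(0, 10, 10); truth[2, 1:5] <- 1
  # truth-row sums: [[90, 5], [3, 2]]
  write_mask(mask_image(pred), file.path(pd, "b_mask.png"))
  write_mask(mask_image(truth), file.path(td, "b_mask.png"))
  ev2 <- evaluate_masks(pd, td, out_dir = file.path(pd, "rep"))
  row <- ev2$per_image[ev2$per_image$file == "b_mask.png", ]
  expect_equal(row$PA, 0.92, tolerance = 1e-12)
  expect_equal(row$MIoU, (90 / 98 + 2 / 10) / 2, tolerance = 1e-12)
  expect_true(file.exists(file.path(pd, "rep", "metrics.csv")))
  expect_true(file.exists(file.path(pd, "rep", "metrics.json")))
  # orphans are listed
  write_mask(m, file.path(pd, "orphan_mask.png"))
  expect_error(evaluate_masks(pd, td), "orphan")
})

test_that("run configs survive the JSON round trip", {
  cfg <- run_config(model = "tiny", loss = "cross_entropy",
                    focal = focal_config(0.4, gamma = 1.5),
                    preprocess = FALSE, epochs = 7, seed = 42,
                    optimizer = list(lr = 5e-4))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(mafcdn:::serialize_run_config(cfg), f,
                       auto_unbox = TRUE, digits = NA)
  back <- read_run_config(f)
  expect_equal(back, cfg)
})
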