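#' Training run configuration
#'
#' Everything needed to launch (or exactly re-launch) a training run: the
#' architecture, the pixel loss, the preprocessing stage, the optimizer and
#' the master seed. The object is fully serializable; [fcdn_train()] writes
#' it alongside its artifacts so a run can be reproduced from disk.
#'
#' @param model an [arch_config()] or preset name (see [fcdn_preset()]).
#' @param loss `"focal"` or `"cross_entropy"`.
#' @param focal a [focal_config()] (used when `loss = "focal"`).
#' @param preprocess logical: apply [preprocess_image()] to every frame
#'   before training/inference (constant frames pass through with a message).
#' @param stretch,gaussian preprocessing stage configurations.
#' @param optimizer list with `lr` (initial learning rate), `rho` (RMSprop
#'   decay), `eps`, and `lr_decay` (per-epoch exponential decay).
#' @param epochs training epochs (>= 1).
#' @param patience early-stopping patience on validation MIoU, in epochs.
#' @param seed master seed: weight init, shuffling and dropout all derive
#'   from it, so identical config + data give identical runs.
#' @return A `run_config` object.
#' @export
run_config <- function(model = fcdn_preset("tiny"),
                       loss = c("focal", "cross_entropy"),
                       focal = focal_config(),
                       preprocess = TRUE,
                       stretch = stretch_config(),
                       gaussian = gaussian_config(),
                       optimizer = list(lr = 1e-3, rho = 0.9, eps = 1e-8,
                                        lr_decay = 0.995),
                       epochs = 15L, patience = 20L, seed = 1L) {
  if (is.character(model)) model <- fcdn_preset(model)
  loss <- match.arg(loss)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  opt <- utils::modifyList(list(lr = 1e-3, rho = 0.9, eps = 1e-8,
                                lr_decay = 0.995), optimizer)
  structure(list(model = model, loss = loss, focal = focal,
                 preprocess = isTRUE(preprocess), stretch = stretch,
                 gaussian = gaussian, optimizer = opt, epochs = epochs,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "run_config")
}

loss_cfg_of <- function(config) {
  if (config$loss == "focal") config$focal
  else focal_config(alpha_ma = 1, alpha_bg = 1, gamma = 0)
}

# Apply the configured preprocessing to one frame, passing constant frames
# through (with a message) instead of failing.
apply_preprocess <- function(img, config) {
  if (!config$preprocess) return(img)
  tryCatch(preprocess_image(img, config$stretch, config$gaussian),
           mafcdn_degenerate_input = function(e) {
             message("pass-through: constant frame cannot be stretched")
             img
           })
}

# mirror-pad a matrix to (H2, W2), keeping the original at the top-left
pad_reflect_to <- function(m, H2, W2) {
  ridx <- vapply(0:(H2 - 1), function(s) {
    n <- nrow(m); if (n == 1) return(1L)
    per <- 2L * (n - 1L); s <- s %% per
    as.integer(if (s >= n) per - s else s) + 1L
  }, integer(1))
  cidx <- vapply(0:(W2 - 1), function(s) {
    n <- ncol(m); if (n == 1) return(1L)
    per <- 2L * (n - 1L); s <- s %% per
    as.integer(if (s >= n) per - s else s) + 1L
  }, integer(1))
  m[ridx, cidx, drop = FALSE]
}

# Load image/mask pairs of one split: files NNN_img.png with NNN_mask.png.
load_split <- function(data_dir, split) {
  sdir <- file.path(data_dir, split)
  imgs <- sort(list.files(sdir, pattern = "_img\\.png$"))
  if (length(imgs) == 0) {
    stop(sprintf("empty split: no *_img.png files in %s", sdir), call. = FALSE)
  }
  lapply(imgs, function(f) {
    mf <- sub("_img\\.png$", "_mask.png", f)
    if (!file.exists(file.path(sdir, mf))) {
      stop(sprintf("image/mask pair broken: %s has no %s", f, mf), call. = FALSE)
    }
    img <- read_gray_image(file.path(sdir, f))
    mask <- read_mask(file.path(sdir, mf))
    check_same_dim(img, mask, sprintf("image and mask (%s)", f))
    list(name = f, image = img, mask = mask)
  })
}

# Crop (training) to the largest size divisible by 2^depth, centred.
crop_divisible <- function(m, div) {
  H <- nrow(m); W <- ncol(m)
  H2 <- (H %/% div) * div; W2 <- (W %/% div) * div
  if (H2 < div || W2 < div) {
    stop(sprintf("frame %dx%d smaller than the network stride %d", H, W, div),
         call. = FALSE)
  }
  r0 <- (H - H2) %/% 2; c0 <- (W - W2) %/% 2
  m[(r0 + 1):(r0 + H2), (c0 + 1):(c0 + W2), drop = FALSE]
}

prepare_pair <- function(pair, config, div) {
  img <- apply_preprocess(pair$image, config)
  x <- unclass(img) / 255
  y <- unclass(pair$mask)
  if (nrow(x) %% div != 0 || ncol(x) %% div != 0) {
    x <- crop_divisible(x, div); y <- crop_divisible(y, div)
  }
  list(x = x, y = y)
}

#' Train an FC-DenseNet on an image/mask dataset
#'
#' Fits the configured network by per-frame stochastic gradient descent
#' (RMSprop) on the configured pixel loss, evaluating validation MIoU after
#' every epoch and keeping the best-by-validation-MIoU weights. The run is
#' deterministic given the config and data. Frames whose size is not a
#' multiple of the network stride are centre-cropped at training time.
#'
#' @param data_dir directory containing `train/` and `val/` subdirectories
#'   of `NNN_img.png` / `NNN_mask.png` pairs (see [generate_dataset()]).
#' @param config a [run_config()].
#' @param out_dir optional artifact directory: writes `epochs.csv`,
#'   `run_config.json`, `checkpoint.rds` (best) and `checkpoint_final.rds`.
#' @param verbose print a line per epoch.
#' @return An `fcdn_fit`: the fitted model (best weights), with the resolved
#'   config, the per-epoch log, and the channel trace. Methods: `print`,
#'   `summary`, `predict`, `plot`.
#' @seealso [predict.fcdn_fit()], [evaluate_masks()], [run_ablation()]
#' @export
fcdn_train <- function(data_dir, config = run_config(), out_dir = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  train <- load_split(data_dir, "train")
  val <- load_split(data_dir, "val")
  div <- 2L^length(config$model$down_block_layers)
  train_xy <- lapply(train, prepare_pair, config = config, div = div)
  val_xy <- lapply(val, prepare_pair, config = config, div = div)
  losscfg <- loss_cfg_of(config)
  opt <- config$optimizer

  fit <- with_seed(config$seed, {
    net <- build_fcdn(config$model, in_channels = 1L)
    s <- tree_map1(net$params, function(x) x * 0)
    log <- data.frame(epoch = integer(0), lr = numeric(0),
                      train_loss = numeric(0), val_miou = numeric(0))
    best <- list(miou = -Inf, epoch = 0L, params = net$params)
    for (epoch in seq_len(config$epochs)) {
      lr <- opt$lr * opt$lr_decay^(epoch - 1)
      order <- sample.int(length(train_xy))
      total <- 0
      for (i in order) {
        fw <- fcdn_forward_full(net, train_xy[[i]]$x, train = TRUE,
                                keep_cache = TRUE)
        lg <- loss_value_grad(fw$probs, train_xy[[i]]$y, losscfg)
        total <- total + lg$value
        g <- fcdn_backward(net, fw$cache, lg$dlogits)
        s <- tree_map2(s, g, function(sv, gv) opt$rho * sv + (1 - opt$rho) * gv^2)
        net$params <- tree_map3(net$params, g, s, function(pv, gv, sv) {
          pv - lr * gv / (sqrt(sv) + opt$eps)
        })
      }
      vm <- mean(vapply(val_xy, function(p) {
        fw <- fcdn_forward_full(net, p$x, train = FALSE, keep_cache = FALSE)
        pred <- (fw$probs[, , 2] > fw$probs[, , 1]) * 1L
        compute_metrics(confusion_table(pred, p$y))$MIoU
      }, numeric(1)))
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_loss = total / length(train_xy),
                                   val_miou = vm))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.5f  val MIoU %.4f",
                        epoch, lr, total / length(train_xy), vm))
      }
      if (vm > best$miou) best <- list(miou = vm, epoch = epoch,
                                       params = net$params)
      if (epoch - best$epoch >= config$patience) break
    }
    list(net = net, log = log, best = best)
  })

  out <- structure(list(
    config = config,
    params = fit$best$params,
    final_params = fit$net$params,
    trace = fit$net$trace,
    in_channels = 1L,
    log = fit$log,
    best_val_miou = fit$best$miou,
    best_epoch = fit$best$epoch
  ), class = "fcdn_fit")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format(fit$log, digits = 15),
                     file.path(out_dir, "epochs.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(serialize_run_config(config),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
    save_checkpoint(out, file.path(out_dir, "checkpoint.rds"))
    final <- out; final$params <- out$final_params
    save_checkpoint(final, file.path(out_dir, "checkpoint_final.rds"))
  }
  out
}

serialize_run_config <- function(config) {
  list(model = unclass(config$model), loss = config$loss,
       focal = unclass(config$focal), preprocess = config$preprocess,
       stretch = unclass(config$stretch), gaussian = unclass(config$gaussian),
       optimizer = config$optimizer, epochs = config$epochs,
       patience = config$patience, seed = config$seed)
}

#' Restore a run configuration from its JSON snapshot
#'
#' @param path path to a `run_config.json` written by [fcdn_train()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    model = arch_config(j$model$variant_name, j$model$first_conv_channels,
                        j$model$growth_rate, j$model$down_block_layers,
                        j$model$bottleneck_layers, j$model$up_block_layers,
                        j$model$dropout_p, j$model$num_classes),
    loss = j$loss,
    focal = focal_config(j$focal$alpha_ma, j$focal$alpha_bg, j$focal$gamma),
    preprocess = j$preprocess,
    stretch = stretch_config(j$stretch$g_min, j$stretch$g_max),
    gaussian = gaussian_config(j$gaussian$sigma, j$gaussian$kernel_size),
    optimizer = j$optimizer, epochs = j$epochs, patience = j$patience,
    seed = j$seed)
}

#' Save / load a self-describing checkpoint
#'
#' A checkpoint is a single file holding the weights together with the full
#' run configuration (architecture, loss, preprocessing), so prediction and
#' evaluation never need the original config file.
#'
#' @param fit an `fcdn_fit`.
#' @param path checkpoint file path.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: an
#'   `fcdn_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "fcdn_fit"))
  saveRDS(list(format = "mafcdn-checkpoint-1",
               config = serialize_run_config(fit$config),
               params = fit$params, in_channels = fit$in_channels,
               log = fit$log, best_val_miou = fit$best_val_miou,
               best_epoch = fit$best_epoch), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "mafcdn-checkpoint-1")) {
    stop(sprintf("not a recognised checkpoint: %s", path), call. = FALSE)
  }
  cfgj <- tempfile(fileext = ".json")
  on.exit(unlink(cfgj))
  jsonlite::write_json(ck$config, cfgj, auto_unbox = TRUE, digits = NA)
  config <- read_run_config(cfgj)
  structure(list(config = config, params = ck$params,
                 final_params = ck$params,
                 trace = NULL, in_channels = ck$in_channels, log = ck$log,
                 best_val_miou = ck$best_val_miou, best_epoch = ck$best_epoch),
            class = "fcdn_fit")
}

as_network <- function(fit) {
  structure(list(config = fit$config$model, in_channels = fit$in_channels,
                 params = fit$params, trace = fit$trace),
            class = "fcdn_network")
}

#' Predict a microaneurysm mask for one frame
#'
#' Applies the checkpoint's stored preprocessing (if the run was trained
#' with preprocessing enabled; constant frames pass through), reflect-pads
#' the frame to the next multiple of the network stride if needed, runs a
#' deterministic forward pass and decodes by per-pixel argmax.
#'
#' @param object an `fcdn_fit`.
#' @param newdata a [gray_image] (or matrix of 8-bit intensities).
#' @param type `"mask"` (argmax decoding) or `"prob"` (the [prob_map]).
#' @param ... unused.
#' @return A [mask_image] or [prob_map] of the input's spatial size.
#' @export
predict.fcdn_fit <- function(object, newdata, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "gray_image")) newdata <- gray_image(newdata)
  img <- apply_preprocess(newdata, object$config)
  x <- unclass(img) / 255
  H <- nrow(x); W <- ncol(x)
  div <- 2L^length(object$config$model$down_block_layers)
  H2 <- ceiling(H / div) * div; W2 <- ceiling(W / div) * div
  if (H2 != H || W2 != W) x <- pad_reflect_to(x, H2, W2)
  fw <- fcdn_forward_full(as_network(object), x, train = FALSE,
                          keep_cache = FALSE)
  probs <- fw$probs[1:H, 1:W, , drop = FALSE]
  if (type == "prob") return(prob_map(probs))
  mask_image((probs[, , 2] > probs[, , 1]) * 1L)
}

#' Predict masks for a directory of frames
#'
#' Runs [predict.fcdn_fit()] on every `*_img.png` (or any PNG not ending in
#' `_mask.png`) in `images_dir` and writes one binary {0, 255} mask PNG per
#' input to `out_dir`, named with `_img` replaced by `_mask` so predictions
#' pair directly with ground-truth files for [evaluate_masks()].
#'
#' @param fit an `fcdn_fit` or path to a checkpoint file.
#' @param images_dir input directory.
#' @param out_dir output directory (created).
#' @return Invisibly, the vector of written paths.
#' @export
predict_masks <- function(fit, images_dir, out_dir) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  stopifnot(inherits(fit, "fcdn_fit"))
  files <- sort(grep("_mask\\.png$",
                     list.files(images_dir, pattern = "\\.png$"),
                     value = TRUE, invert = TRUE))
  if (length(files) == 0) stop(sprintf("no input PNGs in %s", images_dir),
                               call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(length(files))
  for (i in seq_along(files)) {
    img <- read_gray_image(file.path(images_dir, files[i]))
    mask <- predict(fit, img)
    out_name <- if (grepl("_img\\.png$", files[i])) {
      sub("_img\\.png$", "_mask.png", files[i])
    } else files[i]
    written[i] <- file.path(out_dir, out_name)
    write_mask(mask, written[i])
  }
  invisible(written)
}

#' @export
print.fcdn_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<fcdn_fit '%s', loss %s, preprocessing %s>\n",
    "  epochs run: %d  best val MIoU: %.4f (epoch %d)\n"),
    x$config$model$variant_name, x$config$loss,
    if (x$config$preprocess) "on" else "off",
    nrow(x$log), x$best_val_miou, x$best_epoch))
  invisible(x)
}

#' @export
summary.fcdn_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  trainable parameters: %s\n",
              format(fcdn_param_count(object), big.mark = ",")))
  cat("  last epochs:\n")
  print(utils::tail(object$log, 3), row.names = FALSE)
  invisible(object)
}

#' Plot training curves of a fitted network
#'
#' Training loss and validation MIoU per epoch, base graphics.
#'
#' @param x an `fcdn_fit`.
#' @param ... passed to `plot`.
#' @export
plot.fcdn_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$log$epoch, x$log$train_loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "training loss", main = "loss", ...)
  plot(x$log$epoch, x$log$val_miou, type = "b", pch = 16,
       xlab = "epoch", ylab = "validation MIoU", main = "val MIoU", ...)
  invisible(x)
}

#' Default three-arm ablation grid
#'
#' The classic design isolating the two ingredients: preprocessing with the
#' plain cross-entropy loss, the focal loss without preprocessing, and the
#' full pipeline (preprocessing + focal loss). All arms share the data split
#' and master seed; only the named deltas differ.
#'
#' @return A list of arm descriptors (`name`, `preprocess`, `loss`).
#' @export
ablation_grid <- function() {
  list(list(name = "preprocess_ce", preprocess = TRUE, loss = "cross_entropy"),
       list(name = "focal_only", preprocess = FALSE, loss = "focal"),
       list(name = "full", preprocess = TRUE, loss = "focal"))
}

#' Run an ablation grid
#'
#' Trains and evaluates each arm on the same data and master seed, predicts
#' the held-out `test/` split, and emits a comparison table (rows = arms,
#' columns = the six metrics as mean +/- sd over test frames) as
#' `ablation.csv` and `ablation.json` under `out_dir`. A failing arm is
#' marked failed rather than aborting the grid.
#'
#' @param grid an arm list as from [ablation_grid()].
#' @param data_dir dataset directory with `train/`, `val/` and `test/`.
#' @param out_dir output directory; each arm writes its artifacts under
#'   `out_dir/<arm name>/`.
#' @param base_config the shared [run_config()]; each arm overrides only its
#'   `preprocess` and `loss` fields.
#' @return A data frame, one row per arm, with `<metric>_mean` and
#'   `<metric>_sd` columns and a `failed` flag.
#' @export
run_ablation <- function(grid = ablation_grid(), data_dir, out_dir,
                         base_config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(grid))
  for (a in seq_along(grid)) {
    arm <- grid[[a]]
    cfg <- base_config
    cfg$preprocess <- isTRUE(arm$preprocess)
    cfg$loss <- arm$loss
    arm_dir <- file.path(out_dir, arm$name)
    rows[[a]] <- tryCatch({
      fit <- fcdn_train(data_dir, cfg, out_dir = arm_dir)
      predict_masks(fit, file.path(data_dir, "test"),
                    file.path(arm_dir, "pred"))
      truth_dir <- file.path(arm_dir, "truth")
      dir.create(truth_dir, showWarnings = FALSE)
      tf <- list.files(file.path(data_dir, "test"), pattern = "_mask\\.png$")
      file.copy(file.path(data_dir, "test", tf), file.path(truth_dir, tf),
                overwrite = TRUE)
      ev <- evaluate_masks(file.path(arm_dir, "pred"), truth_dir,
                           out_dir = arm_dir)
      mu <- ev$summary$mean; sd <- ev$summary$sd
      data.frame(arm = arm$name, failed = FALSE,
                 t(stats::setNames(mu, paste0(names(mu), "_mean"))),
                 t(stats::setNames(sd, paste0(names(sd), "_sd"))))
    }, error = function(e) {
      warning(sprintf("arm '%s' failed: %s", arm$name, conditionMessage(e)),
              call. = FALSE)
      nm <- c("PA", "MPA", "Pre", "Re", "F1", "MIoU")
      data.frame(arm = arm$name, failed = TRUE,
                 t(stats::setNames(rep(NA_real_, 6), paste0(nm, "_mean"))),
                 t(stats::setNames(rep(NA_real_, 6), paste0(nm, "_sd"))))
    })
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "ablation.csv"), row.names = FALSE)
  jsonlite::write_json(tab, file.path(out_dir, "ablation.json"),
                       auto_unbox = TRUE, digits = NA)
  tab
}
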