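# Independent oracles used across the suite. These are deliberately written
# from the definitions (closed forms, explicit loops), not by calling the
# package's own implementation paths.

# ---- architecture accounting -------------------------------------------

# Closed-form per-stage channel counts from the connectivity rules:
# down-path dense blocks concatenate input with output (input + L*g maps),
# up-path dense blocks forward only their L*g new maps.
oracle_channel_trace <- function(cfg, in_channels = 1L) {
  g <- cfg$growth_rate
  stage <- c("input", "initial_conv")
  channels <- c(in_channels, cfg$first_conv_channels)
  ch <- cfg$first_conv_channels
  skips <- integer(0)
  for (i in seq_along(cfg$down_block_layers)) {
    ch <- ch + cfg$down_block_layers[i] * g
    skips <- c(skips, ch)
    stage <- c(stage, sprintf("down_block_%d", i), sprintf("transition_down_%d", i))
    channels <- c(channels, ch, ch)
  }
  new <- cfg$bottleneck_layers * g
  stage <- c(stage, "bottleneck_new"); channels <- c(channels, new)
  nb <- length(cfg$up_block_layers)
  for (j in seq_len(nb)) {
    tu_ch <- new                      # TU keeps the forwarded map count
    concat <- tu_ch + skips[nb + 1L - j]
    new <- cfg$up_block_layers[j] * g
    stage <- c(stage, sprintf("transition_up_%d", j), sprintf("up_concat_%d", j),
               sprintf("up_block_%d_new", j))
    channels <- c(channels, tu_ch, concat, new)
  }
  stage <- c(stage, "logits"); channels <- c(channels, cfg$num_classes)
  data.frame(stage = stage, channels = as.integer(channels))
}

# Closed-form trainable parameter count: k x k convolution = k^2*cin*cout
# weights + cout biases; normalization = 2 scalars per input channel.
oracle_param_count <- function(cfg, in_channels = 1L) {
  g <- cfg$growth_rate
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  bn <- function(c) 2 * c
  total <- conv(3, in_channels, cfg$first_conv_channels)
  ch <- cfg$first_conv_channels
  skips <- integer(0)
  for (L in cfg$down_block_layers) {
    for (l in seq_len(L)) {
      cin <- ch + (l - 1) * g
      total <- total + bn(cin) + conv(3, cin, g)
    }
    ch <- ch + L * g
    skips <- c(skips, ch)
    total <- total + bn(ch) + conv(1, ch, ch)
  }
  for (l in seq_len(cfg$bottleneck_layers)) {
    cin <- ch + (l - 1) * g
    total <- total + bn(cin) + conv(3, cin, g)
  }
  new <- cfg$bottleneck_layers * g
  nb <- length(cfg$up_block_layers)
  for (j in seq_len(nb)) {
    total <- total + conv(3, new, new)           # transition up
    cin0 <- new + skips[nb + 1L - j]
    L <- cfg$up_block_layers[j]
    for (l in seq_len(L)) {
      cin <- cin0 + (l - 1) * g
      total <- total + bn(cin) + conv(3, cin, g)
    }
    new <- L * g
  }
  total + conv(1, new, cfg$num_classes)
}

# ---- metrics -----------------------------------------------------------

# Brute-force six metrics by explicit loops over the class indices of the
# defining sums, with the package's stated degenerate-frame conventions.
oracle_metrics <- function(p) {
  k <- nrow(p) - 1
  total <- sum(p)
  diag_sum <- 0
  for (i in 0:k) diag_sum <- diag_sum + p[i + 1, i + 1]
  PA <- diag_sum / total
  MPA <- 0
  for (i in 0:k) {
    denom <- 0
    for (j in 0:k) denom <- denom + p[i + 1, j + 1]
    MPA <- MPA + (if (denom == 0) 1 else p[i + 1, i + 1] / denom)
  }
  MPA <- MPA / (k + 1)
  TP <- p[2, 2]; FP <- p[1, 2]; FN <- p[2, 1]
  Pre <- if (TP + FP == 0) as.numeric(TP + FN == 0) else TP / (TP + FP)
  Re <- if (TP + FN == 0) as.numeric(TP + FP == 0) else TP / (TP + FN)
  F1 <- if (Pre + Re == 0) 0 else 2 * Pre * Re / (Pre + Re)
  MIoU <- 0
  for (i in 0:k) {
    denom <- -p[i + 1, i + 1]
    for (j in 0:k) denom <- denom + p[i + 1, j + 1] + p[j + 1, i + 1]
    MIoU <- MIoU + (if (denom == 0) 1 else p[i + 1, i + 1] / denom)
  }
  MIoU <- MIoU / (k + 1)
  list(PA = PA, MPA = MPA, Pre = Pre, Re = Re, F1 = F1, MIoU = MIoU)
}

# ---- convolution -------------------------------------------------------

# Nested-loop 2-D correlation with mirror padding (edge not repeated).
oracle_conv_reflect <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  refl <- function(s, n) {
    if (n == 1) return(1)
    per <- 2 * (n - 1)
    s <- ((s - 1) %% per)
    if (s < 0) s <- s + per
    if (s >= n) per - s + 1 else s + 1
  }
  out <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      acc <- 0
      for (a in 1:kh) {
        for (b in 1:kw) {
          si <- refl(i + a - 1 - ph, H)
          sj <- refl(j + b - 1 - pw, W)
          acc <- acc + kernel[a, b] * img[si, sj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# ---- random fixtures ---------------------------------------------------

random_prob_mask <- function(h, w) {
  p2 <- matrix(stats::runif(h * w, 0.001, 0.999), h, w)
  pred <- prob_map(array(c(1 - p2, p2), c(h, w, 2)))
  truth <- mask_image(matrix(stats::rbinom(h * w, 1, 0.3), h, w))
  list(pred = pred, truth = truth)
}

random_gray <- function(h, w) {
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

# Desk-scale synthetic dataset shared by harness tests.
make_micro_dataset <- function(dir, n_train = 10, n_val = 4, n_test = 4,
                               size = 32, seed = 5) {
  generate_dataset(
    scene_preset("easy", height = size, width = size, n_mas = 2,
                 n_vessels = 1, seed = seed),
    n_train = n_train, n_val = n_val, n_test = n_test, out_dir = dir)
}

micro_run_config <- function(epochs = 2, seed = 9, ...) {
  run_config(model = "tiny", loss = "focal", epochs = epochs, seed = seed, ...)
}

# 8-connected components of a binary matrix, as lists of pixel indices.
disc_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- list()
  nxt <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] == 1 && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i, j)); lab[i, j] <- nxt
        px <- integer(0)
        while (length(queue) > 0) {
          q <- queue[[1]]; queue <- queue[-1]
          px <- c(px, (q[2] - 1L) * nrow(m) + q[1])
          for (di in -1:1) for (dj in -1:1) {
            a <- q[1] + di; b <- q[2] + dj
            if (a >= 1 && a <= nrow(m) && b >= 1 && b <= ncol(m) &&
                m[a, b] == 1 && lab[a, b] == 0L) {
              lab[a, b] <- nxt
              queue <- c(queue, list(c(a, b)))
            }
          }
        }
        comp[[nxt]] <- px
      }
    }
  }
  comp
}
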