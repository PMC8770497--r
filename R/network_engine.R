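# FC-DenseNet engine: parameter initialization, forward pass with caches,
# and backpropagation. Activations are H x W x C numeric arrays; convolution
# weights are flat (k*k*Cin) x Cout matrices (layout fixed by src/kernels.cpp).
# Batch normalization uses per-sample spatial statistics in both training and
# inference (batch-size-1 training), which makes inference fully deterministic.

BN_EPS <- 1e-5

conv_init <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))  # He-uniform for ReLU stacks
  list(W = matrix(stats::runif(k * k * cin * cout, -lim, lim),
                  k * k * cin, cout),
       b = rep(0, cout))
}

dense_layer_init <- function(cin, growth) {
  cv <- conv_init(3, cin, growth)
  list(gamma = rep(1, cin), beta = rep(0, cin), W = cv$W, b = cv$b)
}

td_init <- function(ch) {
  cv <- conv_init(1, ch, ch)
  list(gamma = rep(1, ch), beta = rep(0, ch), W = cv$W, b = cv$b)
}

#' Build an FC-DenseNet segmentation network
#'
#' Allocates and initializes (He-uniform, seeded) all trainable parameters of
#' the configured variant and derives its channel trace from the allocated
#' weight shapes. The network is an untrained handle; see [fcdn_train()] for
#' fitting and [fcdn_forward()] for inference.
#'
#' @param cfg an [arch_config()] or preset name accepted by [fcdn_preset()].
#' @param in_channels input image channels (1 for grayscale FFA).
#' @param seed integer seed for weight initialization (RNG state restored
#'   afterwards); `NULL` uses the current RNG state.
#' @return An object of class `fcdn_network` with elements `config`,
#'   `in_channels`, `params` and `trace` (a data frame of per-stage feature
#'   map counts).
#' @examples
#' net <- build_fcdn(fcdn_preset("tiny"), seed = 1)
#' net$trace
#' fcdn_param_count(net)
#' @export
build_fcdn <- function(cfg, in_channels = 1L, seed = NULL) {
  if (is.character(cfg)) cfg <- fcdn_preset(cfg)
  stopifnot(inherits(cfg, "arch_config"))
  params <- with_seed(seed, init_fcdn_params(cfg, in_channels))
  structure(list(config = cfg, in_channels = as.integer(in_channels),
                 params = params, trace = fcdn_trace_from_params(params, cfg,
                                                                 in_channels)),
            class = "fcdn_network")
}

init_fcdn_params <- function(cfg, in_channels) {
  g <- cfg$growth_rate
  p <- list()
  p$conv0 <- conv_init(3, in_channels, cfg$first_conv_channels)
  ch <- cfg$first_conv_channels
  p$down <- vector("list", length(cfg$down_block_layers))
  for (i in seq_along(cfg$down_block_layers)) {
    L <- cfg$down_block_layers[i]
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      layers[[l]] <- dense_layer_init(ch + (l - 1L) * g, g)
    }
    ch <- ch + L * g
    p$down[[i]] <- list(layers = layers, td = td_init(ch))
  }
  layers <- vector("list", cfg$bottleneck_layers)
  for (l in seq_len(cfg$bottleneck_layers)) {
    layers[[l]] <- dense_layer_init(ch + (l - 1L) * g, g)
  }
  p$bottleneck <- list(layers = layers)
  # skip channel counts, innermost last
  skip_ch <- cfg$first_conv_channels + cumsum(cfg$down_block_layers * g)
  new_ch <- cfg$bottleneck_layers * g
  p$up <- vector("list", length(cfg$up_block_layers))
  for (j in seq_along(cfg$up_block_layers)) {
    L <- cfg$up_block_layers[j]
    tu <- conv_init(3, new_ch, new_ch)  # TU keeps the forwarded map count
    ch <- new_ch + skip_ch[length(skip_ch) + 1L - j]
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      layers[[l]] <- dense_layer_init(ch + (l - 1L) * g, g)
    }
    new_ch <- L * g
    p$up[[j]] <- list(tu = tu, layers = layers)
  }
  p$final <- conv_init(1, new_ch, cfg$num_classes)
  p
}

# Channel trace recomputed from the allocated weight shapes (not from the
# config arithmetic), so the trace reflects what was actually built.
fcdn_trace_from_params <- function(params, cfg, in_channels) {
  g <- cfg$growth_rate
  stage <- character(0); channels <- integer(0)
  add <- function(s, c) {
    stage <<- c(stage, s); channels <<- c(channels, as.integer(c))
  }
  add("input", in_channels)
  add("initial_conv", ncol(params$conv0$W))
  for (i in seq_along(params$down)) {
    lay <- params$down[[i]]$layers
    cin_last <- nrow(lay[[length(lay)]]$W) / 9L
    add(sprintf("down_block_%d", i), cin_last + ncol(lay[[length(lay)]]$W))
    add(sprintf("transition_down_%d", i), ncol(params$down[[i]]$td$W))
  }
  bl <- params$bottleneck$layers
  add("bottleneck_new", length(bl) * ncol(bl[[1]]$W))
  for (j in seq_along(params$up)) {
    add(sprintf("transition_up_%d", j), ncol(params$up[[j]]$tu$W))
    lay <- params$up[[j]]$layers
    add(sprintf("up_concat_%d", j), nrow(lay[[1]]$W) / 9L)
    add(sprintf("up_block_%d_new", j), length(lay) * ncol(lay[[1]]$W))
  }
  add("logits", ncol(params$final$W))
  data.frame(stage = stage, channels = channels)
}

#' Trainable parameter count of a built network
#'
#' @param net an `fcdn_network` or `fcdn_fit`.
#' @return Total number of trainable scalars (convolution weights and biases,
#'   normalization scale and shift).
#' @export
fcdn_param_count <- function(net) {
  p <- if (inherits(net, "fcdn_fit")) net$params else net$params
  tree_length(p)
}

#' @export
print.fcdn_network <- function(x, ...) {
  cat(sprintf("<fcdn_network '%s': %s trainable parameters, %d-stage trace>\n",
              x$config$variant_name,
              format(fcdn_param_count(x), big.mark = ","), nrow(x$trace)))
  invisible(x)
}

## ---- elementary ops ----------------------------------------------------

# Per-channel normalization + affine + ReLU, fused on the flat vector with
# rep(each = hw) broadcasting; dims are preserved through the arithmetic.
bn_relu_fwd <- function(x, gamma, beta) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]
  mu <- .colMeans(x, hw, C)
  xc <- x - rep(mu, each = hw)
  v <- .colMeans(xc * xc, hw, C)
  istd <- 1 / sqrt(v + BN_EPS)
  xn <- xc * rep(istd, each = hw)
  y <- xn * rep(gamma, each = hw) + rep(beta, each = hw)
  relu <- y > 0
  list(out = y * relu,
       cache = list(xn = xn, istd = istd, relu = relu, dim = d))
}

bn_relu_bwd <- function(dy, cache, gamma) {
  d <- cache$dim; hw <- d[1] * d[2]; C <- d[3]
  dy <- dy * cache$relu
  dgamma <- .colSums(dy * cache$xn, hw, C)
  dbeta <- .colSums(dy, hw, C)
  dxn <- dy * rep(gamma, each = hw)
  t1 <- .colSums(dxn, hw, C)
  t2 <- .colSums(dxn * cache$xn, hw, C)
  dx <- (dxn - rep(t1 / hw, each = hw) -
           cache$xn * rep(t2 / hw, each = hw)) * rep(cache$istd, each = hw)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  m <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
  list(out = x * m, mask = m)
}

## ---- composite layers --------------------------------------------------

dense_layer_fwd <- function(x, pars, train, p_drop) {
  br <- bn_relu_fwd(x, pars$gamma, pars$beta)
  y <- conv2d_fwd(br$out, pars$W, pars$b, 3L, 1L)
  dp <- dropout_fwd(y, p_drop, train)
  list(out = dp$out,
       cache = list(br = br$cache, act = br$out, mask = dp$mask))
}

dense_layer_bwd <- function(dy, cache, pars) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  cb <- conv2d_bwd(cache$act, pars$W, dy, 3L, 1L)
  bb <- bn_relu_bwd(cb$dx, cache$br, pars$gamma)
  list(dx = bb$dx,
       grads = list(gamma = bb$dgamma, beta = bb$dbeta,
                    W = cb$dW, b = as.numeric(cb$db)))
}

db_fwd <- function(x, layers, g, train, p_drop, concat_input) {
  d <- dim(x); C0 <- d[3]; L <- length(layers)
  stack <- x
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    r <- dense_layer_fwd(stack, layers[[l]], train, p_drop)
    caches[[l]] <- r$cache
    Cs <- dim(stack)[3]
    stack <- c(stack, r$out)
    dim(stack) <- c(d[1], d[2], Cs + g)
  }
  out <- if (concat_input) stack else
    stack[, , (C0 + 1L):(C0 + L * g), drop = FALSE]
  list(out = out, cache = list(layers = caches, C0 = C0, L = L, dim = d))
}

db_bwd <- function(dout, cache, layers, g, concat_input) {
  d <- cache$dim; C0 <- cache$C0; L <- cache$L
  Cfin <- C0 + L * g
  if (concat_input) {
    dstack <- dout
  } else {
    dstack <- array(0, c(d[1], d[2], Cfin))
    dstack[, , (C0 + 1L):Cfin] <- dout
  }
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    Cl <- C0 + (l - 1L) * g
    dnew <- dstack[, , (Cl + 1L):(Cl + g), drop = FALSE]
    r <- dense_layer_bwd(dnew, cache$layers[[l]], layers[[l]])
    dstack <- dstack[, , 1:Cl, drop = FALSE] + r$dx
    grads[[l]] <- r$grads
  }
  list(dx = dstack, grads = grads)
}

td_fwd <- function(x, pars, train, p_drop) {
  br <- bn_relu_fwd(x, pars$gamma, pars$beta)
  y <- conv2d_fwd(br$out, pars$W, pars$b, 1L, 0L)
  dp <- dropout_fwd(y, p_drop, train)
  mp <- maxpool2_fwd(dp$out)
  list(out = mp$y,
       cache = list(br = br$cache, act = br$out, mask = dp$mask,
                    idx = mp$idx, dim = dim(x)))
}

td_bwd <- function(dy, cache, pars) {
  d <- cache$dim
  dup <- maxpool2_bwd(dy, cache$idx, d[1], d[2])
  if (!is.null(cache$mask)) dup <- dup * cache$mask
  cb <- conv2d_bwd(cache$act, pars$W, dup, 1L, 0L)
  bb <- bn_relu_bwd(cb$dx, cache$br, pars$gamma)
  list(dx = bb$dx,
       grads = list(gamma = bb$dgamma, beta = bb$dbeta,
                    W = cb$dW, b = as.numeric(cb$db)))
}

## ---- full network ------------------------------------------------------

# Input coercion: gray_image (8-bit or unit) or plain matrix/array to an
# H x W x C array on the unit scale.
as_input_array <- function(x, in_channels) {
  if (inherits(x, "gray_image")) {
    v <- unclass(x)
    if (identical(attr(x, "scale"), "8bit")) v <- v / 255
    x <- v
  }
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != in_channels) {
    stop(sprintf("input must be H x W x %d", in_channels), call. = FALSE)
  }
  x
}

#' Forward pass of an FC-DenseNet
#'
#' Runs the network on one frame and returns the per-pixel class probability
#' map (softmax over the class channels). Inference is deterministic:
#' dropout is inactive unless `train = TRUE`.
#'
#' @param net an `fcdn_network` (or `fcdn_fit`).
#' @param x input: a [gray_image], unit-scale matrix, or H x W x C array.
#'   Height and width must be divisible by `2^length(down_block_layers)`.
#' @param train logical; enables dropout and gradient caching.
#' @return A [prob_map] (train mode: an internal list with caches).
#' @export
fcdn_forward <- function(net, x, train = FALSE) {
  r <- fcdn_forward_full(net, x, train = train, keep_cache = FALSE)
  prob_map(r$probs)
}

fcdn_forward_full <- function(net, x, train = FALSE, keep_cache = train) {
  cfg <- net$config; p <- net$params; g <- cfg$growth_rate
  x <- as_input_array(x, net$in_channels)
  d <- dim(x)
  div <- 2L^length(cfg$down_block_layers)
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop(sprintf("input %dx%d: height and width must be divisible by %d",
                 d[1], d[2], div), call. = FALSE)
  }
  pd <- cfg$dropout_p
  cache <- if (keep_cache) list(x = x) else NULL

  stack <- conv2d_fwd(x, p$conv0$W, p$conv0$b, 3L, 1L)
  skips <- vector("list", length(p$down))
  down_caches <- vector("list", length(p$down))
  td_caches <- vector("list", length(p$down))
  for (i in seq_along(p$down)) {
    r <- db_fwd(stack, p$down[[i]]$layers, g, train, pd, concat_input = TRUE)
    skips[[i]] <- r$out
    if (keep_cache) down_caches[[i]] <- r$cache
    r2 <- td_fwd(r$out, p$down[[i]]$td, train, pd)
    stack <- r2$out
    if (keep_cache) td_caches[[i]] <- r2$cache
  }
  rb <- db_fwd(stack, p$bottleneck$layers, g, train, pd, concat_input = FALSE)
  new <- rb$out
  if (keep_cache) cache$bottleneck <- rb$cache
  nb <- length(p$up)
  up_caches <- vector("list", nb)
  tu_inputs <- vector("list", nb)
  for (j in seq_len(nb)) {
    tu_inputs[[j]] <- new
    up <- convt2d_fwd(new, p$up[[j]]$tu$W, p$up[[j]]$tu$b)
    skip <- skips[[nb + 1L - j]]
    du <- dim(up)
    stk <- c(up, skip)
    dim(stk) <- c(du[1], du[2], du[3] + dim(skip)[3])
    r <- db_fwd(stk, p$up[[j]]$layers, g, train, pd, concat_input = FALSE)
    new <- r$out
    if (keep_cache) up_caches[[j]] <- list(db = r$cache, tu_out_ch = du[3])
  }
  logits <- conv2d_fwd(new, p$final$W, p$final$b, 1L, 0L)
  if (keep_cache) {
    cache$down <- down_caches; cache$td <- td_caches
    cache$up <- up_caches; cache$tu_inputs <- tu_inputs
    cache$final_in <- new
  }
  # stable per-pixel softmax over the class channels
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m); e2 <- exp(logits[, , 2] - m)
  s <- e1 + e2
  probs <- array(c(e1 / s, e2 / s), dim(logits))
  list(probs = probs, logits = logits, cache = cache)
}

# Backpropagate d(loss)/d(logits) through the cached forward pass; returns a
# gradient tree mirroring net$params.
fcdn_backward <- function(net, cache, dlogits) {
  cfg <- net$config; p <- net$params; g <- cfg$growth_rate
  grads <- list()
  cb <- conv2d_bwd(cache$final_in, p$final$W, dlogits, 1L, 0L)
  grads$final <- list(W = cb$dW, b = as.numeric(cb$db))
  dnew <- cb$dx
  nb <- length(p$up)
  grads$up <- vector("list", nb)
  dskips <- vector("list", nb)
  for (j in rev(seq_len(nb))) {
    uc <- cache$up[[j]]
    r <- db_bwd(dnew, uc$db, p$up[[j]]$layers, g, concat_input = FALSE)
    tu_ch <- uc$tu_out_ch
    dstk <- r$dx
    dup <- dstk[, , 1:tu_ch, drop = FALSE]
    dskips[[nb + 1L - j]] <- dstk[, , (tu_ch + 1L):dim(dstk)[3], drop = FALSE]
    tb <- convt2d_bwd(cache$tu_inputs[[j]], p$up[[j]]$tu$W, dup)
    grads$up[[j]] <- list(tu = list(W = tb$dW, b = as.numeric(tb$db)),
                          layers = r$grads)
    dnew <- tb$dx
  }
  r <- db_bwd(dnew, cache$bottleneck, p$bottleneck$layers, g,
              concat_input = FALSE)
  grads$bottleneck <- list(layers = r$grads)
  dstack <- r$dx
  grads$down <- vector("list", length(p$down))
  for (i in rev(seq_along(p$down))) {
    rt <- td_bwd(dstack, cache$td[[i]], p$down[[i]]$td)
    dskip_total <- rt$dx + dskips[[i]]
    rd <- db_bwd(dskip_total, cache$down[[i]], p$down[[i]]$layers, g,
                 concat_input = TRUE)
    dstack <- rd$dx
    grads$down[[i]] <- list(layers = rd$grads, td = rt$grads)
  }
  cb0 <- conv2d_bwd(cache$x, p$conv0$W, dstack, 3L, 1L)
  grads$conv0 <- list(W = cb0$dW, b = as.numeric(cb0$db))
  # reorder to match the params tree exactly
  grads[names(p)]
}
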