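#' FC-DenseNet architecture configuration
#'
#' Structural description of a fully convolutional DenseNet variant. The
#' down-sampling path alternates dense blocks (DB) with transition-down (TD)
#' layers; after a bottleneck dense block, the up-sampling path alternates
#' transition-up (TU) layers with dense blocks. Connectivity is asymmetric:
#' a down-path dense block concatenates its input with its output (feature
#' maps grow linearly by `growth_rate` per layer), whereas an up-path dense
#' block forwards only the new feature maps it produces.
#'
#' @param variant_name label for the variant.
#' @param first_conv_channels feature maps of the initial 3x3 convolution.
#' @param growth_rate new feature maps added by each dense layer.
#' @param down_block_layers integer vector: dense layers per down-path block.
#' @param bottleneck_layers dense layers in the bottleneck block.
#' @param up_block_layers integer vector: dense layers per up-path block;
#'   must mirror `down_block_layers` in length.
#' @param dropout_p dropout probability in \[0, 1); 0.2 in the named presets.
#' @param num_classes output classes (2: background, microaneurysm).
#' @return An `arch_config` object.
#' @seealso [fcdn_preset()], [build_fcdn()]
#' @export
arch_config <- function(variant_name = "custom",
                        first_conv_channels = 16L,
                        growth_rate = 8L,
                        down_block_layers = c(2L, 2L),
                        bottleneck_layers = 2L,
                        up_block_layers = rev(down_block_layers),
                        dropout_p = 0,
                        num_classes = 2L) {
  down_block_layers <- as.integer(down_block_layers)
  up_block_layers <- as.integer(up_block_layers)
  if (length(down_block_layers) != length(up_block_layers)) {
    stop("down and up paths must have the same number of blocks", call. = FALSE)
  }
  if (any(c(down_block_layers, up_block_layers, bottleneck_layers) < 1L)) {
    stop("all block layer counts must be >= 1", call. = FALSE)
  }
  if (growth_rate < 1L || first_conv_channels < 1L) {
    stop("growth_rate and first_conv_channels must be >= 1", call. = FALSE)
  }
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("dropout_p must be in [0, 1)", call. = FALSE)
  }
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  structure(list(
    variant_name = variant_name,
    first_conv_channels = as.integer(first_conv_channels),
    growth_rate = as.integer(growth_rate),
    down_block_layers = down_block_layers,
    bottleneck_layers = as.integer(bottleneck_layers),
    up_block_layers = up_block_layers,
    dropout_p = dropout_p,
    num_classes = as.integer(num_classes)
  ), class = "arch_config")
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<arch_config '%s'>\n  first conv: %d  growth: %d  dropout: %g\n",
    "  down blocks: [%s]  bottleneck: %d  up blocks: [%s]\n"),
    x$variant_name, x$first_conv_channels, x$growth_rate, x$dropout_p,
    paste(x$down_block_layers, collapse = ","), x$bottleneck_layers,
    paste(x$up_block_layers, collapse = ",")))
  invisible(x)
}

#' Standard FC-DenseNet presets
#'
#' Returns the configuration of the named variant, following the reference
#' design of the original FC-DenseNet family: `FC-DenseNet56` (4 layers per
#' dense block, growth 12), `FC-DenseNet67` (5 layers per block, growth 16),
#' `FC-DenseNet103` (down blocks 4,5,7,10,12, bottleneck 15, up blocks
#' 12,10,7,5,4, growth 16). All use a 48-channel first convolution, dropout
#' 0.2 and 2 output classes. `"tiny"` is a desk-scale variant for CPU smoke
#' runs.
#'
#' @param name one of `"FC-DenseNet56"`, `"FC-DenseNet67"`,
#'   `"FC-DenseNet103"`, `"tiny"`.
#' @return An [arch_config()].
#' @export
fcdn_preset <- function(name) {
  presets <- c("FC-DenseNet56", "FC-DenseNet67", "FC-DenseNet103", "tiny")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 as.character(name)[1], paste(presets, collapse = ", ")),
         call. = FALSE)
  }
  switch(name,
    "FC-DenseNet56" = arch_config(name, 48L, 12L, rep(4L, 5), 4L, rep(4L, 5),
                                  dropout_p = 0.2),
    "FC-DenseNet67" = arch_config(name, 48L, 16L, rep(5L, 5), 5L, rep(5L, 5),
                                  dropout_p = 0.2),
    "FC-DenseNet103" = arch_config(name, 48L, 16L,
                                   c(4L, 5L, 7L, 10L, 12L), 15L,
                                   c(12L, 10L, 7L, 5L, 4L), dropout_p = 0.2),
    "tiny" = arch_config("tiny", 16L, 8L, c(2L, 2L), 2L, c(2L, 2L),
                         dropout_p = 0)
  )
}
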