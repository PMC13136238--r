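# Four-stage hybrid attention encoder. Stages 0-1 use squeeze-and-excitation
# channel recalibration (low-level texture/edge features); stages 2-3 use CBAM
# channel + spatial attention. Each stage: two 3x3 conv + group norm + ReLU,
# attention, then 2x average-pool downsampling, giving pyramid strides
# 2/4/8/16. Skip features are taken after attention (and after pooling, i.e.
# the pyramid maps themselves feed the decoder).

#' Encoder configuration
#'
#' @param in_channels Number of input image channels (grayscale ultrasound: 1).
#' @param stage_channels Integer vector of 4 strictly increasing channel
#'   widths, one per stage.
#' @param se_reduction Bottleneck reduction of the SE blocks; must divide the
#'   stage-0 and stage-1 channel widths.
#' @param cbam_kernel Odd kernel size of the CBAM spatial-attention conv.
#' @param attention If `FALSE`, all attention blocks are skipped and the
#'   encoder reduces to a plain convolutional downsampler (ablation switch).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(in_channels = 1,
                           stage_channels = c(16, 32, 64, 128),
                           se_reduction = 4,
                           cbam_kernel = 7,
                           attention = TRUE) {
  stopifnot(length(stage_channels) == 4,
            all(diff(stage_channels) > 0),
            stage_channels[1] %% se_reduction == 0,
            stage_channels[2] %% se_reduction == 0,
            cbam_kernel %% 2 == 1)
  structure(list(in_channels = in_channels, stage_channels = stage_channels,
                 se_reduction = se_reduction, cbam_kernel = cbam_kernel,
                 attention = attention),
            class = "encoder_config")
}

new_encoder <- function(cfg) {
  sc <- cfg$stage_channels
  cin <- c(cfg$in_channels, sc[1:3])
  stages <- vector("list", 4)
  for (i in 1:4) {
    st <- list(block = new_conv_block(cin[i], sc[i]))
    if (cfg$attention) {
      st$attn <- if (i <= 2) new_se(sc[i], cfg$se_reduction)
                 else new_cbam(sc[i], spatial_k = cfg$cbam_kernel)
    }
    stages[[i]] <- st
  }
  stages
}

fwd_encoder <- function(tape, x, enc, cfg) {
  out <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    h <- fwd_conv_block(tape, h, enc[[i]]$block)
    if (cfg$attention) {
      h <- if (i <= 2) fwd_se(tape, h, enc[[i]]$attn)
           else fwd_cbam(tape, h, enc[[i]]$attn)
    }
    h <- ag_avgpool2(tape, h)
    out[[i]] <- h
  }
  names(out) <- c("s0", "s1", "s2", "s3")
  out
}

#' Multi-scale feature extraction
#'
#' Runs the hybrid SE/CBAM encoder on a single grayscale image and returns
#' the four pyramid feature maps at strides 2/4/8/16.
#'
#' @param image Numeric matrix in `[0, 1]`; height and width must be
#'   divisible by 16.
#' @param model A model built by [espd_model()], or `NULL` to build a fresh
#'   randomly initialized encoder from `config`.
#' @param config An [encoder_config()]; ignored when `model` is supplied.
#' @return Named list `s0`..`s3` of arrays `(H/2^k, W/2^k, C_k)`.
#' @export
encode <- function(image, model = NULL, config = encoder_config()) {
  image <- as.matrix(image)
  if (nrow(image) %% 16 != 0 || ncol(image) %% 16 != 0) {
    stop("image height and width must be divisible by 16, got ",
         nrow(image), "x", ncol(image))
  }
  if (!is.null(model)) {
    enc <- model$params$encoder
    config <- model$config$encoder
  } else {
    enc <- new_encoder(config)
  }
  tape <- ag_tape()
  x <- ag_const(array(image, c(nrow(image), ncol(image), config$in_channels)))
  lapply(fwd_encoder(tape, x, enc, config), ag_val)
}
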