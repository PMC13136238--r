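# Model assembly: configuration, construction, forward pass, checkpoints.

#' Model configuration
#'
#' Bundles the encoder, bottleneck, decoder and refiner hyperparameters.
#' The `tiny` profile (64 px inputs, 16/32/64/128 encoder channels) is the
#' desk-scale test profile; `full` matches the 320 px training protocol
#' (32/64/128/256 channels).
#'
#' @param profile `"tiny"` or `"full"`.
#' @param variant One of `"espd_full"`, `"softmax_baseline"`, `"no_dbar"`,
#'   `"no_degd"`, `"no_spdf"`. The softmax baseline shares the encoder and
#'   bottleneck but decodes with a plain softmax head and no evidential
#'   machinery, and is trained with Dice + Focal only.
#' @param input_size Input image side length (divisible by 16).
#' @param window Attention window of the probabilistic path and of the
#'   Dirichlet cross-attention.
#' @param dbar_iterations Number of gated residual refinement iterations.
#' @param encoder_attention Ablation switch; `FALSE` strips SE/CBAM.
#' @return A list of class `espd_config`.
#' @export
espd_config <- function(profile = c("tiny", "full"),
                        variant = c("espd_full", "softmax_baseline",
                                    "no_dbar", "no_degd", "no_spdf"),
                        input_size = NULL,
                        window = 4,
                        dbar_iterations = 2,
                        encoder_attention = TRUE) {
  profile <- match.arg(profile)
  variant <- match.arg(variant)
  sc <- if (profile == "tiny") c(16, 32, 64, 128) else c(32, 64, 128, 256)
  input_size <- input_size %||% (if (profile == "tiny") 64 else 320)
  stopifnot(input_size %% 16 == 0)
  structure(list(
    profile = profile,
    variant = variant,
    input_size = input_size,
    encoder = encoder_config(stage_channels = sc,
                             se_reduction = if (profile == "tiny") 4 else 8,
                             attention = encoder_attention),
    spdf = spdf_config(window = window),
    bottleneck_channels = sc[4],
    decoder_channels = if (profile == "tiny") c(64, 48, 32, 16)
                       else c(128, 96, 64, 32),
    skip_red = if (profile == "tiny") c(32, 16, 8) else c(64, 32, 16),
    cross_attn_channels = 8,
    dbar_iterations = dbar_iterations,
    evidential = variant %in% c("espd_full", "no_dbar", "no_spdf"),
    use_spdf = variant != "no_spdf",
    use_dbar = variant %in% c("espd_full", "no_degd", "no_spdf")
  ), class = "espd_config")
}

#' Build a model with randomly initialized weights
#'
#' @param config An [espd_config()].
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `espd_model` holding the parameter tree and
#'   the configuration.
#' @export
espd_model <- function(config = espd_config(), seed = 0) {
  with_local_seed(seed, {
    sc <- config$encoder$stage_channels
    params <- list(encoder = new_encoder(config$encoder))
    params$bottleneck <- if (config$use_spdf) {
      new_spdf(sc[3], sc[4], config$bottleneck_channels, config$spdf)
    } else {
      new_plain_bottleneck(sc[3], config$bottleneck_channels)
    }
    params$decoder <- new_degd(config)
    if (config$use_dbar) {
      params$dbar <- new_dbar(config$bottleneck_channels,
                              config$decoder_channels[4])
    }
    structure(list(params = params, config = config, seed = seed),
              class = "espd_model")
  })
}

#' @export
print.espd_model <- function(x, ...) {
  cat("<espd_model> variant:", x$config$variant,
      "profile:", x$config$profile,
      "parameters:", n_parameters(x), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model An `espd_model`.
#' @return Integer number of scalar weights.
#' @export
n_parameters <- function(model) {
  sum(vapply(ag_collect_params(model$params), function(p) length(p$val),
             numeric(1)))
}

# Full forward pass on one image. Returns tape nodes so the caller can
# attach losses; use ag_val() (or espd_predict) for plain arrays.
model_forward <- function(model, image, tape = ag_tape()) {
  cfg <- model$config
  p <- model$params
  h <- nrow(image)
  x <- ag_const(array(image, c(h, ncol(image), 1)))
  pyr <- fwd_encoder(tape, x, p$encoder, cfg$encoder)
  if (cfg$use_spdf) {
    sp <- fwd_spdf(tape, pyr$s2, pyr$s3, p$bottleneck)
    s_final <- sp$s_final
  } else {
    sp <- NULL
    s_final <- fwd_plain_bottleneck(tape, pyr$s2, p$bottleneck)
  }

  # edges are needed both by the decoder's Dirichlet attention and by DBAR
  if (cfg$use_dbar) {
    sob <- cpp_sobel(image)
    sob_n <- array(sob / max(sob, 1e-8), c(dim(sob), 1))
    e_sem <- fwd_semantic_edges(tape, s_final, p$dbar, h)
    e_boundary <- fwd_fuse_edges(tape, sob_n, e_sem, p$dbar)
  } else {
    e_boundary <- ag_const(array(0, c(h, ncol(image), 1)))
    e_sem <- NULL
  }

  dec <- if (cfg$evidential) {
    fwd_degd(tape, pyr, s_final, e_boundary, p$decoder, cfg)
  } else {
    fwd_softmax_decoder(tape, pyr, s_final, p$decoder, cfg)
  }

  out <- list(tape = tape, pyramid = pyr, spdf = sp, s_final = s_final,
              m_coarse = dec$m_coarse, u_full = dec$u_full,
              fields = dec$fields, e_boundary = e_boundary, e_sem = e_sem)
  if (cfg$use_dbar) {
    ref <- fwd_dbar_from_edges(tape, image, dec, s_final, e_boundary, p$dbar,
                               cfg$dbar_iterations)
    out$m_refined <- ref$m_refined
    out$a_boundary <- ref$a_boundary
    out$e_sobel <- ref$e_sobel
  } else {
    out$m_refined <- dec$m_coarse
    out$a_boundary <- NULL
  }
  out
}

# DBAR forward when the fused edge map already exists
fwd_dbar_from_edges <- function(tape, image, dec, s_final, e_boundary, p,
                                iterations) {
  hw <- nrow(image)
  sob <- cpp_sobel(image)
  featup <- fwd_upsample_to(tape, fwd_conv(tape, dec$feat0, p$featproj), hw)
  base <- ag_relu(tape, fwd_conv(tape, ag_concat_c(tape, list(
    ag_const(array(image, c(dim(sob), 1))), e_boundary, featup)), p$base))
  m <- dec$m_coarse
  a_boundary <- NULL
  for (it in seq_len(iterations)) {
    a_boundary <- fwd_boundary_attention(tape, dec$u_full, m, e_boundary, p)
    hh <- ag_relu(tape, fwd_conv(tape,
      ag_concat_c(tape, list(base, m, a_boundary)), p$ref1))
    delta <- ag_tanh(tape, fwd_conv(tape, hh, p$ref2))
    m <- ag_clamp01(tape, ag_add(tape, m, ag_mul(tape, a_boundary, delta)))
  }
  list(m_refined = m, a_boundary = a_boundary, e_sobel = sob)
}

#' Segment a single image
#'
#' Runs the full forward pass and returns plain arrays: the coarse and
#' refined foreground-probability masks, the per-pixel epistemic uncertainty
#' map (evidential variants) or predictive entropy (softmax variants), the
#' fused edge map, and the per-scale uncertainty pyramid.
#'
#' @param model An `espd_model` (typically a trained `fit$model`).
#' @param image Numeric matrix in `[0, 1]`, sides divisible by 16.
#' @return List with `m_coarse`, `m_refined`, `uncertainty`, `e_boundary`,
#'   `uncertainty_pyramid` (coarsest first), and `a_boundary` (or `NULL`).
#' @export
espd_predict <- function(model, image) {
  image <- as.matrix(image)
  fw <- model_forward(model, image)
  upyr <- if (!is.null(fw$fields)) {
    lapply(fw$fields, function(f) drop(ag_val(f$U)))
  } else {
    NULL
  }
  list(m_coarse = drop(ag_val(fw$m_coarse)),
       m_refined = drop(ag_val(fw$m_refined)),
       uncertainty = drop(ag_val(fw$u_full)),
       e_boundary = drop(ag_val(fw$e_boundary)),
       uncertainty_pyramid = upyr,
       a_boundary = if (!is.null(fw$a_boundary)) drop(ag_val(fw$a_boundary)))
}

# ---- checkpoints: RDS weight archive with a JSON config header ----

#' Save / load model checkpoints
#'
#' The archive stores every weight array plus a JSON header describing the
#' configuration, so a checkpoint restores an identical model.
#'
#' @param model An `espd_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `espd_model`.
#' @export
save_checkpoint <- function(model, path) {
  ps <- ag_collect_params(model$params)
  weights <- lapply(ps, function(p) p$val)
  header <- jsonlite::toJSON(model$config[setdiff(names(model$config),
                                                  c("encoder", "spdf"))],
                             auto_unbox = TRUE)
  saveRDS(list(header = as.character(header),
               config = model$config, seed = model$seed,
               weights = weights), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- espd_model(ck$config, seed = ck$seed)
  ps <- ag_collect_params(model$params)
  stopifnot(length(ps) == length(ck$weights))
  for (i in seq_along(ps)) ps[[i]]$val <- ck$weights[[i]]
  model
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
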