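# Semantic-probabilistic dual-path fusion bottleneck.
#
# Semantic path: two deformable convolutions (per-location offsets predicted
# by a zero-initialized conv) on the stride-8 map s2, adapting receptive
# fields to irregular nodule morphology. Probabilistic path: the stride-16
# map s3 is upsampled to s2's grid, projected, and passed through windowed
# self-attention; the per-pixel variance across channels of the attention
# output, through a learnable affine, is the probabilistic attention map
# A_prob. Fusion: F_guided = F_sem * (1 + alpha * sigmoid(A_prob)), then
# s_final = FFN(concat[F_guided, F_prob]) + proj(s2), a residual on the
# bottleneck input.

#' SPDF bottleneck configuration
#'
#' @param window Window size of the probabilistic path's self-attention;
#'   must divide the bottleneck spatial size, and be at least 2.
#' @param deform_kernel Odd kernel size of the deformable convolutions.
#' @param ffn_expansion Hidden-width expansion ratio of the fusion FFN.
#' @param alpha_init Initial value of the learnable modulation strength
#'   `alpha`; 0 starts the fusion at identity modulation.
#' @return A list of class `spdf_config`.
#' @export
spdf_config <- function(window = 4, deform_kernel = 3, ffn_expansion = 2,
                        alpha_init = 0) {
  stopifnot(window >= 2, deform_kernel %% 2 == 1)
  structure(list(window = window, deform_kernel = deform_kernel,
                 ffn_expansion = ffn_expansion, alpha_init = alpha_init),
            class = "spdf_config")
}

new_spdf <- function(c2, c3, cbott, cfg) {
  k <- cfg$deform_kernel
  list(
    off1 = new_conv(c2, 2 * k * k, k, zero = TRUE),
    d1 = new_conv(c2, c2, k), n1 = new_gn(c2),
    off2 = new_conv(c2, 2 * k * k, k, zero = TRUE),
    d2 = new_conv(c2, c2, k),
    probproj = new_conv(c3, c2, 1),
    attn = new_window_attn(c2, cfg$window),
    aproj = {
      p <- new_conv(1, 1, 1, zero = TRUE)
      p$w$val[1, 1] <- 1  # identity affine on the raw variance at init
      p
    },
    alpha = scalar_param(cfg$alpha_init),
    ffn = new_ffn(2 * c2, cbott, cfg$ffn_expansion),
    resproj = new_conv(c2, cbott, 1)
  )
}

fwd_spdf_semantic <- function(tape, s2, p) {
  off1 <- fwd_conv(tape, s2, p$off1)
  h <- ag_deform_conv(tape, s2, off1, p$d1$w, p$d1$b)
  h <- ag_relu(tape, fwd_gn(tape, h, p$n1))
  off2 <- fwd_conv(tape, h, p$off2)
  ag_deform_conv(tape, h, off2, p$d2$w, p$d2$b)
}

fwd_spdf_prob <- function(tape, s3, p) {
  h <- fwd_conv(tape, ag_upsample2(tape, s3), p$probproj)
  f_prob <- fwd_window_self_attn(tape, h, p$attn)
  a_prob <- fwd_conv(tape, ag_chan_var(tape, f_prob), p$aproj)
  list(f_prob = f_prob, a_prob = a_prob)
}

# probability-guided modulation: F_sem * (1 + alpha * sigmoid(A_prob))
fwd_probability_guided_fusion <- function(tape, f_sem, a_prob, alpha) {
  gate <- ag_add_const(tape,
                       ag_scalar_mul(tape, ag_sigmoid(tape, a_prob), alpha), 1)
  ag_mul_bchan(tape, f_sem, gate)
}

fwd_spdf <- function(tape, s2, s3, p) {
  f_sem <- fwd_spdf_semantic(tape, s2, p)
  pr <- fwd_spdf_prob(tape, s3, p)
  f_guided <- fwd_probability_guided_fusion(tape, f_sem, pr$a_prob, p$alpha)
  fused <- fwd_ffn(tape, ag_concat_c(tape, list(f_guided, pr$f_prob)), p$ffn)
  s_final <- ag_add(tape, fused, fwd_conv(tape, s2, p$resproj))
  list(s_final = s_final, f_sem = f_sem, f_prob = pr$f_prob,
       a_prob = pr$a_prob, f_guided = f_guided)
}

# plain bottleneck used by the no_spdf ablation variant: a single 3x3
# conv + GN + ReLU, deliberately lighter than the dual-path module it
# replaces so the "+ SPDF" ablation switch adds parameters
new_plain_bottleneck <- function(c2, cbott) {
  list(c1 = new_conv(c2, cbott, 3), n1 = new_gn(cbott))
}

fwd_plain_bottleneck <- function(tape, s2, p) {
  ag_relu(tape, fwd_gn(tape, fwd_conv(tape, s2, p$c1), p$n1))
}
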