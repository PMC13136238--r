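# Dirichlet boundary-aware refinement.
#
# A physical edge path (Sobel magnitude of the raw image, normalized by its
# per-image maximum) and a learnable semantic edge path (small conv stack on
# the bottleneck features, upsampled and sigmoid-bounded) are adaptively
# fused into E_boundary. The boundary attention A_boundary aggregates the
# explicit uncertainty map U, the probabilistic ambiguity 1 - 2|M - 0.5|,
# and E_boundary through cascaded 3x3 convs with a terminal sigmoid. A
# gated residual update M <- clamp01(M + A_boundary * dM) is applied
# iteratively (dM predicted by shared-weight refinement convs, tanh-bounded);
# A_boundary is recomputed each iteration from the updated mask so the gate
# tracks the evolving ambiguity band. Wherever A_boundary = 0 the coarse
# prediction is preserved exactly.

#' Sobel gradient-magnitude edges
#'
#' Applies the standard 3x3 Sobel kernels with reflect padding and returns
#' `sqrt(Gx^2 + Gy^2)`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @return Non-negative matrix of the same size.
#' @export
sobel_edges <- function(image) {
  image <- as.matrix(image)
  cpp_sobel(image)
}

new_dbar <- function(cbott, d0, hid = 8) {
  list(
    sem1 = new_conv(cbott, hid, 1),
    sem2 = new_conv(hid, 1, 3),
    w1 = scalar_param(1), w2 = scalar_param(1), bfuse = scalar_param(0),
    battn1 = new_conv(3, hid, 3),
    battn2 = new_conv(hid, 1, 3),
    featproj = new_conv(d0, hid - 2, 1),
    base = new_conv(hid, hid, 3),
    ref1 = new_conv(hid + 2, hid, 3),
    ref2 = new_conv(hid, 1, 3)
  )
}

# learnable semantic edges from high-level (bottleneck) features,
# upsampled to the input grid
fwd_semantic_edges <- function(tape, s_final, p, target_hw) {
  h <- ag_relu(tape, fwd_conv(tape, s_final, p$sem1))
  e <- fwd_conv(tape, h, p$sem2)
  ag_sigmoid(tape, fwd_upsample_to(tape, e, target_hw))
}

# adaptive fusion of physical and semantic edges:
# sigmoid(w1 * normalize(E_sobel) + w2 * E_sem + b)
fwd_fuse_edges <- function(tape, e_sobel_norm, e_sem, p) {
  z <- ag_add(tape, ag_scalar_mul(tape, ag_const(e_sobel_norm), p$w1),
              ag_scalar_mul(tape, e_sem, p$w2))
  zb <- ag_node(tape, ag_val(z) + as.numeric(ag_val(p$bfuse)), local({
    zz <- z; bb <- p$bfuse
    function(nd) {
      ag_accum(zz, nd$grad)
      ag_accum(bb, sum(nd$grad))
    }
  }))
  ag_sigmoid(tape, zb)
}

# A_boundary from [U, ambiguity, E_boundary]; ambiguity = 1 - 2|M - 0.5|
fwd_boundary_attention <- function(tape, u, m, e_boundary, p) {
  amb <- ag_add_const(tape, ag_mul_const(tape,
    ag_abs(tape, ag_add_const(tape, m, -0.5)), -2), 1)
  h <- ag_relu(tape, fwd_conv(tape,
    ag_concat_c(tape, list(u, amb, e_boundary)), p$battn1))
  ag_sigmoid(tape, fwd_conv(tape, h, p$battn2))
}

#' Gated residual boundary update
#'
#' The scalar/array form of the refinement update
#' `M_refined = clamp01(M_coarse + A_boundary * delta_M)`. Wherever
#' `A_boundary = 0` the coarse prediction is preserved exactly.
#'
#' @param m_coarse Coarse mask values in `[0, 1]`.
#' @param a_boundary Boundary attention gate in `[0, 1]`.
#' @param delta_m Signed residual correction.
#' @return Refined values, clamped to `[0, 1]`.
#' @export
refine_update <- function(m_coarse, a_boundary, delta_m) {
  pmin(pmax(m_coarse + a_boundary * delta_m, 0), 1)
}
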