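# Dirichlet evidential guided decoder.
#
# Four decoder stages upsample 2x each, starting from the stride-16 grid.
# Every stage carries an evidence head (3x3 conv -> K=2 logits ->
# alpha = 1 + softplus) whose Dirichlet field supplies the per-stage
# uncertainty map; the four maps are exported coarsest-to-finest as the
# evidence pyramid. Skip connections from the encoder are modulated by the
# Dirichlet attention map A_Dir (windowed cross-attention with queries from
# the evidential probability mask and keys/values from bottleneck semantics
# plus fused edges) via F * (1 + alpha * A_Dir) and a 1x1 channel-reduction
# conv. A gated-residual attention over [Q_pred, K_conf = 1 - U, V_evidence]
# additionally re-weights decoder features; its output starts at 0.5 and its
# effect at identity. The coarse mask is the expected foreground probability
# of the finest Dirichlet field, upsampled to input size, so mask and
# evidence stay consistent by construction.

new_evidence_head <- function(cin) new_conv(cin, 2, 3)

# differentiable Dirichlet field from decoder features
fwd_dirichlet_field <- function(tape, feat, head) {
  logits <- fwd_conv(tape, feat, head)
  alpha <- ag_add_const(tape, ag_softplus(tape, logits), 1)
  s <- ag_chan_sum(tape, alpha)
  u <- ag_node(tape, 2 / ag_val(s), local({
    sn <- s
    function(nd) ag_accum(sn, -2 * nd$grad / ag_val(sn)^2)
  }))
  p <- ag_div_bchan(tape, alpha, s)
  list(alpha = alpha, S = s, U = u, p = p)
}

new_guided_attn <- function(cfeat, hid = 8) {
  list(qconv = new_conv(2, hid, 1),
       vconv = new_conv(cfeat, hid, 1),
       mlp1 = new_conv(2 * hid + 1, hid, 1),
       mlp2 = new_conv(hid, 1, 1, zero = TRUE),
       gate_bias = scalar_param(0),
       lambda = scalar_param(0))
}

# gated residual attention over prediction/confidence/evidence cues;
# returns A_guided in (0, 1)
fwd_evidence_guided_attention <- function(tape, p_prev, u_prev, feat, pa) {
  q <- fwd_conv(tape, p_prev, pa$qconv)
  kconf <- ag_add_const(tape, ag_mul_const(tape, u_prev, -1), 1)  # 1 - U
  v <- fwd_conv(tape, feat, pa$vconv)
  h <- ag_relu(tape, fwd_conv(tape, ag_concat_c(tape, list(q, kconf, v)), pa$mlp1))
  z <- fwd_conv(tape, h, pa$mlp2)
  zg <- ag_node(tape, ag_val(z) + as.numeric(ag_val(pa$gate_bias)), local({
    zz <- z; gb <- pa$gate_bias
    function(nd) {
      ag_accum(zz, nd$grad)
      ag_accum(gb, sum(nd$grad))
    }
  }))
  ag_sigmoid(tape, zg)
}

new_dirichlet_attn <- function(cbott, ca = 8, win = 4) {
  list(qproj = new_conv(3, ca, 1),
       semproj = new_conv(cbott, ca, 1),
       edgeproj = new_conv(1, ca, 1),
       attn = new_window_cross_attn(ca, 2 * ca, ca, win),
       outproj = new_conv(ca, 1, 1))
}

# Dirichlet attention: queries from the evidential probability
# mask (p, U), keys/values from bottleneck semantics + edge features.
fwd_dirichlet_attention <- function(tape, p_ev, u_ev, sem, edge, pa) {
  q <- fwd_conv(tape, ag_concat_c(tape, list(p_ev, u_ev)), pa$qproj)
  kv <- ag_concat_c(tape, list(fwd_conv(tape, sem, pa$semproj),
                               fwd_conv(tape, edge, pa$edgeproj)))
  h <- fwd_window_cross_attn(tape, q, kv, pa$attn)
  ag_sigmoid(tape, fwd_conv(tape, h, pa$outproj))
}

# evidential skip modulation: F * (1 + alpha * A_Dir), then 1x1 channel reduction.
fwd_modulate_skip <- function(tape, f_skip, a_dir, alpha, redconv) {
  gate <- ag_add_const(tape, ag_scalar_mul(tape, a_dir, alpha), 1)
  fwd_conv(tape, ag_mul_bchan(tape, f_skip, gate), redconv)
}

new_degd <- function(cfg) {
  sc <- cfg$encoder$stage_channels
  dc <- cfg$decoder_channels      # stages 3..0 (coarse to fine)
  sr <- cfg$skip_red              # reduced widths for skips s2, s1, s0
  cbott <- cfg$bottleneck_channels
  evidential <- cfg$evidential
  d <- list(
    block3 = new_conv_block(sc[4], dc[1]),
    head3 = new_evidence_head(dc[1]),
    sfinred = new_conv(cbott, sr[1], 1),
    skipred2 = new_conv(sc[3], sr[1], 1),
    block2 = new_conv_block(dc[1] + 2 * sr[1], dc[2]),
    head2 = new_evidence_head(dc[2]),
    skipred1 = new_conv(sc[2], sr[2], 1),
    block1 = new_conv_block(dc[2] + sr[2], dc[3]),
    head1 = new_evidence_head(dc[3]),
    skipred0 = new_conv(sc[1], sr[3], 1),
    block0 = new_conv_block(dc[3] + sr[3], dc[4]),
    head0 = new_evidence_head(dc[4])
  )
  if (evidential) {
    d$adir2 <- new_dirichlet_attn(cbott, cfg$cross_attn_channels, cfg$spdf$window)
    d$adir1 <- new_dirichlet_attn(cbott, cfg$cross_attn_channels, cfg$spdf$window)
    d$skip_alpha <- list(scalar_param(0), scalar_param(0), scalar_param(0))
    d$ga2 <- new_guided_attn(dc[2])
    d$ga1 <- new_guided_attn(dc[3])
    d$ga0 <- new_guided_attn(dc[4])
  }
  d
}

fwd_apply_guided <- function(tape, feat, field_prev, pa) {
  a_g <- fwd_evidence_guided_attention(tape, field_prev$p_up, field_prev$u_up,
                                       feat, pa)
  gate <- ag_add_const(tape, ag_scalar_mul(tape, a_g, pa$lambda), 1)
  list(feat = ag_mul_bchan(tape, feat, gate), a_guided = a_g)
}

up_field <- function(tape, field) {
  list(p_up = ag_upsample2(tape, field$p), u_up = ag_upsample2(tape, field$U))
}

# pyramid: encoder skips; s_final: bottleneck output at s2 grid;
# e_boundary: fused edge map node at input resolution.
fwd_degd <- function(tape, pyramid, s_final, e_boundary, d, cfg) {
  evidential <- cfg$evidential
  # edge features resampled to the two cross-attention grids
  g8 <- dim(ag_val(s_final))[1]
  eb <- e_boundary
  eb_stack <- list()
  while (dim(ag_val(eb))[1] > g8) {
    eb <- ag_avgpool2(tape, eb)
    eb_stack[[as.character(dim(ag_val(eb))[1])]] <- eb
  }

  fields <- list()
  # stage 3 (stride 16)
  f3 <- fwd_conv_block(tape, pyramid$s3, d$block3)
  fields$s3 <- fwd_dirichlet_field(tape, f3, d$head3)

  # stage 2 (stride 8): skip s2 + bottleneck features
  up3 <- ag_upsample2(tape, f3)
  prev <- up_field(tape, fields$s3)
  if (evidential) {
    a_dir2 <- fwd_dirichlet_attention(tape, prev$p_up, prev$u_up, s_final,
                                      eb_stack[[as.character(g8)]], d$adir2)
    skip2 <- fwd_modulate_skip(tape, pyramid$s2, a_dir2, d$skip_alpha[[1]],
                               d$skipred2)
  } else {
    a_dir2 <- NULL
    skip2 <- fwd_conv(tape, pyramid$s2, d$skipred2)
  }
  f2 <- fwd_conv_block(tape, ag_concat_c(tape, list(
    up3, skip2, fwd_conv(tape, s_final, d$sfinred))), d$block2)
  if (evidential) f2 <- fwd_apply_guided(tape, f2, prev, d$ga2)$feat
  fields$s2 <- fwd_dirichlet_field(tape, f2, d$head2)

  # stage 1 (stride 4)
  up2 <- ag_upsample2(tape, f2)
  prev <- up_field(tape, fields$s2)
  if (evidential) {
    sem16 <- ag_upsample2(tape, s_final)
    a_dir1 <- fwd_dirichlet_attention(tape, prev$p_up, prev$u_up, sem16,
                                      eb_stack[[as.character(2 * g8)]], d$adir1)
    skip1 <- fwd_modulate_skip(tape, pyramid$s1, a_dir1, d$skip_alpha[[2]],
                               d$skipred1)
  } else {
    a_dir1 <- NULL
    skip1 <- fwd_conv(tape, pyramid$s1, d$skipred1)
  }
  f1 <- fwd_conv_block(tape, ag_concat_c(tape, list(up2, skip1)), d$block1)
  if (evidential) f1 <- fwd_apply_guided(tape, f1, prev, d$ga1)$feat
  fields$s1 <- fwd_dirichlet_field(tape, f1, d$head1)

  # stage 0 (stride 2): reuse the upsampled A_Dir from the previous stage
  up1 <- ag_upsample2(tape, f1)
  prev <- up_field(tape, fields$s1)
  if (evidential) {
    a_dir0 <- ag_upsample2(tape, a_dir1)
    skip0 <- fwd_modulate_skip(tape, pyramid$s0, a_dir0, d$skip_alpha[[3]],
                               d$skipred0)
  } else {
    skip0 <- fwd_conv(tape, pyramid$s0, d$skipred0)
  }
  f0 <- fwd_conv_block(tape, ag_concat_c(tape, list(up1, skip0)), d$block0)
  if (evidential) f0 <- fwd_apply_guided(tape, f0, prev, d$ga0)$feat
  fields$s0 <- fwd_dirichlet_field(tape, f0, d$head0)

  # bilinear (not nearest) final upsampling: the stride-2 grid would
  # otherwise quantize every mask boundary to 2x2 blocks
  p_fg <- ag_slice_chan(tape, fields$s0$p, 2)
  m_coarse <- ag_upsample2_bilinear(tape, p_fg)
  u_full <- ag_upsample2_bilinear(tape, fields$s0$U)
  list(m_coarse = m_coarse, u_full = u_full, fields = fields,
       feat0 = f0, a_dir2 = a_dir2)
}

# plain softmax decoder used by the softmax_baseline / no_degd variants
fwd_softmax_decoder <- function(tape, pyramid, s_final, d, cfg) {
  f3 <- fwd_conv_block(tape, pyramid$s3, d$block3)
  f2 <- fwd_conv_block(tape, ag_concat_c(tape, list(
    ag_upsample2(tape, f3),
    fwd_conv(tape, pyramid$s2, d$skipred2),
    fwd_conv(tape, s_final, d$sfinred))), d$block2)
  f1 <- fwd_conv_block(tape, ag_concat_c(tape, list(
    ag_upsample2(tape, f2), fwd_conv(tape, pyramid$s1, d$skipred1))), d$block1)
  f0 <- fwd_conv_block(tape, ag_concat_c(tape, list(
    ag_upsample2(tape, f1), fwd_conv(tape, pyramid$s0, d$skipred0))), d$block0)
  logits <- fwd_conv(tape, f0, d$head0)
  # 2-class softmax over channels via sigmoid of the logit difference
  l1 <- ag_slice_chan(tape, logits, 1)
  l2 <- ag_slice_chan(tape, logits, 2)
  p_fg <- ag_sigmoid(tape, ag_sub(tape, l2, l1))
  m_coarse <- ag_upsample2_bilinear(tape, p_fg)
  # predictive entropy as the (non-evidential) uncertainty surrogate
  pv <- ag_val(m_coarse)
  pc <- pmin(pmax(pv, 1e-7), 1 - 1e-7)
  ent <- -(pc * log2(pc) + (1 - pc) * log2(1 - pc))
  list(m_coarse = m_coarse, u_full = ag_const(ent), fields = NULL,
       feat0 = f0, a_dir2 = NULL)
}
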