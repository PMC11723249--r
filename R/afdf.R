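#' Adaptive frequency-domain fusion (AFDF)
#'
#' Per-stage fusion of the local branch output `L_i`, the global branch
#' output `G_i` and the previous stage's fused map: the combined map is
#' expanded into multi-scale context by a sequence of depthwise
#' convolutions (5x5 then 7x7, a decomposed large kernel with an 11x11
#' effective receptive field), the concatenated scales are gated by an
#' MSCA middle branch, and two single-channel weight maps (the channel
#' sums of each scale) modulate the gated features before a pointwise
#' projection back to the stage width.
#'
#' The sum-then-multiply form is implemented exactly as specified even
#' though it is algebraically `U * (Y_up + Y_down)`; the identity is
#' asserted in the tests.
#'
#' @name afdf
#' @keywords internal
NULL

#' @keywords internal
afdf_new <- function(C, H, W, msca_opts, materialize = TRUE) {
  list(type = "afdf", C = as.integer(C),
       dw5_w = ag_param(c(C, 5L, 5L), "he", materialize),
       dw5_b = ag_param(C, "zeros", materialize),
       dw7_w = ag_param(c(C, 7L, 7L), "he", materialize),
       dw7_b = ag_param(C, "zeros", materialize),
       msca = msca_state(2L * C, H, W, n = msca_opts$n, r = msca_opts$r,
                         freq_set = msca_opts$freq_set %||% "zigzag7",
                         materialize = materialize),
       proj_w = ag_param(c(2L * C, C), "he", materialize),
       proj_b = ag_param(C, "zeros", materialize))
}

#' Combine the stage inputs of the fusion block: X_i = L_i + G_i + bridge,
#' where `bridge` is the previous fused map already resampled to stage-i
#' shape (the stage input itself), or absent at stage 1 (fuse_0 = 0).
#' @keywords internal
combine_stage_inputs <- function(L, G, bridge = NULL) {
  X <- t_add(L, G)
  if (!is.null(bridge)) X <- t_add(X, bridge)
  X
}

#' Multi-scale context: U1 = DW5x5(X), U2 = DW7x7(U1). The convolutions are
#' bare depthwise maps (no normalisation): a channel-zero-centering norm
#' here would annul the channel-sum weight maps of [fuse_branches()].
#' @keywords internal
multiscale_context <- function(X, w) {
  d <- dim(val(X))
  U1 <- t_conv2d(X, w$dw5_w, w$dw5_b, stride = 1L, padding = 2L, groups = d[2])
  U2 <- t_conv2d(U1, w$dw7_w, w$dw7_b, stride = 1L, padding = 3L, groups = d[2])
  list(U1 = U1, U2 = U2)
}

#' Three-branch fusion: MSCA-gated concatenation (middle), channel-sum
#' weight maps (upper/lower), pointwise projection 2C -> C.
#' @keywords internal
fuse_branches <- function(U1, U2, w) {
  d <- dim(val(U1))
  cat12 <- t_cat_c(U1, U2)                              # (N, 2C, H, W)
  gate <- t_sigmoid(msca_forward(cat12, w$msca))
  U <- t_channel_gate(cat12, gate)
  Yup <- t_sum_channels(U1)
  Ydown <- t_sum_channels(U2)
  S <- t_add(t_mul_spatial(U, Yup), t_mul_spatial(U, Ydown))
  m <- t_reshape(t_aperm(S, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], 2L * d[2]))
  m <- t_linear(m, w$proj_w, w$proj_b)
  t_aperm(t_reshape(m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

#' @keywords internal
afdf_forward <- function(L, G, bridge, w) {
  X <- combine_stage_inputs(L, G, bridge)
  ms <- multiscale_context(X, w)
  fuse_branches(ms$U1, ms$U2, w)
}
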