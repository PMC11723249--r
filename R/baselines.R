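#' Reference baseline architectures for cost accounting
#'
#' The two parent architectures of the dual-branch network, at their "-B"
#' scale, are used as published-budget anchors: parameter counts (with the
#' task-specific head) and conv/linear MAC counts validate the accounting
#' convention before it is applied to the fusion network. Only shapes are
#' needed, so these builders never allocate weights.
#'
#' @name baselines
NULL

#' @keywords internal
patch_merge_new <- function(C, materialize = FALSE) {
  # layer norm over the 4C concatenated sub-pixels + bias-free reduction
  list(type = "patch_merge", C = as.integer(C),
       ln_g = ag_param(4L * C, "ones", materialize),
       ln_b = ag_param(4L * C, "zeros", materialize),
       w = ag_param(c(4L * C, 2L * C), "trunc_normal", materialize))
}

#' Standard ConvNeXt-B classifier (shape-only)
#'
#' Depths `[3, 3, 27, 3]`, dims `[128, 256, 512, 1024]`, 7x7 depthwise
#' blocks with layer scale, strided-conv downsampling, pooled LN head.
#'
#' @param num_classes output classes (default 8).
#' @return shape-only model list compatible with [count_parameters()].
#' @export
convnext_b_model <- function(num_classes = 8L) {
  dims <- c(128L, 256L, 512L, 1024L)
  depths <- c(3L, 3L, 27L, 3L)
  stages <- lapply(1:4, function(i) {
    list(cnn = lapply(seq_len(depths[i]), function(b) {
      convnext_block_new(dims[i], msca_opts = NULL, materialize = FALSE)
    }))
  })
  structure(list(
    config = list(arch = "convnext_b", dims = dims, depths = depths,
                  num_classes = as.integer(num_classes), input_size = 224L),
    stem = stem_new(dims[1], materialize = FALSE),
    stages = stages,
    downsamples = lapply(1:3, function(i) downsample_new(dims[i], FALSE)),
    head = head_new(dims[4], num_classes, materialize = FALSE),
    materialized = FALSE
  ), class = c("baseline_model", "list"))
}

#' Standard Swin Transformer-B classifier (shape-only)
#'
#' Patch size 4, window 7, depths `[2, 2, 18, 2]`, dims
#' `[128, 256, 512, 1024]`, heads `[4, 8, 16, 32]`, patch-merging
#' downsampling, pooled LN head.
#'
#' @param num_classes output classes (default 8).
#' @return shape-only model list compatible with [count_parameters()].
#' @export
swin_b_model <- function(num_classes = 8L) {
  dims <- c(128L, 256L, 512L, 1024L)
  depths <- c(2L, 2L, 18L, 2L)
  heads <- c(4L, 8L, 16L, 32L)
  hs <- 56L %/% (2L^(0:3))
  stages <- lapply(1:4, function(i) {
    list(swin = lapply(seq_len(depths[i]), function(b) {
      swin_block_new(dims[i], hs[i], hs[i], 7L, shifted = (b %% 2L == 0L),
                     heads = heads[i], materialize = FALSE)
    }))
  })
  structure(list(
    config = list(arch = "swin_b", dims = dims, depths = depths, heads = heads,
                  num_classes = as.integer(num_classes), input_size = 224L),
    stem = stem_new(dims[1], materialize = FALSE),
    stages = stages,
    downsamples = lapply(1:3, function(i) patch_merge_new(dims[i], FALSE)),
    head = head_new(dims[4], num_classes, materialize = FALSE),
    materialized = FALSE
  ), class = c("baseline_model", "list"))
}
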