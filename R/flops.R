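#' FLOP accounting (multiply-accumulate convention)
#'
#' Forward-pass cost is reported as multiply-accumulate operations (one MAC
#' = one FLOP) of the learned convolution and dense layers: convolutions
#' (dense, depthwise and strided), the pointwise/token MLPs, attention
#' qkv/projection layers and classifier heads. Excluded are attention
#' score/value batched products, the FFT/DCT transforms and per-bin
#' spectral filters, normalisations and elementwise activations — the
#' convention under which the parent architectures' budgets are published;
#' the counter is validated by reproducing both baseline figures before
#' being applied to the fusion network.
#'
#' @name flops
NULL

conv_macs <- function(cin, cout, k, hout, wout = hout) cin * cout * k * k * hout * wout
dw_macs <- function(c, k, hout, wout = hout) c * k * k * hout * wout
linear_macs <- function(cin, cout, tokens = 1) cin * cout * tokens

#' @keywords internal
flops_convnext_block <- function(C, H, msca = NULL) {
  f <- dw_macs(C, 7, H) + linear_macs(C, 4 * C, H * H) + linear_macs(4 * C, C, H * H)
  if (!is.null(msca)) {
    cr <- max(1, C %/% msca$r)
    f <- f + 2 * C * cr              # squeeze-excitation bottleneck
  }
  f
}

#' @keywords internal
flops_swin_block <- function(C, H) {
  # qkv + proj + 4x MLP per token; attention matmuls excluded by convention
  linear_macs(C, 3 * C, H * H) + linear_macs(C, C, H * H) +
    linear_macs(C, 4 * C, H * H) + linear_macs(4 * C, C, H * H)
}

#' @keywords internal
flops_afdf <- function(C, H, msca) {
  cr <- max(1, (2 * C) %/% msca$r)
  dw_macs(C, 5, H) + dw_macs(C, 7, H) +
    2 * (2 * C) * cr +
    linear_macs(2 * C, C, H * H)
}

#' Count forward-pass MACs
#'
#' @param model an [affnet_config()], `affnet_model`, or one of the baseline
#'   builders' results.
#' @return a `cost_report` with `flops` (MACs at the configured input size,
#'   batch 1) alongside the parameter counts.
#' @export
count_flops <- function(model) {
  cfg <- if (inherits(model, "affnet_config")) model else model$config
  rep_ <- count_parameters(if (inherits(model, "affnet_config")) model else model)
  arch <- cfg$arch %||% "affnet"
  f <- switch(arch,
    affnet = {
      hs <- stage_sizes(cfg)
      dual <- length(cfg$branches) == 2L
      total <- conv_macs(3, cfg$dims[1], 4, hs[1])          # stem
      for (i in 1:4) {
        C <- cfg$dims[i]; H <- hs[i]
        if ("cnn" %in% cfg$branches) {
          total <- total + cfg$depths[i] *
            flops_convnext_block(C, H, if (cfg$enable_msca) cfg$msca else NULL)
        }
        if ("swin" %in% cfg$branches) {
          total <- total + cfg$depths[i] * flops_swin_block(C, H)
        }
        if (dual && cfg$fusion == "afdf") {
          total <- total + flops_afdf(C, H, cfg$msca)
        }
        if (i < 4L) {
          total <- total + conv_macs(C, 2 * C, 2, hs[i + 1])
        }
      }
      total + linear_macs(cfg$dims[4], cfg$num_classes)
    },
    convnext_b = {
      hs <- 56L %/% (2L^(0:3))
      total <- conv_macs(3, cfg$dims[1], 4, hs[1])
      for (i in 1:4) {
        total <- total + cfg$depths[i] * flops_convnext_block(cfg$dims[i], hs[i])
        if (i < 4L) total <- total + conv_macs(cfg$dims[i], 2 * cfg$dims[i], 2, hs[i + 1])
      }
      total + linear_macs(cfg$dims[4], cfg$num_classes)
    },
    swin_b = {
      hs <- 56L %/% (2L^(0:3))
      total <- conv_macs(3, cfg$dims[1], 4, hs[1])
      for (i in 1:4) {
        total <- total + cfg$depths[i] * flops_swin_block(cfg$dims[i], hs[i])
        if (i < 4L) {
          # patch merging: bias-free 4C -> 2C reduction on the merged tokens
          total <- total + linear_macs(4 * cfg$dims[i], 2 * cfg$dims[i],
                                       hs[i + 1]^2)
        }
      }
      total + linear_macs(cfg$dims[4], cfg$num_classes)
    },
    stop("unknown architecture: ", arch)
  )
  rep_$flops <- f
  rep_
}
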