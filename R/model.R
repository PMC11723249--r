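#' Model configuration, assembly, checkpointing and cost accounting
#'
#' The reference network is a four-stage dual-branch hierarchy: a shared
#' 4x-reduction stem feeds stage 1; inside each stage the ConvNeXt-style
#' branch (MSCA-gated) and the Swin-style branch (FFEO-gated) both consume
#' the stage input, their outputs are fused (adaptively via AFDF, or by
#' plain addition), and a single strided conv carries the fused map to the
#' next stage, doubling channels and halving resolution. A pooled
#' layer-normalised linear head produces the class logits.
#'
#' Ablation variants (single branches, gates on/off, fusion mode) are all
#' reachable through [affnet_config()] flags.
#'
#' @name model
NULL

#' Build an AFFNet model configuration
#'
#' Defaults reproduce the reference configuration: base width 128 doubling
#' over four stages of depth 2, 16-part MSCA with reduction 16, FFEO with 4
#' diagonal blocks and `alpha = 0.5`, window-7 attention, AFDF fusion and an
#' 8-class head.
#'
#' @param dims channel widths per stage (must double stage to stage).
#' @param depths blocks per stage per branch (default `c(2, 2, 2, 2)`).
#' @param num_classes number of output classes (8 for the BreaKHis subtypes,
#'   4 for BACH).
#' @param input_size square input resolution in pixels (default 224).
#' @param window attention window size; shrunk per stage to the largest
#'   divisor of the stage resolution.
#' @param heads attention heads per stage (default `max(1, dims / 32)`).
#' @param msca list with `n` (channel parts), `r` (reduction), `freq_set`.
#' @param ffeo list with `N` (diagonal blocks), `alpha`, `lambda`.
#' @param enable_msca,enable_ffeo gate toggles for the two branches.
#' @param fusion `"afdf"` or `"add"` (plain branch addition).
#' @param branches subset of `c("cnn", "swin")`.
#' @param norm_mean,norm_sd per-channel input normalisation.
#' @param init `"random"` (seeded truncated-normal) parameter init.
#' @param seed integer seed controlling parameter initialisation.
#' @return a list of class `affnet_config`.
#' @export
affnet_config <- function(dims = c(128L, 256L, 512L, 1024L),
                          depths = c(2L, 2L, 2L, 2L),
                          num_classes = 8L,
                          input_size = 224L,
                          window = 7L,
                          heads = pmax(1L, dims %/% 32L),
                          msca = list(n = 16L, r = 16L, freq_set = "zigzag7"),
                          ffeo = list(N = 4L, alpha = 0.5, lambda = 0.01),
                          enable_msca = TRUE,
                          enable_ffeo = TRUE,
                          fusion = c("afdf", "add"),
                          branches = c("cnn", "swin"),
                          norm_mean = c(0.5, 0.5, 0.5),
                          norm_sd = c(0.25, 0.25, 0.25),
                          init = "random",
                          seed = 0L) {
  fusion <- match.arg(fusion)
  stopifnot(length(dims) == 4L, length(depths) == 4L, length(heads) == 4L)
  if (!all(dims[-1] == 2L * dims[-4])) {
    stop("stage widths must double: C_i = 2 * C_{i-1}")
  }
  if (input_size %% 32L != 0L) {
    stop("input_size must be divisible by 32 (stem 4x, then three 2x stages)")
  }
  branches <- match.arg(branches, c("cnn", "swin"), several.ok = TRUE)
  if (("cnn" %in% branches) && enable_msca && any(dims %% msca$n != 0L)) {
    stop("all stage widths must be divisible by the MSCA part count n")
  }
  if (("swin" %in% branches) && enable_ffeo && any(dims %% ffeo$N != 0L)) {
    stop("all stage widths must be divisible by the FFEO block count N")
  }
  if (any(dims %% heads != 0L)) stop("heads must divide the stage widths")
  structure(list(
    dims = as.integer(dims), depths = as.integer(depths),
    num_classes = as.integer(num_classes), input_size = as.integer(input_size),
    window = as.integer(window), heads = as.integer(heads),
    msca = msca, ffeo = ffeo,
    enable_msca = isTRUE(enable_msca), enable_ffeo = isTRUE(enable_ffeo),
    fusion = fusion, branches = branches,
    norm_mean = norm_mean, norm_sd = norm_sd,
    init = init, seed = as.integer(seed)
  ), class = "affnet_config")
}

#' Stage resolutions implied by a config: input/4, then halving.
#' @keywords internal
stage_sizes <- function(cfg) cfg$input_size %/% 4L %/% (2L^(0:3))

#' Build a model from a configuration
#'
#' With `materialize = TRUE` all parameters are allocated and initialised
#' reproducibly from `cfg$seed`; with `FALSE` only shapes are created,
#' which is sufficient for parameter and FLOP accounting of large reference
#' configurations.
#'
#' @param cfg an [affnet_config()].
#' @param materialize allocate parameter values (default TRUE).
#' @return a list of class `affnet_model`.
#' @export
build_model <- function(cfg, materialize = TRUE) {
  stopifnot(inherits(cfg, "affnet_config"))
  if (materialize) set.seed(cfg$seed)
  hs <- stage_sizes(cfg)
  dual <- length(cfg$branches) == 2L
  stages <- vector("list", 4L)
  for (i in 1:4) {
    C <- cfg$dims[i]; H <- hs[i]
    st <- list()
    if ("cnn" %in% cfg$branches) {
      st$cnn <- lapply(seq_len(cfg$depths[i]), function(b) {
        convnext_block_new(C, H, H,
                           msca_opts = if (cfg$enable_msca) cfg$msca else NULL,
                           materialize = materialize)
      })
    }
    if ("swin" %in% cfg$branches) {
      st$swin <- lapply(seq_len(cfg$depths[i]), function(b) {
        swin_block_new(C, H, H, cfg$window, shifted = (b %% 2L == 0L),
                       heads = cfg$heads[i], materialize = materialize)
      })
      if (cfg$enable_ffeo) {
        st$ffeo <- lapply(seq_len(cfg$depths[i]), function(b) {
          ffeo_state(C, H, H, N = cfg$ffeo$N, alpha = cfg$ffeo$alpha,
                     lambda = cfg$ffeo$lambda, materialize = materialize)
        })
      }
    }
    if (dual && cfg$fusion == "afdf") {
      st$afdf <- afdf_new(C, H, H, cfg$msca, materialize = materialize)
    }
    stages[[i]] <- st
  }
  structure(list(
    config = cfg,
    stem = stem_new(cfg$dims[1], materialize),
    stages = stages,
    downsamples = lapply(1:3, function(i) downsample_new(cfg$dims[i], materialize)),
    head = head_new(cfg$dims[4], cfg$num_classes, materialize),
    materialized = materialize
  ), class = "affnet_model")
}

#' Forward pass through the full network
#'
#' @param model a materialised [build_model()] result.
#' @param x input batch, array `(N, 3, H, W)` (or an internal tensor).
#' @param return_stages also return the per-stage fused map shapes (and the
#'   branch map shapes) for shape-contract checks.
#' @return list with `logits` (`(N, M)`) and `features` (pooled pre-head
#'   activations, `(N, C4)`); plain matrices for plain-array input,
#'   tensors when called under an open tape. With `return_stages = TRUE`, a
#'   `stages` list of dim vectors is attached.
#' @export
model_forward <- function(model, x, return_stages = FALSE) {
  stopifnot(inherits(model, "affnet_model"))
  if (!model$materialized) stop("model was built without parameter values")
  plain <- !ag_is(x)
  xt <- if (plain) ag_tensor(x) else x
  cfg <- model$config
  dual <- length(cfg$branches) == 2L
  I <- stem_forward(xt, model$stem)
  Y <- NULL
  stage_shapes <- list()
  for (i in 1:4) {
    st <- model$stages[[i]]
    L <- G <- NULL
    if (!is.null(st$cnn)) {
      xx <- I
      for (blk in st$cnn) xx <- convnext_block_forward(xx, blk)
      L <- xx
    }
    if (!is.null(st$swin)) {
      xx <- I
      for (b in seq_along(st$swin)) {
        xx <- swin_block_forward(xx, st$swin[[b]])
        if (!is.null(st$ffeo)) {
          gate <- t_sigmoid(ffeo_forward(xx, st$ffeo[[b]]))
          xx <- t_mul(gate, xx)
        }
      }
      G <- xx
    }
    Y <- if (dual) {
      if (cfg$fusion == "afdf") {
        afdf_forward(L, G, bridge = if (i > 1L) I else NULL, st$afdf)
      } else {
        t_add(L, G)
      }
    } else {
      L %||% G
    }
    if (return_stages) {
      stage_shapes[[i]] <- list(
        fused = dim(val(Y)),
        local = if (!is.null(L)) dim(val(L)),
        global = if (!is.null(G)) dim(val(G)))
    }
    if (i < 4L) I <- downsample_forward(Y, model$downsamples[[i]])
  }
  hd <- head_forward(Y, model$head)
  out <- if (plain) {
    list(logits = val(hd$logits), features = val(hd$features))
  } else {
    hd
  }
  if (return_stages) out$stages <- stage_shapes
  out
}

# ---- parameter accounting ---------------------------------------------------

#' Coarse module label for a parameter path (for the cost breakdown).
#' @keywords internal
param_module_label <- function(name) {
  if (grepl("^stem", name)) return("stem")
  if (grepl("^downsamples", name)) return("downsample")
  if (grepl("^head", name)) return("head")
  if (grepl("\\.afdf\\.msca\\.", name)) return("afdf")
  if (grepl("\\.afdf\\.", name)) return("afdf")
  if (grepl("\\.ffeo\\.", name)) return("ffeo")
  if (grepl("\\.msca\\.", name)) return("msca")
  if (grepl("\\.cnn\\.", name)) return("cnn_branch")
  if (grepl("\\.swin\\.", name)) return("swin_branch")
  if (grepl("\\.merge", name)) return("downsample")
  "other"
}

#' Count trainable parameters
#'
#' Exact integer parameter count with a per-module breakdown; works on
#' shape-only (non-materialised) models, so the 68 M reference
#' configuration and the two published baselines can be accounted without
#' allocating weights.
#'
#' @param model a model built by [build_model()], [convnext_b_model()] or
#'   [swin_b_model()] (or an [affnet_config()], which is built shape-only).
#' @return list of class `cost_report` with `total_params`,
#'   `params_by_module` and `flops` (filled by [count_flops()]).
#' @export
count_parameters <- function(model) {
  if (inherits(model, "affnet_config")) model <- build_model(model, materialize = FALSE)
  ps <- ag_collect_params(model[intersect(
    c("stem", "stages", "downsamples", "head"), names(model))])
  sizes <- vapply(ps, function(p) prod(p$shape), 0)
  labels <- vapply(names(ps), param_module_label, "")
  by_mod <- tapply(sizes, labels, sum)
  structure(list(total_params = sum(sizes),
                 params_by_module = as.list(by_mod),
                 flops = NA_real_),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("parameters: %.2f M (%s)\n", x$total_params / 1e6,
              format(x$total_params, big.mark = ",")))
  for (nm in names(x$params_by_module)) {
    cat(sprintf("  %-12s %12s\n", nm,
                format(x$params_by_module[[nm]], big.mark = ",")))
  }
  if (!is.na(x$flops)) cat(sprintf("flops: %.2f G (MACs, 224 input)\n", x$flops / 1e9))
  invisible(x)
}

# ---- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' A single file embedding the configuration (JSON-serialisable) and all
#' parameter arrays; [load_checkpoint()] restores them bit-exactly.
#' @param model a materialised model.
#' @param path file path to write.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "affnet_model"), model$materialized)
  ps <- ag_collect_params(model[c("stem", "stages", "downsamples", "head")])
  saveRDS(list(format = "affnet_checkpoint", version = 1L,
               config = model$config,
               config_json = config_to_json(model$config),
               params = lapply(ps, val)),
          path)
  invisible(path)
}

#' Read only the embedded configuration of a checkpoint.
#' @param path checkpoint file.
#' @export
checkpoint_config <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "affnet_checkpoint")) stop("not an affnet checkpoint")
  ck$config
}

#' Load a model checkpoint
#'
#' Rebuilds the model from the embedded configuration and restores every
#' parameter. If `config` is supplied it must match the embedded one
#' exactly; any shape mismatch raises an error rather than silently
#' reshaping.
#' @param path checkpoint file.
#' @param config optional expected configuration.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "affnet_checkpoint")) stop("not an affnet checkpoint")
  cfg <- ck$config
  if (!is.null(config) && !isTRUE(all.equal(unclass(config), unclass(cfg)))) {
    stop("supplied config does not match the checkpoint's embedded config")
  }
  model <- build_model(cfg, materialize = TRUE)
  ps <- ag_collect_params(model[c("stem", "stages", "downsamples", "head")])
  if (!setequal(names(ps), names(ck$params))) {
    stop("checkpoint parameter names do not match the rebuilt model")
  }
  for (nm in names(ps)) {
    v <- ck$params[[nm]]
    if (!identical(dim(v) %||% length(v), dim(ps[[nm]]$v) %||% length(ps[[nm]]$v))) {
      stop("shape mismatch for parameter ", nm)
    }
    ps[[nm]]$v <- v
  }
  model
}

#' Serialise / parse a configuration as JSON (round-trips exactly).
#' @keywords internal
config_to_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
}

#' @keywords internal
config_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  do.call(affnet_config, x[setdiff(names(x), character())])
}

#' Write / read a configuration JSON file.
#' @param cfg an [affnet_config()]; @param path file path.
#' @export
write_config <- function(cfg, path) {
  writeLines(config_to_json(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
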