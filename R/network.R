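#' Network configuration
#'
#' All architecture hyperparameters of the segmentation network: the five
#' stage widths of the asymmetric encoder-decoder, the component toggles
#' used by the ablation variants, and the per-block settings.
#'
#' @param stage_widths five even positive integers, default `c(4, 8, 16, 32,
#'   64)` (the reduced-channel configuration; the fifth width is the
#'   bottleneck).
#' @param in_channels input image channels (default 3, RGB).
#' @param out_channels output probability channels (default 1, binary mask).
#' @param input_size `(rows, cols)`, each divisible by 16 (four 2x2
#'   poolings); default `c(256, 256)`, the profiling resolution.
#' @param use_scfc replace the second 3x3 convolution of every stage by the
#'   calibration convolution ([new_scfc_block()]).
#' @param use_fsf place [new_fsf_block()] on every skip connection.
#' @param use_farm wrap the bottleneck output in [new_farm_block()].
#' @param use_aggregation add the multi-level aggregation second decoder.
#' @param scfc_dilation,farm_dilations,attention_reduction forwarded to
#'   [block_config()].
#' @param eca_kernel odd kernel size of the aggregation branch's channel
#'   attention (default 3).
#' @return a `network_config` list.
#' @export
network_config <- function(stage_widths = c(4L, 8L, 16L, 32L, 64L),
                           in_channels = 3L, out_channels = 1L,
                           input_size = c(256L, 256L),
                           use_scfc = TRUE, use_fsf = TRUE,
                           use_farm = TRUE, use_aggregation = TRUE,
                           scfc_dilation = 7L,
                           farm_dilations = c(2L, 4L, 6L),
                           attention_reduction = 4L,
                           eca_kernel = 3L) {
  stage_widths <- as.integer(stage_widths)
  if (length(stage_widths) != 5L || any(stage_widths < 2L))
    stop("`stage_widths` must be five positive integers", call. = FALSE)
  if (use_scfc && any(stage_widths %% 2L != 0L))
    stop("`stage_widths` must all be even when `use_scfc` is enabled ",
         "(the calibration convolution splits channels in half)", call. = FALSE)
  if (use_fsf && any(stage_widths[2:5] != 2L * stage_widths[1:4]))
    stop("`stage_widths` must double at every stage when `use_fsf` is ",
         "enabled (the fusion block pairs C with 2C channels)", call. = FALSE)
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size %% 16L != 0L))
    stop("`input_size` dims must be divisible by 16", call. = FALSE)
  structure(list(stage_widths = stage_widths,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 input_size = input_size,
                 use_scfc = isTRUE(use_scfc), use_fsf = isTRUE(use_fsf),
                 use_farm = isTRUE(use_farm),
                 use_aggregation = isTRUE(use_aggregation),
                 scfc_dilation = as.integer(scfc_dilation),
                 farm_dilations = as.integer(farm_dilations),
                 attention_reduction = as.integer(attention_reduction),
                 eca_kernel = as.integer(eca_kernel)),
            class = "network_config")
}

#' Ablation-study variant configurations
#'
#' The nine buildable variants: step 0 is the reduced-width plain U-Net
#' baseline, steps 1-7 toggle the three feature blocks singly and in
#' combination, and step 8 is the full network including the aggregation
#' branch.
#'
#' @param step integer 0-8 or one of the names returned in the `variant`
#'   attribute ("baseline", "scfc", "fsf", "farm", "scfc+fsf", "scfc+farm",
#'   "fsf+farm", "scfc+fsf+farm", "full").
#' @param ... further arguments passed to [network_config()].
#' @return a `network_config`.
#' @export
table_variant_config <- function(step, ...) {
  names <- c("baseline", "scfc", "fsf", "farm", "scfc+fsf", "scfc+farm",
             "fsf+farm", "scfc+fsf+farm", "full")
  if (is.character(step)) {
    idx <- match(step, names)
    if (is.na(idx)) stop("unknown variant name: ", step, call. = FALSE)
    step <- idx - 1L
  }
  step <- as.integer(step)
  if (is.na(step) || step < 0L || step > 8L)
    stop("`step` must be 0..8 or a variant name", call. = FALSE)
  toggles <- list(
    c(FALSE, FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE),
    c(FALSE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, FALSE),
    c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE),
    c(FALSE, TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE, FALSE),
    c(TRUE, TRUE, TRUE, TRUE))[[step + 1L]]
  cfg <- network_config(use_scfc = toggles[1], use_fsf = toggles[2],
                        use_farm = toggles[3], use_aggregation = toggles[4], ...)
  attr(cfg, "variant") <- names[step + 1L]
  cfg
}

second_conv <- function(width, cfg, norm = TRUE) {
  if (cfg$use_scfc)
    new_scfc_block(block_config(width, scfc_dilation = cfg$scfc_dilation,
                                farm_dilations = cfg$farm_dilations,
                                attention_reduction = cfg$attention_reduction),
                   norm = norm)
  else
    nn_conv_unit(width, width, 3L, norm = norm)
}

#' Build the segmentation network
#'
#' Assembles the asymmetric encoder-decoder: four encoder stages (3x3
#' conv-BN-ReLU widening to the stage width, then the calibration
#' convolution or a second 3x3 conv, then 2x2 max pooling), a double-conv
#' bottleneck optionally wrapped by the multi-scale attention module, four
#' decoder stages (bilinear x2 upsampling + 1x1 conv, skip concatenation,
#' two convolutions mirroring the encoder) with the symmetric fusion block
#' optionally transforming each skip, an optional multi-level aggregation
#' second decoder, and a 1x1 convolution + sigmoid head.
#'
#' @param cfg a [network_config()].
#' @param seed optional integer; when given, weight initialisation is seeded.
#' @return an object of class `afcf_net`.
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- cfg$stage_widths
  net <- new_module()
  net$cfg <- cfg
  prev <- cfg$in_channels
  for (i in 1:4) {
    net$children[[paste0("enc", i, "_a")]] <- nn_conv_unit(prev, w[i], 3L)
    net$children[[paste0("enc", i, "_b")]] <- second_conv(w[i], cfg)
    prev <- w[i]
  }
  net$children$bott_a <- nn_conv_unit(w[4], w[5], 3L)
  net$children$bott_b <- second_conv(w[5], cfg)
  if (cfg$use_farm)
    net$children$farm <- new_farm_block(
      block_config(w[5], scfc_dilation = cfg$scfc_dilation,
                   farm_dilations = cfg$farm_dilations,
                   attention_reduction = cfg$attention_reduction))
  for (i in 4:1) {
    # decoder stage at encoder level i: input from the level below, output w[i]
    wb <- if (i == 4L) w[5] else w[i + 1L]
    net$children[[paste0("dec", i, "_up")]] <- nn_conv_unit(wb, w[i], 1L)
    if (cfg$use_fsf)
      net$children[[paste0("skip", i)]] <- new_fsf_block(w[i])
    net$children[[paste0("dec", i, "_a")]] <- nn_conv_unit(2L * w[i], w[i], 3L)
    net$children[[paste0("dec", i, "_b")]] <- second_conv(w[i], cfg)
  }
  if (cfg$use_aggregation) {
    for (j in 1:3) net$children[[paste0("eca", j)]] <- new_eca(cfg$eca_kernel)
    net$children$agg_fuse <- nn_conv_unit(sum(w[2:4]), w[1], 1L)
  }
  net$children$head <- nn_conv2d(w[1], cfg$out_channels, 1L)
  class(net) <- c("afcf_net", class(net))
  net
}

#' @export
print.afcf_net <- function(x, ...) {
  cfg <- x$cfg
  on <- c("SCFCConv" = cfg$use_scfc, "FSFConv" = cfg$use_fsf,
          "FARM" = cfg$use_farm, "aggregation" = cfg$use_aggregation)
  cat("<afcf_net> stage widths (", paste(cfg$stage_widths, collapse = ", "),
      "), components: ",
      if (any(on)) paste(names(on)[on], collapse = " + ") else "none (baseline)",
      "\n  parameters: ", format(count_params(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Forward pass of the network
#'
#' @param net an `afcf_net`.
#' @param x rank-4 array or tensor `(rows, cols, in_channels, batch)`;
#'   spatial dims must be divisible by 16.
#' @param training training mode (batch statistics, gradient tape)?
#' @return probability map `(rows, cols, out_channels, batch)` with values
#'   in (0, 1); an array when `x` is an array, a tensor when `x` is a tensor.
#' @export
net_forward <- function(net, x, training = FALSE) {
  if (!inherits(x, "ag_tensor")) {
    check_feature_map(x)
    return(ag_no_grad(net_forward(net, ag_tensor(x), training))$value)
  }
  d <- dim(x$value)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input spatial dims (", d[1], "x", d[2], ") must be divisible by 16 ",
         "(four 2x2 poolings)", call. = FALSE)
  if (d[3] != net$cfg$in_channels)
    stop("expected ", net$cfg$in_channels, " input channels, got ", d[3],
         call. = FALSE)
  ch <- net$children
  enc <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    h <- ch[[paste0("enc", i, "_a")]]$forward(h, training)
    h <- ch[[paste0("enc", i, "_b")]]$forward(h, training)
    enc[[i]] <- h
    h <- ag_maxpool2(h)
  }
  h <- ch$bott_a$forward(h, training)
  h <- ch$bott_b$forward(h, training)
  if (!is.null(ch$farm)) h <- ch$farm$forward(h, training)
  dec <- vector("list", 4)  # dec[[1]] = deepest decoder output (D1)
  for (i in 4:1) {
    di <- dim(enc[[i]]$value)
    up <- ch[[paste0("dec", i, "_up")]]$forward(
      ag_resize_bilinear(h, di[1], di[2]), training)
    skip <- if (!is.null(ch[[paste0("skip", i)]]))
      ch[[paste0("skip", i)]]$forward(h, enc[[i]], training)
    else enc[[i]]
    g <- ch[[paste0("dec", i, "_a")]]$forward(ag_concat_c(list(skip, up)), training)
    h <- ch[[paste0("dec", i, "_b")]]$forward(g, training)
    dec[[5L - i]] <- h
  }
  fused <- if (!is.null(ch$agg_fuse))
    aggregation_forward(net, dec[[1]], dec[[2]], dec[[3]], dec[[4]], training)
  else dec[[4]]
  ag_sigmoid(ch$head$forward(fused, training))
}

#' Multi-level feature aggregation branch
#'
#' The second decoder: the outputs of the first three decoder stages
#' (deepest first, at 1/8, 1/4 and 1/2 of the input resolution) are
#' re-weighted by non-residual channel attention, bilinearly upsampled to
#' full resolution, concatenated, mapped by a 1x1 convolution to the width
#' of the final decoder output, and fused with it by elementwise addition.
#'
#' @param net an `afcf_net` built with `use_aggregation = TRUE`.
#' @param d1,d2,d3,d4 decoder stage outputs, deepest first; arrays or
#'   tensors.
#' @param training training mode?
#' @return feature map shaped like `d4`.
#' @export
aggregation_forward <- function(net, d1, d2, d3, d4, training = FALSE) {
  if (!inherits(d1, "ag_tensor")) {
    for (a in list(d1, d2, d3, d4)) check_feature_map(a)
    return(ag_no_grad(aggregation_forward(net, ag_tensor(d1), ag_tensor(d2),
                                          ag_tensor(d3), ag_tensor(d4),
                                          training))$value)
  }
  ds <- list(d1, d2, d3)
  d4d <- dim(d4$value)
  for (j in 1:3) {
    dj <- dim(ds[[j]]$value)
    sc <- 2L^(4L - j)
    if (dj[1] * sc != d4d[1] || dj[2] * sc != d4d[2])
      stop("aggregation: d", j, " must be at 1/", sc, " of the full resolution",
           call. = FALSE)
  }
  ch <- net$children
  if (is.null(ch$agg_fuse))
    stop("network was built without the aggregation branch", call. = FALSE)
  paths <- lapply(1:3, function(j) {
    wts <- ch[[paste0("eca", j)]]$forward(ds[[j]], training)
    ag_resize_bilinear(ag_scale_channels(ds[[j]], wts), d4d[1], d4d[2])
  })
  ag_add(ch$agg_fuse$forward(ag_concat_c(paths), training), d4)
}

#' Count trainable parameters
#'
#' Every trainable scalar: convolution kernels and biases, normalisation
#' scale/shift terms. Running statistics are buffers, not parameters.
#'
#' @param net an `afcf_net` (or any module).
#' @return integer-valued double.
#' @export
count_params <- function(net) {
  sum(vapply(collect_params(net), function(p) length(p$value), numeric(1)))
}

#' Count forward-pass multiply-accumulate operations
#'
#' Runs one instrumented batch-1 forward pass at the given resolution and
#' returns the multiply-accumulate count of all convolution and batched
#' matrix-product operations (one MAC = one reported FLOP; normalisation,
#' activations, pooling and interpolation are excluded). Because the count
#' is accumulated by the ops as they execute, it always reflects the graph
#' actually run for the given configuration.
#'
#' @param net an `afcf_net`.
#' @param input_size `(rows, cols)`; defaults to the configured input size.
#' @return MAC count (double).
#' @export
count_macs <- function(net, input_size = NULL) {
  if (is.null(input_size)) input_size <- net$cfg$input_size
  input_size <- as.integer(input_size)
  x <- array(0, c(input_size[1], input_size[2], net$cfg$in_channels, 1L))
  ag_count_macs(ag_no_grad(net_forward(net, ag_tensor(x), training = FALSE)))
}

#' Complexity summary of a configuration or ablation variant
#'
#' @param cfg a [network_config()], or an ablation step number/name accepted
#'   by [table_variant_config()].
#' @param input_size profiling resolution; defaults to the configured one.
#' @param seed seed for the (count-irrelevant) weight initialisation.
#' @return list with the raw counts and the rounded `params_m` (millions,
#'   2 decimals) and `flops_g` (billions of MACs, 2 decimals).
#' @export
summarize_complexity <- function(cfg, input_size = NULL, seed = 1L) {
  if (!inherits(cfg, "network_config")) cfg <- table_variant_config(cfg)
  net <- build_network(cfg, seed = seed)
  p <- count_params(net)
  m <- count_macs(net, input_size)
  list(variant = attr(cfg, "variant") %||% "custom",
       param_count = p, mac_count = m,
       params_m = round(p / 1e6, 2), flops_g = round(m / 1e9, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- checkpoints -----------------------------------------------------------

#' Save network weights and configuration to one file
#'
#' The checkpoint holds every parameter array, the normalisation running
#' statistics, and the configuration as a plain key/value list (YAML
#' compatible).
#'
#' @param net an `afcf_net`.
#' @param path file to write (RDS format).
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(net, path) {
  params <- collect_params(net)
  state <- lapply(params, function(p) p$value)
  buffers <- collect_buffers(net)
  saveRDS(list(config = unclass(net$cfg), state = state, buffers = buffers),
          path)
  invisible(path)
}

collect_buffers <- function(mod, prefix = "") {
  out <- list()
  if (!is.null(mod$running_mean)) {
    out[[paste0(prefix, "running_mean")]] <- mod$running_mean
    out[[paste0(prefix, "running_var")]] <- mod$running_var
  }
  for (nm in names(mod$children))
    out <- c(out, collect_buffers(mod$children[[nm]], paste0(prefix, nm, ".")))
  out
}

restore_buffers <- function(mod, buffers, prefix = "") {
  if (!is.null(mod$running_mean)) {
    mod$running_mean <- buffers[[paste0(prefix, "running_mean")]]
    mod$running_var <- buffers[[paste0(prefix, "running_var")]]
  }
  for (nm in names(mod$children))
    restore_buffers(mod$children[[nm]], buffers, paste0(prefix, nm, "."))
  invisible(NULL)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return an `afcf_net` with restored weights and running statistics.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$config)
  net <- build_network(cfg)
  params <- collect_params(net)
  stopifnot(identical(names(params), names(ck$state)))
  for (nm in names(params)) params[[nm]]$value <- ck$state[[nm]]
  restore_buffers(net, ck$buffers)
  net
}
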