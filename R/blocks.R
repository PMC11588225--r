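#' Configuration for the bespoke feature blocks
#'
#' Collects the per-stage hyperparameters of the three feature blocks: the
#' channel width, the dilation rate of the atrous branch of the
#' spatial-channel calibration convolution, the dilation triple of the
#' multi-scale attention bottleneck, and the channel-reduction factor of its
#' query/key/value projections.
#'
#' @param channels even positive integer; feature width the blocks operate at.
#' @param scfc_dilation dilation rate of the atrous branch (default 7, the
#'   best-performing rate).
#' @param farm_dilations strictly increasing triple of dilation rates for the
#'   bottleneck branches (default `c(2, 4, 6)`).
#' @param attention_reduction channel-reduction factor of the attention
#'   projections (default 4).
#' @return a `block_config` list.
#' @export
block_config <- function(channels, scfc_dilation = 7L,
                         farm_dilations = c(2L, 4L, 6L),
                         attention_reduction = 4L) {
  channels <- as.integer(channels)
  if (length(channels) != 1L || is.na(channels) || channels < 2L)
    stop("`channels` must be a positive integer >= 2", call. = FALSE)
  if (channels %% 2L != 0L)
    stop("`channels` must be even: the calibration convolution splits the ",
         "feature map into two halves along the channel axis", call. = FALSE)
  if (scfc_dilation < 1L) stop("`scfc_dilation` must be positive", call. = FALSE)
  if (length(farm_dilations) != 3L || any(diff(farm_dilations) <= 0))
    stop("`farm_dilations` must be a strictly increasing triple", call. = FALSE)
  if (attention_reduction < 1L)
    stop("`attention_reduction` must be a positive integer", call. = FALSE)
  structure(list(channels = channels,
                 scfc_dilation = as.integer(scfc_dilation),
                 farm_dilations = as.integer(farm_dilations),
                 attention_reduction = as.integer(attention_reduction)),
            class = "block_config")
}

check_feature_map <- function(x, what = "x") {
  v <- if (inherits(x, "ag_tensor")) x$value else x
  if (!is.array(v) || length(dim(v)) != 4L)
    stop("`", what, "` must be a rank-4 array (rows, cols, channels, batch)",
         call. = FALSE)
  if (!all(is.finite(v)))
    stop("`", what, "` contains non-finite values", call. = FALSE)
  invisible(v)
}

## ---- SCFCConv --------------------------------------------------------------

#' Spatial-channel feature calibration convolution (SCFCConv)
#'
#' A dual-branch replacement for the second 3x3 convolution of a U-Net
#' stage. The input (C channels) is split evenly into two halves. The first
#' half passes through a 3x3 convolution whose output feeds both an atrous
#' 3x3 convolution (rate `scfc_dilation`) and a channel concatenation,
#' reduced back to C/2 by a 1x1 convolution: local and wide-receptive-field
#' features are captured together. The second half is calibrated by a
#' low-resolution gate: average-pool (k = 2), 3x3 convolution, bilinear
#' upsampling back to size, a residual addition of the input half, and a
#' sigmoid; the gate multiplies a 3x3-convolved copy of the half and a final
#' 3x3 convolution yields the second C/2-channel output. The two branch
#' outputs are concatenated, so output width equals input width.
#'
#' @param cfg a [block_config()].
#' @param norm keep batch normalisation inside the conv units (disable only
#'   for numerical equivalence testing).
#' @return a module with `$forward(x, training)`.
#' @export
new_scfc_block <- function(cfg, norm = TRUE) {
  stopifnot(inherits(cfg, "block_config"))
  C <- cfg$channels
  h <- C %/% 2L
  m <- new_module()
  m$cfg <- cfg
  m$children$c3a <- nn_conv_unit(h, h, 3L, norm = norm)
  m$children$c3d <- nn_conv_unit(h, h, 3L, dilation = cfg$scfc_dilation, norm = norm)
  m$children$c1 <- nn_conv_unit(C, h, 1L, norm = norm)
  m$children$c3low <- nn_conv_unit(h, h, 3L, norm = norm, act = FALSE)  # feeds sigmoid
  m$children$c3hi <- nn_conv_unit(h, h, 3L, norm = norm)
  m$children$c3out <- nn_conv_unit(h, h, 3L, norm = norm)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$value)
    if (d[3] != C)
      stop("SCFCConv configured for ", C, " channels, got ", d[3], call. = FALSE)
    if (d[1] < 2L || d[2] < 2L)
      stop("SCFCConv needs spatial dims >= 2 (average pooling with kernel 2)",
           call. = FALSE)
    x1 <- ag_narrow_c(x, 1L, h)
    x2 <- ag_narrow_c(x, h + 1L, C)
    # branch 1: local + atrous features, fused by 1x1
    t1 <- m$children$c3a$forward(x1, training)
    y1 <- m$children$c1$forward(
      ag_concat_c(list(m$children$c3d$forward(t1, training), t1)), training)
    # branch 2: low-resolution sigmoid gate calibrates the high-resolution path
    low <- m$children$c3low$forward(ag_avgpool2(x2), training)
    gate <- ag_sigmoid(ag_add(ag_resize_bilinear(low, d[1], d[2]), x2))
    y2 <- m$children$c3out$forward(
      ag_mul(m$children$c3hi$forward(x2, training), gate), training)
    ag_concat_c(list(y1, y2))
  }
  m
}

#' Apply an SCFCConv block to a feature map
#'
#' @param block module from [new_scfc_block()].
#' @param x rank-4 array or `ag_tensor`, (rows, cols, channels, batch).
#' @param training use batch statistics in normalisation layers?
#' @return same type as `x`, same shape.
#' @export
scfc_forward <- function(block, x, training = FALSE) {
  run_block(function(t) block$forward(t, training), x)
}

run_block <- function(f, x) {
  if (inherits(x, "ag_tensor")) return(f(x))
  check_feature_map(x)
  ag_no_grad(f(ag_tensor(x)))$value
}

## ---- FSFConv ---------------------------------------------------------------

#' Feature symmetric fusion convolution (FSFConv)
#'
#' Skip-connection block that cross-fuses a high-level feature map (2C
#' channels at half resolution) with the same-level encoder feature (C
#' channels at full resolution). Both inputs are read symmetrically at the
#' two resolutions (1x1 convolution after resampling, 3x3 convolution in
#' place), the cross-sums are convolved, and a sigmoid of the upsampled
#' low-resolution fusion gates the high-frequency fusion before a residual
#' addition of the low-level input:
#' `Z = C3(X1 + Y2) * sigmoid(U(C3(X2 + Y1))) + Y`.
#'
#' With all weights and biases zero the gate sees zero, the gated product is
#' zero, and the block returns its low-level input exactly.
#'
#' @param channels C, the width of the low-level input (the high-level input
#'   carries 2C channels).
#' @param norm keep batch normalisation (see [new_scfc_block()]).
#' @return a module with `$forward(x_high, y_low, training)`.
#' @export
new_fsf_block <- function(channels, norm = TRUE) {
  C <- as.integer(channels)
  m <- new_module()
  m$channels <- C
  m$children$cx1 <- nn_conv_unit(2L * C, C, 1L, norm = norm)
  m$children$cx2 <- nn_conv_unit(2L * C, 2L * C, 3L, norm = norm)
  m$children$cy1 <- nn_conv_unit(C, 2L * C, 1L, norm = norm)
  m$children$cy2 <- nn_conv_unit(C, C, 3L, norm = norm)
  m$children$cgate <- nn_conv_unit(2L * C, C, 3L, norm = norm, act = FALSE)
  m$children$cz <- nn_conv_unit(C, C, 3L, norm = norm)
  m$forward <- function(x_high, y_low, training = FALSE) {
    dh <- dim(x_high$value)
    dl <- dim(y_low$value)
    if (dh[3] != 2L * dl[3])
      stop("FSFConv: high-level input must carry twice the channels of the ",
           "low-level input (got ", dh[3], " vs ", dl[3], ")", call. = FALSE)
    if (dh[1] * 2L != dl[1] || dh[2] * 2L != dl[2])
      stop("FSFConv: high-level spatial dims must be exactly half of the ",
           "low-level dims", call. = FALSE)
    X1 <- m$children$cx1$forward(ag_resize_bilinear(x_high, dl[1], dl[2]), training)
    X2 <- m$children$cx2$forward(x_high, training)
    Y1 <- m$children$cy1$forward(ag_avgpool2(y_low), training)
    Y2 <- m$children$cy2$forward(y_low, training)
    gate <- ag_sigmoid(ag_resize_bilinear(
      m$children$cgate$forward(ag_add(X2, Y1), training), dl[1], dl[2]))
    ag_add(ag_mul(m$children$cz$forward(ag_add(X1, Y2), training), gate), y_low)
  }
  m
}

#' Apply an FSFConv block
#'
#' @param block module from [new_fsf_block()].
#' @param x_high high-level feature, 2C channels at (H/2, W/2).
#' @param y_low low-level feature, C channels at (H, W).
#' @param training use batch statistics?
#' @return feature map shaped like `y_low`.
#' @export
fsf_forward <- function(block, x_high, y_low, training = FALSE) {
  if (inherits(x_high, "ag_tensor")) return(block$forward(x_high, y_low, training))
  check_feature_map(x_high, "x_high")
  check_feature_map(y_low, "y_low")
  ag_no_grad(block$forward(ag_tensor(x_high), ag_tensor(y_low), training))$value
}

## ---- FARM ------------------------------------------------------------------

#' Sigmoid spatial self-attention used inside the bottleneck module
#'
#' Query, key and value are 1x1 projections with channels reduced by
#' `reduction`. The affinity between flattened spatial positions is
#' `sigmoid(Q^T K)` (sigmoid, not softmax), applied to the value; the
#' attended map is broadcast back over channel groups and multiplies the
#' input elementwise, so the output keeps the input shape.
#'
#' @param channels input width C.
#' @param reduction channel-reduction factor (must divide C).
#' @param norm keep batch normalisation in the projections.
#' @return a module with `$forward(a, training)`.
#' @export
new_farm_attention <- function(channels, reduction = 4L, norm = TRUE) {
  C <- as.integer(channels)
  r <- as.integer(reduction)
  if (C %% r != 0L) stop("`reduction` must divide `channels`", call. = FALSE)
  Cr <- C %/% r
  m <- new_module()
  m$channels <- C
  m$reduction <- r
  m$children$q <- nn_conv_unit(C, Cr, 1L, norm = norm)
  m$children$k <- nn_conv_unit(C, Cr, 1L, norm = norm)
  m$children$v <- nn_conv_unit(C, Cr, 1L, norm = norm)
  m$forward <- function(a, training = FALSE) {
    d <- dim(a$value)
    hw <- d[1] * d[2]
    flat <- function(t) ag_reshape(t, c(hw, Cr, d[4]))  # (positions, channels, B)
    Q <- flat(m$children$q$forward(a, training))
    K <- flat(m$children$k$forward(a, training))
    V <- flat(m$children$v$forward(a, training))
    affinity <- ag_sigmoid(ag_bmm(Q, ag_btranspose(K)))   # (hw, hw, B), in (0,1)
    attended <- ag_bmm(affinity, V)                        # (hw, Cr, B)
    attended <- ag_reshape(attended, c(d[1], d[2], Cr, d[4]))
    ag_mul(ag_channel_repeat(attended, r), a)
  }
  m
}

#' Apply the bottleneck attention to a feature map
#'
#' @param attn module from [new_farm_attention()].
#' @param a rank-4 array or tensor.
#' @param training use batch statistics?
#' @return re-weighted feature map, same shape as `a`.
#' @export
farm_attention <- function(attn, a, training = FALSE) {
  run_block(function(t) attn$forward(t, training), a)
}

#' Feature attention recombination module (FARM)
#'
#' Bottleneck module in the style of atrous spatial pyramid pooling with
#' dense multi-scale branches and sigmoid self-attention. A global
#' average-pooling branch (1x1 convolution, bilinear upsampling back to
#' size) is added to the input; a 1x1 convolution and three dilated 3x3
#' convolutions (rates `farm_dilations`) read the sum, each dilated branch
#' followed by [new_farm_attention()]; the attended branches are
#' concatenated and a final 1x1 convolution maps everything back to the
#' input width.
#'
#' @param cfg a [block_config()].
#' @param norm keep batch normalisation.
#' @return a module with `$forward(x, training)`.
#' @export
new_farm_block <- function(cfg, norm = TRUE) {
  stopifnot(inherits(cfg, "block_config"))
  C <- cfg$channels
  m <- new_module()
  m$cfg <- cfg
  m$children$cpool <- nn_conv_unit(C, C, 1L, norm = norm)
  m$children$cx2 <- nn_conv_unit(C, C, 1L, norm = norm)
  for (i in 1:3) {
    m$children[[paste0("cd", i)]] <-
      nn_conv_unit(C, C, 3L, dilation = cfg$farm_dilations[i], norm = norm)
    m$children[[paste0("att", i)]] <-
      new_farm_attention(C, cfg$attention_reduction, norm = norm)
  }
  m$children$cout <- nn_conv_unit(5L * C, C, 1L, norm = norm)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$value)
    if (d[1] < 2L || d[2] < 2L)
      stop("FARM needs spatial dims >= 2", call. = FALSE)
    X1 <- ag_resize_bilinear(
      m$children$cpool$forward(ag_global_avgpool(x), training), d[1], d[2])
    base <- ag_add(x, X1)
    X2 <- m$children$cx2$forward(base, training)
    branches <- lapply(1:3, function(i) {
      a <- m$children[[paste0("cd", i)]]$forward(base, training)
      m$children[[paste0("att", i)]]$forward(a, training)
    })
    X3 <- ag_concat_c(branches)
    m$children$cout$forward(ag_concat_c(list(X1, X2, X3)), training)
  }
  m
}

#' Apply a FARM block
#'
#' @param block module from [new_farm_block()].
#' @param x rank-4 array or tensor.
#' @param training use batch statistics?
#' @return feature map, same shape as `x`.
#' @export
farm_forward <- function(block, x, training = FALSE) {
  run_block(function(t) block$forward(t, training), x)
}

## ---- ECA -------------------------------------------------------------------

#' Efficient channel attention weights (non-residual form)
#'
#' Global average pooling per channel followed by a 1-D convolution across
#' the channel axis (odd kernel, symmetric zero padding) and a sigmoid.
#' Only the weight vector is returned; the aggregation branch multiplies it
#' into the feature map once, without the residual re-multiplication of
#' standard ECA.
#'
#' @param kernel_size odd positive integer (default 3).
#' @return a module with `$forward(x, training)` returning per-channel
#'   weights shaped (channels, batch), each strictly in (0, 1).
#' @export
new_eca <- function(kernel_size = 3L) {
  k <- as.integer(kernel_size)
  if (k < 1L || k %% 2L == 0L)
    stop("`kernel_size` must be an odd positive integer", call. = FALSE)
  m <- new_module()
  m$kernel_size <- k
  bound <- sqrt(6 / k)
  m$params$w <- mk_param(stats::runif(k, -bound, bound))
  m$params$b <- mk_param(0)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$value)
    means <- ag_reshape(ag_global_avgpool(x), c(d[3], d[4]))
    ag_sigmoid(ag_conv1d_channels(means, m$params$w, m$params$b))
  }
  m
}

#' Compute ECA channel weights for a feature map
#'
#' @param eca module from [new_eca()].
#' @param x rank-4 array or tensor.
#' @return matrix (channels, batch) of weights in (0, 1), or a tensor if `x`
#'   is a tensor.
#' @export
eca_weights <- function(eca, x) {
  if (inherits(x, "ag_tensor")) return(eca$forward(x))
  check_feature_map(x)
  ag_no_grad(eca$forward(ag_tensor(x)))$value
}
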