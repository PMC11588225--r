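#' @useDynLib afcfnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reverse-mode automatic differentiation over rank-4 feature maps.
#
# A tensor is an environment holding $value (an R array), $grad, and a
# requires_grad flag. Every differentiable operation appends a node (output,
# inputs, backward closure) to a global tape; ag_backward() walks the tape in
# reverse and accumulates gradients into the tensors that require them.
# Conv and batched-matrix ops also add their multiply-accumulate counts to a
# counter when profiling is switched on, so complexity reports are measured
# from the graph that actually executes.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$recording <- TRUE
.ag$count_macs <- FALSE
.ag$macs <- 0

#' Create an autograd tensor
#'
#' Wraps a numeric array so it can participate in the package's reverse-mode
#' differentiation. Values carried between layers are rank-4 arrays with
#' dimensions (rows, cols, channels, batch).
#'
#' @param value numeric array (any rank; network features are rank 4).
#' @param requires_grad should gradients be accumulated into this tensor?
#' @return an object of class `ag_tensor`.
#' @export
ag_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires_grad <- isTRUE(requires_grad)
  t$is_param <- FALSE
  class(t) <- "ag_tensor"
  t
}

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor ", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires_grad) " (grad)" else "", ">\n", sep = "")
  invisible(x)
}

as_tensor <- function(x) if (inherits(x, "ag_tensor")) x else ag_tensor(x)

#' Reset the autograd tape
#'
#' Discards all recorded operations. Called at the start of every training
#' step and around no-gradient evaluations.
#' @return invisibly, NULL.
#' @export
ag_tape_reset <- function() {
  .ag$tape <- list()
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#'
#' @param expr expression to evaluate (e.g. a forward pass used for
#'   validation or prediction).
#' @return the value of `expr`.
#' @export
ag_no_grad <- function(expr) {
  old <- .ag$recording
  .ag$recording <- FALSE
  on.exit(.ag$recording <- old)
  force(expr)
}

# Record a node. backward(grad_out) must return a list of gradients aligned
# with `inputs` (NULL entries for inputs that need none).
ag_op <- function(value, inputs, backward) {
  rg <- .ag$recording &&
    any(vapply(inputs, function(t) t$requires_grad, logical(1)))
  out <- ag_tensor(value, requires_grad = rg)
  if (rg) .ag$tape[[length(.ag$tape) + 1L]] <-
      list(out = out, inputs = inputs, backward = backward)
  out
}

add_macs <- function(n) if (.ag$count_macs) .ag$macs <- .ag$macs + n

#' Backpropagate from a scalar loss tensor
#'
#' Walks the tape in reverse, accumulating gradients into every tensor with
#' `requires_grad = TRUE`. Gradients of intermediate (non-parameter) tensors
#' are released as soon as they have been consumed.
#'
#' @param loss an `ag_tensor` holding a scalar value.
#' @return invisibly, `loss`.
#' @export
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_tensor"), length(loss$value) == 1L)
  loss$grad <- 1
  tape <- .ag$tape
  for (i in rev(seq_along(tape))) {
    node <- tape[[i]]
    g <- node$out$grad
    if (is.null(g)) next
    gl <- node$backward(g)
    ins <- node$inputs
    for (j in seq_along(ins)) {
      gi <- gl[[j]]
      if (is.null(gi)) next
      t <- ins[[j]]
      if (!t$requires_grad) next
      t$grad <- if (is.null(t$grad)) gi else t$grad + gi
    }
    if (!isTRUE(node$out$is_param)) node$out$grad <- NULL
  }
  .ag$tape <- list()
  invisible(loss)
}

#' Count multiply-accumulate operations of an expression
#'
#' Runs `expr` with the profiler enabled and returns the number of
#' multiply-accumulate operations executed by convolution, batched
#' matrix-product and channel-convolution ops (the conv + matmul counting
#' convention; normalisation, activations, pooling and interpolation count
#' zero).
#'
#' @param expr expression performing forward computation.
#' @return number of MACs (a double, since counts exceed 2^31).
#' @export
ag_count_macs <- function(expr) {
  old <- .ag$count_macs
  .ag$count_macs <- TRUE
  .ag$macs <- 0
  on.exit(.ag$count_macs <- old)
  force(expr)
  .ag$macs
}

## ---- elementwise ----------------------------------------------------------

ag_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_relu <- function(x) {
  v <- x$value
  m <- v > 0
  ag_op(v * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_sumsq_mean <- function(x) {
  v <- x$value
  n <- length(v)
  ag_op(sum(v^2) / n, list(x), function(g) list((2 * g / n) * v))
}

## ---- shape ops ------------------------------------------------------------

ag_reshape <- function(x, newdim) {
  v <- x$value
  olddim <- dim(v)
  dim(v) <- newdim
  ag_op(v, list(x), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

# concatenate along the channel axis (3rd dim)
ag_concat_c <- function(tensors) {
  dims <- lapply(tensors, function(t) dim(t$value))
  d1 <- dims[[1]]
  cs <- vapply(dims, `[`, integer(1), 3L)
  Ctot <- sum(cs)
  out <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  at <- 0L
  for (i in seq_along(tensors)) {
    out[, , at + seq_len(cs[i]), ] <- tensors[[i]]$value
    at <- at + cs[i]
  }
  ag_op(out, tensors, function(g) {
    res <- vector("list", length(tensors))
    at <- 0L
    for (i in seq_along(tensors)) {
      res[[i]] <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      at <- at + cs[i]
    }
    res
  })
}

# channels from..to (inclusive, 1-based)
ag_narrow_c <- function(x, from, to) {
  d <- dim(x$value)
  v <- x$value[, , from:to, , drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , from:to, ] <- g
    list(gx)
  })
}

# repeat each channel `r` times (C -> C*r), used to broadcast reduced
# attention maps back over channel groups
ag_channel_repeat <- function(x, r) {
  d <- dim(x$value)
  C <- d[3]
  sel <- rep(seq_len(C), each = r)
  v <- x$value[, , sel, , drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, d)
    for (c in seq_len(C)) {
      cols <- (c - 1L) * r + seq_len(r)
      gx[, , c, ] <- apply(g[, , cols, , drop = FALSE], c(1, 2, 4), sum)
    }
    list(gx)
  })
}

## ---- conv / pool / resize -------------------------------------------------

ag_conv2d <- function(x, w, b, pad, dilation = 1L) {
  xv <- x$value; wv <- w$value
  bv <- if (is.null(b)) numeric(0) else b$value
  out <- cpp_conv2d_fw(xv, wv, bv, as.integer(pad), as.integer(dilation))
  d <- dim(out); wd <- dim(wv)
  add_macs(as.double(d[1]) * d[2] * d[4] * wd[1] * wd[2] * wd[3] * wd[4])
  inputs <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_op(out, inputs, function(g) {
    r <- cpp_conv2d_bw(xv, wv, g, as.integer(pad), as.integer(dilation),
                       need_gx = x$requires_grad, need_gw = w$requires_grad)
    gx <- if (x$requires_grad) r$gx else NULL
    gw <- if (w$requires_grad) r$gw else NULL
    if (is.null(b)) list(gx, gw) else list(gx, gw, r$gb)
  })
}

ag_avgpool2 <- function(x) {
  d <- dim(x$value)
  out <- cpp_avgpool2_fw(x$value)
  ag_op(out, list(x), function(g) list(cpp_avgpool2_bw(g, d[1], d[2])))
}

ag_maxpool2 <- function(x) {
  d <- dim(x$value)
  r <- cpp_maxpool2_fw(x$value)
  ag_op(r$out, list(x),
        function(g) list(cpp_maxpool2_bw(g, r$idx, d[1], d[2], d[3], d[4])))
}

ag_global_avgpool <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  xm <- x$value
  dim(xm) <- c(hw, d[3], d[4])
  v <- apply(xm, c(2, 3), mean)
  dim(v) <- c(1, 1, d[3], d[4])
  ag_op(v, list(x), function(g) {
    gv <- as.vector(g) / hw
    gx <- array(rep(gv, each = hw), d)
    list(gx)
  })
}

ag_resize_bilinear <- function(x, h_out, w_out) {
  d <- dim(x$value)
  if (d[1] == h_out && d[2] == w_out) return(x)
  out <- cpp_resize_bilinear_fw(x$value, as.integer(h_out), as.integer(w_out))
  ag_op(out, list(x), function(g) list(cpp_resize_bilinear_bw(g, d[1], d[2])))
}

## ---- batched matrix product ------------------------------------------------

# a: (n, k, B), b: (k, m, B) -> (n, m, B)
ag_bmm <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(da[2] == db[1], da[3] == db[3])
  B <- da[3]
  sl <- function(x, d, i) matrix(x[, , i], d[1], d[2])
  out <- array(0, c(da[1], db[2], B))
  dg <- c(da[1], db[2])
  for (i in seq_len(B)) out[, , i] <- sl(av, da, i) %*% sl(bv, db, i)
  add_macs(as.double(da[1]) * da[2] * db[2] * B)
  ag_op(out, list(a, b), function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (i in seq_len(B)) {
      gi <- sl(g, dg, i)
      ga[, , i] <- gi %*% t(sl(bv, db, i))
      gb[, , i] <- t(sl(av, da, i)) %*% gi
    }
    list(ga, gb)
  })
}

# (n, m, B) -> (m, n, B)
ag_btranspose <- function(x) {
  v <- aperm(x$value, c(2, 1, 3))
  ag_op(v, list(x), function(g) list(aperm(g, c(2, 1, 3))))
}

## ---- channel-wise helpers --------------------------------------------------

# multiply feature map (H, W, C, B) by per-channel weights (C, B)
ag_scale_channels <- function(x, w) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  expand <- function(wv) array(rep(wv, each = hw), d)
  wfull <- expand(w$value)
  xv <- x$value
  ag_op(xv * wfull, list(x, w), function(g) {
    gw_full <- g * xv
    dim(gw_full) <- c(hw, d[3], d[4])
    gw <- apply(gw_full, c(2, 3), sum)
    dim(gw) <- c(d[3], d[4])
    list(g * wfull, gw)
  })
}

# 1-D convolution across the channel axis with symmetric (edge-replicating)
# padding, so a channel-constant input yields channel-constant output;
# x: (C, B) tensor, w: length-k weights, b: length-1 bias
ag_conv1d_channels <- function(x, w, b) {
  xv <- x$value
  if (is.null(dim(xv))) dim(xv) <- c(length(xv), 1L)
  C <- nrow(xv); B <- ncol(xv)
  k <- length(w$value)
  half <- (k - 1L) %/% 2L
  # source channel for padded position: clamp into 1..C
  src <- pmin(pmax(seq_len(C + 2L * half) - half, 1L), C)
  pad <- xv[src, , drop = FALSE]
  out <- matrix(b$value, C, B)
  for (j in seq_len(k)) out <- out + w$value[j] * pad[(j - 1L) + seq_len(C), , drop = FALSE]
  add_macs(as.double(C) * k * B)
  ag_op(out, list(x, w, b), function(g) {
    gx <- matrix(0, C, B)
    gw <- numeric(k)
    for (j in seq_len(k)) {
      rows <- (j - 1L) + seq_len(C)
      gw[j] <- sum(g * pad[rows, , drop = FALSE])
      gpad <- matrix(0, C + 2L * half, B)
      gpad[rows, ] <- g
      # scatter padded-row gradients back onto their (clamped) source rows
      for (rr in seq_along(src)) gx[src[rr], ] <- gx[src[rr], ] + w$value[j] * gpad[rr, ]
    }
    list(gx, gw, sum(g))
  })
}

## ---- batch normalisation ---------------------------------------------------

# Per-channel normalisation over (rows, cols, batch). In training mode uses
# batch statistics and updates the module's running estimates; in eval mode
# uses the running estimates (so inference is deterministic).
ag_batchnorm <- function(x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  C <- d[3]
  hw <- d[1] * d[2]
  n <- hw * d[4]
  xm <- xv
  dim(xm) <- c(hw, C, d[4])
  if (training) {
    mu <- vapply(seq_len(C), function(c) mean(xm[, c, ]), numeric(1))
    va <- vapply(seq_len(C), function(c) {
      z <- xm[, c, ] - mu[c]
      sum(z * z) / n
    }, numeric(1))
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    ub <- if (n > 1) va * n / (n - 1) else va
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  bc <- function(v) array(rep(rep(v, each = hw), times = d[4]), d)
  xhat <- (xv - bc(mu)) * bc(inv)
  out <- xhat * bc(gamma$value) + bc(beta$value)
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(hw, C, d[4])
    xh <- xhat
    dim(xh) <- c(hw, C, d[4])
    dgamma <- vapply(seq_len(C), function(c) sum(gm[, c, ] * xh[, c, ]), numeric(1))
    dbeta <- vapply(seq_len(C), function(c) sum(gm[, c, ]), numeric(1))
    if (training) {
      # dx = (gamma*inv/n) * (n*g - sum(g) - xhat * sum(g*xhat)) per channel
      coef <- gamma$value * inv / n
      gx <- array(0, d)
      for (c in seq_len(C)) {
        gc <- gm[, c, ]
        xc <- xh[, c, ]
        dxc <- coef[c] * (n * gc - dbeta[c] - xc * dgamma[c])
        gx[, , c, ] <- dxc
      }
      list(gx, dgamma, dbeta)
    } else {
      gx <- g * bc(gamma$value * inv)
      list(gx, dgamma, dbeta)
    }
  })
}
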