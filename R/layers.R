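# Trainable layer constructors. A "module" is an environment with
#   $params   named list of ag_tensor parameters
#   $children named list of sub-modules
#   $forward  function(x, training = FALSE) (signature varies per module)
# Parameters use Kaiming-uniform initialisation (bound sqrt(6 / fan_in));
# batch-norm starts at gamma = 1, beta = 0.

new_module <- function() {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$children <- list()
  class(m) <- "ag_module"
  m
}

mk_param <- function(value) {
  t <- ag_tensor(value, requires_grad = TRUE)
  t$is_param <- TRUE
  t
}

#' Collect trainable parameters of a module tree
#'
#' @param mod a module (network, block or layer).
#' @return named list of `ag_tensor` parameters, depth-first.
#' @export
collect_params <- function(mod) {
  out <- mod$params
  for (nm in names(mod$children)) {
    sub <- collect_params(mod$children[[nm]])
    if (length(sub))
      names(sub) <- paste(nm, names(sub), sep = ".")
    out <- c(out, sub)
  }
  out
}

nn_conv2d <- function(in_ch, out_ch, k, dilation = 1L, bias = TRUE) {
  m <- new_module()
  fan_in <- k * k * in_ch
  bound <- sqrt(6 / fan_in)
  m$params$w <- mk_param(array(stats::runif(k * k * in_ch * out_ch, -bound, bound),
                               c(k, k, in_ch, out_ch)))
  if (bias) {
    bb <- 1 / sqrt(fan_in)
    m$params$b <- mk_param(stats::runif(out_ch, -bb, bb))
  }
  m$pad <- as.integer(dilation * (k - 1L) / 2L)  # size-preserving zero padding
  m$dilation <- as.integer(dilation)
  m$forward <- function(x, training = FALSE) {
    ag_conv2d(x, m$params$w, m$params$b, m$pad, m$dilation)
  }
  m
}

nn_batchnorm <- function(ch) {
  m <- new_module()
  m$params$gamma <- mk_param(rep(1, ch))
  m$params$beta <- mk_param(rep(0, ch))
  m$running_mean <- rep(0, ch)
  m$running_var <- rep(1, ch)
  m$forward <- function(x, training = FALSE) {
    ag_batchnorm(x, m$params$gamma, m$params$beta, m, training)
  }
  m
}

# conv (+ BN) (+ ReLU): the composite unit used throughout the network.
# Gate convolutions that feed a sigmoid are built with act = FALSE so the
# sigmoid sees signed values; norm = FALSE disables normalisation (used by
# the loop-oracle equivalence tests).
nn_conv_unit <- function(in_ch, out_ch, k = 3L, dilation = 1L,
                         norm = TRUE, act = TRUE) {
  m <- new_module()
  # a bias ahead of batch normalisation is redundant (BN subtracts the
  # channel mean, so its gradient is identically zero); convs keep a bias
  # only when normalisation is off
  m$children$conv <- nn_conv2d(in_ch, out_ch, k, dilation, bias = !norm)
  if (norm) m$children$bn <- nn_batchnorm(out_ch)
  m$act <- act
  m$forward <- function(x, training = FALSE) {
    h <- m$children$conv$forward(x, training)
    if (!is.null(m$children$bn)) h <- m$children$bn$forward(h, training)
    if (m$act) h <- ag_relu(h)
    h
  }
  m
}

# Adam optimiser over a flat parameter list.
new_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim(as.array(p$value))))
  opt$v <- lapply(params, function(p) array(0, dim(as.array(p$value))))
  opt$step <- function() {
    opt$t <- opt$t + 1L
    bc1 <- 1 - opt$beta1^opt$t
    bc2 <- 1 - opt$beta2^opt$t
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
      opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
      mhat <- opt$m[[i]] / bc1
      vhat <- opt$v[[i]] / bc2
      p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  opt$zero_grad <- function() {
    for (p in opt$params) p$grad <- NULL
  }
  opt
}
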