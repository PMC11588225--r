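# Finite-difference gradient checking utilities.
#
# An op is checked by projecting its output onto a fixed random array P
# (scalar loss s = sum(out * P)), backpropagating, and comparing each
# analytic input gradient against central differences.

proj_loss <- function(out, P) {
  afcfnet:::ag_op(sum(out$value * P), list(out), function(g) list(g * P))
}

numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_grad_match <- function(analytic, numeric, tol = 1e-5) {
  scale <- max(1, max(abs(numeric)))
  expect_lt(max(abs(analytic - numeric)) / scale, tol)
}

# Check gradients of `op_fn(tensors...) -> tensor` w.r.t. each input value.
check_op_grads <- function(op_fn, values, tol = 1e-5, seed = 99) {
  set.seed(seed)
  tensors <- lapply(values, ag_tensor, requires_grad = TRUE)
  out <- do.call(op_fn, tensors)
  P <- array(stats::rnorm(length(out$value)), dim(as.array(out$value)))
  ag_tape_reset()
  tensors <- lapply(values, ag_tensor, requires_grad = TRUE)
  out <- do.call(op_fn, tensors)
  loss <- proj_loss(out, P)
  ag_backward(loss)
  for (j in seq_along(values)) {
    f <- function(v) {
      vs <- values
      vs[[j]] <- v
      ts <- lapply(vs, ag_tensor)
      sum(do.call(op_fn, ts)$value * P)
    }
    expect_grad_match(tensors[[j]]$grad, numeric_grad(f, values[[j]]), tol)
  }
  invisible(NULL)
}
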