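# Independent nested-loop reference implementations of the block equations.
# These operate on single-sample 3-D arrays (rows, cols, channels) with
# plain R loops and never call the package's C++ kernels or autograd ops,
# so agreement with the blocks is a genuine dual-route check. The blocks
# under test are built with norm = FALSE so only conv / pool / resize /
# activation arithmetic is compared.

o_conv2d <- function(x, w, b, pad, dil = 1L) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]
  k <- dim(w)[1]; Co <- dim(w)[4]
  out <- array(0, c(H, W, Co))
  for (co in seq_len(Co)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Ci)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      wv <- w[kh, kw, ci, co]
      if (wv == 0) next
      for (wo in seq_len(W)) {
        wi <- wo - pad + dil * (kw - 1L)
        if (wi < 1 || wi > W) next
        for (ho in seq_len(H)) {
          hi <- ho - pad + dil * (kh - 1L)
          if (hi < 1 || hi > H) next
          acc[ho, wo] <- acc[ho, wo] + wv * x[hi, wi, ci]
        }
      }
    }
    out[, , co] <- acc
  }
  out
}

o_avgpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H %/% 2L, W %/% 2L, C))
  for (c in seq_len(C)) for (wo in seq_len(W %/% 2L)) for (ho in seq_len(H %/% 2L))
    out[ho, wo, c] <- mean(x[2 * ho - 1:0, 2 * wo - 1:0, c])
  out
}

o_bilinear <- function(x, Ho, Wo) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (H == Ho && W == Wo) return(x)
  coef <- function(n_in, n_out) {
    src <- pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
    i0 <- floor(src)
    list(i0 = i0 + 1, i1 = pmin(i0 + 1, n_in - 1) + 1, fr = src - i0)
  }
  ch <- coef(H, Ho); cw <- coef(W, Wo)
  out <- array(0, c(Ho, Wo, C))
  for (c in seq_len(C)) for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
    th <- ch$fr[ho]; tw <- cw$fr[wo]
    c0 <- x[ch$i0[ho], cw$i0[wo], c] +
      th * (x[ch$i1[ho], cw$i0[wo], c] - x[ch$i0[ho], cw$i0[wo], c])
    c1 <- x[ch$i0[ho], cw$i1[wo], c] +
      th * (x[ch$i1[ho], cw$i1[wo], c] - x[ch$i0[ho], cw$i1[wo], c])
    out[ho, wo, c] <- c0 + tw * (c1 - c0)
  }
  out
}

o_sig <- function(x) 1 / (1 + exp(-x))

# replicate a norm-free conv unit from its module weights
o_unit <- function(unit, x, act = TRUE) {
  conv <- unit$children$conv
  b <- if (is.null(conv$params$b)) rep(0, dim(conv$params$w$value)[4])
       else conv$params$b$value
  y <- o_conv2d(x, conv$params$w$value, b, conv$pad, conv$dilation)
  if (act) pmax(y, 0) else y
}

cat3 <- function(...) {
  parts <- list(...)
  do.call(function(...) {
    arrs <- list(...)
    H <- dim(arrs[[1]])[1]; W <- dim(arrs[[1]])[2]
    array(unlist(arrs), c(H, W, sum(vapply(arrs, function(a) dim(a)[3], 0))))
  }, parts)
}

# SCFCConv: split, local+atrous branch, pooled sigmoid-gate branch, concat
oracle_scfc <- function(block, x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  h <- C %/% 2L
  x1 <- x[, , seq_len(h), drop = FALSE]
  x2 <- x[, , h + seq_len(h), drop = FALSE]
  ch <- block$children
  t1 <- o_unit(ch$c3a, x1)
  y1 <- o_unit(ch$c1, cat3(o_unit(ch$c3d, t1), t1))
  low <- o_bilinear(o_unit(ch$c3low, o_avgpool2(x2), act = FALSE), H, W)
  gate <- o_sig(low + x2)
  y2 <- o_unit(ch$c3out, o_unit(ch$c3hi, x2) * gate)
  cat3(y1, y2)
}

# FSFConv: Z = C3(X1 + Y2) * sigmoid(U(C3(X2 + Y1))) + Y
oracle_fsf <- function(block, x_high, y_low) {
  H <- dim(y_low)[1]; W <- dim(y_low)[2]
  ch <- block$children
  X1 <- o_unit(ch$cx1, o_bilinear(x_high, H, W))
  X2 <- o_unit(ch$cx2, x_high)
  Y1 <- o_unit(ch$cy1, o_avgpool2(y_low))
  Y2 <- o_unit(ch$cy2, y_low)
  gate <- o_sig(o_bilinear(o_unit(ch$cgate, X2 + Y1, act = FALSE), H, W))
  o_unit(ch$cz, X1 + Y2) * gate + y_low
}

# sigmoid spatial self-attention with explicit matrix arithmetic
oracle_attention <- function(attn, a) {
  H <- dim(a)[1]; W <- dim(a)[2]; C <- dim(a)[3]
  r <- attn$reduction
  Cr <- C %/% r
  ch <- attn$children
  tomat <- function(arr) matrix(as.vector(arr), H * W, Cr)
  Q <- tomat(o_unit(ch$q, a))
  K <- tomat(o_unit(ch$k, a))
  V <- tomat(o_unit(ch$v, a))
  S <- o_sig(Q %*% t(K))          # (positions x positions) affinity
  att <- S %*% V                  # attended value, (positions x Cr)
  full <- array(att, c(H, W, Cr))[, , rep(seq_len(Cr), each = r), drop = FALSE]
  full * a
}

# FARM, Algorithm-style: pooling branch, 1x1 branch, three attended
# dilated branches, concat, 1x1 out
oracle_farm <- function(block, x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ch <- block$children
  gap <- array(apply(x, 3, mean), c(1, 1, dim(x)[3]))
  X1 <- o_bilinear(o_unit(ch$cpool, gap), H, W)
  base <- x + X1
  X2 <- o_unit(ch$cx2, base)
  br <- lapply(1:3, function(i) {
    a <- o_unit(ch[[paste0("cd", i)]], base)
    oracle_attention(ch[[paste0("att", i)]], a)
  })
  o_unit(ch$cout, cat3(X1, X2, br[[1]], br[[2]], br[[3]]))
}

to4 <- function(a) array(a, c(dim(a)[1], dim(a)[2], dim(a)[3], 1L))
drop4 <- function(a) array(a, dim(a)[1:3])

# set every conv weight in a module tree to 1/fan_in and biases to zero
set_uniform_weights <- function(mod) {
  if (!is.null(mod$params$w) && length(dim(mod$params$w$value)) == 4L) {
    d <- dim(mod$params$w$value)
    mod$params$w$value <- array(1 / (d[1] * d[2] * d[3]), d)
    if (!is.null(mod$params$b)) mod$params$b$value[] <- 0
  }
  for (child in mod$children) set_uniform_weights(child)
  invisible(mod)
}

zero_all_weights <- function(mod) {
  if (!is.null(mod$params$w)) {
    mod$params$w$value[] <- 0
    if (!is.null(mod$params$b)) mod$params$b$value[] <- 0
  }
  for (child in mod$children) zero_all_weights(child)
  invisible(mod)
}
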