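# The three feature blocks and the channel attention: shape contracts,
# validation, loop-oracle equivalence, gate ranges and differentiability.

test_that("block configuration enforces its invariants", {
  expect_s3_class(block_config(8L), "block_config")
  expect_error(block_config(7L), "even")
  expect_error(block_config(8L, farm_dilations = c(4, 2, 6)), "increasing")
  expect_error(new_farm_attention(6L, reduction = 4L), "divide")
})

test_that("SCFCConv preserves shape over a grid of sizes and rejects bad input", {
  set.seed(21)
  for (C in c(2L, 4L, 8L)) {
    blk <- new_scfc_block(block_config(C, scfc_dilation = 2L))
    for (hw in list(c(4L, 4L), c(6L, 10L), c(32L, 32L))) {
      x <- array(rnorm(hw[1] * hw[2] * C * 2), c(hw, C, 2L))
      y <- scfc_forward(blk, x)
      expect_identical(dim(y), dim(x))
      expect_true(all(is.finite(y)))
    }
  }
  blk <- new_scfc_block(block_config(4L))
  expect_error(scfc_forward(blk, array(0, c(8, 8, 6, 1))), "channels")
  expect_error(scfc_forward(blk, array(0, c(1, 8, 4, 1))), ">= 2")
})

test_that("SCFCConv matches the nested-loop oracle", {
  # all-ones input with 1/fan-in weights, and a random seeded instance
  for (variant in c("uniform", "random")) {
    set.seed(22)
    blk <- new_scfc_block(block_config(4L, scfc_dilation = 2L), norm = FALSE)
    if (variant == "uniform") set_uniform_weights(blk)
    x <- if (variant == "uniform") array(1, c(8, 8, 4, 1))
         else array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)) * 0.5
    got <- scfc_forward(blk, x)
    want <- oracle_scfc(blk, drop4(x))
    expect_lt(max(abs(drop4(got) - want)), 1e-5)
  }
})

test_that("FSFConv shape contract, input validation and oracle equivalence", {
  set.seed(23)
  blk <- new_fsf_block(8L)
  xh <- array(rnorm(16 * 16 * 16), c(16, 16, 16, 1))
  yl <- array(rnorm(32 * 32 * 8), c(32, 32, 8, 1))
  z <- fsf_forward(blk, xh, yl)
  expect_identical(dim(z), dim(yl))
  expect_error(fsf_forward(blk, array(0, c(16, 16, 12, 1)), yl), "twice")
  expect_error(fsf_forward(blk, array(0, c(12, 16, 16, 1)), yl), "half")

  blk2 <- new_fsf_block(2L, norm = FALSE)
  xh2 <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)) * 0.5
  yl2 <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)) * 0.5
  got <- fsf_forward(blk2, xh2, yl2)
  want <- oracle_fsf(blk2, drop4(xh2), drop4(yl2))
  expect_lt(max(abs(drop4(got) - want)), 1e-5)
})

test_that("FSFConv with zeroed weights is the identity on its low-level input", {
  set.seed(24)
  for (norm in c(TRUE, FALSE)) {
    blk <- new_fsf_block(4L, norm = norm)
    zero_all_weights(blk)
    xh <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
    yl <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 1))
    expect_equal(fsf_forward(blk, xh, yl), yl, tolerance = 1e-12)
  }
})

test_that("FARM attention matches explicit matrix arithmetic and keeps affinities in (0,1)", {
  set.seed(25)
  attn <- new_farm_attention(2L, reduction = 2L, norm = FALSE)
  a <- array(rnorm(2 * 2 * 2), c(2, 2, 2, 1))
  got <- farm_attention(attn, a)
  expect_identical(dim(got), dim(a))
  want <- oracle_attention(attn, drop4(a))
  expect_lt(max(abs(drop4(got) - want)), 1e-10)

  # hand-computable instance: projections fixed so Q = K = V = first channel
  attn2 <- new_farm_attention(2L, reduction = 2L, norm = FALSE)
  for (nm in c("q", "k", "v")) {
    conv <- attn2$children[[nm]]$children$conv
    conv$params$w$value[] <- 0
    conv$params$w$value[1, 1, 1, 1] <- 1
    conv$params$b$value[] <- 0
  }
  a2 <- array(0, c(1, 2, 2, 1))
  a2[, , 1, ] <- c(1, -1)   # the projected (ReLU-ed) channel: (1, 0)
  a2[, , 2, ] <- c(2, 3)
  q <- c(1, 0)
  S <- 1 / (1 + exp(-outer(q, q)))        # affinities sigma(q_i q_j)
  att <- as.vector(S %*% q)               # attended value per position
  want2 <- a2
  want2[, , 1, ] <- att * a2[, , 1, ]
  want2[, , 2, ] <- att * a2[, , 2, ]
  expect_equal(drop4(farm_attention(attn2, a2)), drop4(want2), tolerance = 1e-12)
  expect_true(all(S > 0 & S < 1))
})

test_that("FARM preserves shape, uses the configured dilation rates, and matches the oracle", {
  set.seed(26)
  cfg <- block_config(8L, farm_dilations = c(2L, 4L, 6L))
  blk <- new_farm_block(cfg)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  y <- farm_forward(blk, x)
  expect_identical(dim(y), dim(x))
  # the dilated branches in the graph carry exactly the configured rates
  rates <- vapply(1:3, function(i)
    blk$children[[paste0("cd", i)]]$children$conv$dilation, integer(1))
  expect_identical(rates, cfg$farm_dilations)

  blk2 <- new_farm_block(block_config(4L, farm_dilations = c(1L, 2L, 3L),
                                      attention_reduction = 2L), norm = FALSE)
  x2 <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1)) * 0.5
  got <- farm_forward(blk2, x2)
  want <- oracle_farm(blk2, drop4(x2))
  expect_lt(max(abs(drop4(got) - want)), 1e-5)
})

test_that("FARM pooling branch reproduces a spatially constant input", {
  # with identity 1x1 pooling conv, no normalisation, a constant map's
  # global average equals the map, so X1 == input
  blk <- new_farm_block(block_config(2L, attention_reduction = 2L), norm = FALSE)
  cpool <- blk$children$cpool$children$conv
  cpool$params$w$value[] <- 0
  for (c in 1:2) cpool$params$w$value[1, 1, c, c] <- 1
  cpool$params$b$value[] <- 0
  x <- array(rep(c(0.7, 0.3), each = 16), c(4, 4, 2, 1))
  X1 <- afcfnet:::ag_no_grad({
    g <- afcfnet:::ag_global_avgpool(ag_tensor(x))
    afcfnet:::ag_resize_bilinear(blk$children$cpool$forward(g), 4L, 4L)
  })
  expect_equal(X1$value, x, tolerance = 1e-12)
})

test_that("ECA weights: symmetry, range, and the hand-evaluated 1-D convolution", {
  eca <- new_eca(3L)
  expect_error(new_eca(4L), "odd")
  x_const <- array(0.4, c(6, 6, 5, 2))
  w <- eca_weights(eca, x_const)
  expect_equal(dim(w), c(5L, 2L))
  expect_true(all(abs(w - w[1, 1]) < 1e-12))  # all channels identical
  set.seed(27)
  w2 <- eca_weights(eca, array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2)))
  expect_true(all(w2 > 0 & w2 < 1))

  # kernel (0, 1, 0), zero bias: weights are sigmoid of the channel means
  eca$params$w$value <- c(0, 1, 0)
  eca$params$b$value <- 0
  x <- array(0, c(2, 2, 4, 1))
  for (c in 1:4) x[, , c, ] <- c
  expect_equal(as.vector(eca_weights(eca, x)), 1 / (1 + exp(-(1:4))),
               tolerance = 1e-12)
})

test_that("every trainable weight of every block receives gradient", {
  set.seed(28)
  blocks <- list(
    scfc = list(mod = new_scfc_block(block_config(4L, scfc_dilation = 2L)),
                fwd = function(m, t) m$forward(t, training = TRUE)),
    farm = list(mod = new_farm_block(block_config(4L, attention_reduction = 2L)),
                fwd = function(m, t) m$forward(t, training = TRUE)),
    fsf = list(mod = new_fsf_block(4L),
               fwd = function(m, t) m$forward(
                 ag_tensor(array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))),
                 t, training = TRUE)))
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    ag_tape_reset()
    x <- ag_tensor(array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2)))
    out <- b$fwd(b$mod, x)
    ag_backward(afcfnet:::ag_sumsq_mean(out))
    params <- collect_params(b$mod)
    dead <- names(params)[vapply(params, function(p)
      is.null(p$grad) || all(p$grad == 0), logical(1))]
    expect_length(dead, 0)
    for (p in params) p$grad <- NULL
  }
})
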