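# Network assembly: configuration validation, forward contracts, ablation
# variants, parameter and MAC accounting, determinism, checkpoints.

test_that("configuration validation rejects invalid settings", {
  expect_error(network_config(stage_widths = c(4, 8, 16, 32)), "five")
  expect_error(network_config(stage_widths = c(3, 8, 16, 32, 64),
                              use_scfc = TRUE), "even")
  expect_error(network_config(input_size = c(100, 100)), "divisible by 16")
  # odd widths are fine when the calibration conv is off... but still >= 2
  cfg <- network_config(stage_widths = c(6, 10, 18, 34, 66), use_scfc = FALSE,
                        use_fsf = FALSE, use_farm = FALSE,
                        use_aggregation = FALSE)
  expect_s3_class(cfg, "network_config")
})

test_that("forward maps (rows, cols, 3, B) to a probability map of the same size", {
  cfg <- network_config(input_size = c(32L, 32L))
  net <- build_network(cfg, seed = 3)
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p <- net_forward(net, x)
  expect_identical(dim(p), c(32L, 32L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))
  # a different divisible-by-16 size works on the same weights
  x2 <- array(runif(48 * 48 * 3), c(48, 48, 3, 1))
  expect_identical(dim(net_forward(net, x2)), c(48L, 48L, 1L, 1L))
  expect_error(net_forward(net, array(0, c(40, 40, 3, 1))), "divisible by 16")
  expect_error(net_forward(net, array(0, c(32, 32, 4, 1))), "channels")
})

test_that("forward is deterministic in eval mode", {
  net <- build_network(network_config(input_size = c(32L, 32L)), seed = 5)
  set.seed(9)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(net_forward(net, x), net_forward(net, x))
  net2 <- build_network(network_config(input_size = c(32L, 32L)), seed = 5)
  expect_identical(net_forward(net, x), net_forward(net2, x))
})

test_that("parameter counting matches closed forms", {
  # single 3x3 conv, 3 -> 4 channels, with bias: 3*3*3*4 + 4 = 112
  set.seed(1)
  conv <- afcfnet:::nn_conv2d(3L, 4L, 3L, bias = TRUE)
  expect_equal(count_params(conv), 112)
  # baseline U-Net: closed-form sum over its conv/BN layers
  w <- c(4L, 8L, 16L, 32L, 64L)
  conv_bn <- function(cin, cout, k) k * k * cin * cout + 2 * cout
  expected <- conv_bn(3, w[1], 3) + conv_bn(w[1], w[1], 3)
  for (i in 2:5) expected <- expected +
    conv_bn(w[i - 1], w[i], 3) + conv_bn(w[i], w[i], 3)
  for (i in 4:1) expected <- expected +
    conv_bn(2 * w[i], w[i], 1) +      # upsample conv
    conv_bn(2 * w[i], w[i], 3) + conv_bn(w[i], w[i], 3)
  expected <- expected + (w[1] * 1 + 1)   # head, bias, no BN
  net <- build_network(table_variant_config(0), seed = 2)
  expect_equal(count_params(net), expected)
})

test_that("MAC counting: pointwise closed form and area scaling", {
  # 1x1 conv C1 -> C2 on H x W costs H*W*C1*C2
  set.seed(1)
  conv <- afcfnet:::nn_conv2d(6L, 4L, 1L)
  x <- ag_tensor(array(0, c(10, 12, 6, 1)))
  macs <- ag_count_macs(afcfnet:::ag_no_grad(conv$forward(x)))
  expect_equal(macs, 10 * 12 * 6 * 4)
  # conv-only counting quadruples when both spatial dims double
  net <- build_network(table_variant_config(0), seed = 2)
  expect_equal(count_macs(net, c(64, 64)), 4 * count_macs(net, c(32, 32)))
})

test_that("the ablation variants are all constructible, distinct, and monotone", {
  counts <- vapply(0:8, function(s) {
    net <- build_network(table_variant_config(s), seed = 1)
    c(count_params(net), count_macs(net, c(64, 64)))
  }, numeric(2))
  expect_equal(anyDuplicated(counts[1, ]), 0)
  expect_equal(anyDuplicated(counts[2, ]), 0)
  # enabling a component never decreases either count
  leq <- function(a, b) all(counts[, a + 1] <= counts[, b + 1])
  expect_true(leq(0, 1)); expect_true(leq(0, 2)); expect_true(leq(0, 3))
  expect_true(leq(1, 4)); expect_true(leq(2, 4)); expect_true(leq(1, 5))
  expect_true(leq(3, 5)); expect_true(leq(2, 6)); expect_true(leq(3, 6))
  expect_true(leq(4, 7)); expect_true(leq(5, 7)); expect_true(leq(6, 7))
  expect_true(leq(7, 8))
  # mac ordering reported for the study: baseline < +scfc < +scfc+fsf < all three <= full
  expect_true(counts[2, 1] < counts[2, 2])
  expect_true(counts[2, 2] < counts[2, 5])
  expect_true(counts[2, 5] < counts[2, 8])
  expect_true(counts[2, 8] <= counts[2, 9])
})

test_that("decoder widths mirror the encoder stage widths in reverse", {
  net <- build_network(network_config(), seed = 1)
  w <- net$cfg$stage_widths
  for (i in 4:1) {
    up <- net$children[[paste0("dec", i, "_up")]]$children$conv
    expect_identical(dim(up$params$w$value)[3:4], c(2L * w[i], w[i]))
    second <- net$children[[paste0("dec", i, "_b")]]
    expect_equal(second$cfg$channels, w[i])
  }
})

test_that("aggregation with zeroed side paths returns D4, and its gradients flow", {
  net <- build_network(network_config(input_size = c(32L, 32L)), seed = 6)
  set.seed(6)
  d1 <- array(rnorm(4 * 4 * 32), c(4, 4, 32, 1))
  d2 <- array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))
  d3 <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  d4 <- array(rnorm(32 * 32 * 4), c(32, 32, 4, 1))
  out <- aggregation_forward(net, d1, d2, d3, d4)
  expect_identical(dim(out), dim(d4))
  expect_error(aggregation_forward(net, d2, d2, d3, d4), "1/8")
  # gradient reaches every channel-attention kernel from the network output
  ag_tape_reset()
  x <- ag_tensor(array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  pred <- net_forward(net, x, training = TRUE)
  ag_backward(afcfnet:::ag_sumsq_mean(pred))
  for (j in 1:3) {
    g <- net$children[[paste0("eca", j)]]$params$w$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
  for (p in collect_params(net)) p$grad <- NULL
  # zero the fusing convolution (fresh normalisation statistics):
  # additive identity on D4
  net_id <- build_network(network_config(input_size = c(32L, 32L)), seed = 6)
  net_id$children$agg_fuse$children$conv$params$w$value[] <- 0
  expect_equal(aggregation_forward(net_id, d1, d2, d3, d4), d4,
               tolerance = 1e-12)
})

test_that("checkpoints round-trip weights, buffers and configuration", {
  cfg <- network_config(stage_widths = c(2L, 4L, 8L, 16L, 32L),
                        attention_reduction = 2L,
                        input_size = c(32L, 32L))
  net <- build_network(cfg, seed = 8)
  set.seed(8)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p1 <- net_forward(net, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(net2$cfg$stage_widths, cfg$stage_widths)
  expect_identical(net_forward(net2, x), p1)
  unlink(path)
})
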