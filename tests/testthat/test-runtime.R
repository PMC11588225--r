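# Dataset round trips, the training loop contract, evaluation averaging
# and file prediction.

make_tmp_dataset <- function(n = 10, size = 32L, seed = 300) {
  sp <- scene_params(image_size = c(size, size), hair_count = 1L)
  split <- generate_split(sp, n, seed = seed)
  dir <- tempfile("ds_")
  write_dataset(split, dir)
  list(split = split, dir = dir)
}

test_that("a written split loads back bit-exactly", {
  ds <- make_tmp_dataset()
  on.exit(unlink(ds$dir, recursive = TRUE))
  loaded <- load_dataset(file.path(ds$dir, "train"))
  expect_length(loaded, length(ds$split$train))
  expect_length(attr(loaded, "missing_masks"), 0)
  for (i in seq_along(loaded)) {
    expect_equal(loaded[[i]]$image, ds$split$train[[i]]$image,
                 tolerance = 1e-12)
    expect_identical(loaded[[i]]$mask, ds$split$train[[i]]$mask)
  }
  expect_true(file.exists(file.path(ds$dir, "manifest.csv")))
})

test_that("an image without a mask is flagged, not silently dropped", {
  ds <- make_tmp_dataset()
  on.exit(unlink(ds$dir, recursive = TRUE))
  orphan <- file.path(ds$dir, "train", "images", "orphan.png")
  file.copy(list.files(file.path(ds$dir, "train", "images"),
                       full.names = TRUE)[1], orphan)
  expect_warning(loaded <- load_dataset(file.path(ds$dir, "train")),
                 "lack a mask")
  expect_identical(attr(loaded, "missing_masks"), "orphan.png")
  expect_length(loaded, length(ds$split$train))
})

test_that("grayscale {0, 255} masks binarize to {0, 1} and resizing keeps masks binary", {
  ds <- make_tmp_dataset(size = 48L)
  on.exit(unlink(ds$dir, recursive = TRUE))
  loaded <- load_dataset(file.path(ds$dir, "train"), input_size = c(32L, 32L))
  for (s in loaded) {
    expect_true(all(s$mask %in% c(0, 1)))
    expect_identical(dim(s$image), c(32L, 32L, 3L))
  }
})

test_that("training decreases the loss deterministically and decay halves the rate", {
  sp <- scene_params(image_size = c(32L, 32L), hair_count = 1L)
  samples <- lapply(1:4, function(i) generate_sample(sp, 400 + i))
  net <- build_network(network_config(input_size = c(32L, 32L)), seed = 11)
  cfg <- train_config(epochs = 12, batch_size = 4, initial_lr = 3e-3,
                      seed = 12)
  r1 <- train_network(net, samples, cfg = cfg)
  expect_equal(nrow(r1$history), 12)
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  net2 <- build_network(network_config(input_size = c(32L, 32L)), seed = 11)
  r2 <- train_network(net2, samples, cfg = cfg)
  expect_identical(r1$history$train_loss, r2$history$train_loss)

  # with a vanishing learning rate the validation loss cannot improve, so
  # the plateau rule must multiply the rate by exactly the decay factor
  net3 <- build_network(network_config(input_size = c(32L, 32L)), seed = 11)
  cfg3 <- train_config(epochs = 4, batch_size = 4, initial_lr = 1e-12,
                       lr_decay_factor = 0.5, decay_patience_epochs = 2L,
                       seed = 12)
  r3 <- train_network(net3, samples, val_samples = samples[1:2], cfg = cfg3)
  expect_equal(tail(r3$history$lr, 1), 1e-12 * 0.5)
  expect_true(all(diff(r3$history$lr) <= 0))  # lr is non-increasing
  expect_error(train_network(net3, list()), "empty")
})

test_that("macro evaluation equals the hand-computed mean of per-image IoUs", {
  sp <- scene_params(image_size = c(32L, 32L), hair_count = 1L)
  samples <- lapply(1:3, function(i) generate_sample(sp, 500 + i))
  net <- build_network(network_config(input_size = c(32L, 32L)), seed = 13)
  ev <- evaluate_network(net, samples)
  by_hand <- vapply(samples, function(s) {
    x <- array(c(s$image), c(32, 32, 3, 1))
    p <- net_forward(net, x)
    seg_metrics(confusion(p[, , 1, 1], s$mask, 0.5))$iou
  }, numeric(1))
  expect_equal(ev$per_image$iou, by_hand, tolerance = 1e-12)
  expect_equal(ev$macro$mean[ev$macro$metric == "iou"], mean(by_hand),
               tolerance = 1e-12)
  expect_true(all(ev$per_image$iou >= 0 & ev$per_image$iou <= 1, na.rm = TRUE))
  expect_error(evaluate_network(net, list()), "empty")
})

test_that("file prediction writes a binary mask at the input resolution", {
  sp <- scene_params(image_size = c(48L, 48L))
  s <- generate_sample(sp, 600)
  dir <- tempfile("pred_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  img_path <- file.path(dir, "img.png")
  out_path <- file.path(dir, "img_pred.png")
  afcfnet:::write_image_file(s$image, img_path)
  net <- build_network(network_config(input_size = c(32L, 32L)), seed = 14)
  mask <- predict_mask(net, img_path, out_path)
  expect_identical(dim(mask), c(48L, 48L))
  written <- EBImage::imageData(EBImage::readImage(out_path))
  expect_true(all(written %in% c(0, 1)))      # {0, 255} in the 8-bit file
  expect_identical(dim(written), c(48L, 48L))
  expect_error(predict_mask(net, file.path(dir, "nope.png"), out_path),
               "cannot read")
})

test_that("prediction through files is consistent with in-memory evaluation", {
  sp <- scene_params(image_size = c(32L, 32L))
  s <- generate_sample(sp, 601)
  dir <- tempfile("pred2_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  img_path <- file.path(dir, "img.png")
  afcfnet:::write_image_file(s$image, img_path)
  net <- build_network(network_config(input_size = c(32L, 32L)), seed = 15)
  mask <- predict_mask(net, img_path, file.path(dir, "out.png"))
  p <- net_forward(net, array(c(s$image), c(32, 32, 3, 1)))
  expect_identical(mask, matrix(as.numeric(p[, , 1, 1] >= 0.5), 32, 32))
})
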