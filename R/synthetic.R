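# Deterministic synthetic dermoscopy generator. Emulates the phenomenology
# the segmentation task has to cope with: roughly elliptical lesions with
# irregular (star-convex) boundaries and soft edges, lower-frequency texture
# inside the lesion, a background illumination gradient, hair-like
# curvilinear distractors that are NOT part of the mask, and additive
# Gaussian pixel noise. All randomness flows through an explicit seed and
# the generator restores the caller's RNG state.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Scene parameters for the synthetic generator
#'
#' @param image_size `(rows, cols)` of the generated images.
#' @param lesion_area_fraction closed interval inside (0, 1); the mask area
#'   fraction is drawn uniformly from it and enforced by construction.
#' @param boundary_harmonics number of random radial harmonics perturbing
#'   the elliptical boundary.
#' @param boundary_amplitude scale of the harmonic perturbation.
#' @param lesion_contrast how much darker the lesion is than the background
#'   (in [0, 1] intensity units).
#' @param hair_count number of hair-like curvilinear distractors.
#' @param hair_width_px stroke width of the hairs, pixels.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param background_gradient amplitude of the linear illumination gradient.
#' @return a `scene_params` list.
#' @export
scene_params <- function(image_size = c(128L, 128L),
                         lesion_area_fraction = c(0.10, 0.40),
                         boundary_harmonics = 6L,
                         boundary_amplitude = 0.25,
                         lesion_contrast = 0.35,
                         hair_count = 4L,
                         hair_width_px = 1.5,
                         noise_sd = 0.02,
                         background_gradient = 0.15) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 16L))
  if (length(lesion_area_fraction) != 2L ||
      lesion_area_fraction[1] <= 0 || lesion_area_fraction[2] >= 1 ||
      diff(lesion_area_fraction) < 0)
    stop("`lesion_area_fraction` must be a closed interval inside (0, 1)",
         call. = FALSE)
  vals <- c(boundary_amplitude, lesion_contrast, hair_width_px, noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0) || hair_count < 0)
    stop("magnitudes must be finite and nonnegative", call. = FALSE)
  structure(list(image_size = image_size,
                 lesion_area_fraction = as.numeric(lesion_area_fraction),
                 boundary_harmonics = as.integer(boundary_harmonics),
                 boundary_amplitude = boundary_amplitude,
                 lesion_contrast = lesion_contrast,
                 hair_count = as.integer(hair_count),
                 hair_width_px = hair_width_px,
                 noise_sd = noise_sd,
                 background_gradient = background_gradient),
            class = "scene_params")
}

resize_plane <- function(a, h_out, w_out) {
  d <- dim(a)
  x <- array(a, c(d[1], d[2], 1L, 1L))
  out <- cpp_resize_bilinear_fw(x, as.integer(h_out), as.integer(w_out))
  array(out, c(h_out, w_out))
}

#' Generate one labeled synthetic sample
#'
#' @param params a [scene_params()].
#' @param seed integer seed; the same `(params, seed)` pair always produces
#'   a bit-identical sample.
#' @param max_tries bounded retries for the area constraint.
#' @return list with `image` (rows x cols x 3 array in [0, 1], quantized to
#'   the 8-bit grid so PNG round trips are exact), `mask` (binary rows x
#'   cols matrix) and `meta` (parameters, seed and achieved area fraction).
#' @export
generate_sample <- function(params, seed, max_tries = 10L) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    H <- params$image_size[1]
    W <- params$image_size[2]
    lo <- params$lesion_area_fraction[1]
    hi <- params$lesion_area_fraction[2]
    ys <- matrix(seq_len(H), H, W)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    mask <- NULL
    for (try in seq_len(max_tries)) {
      target <- stats::runif(1, lo, hi)
      cx <- W * stats::runif(1, 0.40, 0.60)
      cy <- H * stats::runif(1, 0.40, 0.60)
      aspect <- stats::runif(1, 0.75, 1.30)
      phi <- stats::runif(1, 0, pi)
      u <- xs - cx
      v <- ys - cy
      ur <- (u * cos(phi) + v * sin(phi)) * aspect
      vr <- (-u * sin(phi) + v * cos(phi)) / aspect
      rho <- sqrt(ur^2 + vr^2)
      theta <- atan2(vr, ur)
      rfun <- matrix(1, H, W)
      K <- params$boundary_harmonics
      if (K > 0) {
        amp <- params$boundary_amplitude * stats::rnorm(K) / seq_len(K)
        phase <- stats::runif(K, 0, 2 * pi)
        for (k in seq_len(K)) rfun <- rfun + amp[k] * cos(k * theta + phase[k])
      }
      rfun <- pmax(rfun, 0.3)
      rho_n <- rho / rfun
      r0 <- stats::quantile(rho_n, probs = target, names = FALSE, type = 1)
      cand <- rho_n <= r0
      frac <- mean(cand)
      if (frac >= lo && frac <= hi) {
        mask <- cand
        break
      }
    }
    if (is.null(mask))
      stop("could not satisfy the lesion area constraint after ", max_tries,
           " attempts", call. = FALSE)

    base <- c(0.78, 0.60, 0.52)                     # light skin tone
    grad <- params$background_gradient *
      ((xs / W - 0.5) + 0.4 * (ys / H - 0.5))
    # soft visual lesion edge; the label mask itself stays hard
    soft <- pmin(1, pmax(0, (r0 - rho_n) / (0.05 * r0 + 1e-9)))
    gh <- max(4L, ceiling(H / 16))
    gw <- max(4L, ceiling(W / 16))
    tex <- resize_plane(matrix(stats::rnorm(gh * gw), gh, gw), H, W)
    lesion_shift <- params$lesion_contrast * c(1.00, 1.15, 1.25)
    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) {
      plane <- base[ch] + grad - soft * lesion_shift[ch] +
        soft * 0.25 * params$lesion_contrast * tex
      img[, , ch] <- plane
    }
    if (params$hair_count > 0) {
      cov <- matrix(0, H, W)
      for (i in seq_len(params$hair_count))
        cov <- pmax(cov, draw_hair(H, W, params$hair_width_px))
      hair_shade <- c(0.35, 0.38, 0.40)
      for (ch in 1:3) img[, , ch] <- img[, , ch] - hair_shade[ch] * cov
    }
    if (params$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$noise_sd)
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255
    list(image = img,
         mask = matrix(as.numeric(mask), H, W),
         meta = list(params = params, seed = as.integer(seed),
                     area_fraction = mean(mask)))
  })
}

# One anti-aliased quadratic Bezier stroke; returns a coverage plane in [0,1].
draw_hair <- function(H, W, width) {
  p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
  p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
  mid <- (p0 + p2) / 2
  p1 <- mid + c(stats::rnorm(1, 0, H / 4), stats::rnorm(1, 0, W / 4))
  ts <- seq(0, 1, length.out = 4L * max(H, W))
  py <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1]
  px <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2]
  cov <- matrix(0, H, W)
  rb <- ceiling(width / 2 + 1)
  half <- width / 2
  for (j in seq_along(ts)) {
    yc <- py[j]; xc <- px[j]
    y0 <- max(1L, floor(yc - rb)); y1 <- min(H, ceiling(yc + rb))
    x0 <- max(1L, floor(xc - rb)); x1 <- min(W, ceiling(xc + rb))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    dmat <- sqrt(outer((yy - yc)^2, (xx - xc)^2, "+"))
    a <- pmin(1, pmax(0, 1 - (dmat - half)))
    cov[yy, xx] <- pmax(cov[yy, xx], a)
  }
  cov
}

#' Generate a reproducible train/validation/test split
#'
#' Samples are generated with counter-based seeds (`seed + i - 1` for the
#' i-th sample) and assigned to splits in a 7:2:1 ratio: `round(0.7 n)`
#' training, `round(0.2 n)` validation, remainder test. The three seed sets
#' are disjoint by construction and recorded in the manifest.
#'
#' @param params a [scene_params()].
#' @param n total number of samples, at least 10.
#' @param seed base seed.
#' @return list with `train`, `val`, `test` (lists of samples) and
#'   `manifest` (data frame: id, split, seed, area_fraction).
#' @export
generate_split <- function(params, n, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L)
    stop("`n` must be at least 10 for a 7:2:1 split", call. = FALSE)
  n_train <- round(0.7 * n)
  n_val <- round(0.2 * n)
  n_test <- n - n_train - n_val
  seeds <- as.integer(seed) + seq_len(n) - 1L
  split <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  samples <- lapply(seeds, function(s) generate_sample(params, s))
  manifest <- data.frame(id = sprintf("sample_%04d", seq_len(n)),
                         split = split, seed = seeds,
                         area_fraction = vapply(samples,
                                                function(s) s$meta$area_fraction,
                                                numeric(1)))
  list(train = samples[split == "train"],
       val = samples[split == "val"],
       test = samples[split == "test"],
       manifest = manifest)
}

# Inverse-map rotation about the image centre. mode "bilinear" for images,
# "nearest" for masks; pixels sampled from outside are filled with `fill`.
rotate_plane <- function(a, angle_deg, mode = c("bilinear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  if (angle_deg == 0) return(a)
  H <- nrow(a); W <- ncol(a)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- matrix(seq_len(H), H, W) - cy
  xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  sx <- cos(th) * xs + sin(th) * ys + cx
  if (mode == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    out <- matrix(fill, H, W)
    out[ok] <- a[cbind(iy[ok], ix[ok])]
    return(out)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gv <- function(iy, ix) {
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    v <- matrix(fill, H, W)
    v[ok] <- a[cbind(iy[ok], ix[ok])]
    v
  }
  (1 - fy) * (1 - fx) * gv(y0, x0) + fy * (1 - fx) * gv(y0 + 1, x0) +
    (1 - fy) * fx * gv(y0, x0 + 1) + fy * fx * gv(y0 + 1, x0 + 1)
}

#' Augment a labeled sample
#'
#' Rotates image and mask by the same seeded random angle (the mask is
#' resampled nearest-neighbour so it stays strictly binary) and adds
#' Gaussian pixel noise to the image only. With `max_angle = 0` and
#' `noise_sd = 0` the sample is returned unchanged.
#'
#' @param sample a sample from [generate_sample()].
#' @param seed integer seed.
#' @param max_angle rotation drawn uniformly from `[-max_angle, max_angle]`
#'   degrees (default 30).
#' @param noise_sd standard deviation of the added image noise (default
#'   0.01).
#' @return an augmented sample with the same structure.
#' @export
augment_sample <- function(sample, seed, max_angle = 30, noise_sd = 0.01) {
  with_seed(seed, {
    angle <- if (max_angle > 0) stats::runif(1, -max_angle, max_angle) else 0
    img <- sample$image
    mask <- sample$mask
    if (angle != 0) {
      bg <- stats::median(img)
      for (ch in seq_len(dim(img)[3]))
        img[, , ch] <- rotate_plane(img[, , ch], angle, "bilinear",
                                    fill = bg)
      mask <- rotate_plane(mask, angle, "nearest", fill = 0)
      mask <- as.numeric(mask > 0.5)
      dim(mask) <- dim(sample$mask)
    }
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    img <- pmin(pmax(img, 0), 1)
    out <- sample
    out$image <- img
    out$mask <- mask
    out$meta$augmented <- list(angle = angle, noise_sd = noise_sd,
                               seed = as.integer(seed))
    out
  })
}
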