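#' Synthetic eye-image generator configuration
#'
#' Parameters of the synthetic grayscale eye renderer. The scene is a
#' bright sclera field, an iris disc, and a dark filled rotated ellipse for
#' the pupil, plus optional nuisance effects that emulate the conditions
#' real near-infrared eye images are collected under: a bright corneal
#' glint overlapping the pupil, a dark occluder band across the top of the
#' frame (eyelid/mascara-like), a linear illumination gradient, and
#' additive Gaussian pixel noise.
#'
#' Gray levels follow the ordering pupil < iris < sclera; the pupil center
#' is drawn uniformly at least `margin` pixels from every border, and the
#' configuration requires `margin >= max(pupil_radius_range)` so the pupil
#' is always fully inside the frame.
#'
#' @param image_width,image_height frame size in pixels.
#' @param pupil_radius_range (min, max) pupil semi-major axis, pixels.
#' @param pupil_eccentricity_range (min, max) minor/major axis ratio in (0, 1].
#' @param pupil_intensity,iris_intensity,sclera_intensity gray levels 0-255,
#'   strictly increasing in that order.
#' @param glint_probability probability a sample carries a glint.
#' @param glint_radius glint disc radius, pixels.
#' @param occluder_probability probability of a dark top occluder band.
#' @param illumination_gradient_amplitude peak-to-center amplitude of the
#'   additive linear illumination ramp, gray levels (0 disables).
#' @param noise_std additive Gaussian pixel noise standard deviation,
#'   gray levels (0 disables).
#' @param margin minimum distance of the pupil center from any border,
#'   pixels; must be at least `max(pupil_radius_range)`.
#' @param iris_radius_factor iris radius as a multiple of the drawn pupil
#'   semi-major axis.
#' @param seed optional integer recorded in the config (generation
#'   functions also accept a seed directly).
#' @return object of class `eye_config` (a validated list).
#' @export
#' @examples
#' cfg <- eye_config(image_width = 64, image_height = 48,
#'                   pupil_radius_range = c(4, 9), margin = 10,
#'                   noise_std = 0, glint_probability = 0,
#'                   occluder_probability = 0,
#'                   illumination_gradient_amplitude = 0)
eye_config <- function(image_width = 384, image_height = 288,
                       pupil_radius_range = c(15, 40),
                       pupil_eccentricity_range = c(0.6, 1),
                       pupil_intensity = 20, iris_intensity = 90,
                       sclera_intensity = 170,
                       glint_probability = 0.3, glint_radius = 4,
                       occluder_probability = 0.15,
                       illumination_gradient_amplitude = 30,
                       noise_std = 8,
                       margin = ceiling(max(pupil_radius_range)) + 2,
                       iris_radius_factor = 2.5,
                       seed = NULL) {
  cfg <- list(image_width = image_width, image_height = image_height,
              pupil_radius_range = pupil_radius_range,
              pupil_eccentricity_range = pupil_eccentricity_range,
              pupil_intensity = pupil_intensity,
              iris_intensity = iris_intensity,
              sclera_intensity = sclera_intensity,
              glint_probability = glint_probability,
              glint_radius = glint_radius,
              occluder_probability = occluder_probability,
              illumination_gradient_amplitude = illumination_gradient_amplitude,
              noise_std = noise_std, margin = margin,
              iris_radius_factor = iris_radius_factor, seed = seed)
  validate_eye_config(cfg)
  class(cfg) <- "eye_config"
  cfg
}

validate_eye_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("eye_config: invalid `%s` (%s)", field, why),
                  call. = FALSE)
  }
  chk(is_count(cfg$image_width), "image_width", "must be a positive integer")
  chk(is_count(cfg$image_height), "image_height", "must be a positive integer")
  chk(length(cfg$pupil_radius_range) == 2L &&
        all(cfg$pupil_radius_range > 0) && !is.unsorted(cfg$pupil_radius_range),
      "pupil_radius_range", "must be an increasing positive pair")
  chk(length(cfg$pupil_eccentricity_range) == 2L &&
        all(cfg$pupil_eccentricity_range > 0) &&
        all(cfg$pupil_eccentricity_range <= 1) &&
        !is.unsorted(cfg$pupil_eccentricity_range),
      "pupil_eccentricity_range", "must be an increasing pair in (0, 1]")
  for (f in c("pupil_intensity", "iris_intensity", "sclera_intensity")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 255, f, "gray level must lie in [0, 255]")
  }
  chk(cfg$pupil_intensity < cfg$iris_intensity, "pupil_intensity",
      "pupil must be darker than iris")
  chk(cfg$iris_intensity < cfg$sclera_intensity, "iris_intensity",
      "iris must be darker than sclera")
  for (f in c("glint_probability", "occluder_probability")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a probability in [0, 1]")
  }
  chk(cfg$glint_radius > 0, "glint_radius", "must be positive")
  chk(cfg$illumination_gradient_amplitude >= 0,
      "illumination_gradient_amplitude", "must be non-negative")
  chk(cfg$noise_std >= 0, "noise_std", "must be non-negative")
  chk(cfg$margin >= max(cfg$pupil_radius_range), "margin",
      "must be at least the maximum pupil radius")
  chk(2 * cfg$margin < cfg$image_width && 2 * cfg$margin < cfg$image_height,
      "margin", "leaves no room for the pupil center")
  invisible(cfg)
}

#' Generate one labeled synthetic eye image
#'
#' Renders a single sample under `config`. Pixel membership in the pupil is
#' decided exactly: a pixel belongs to the pupil iff its (integer) center
#' satisfies the rotated-ellipse inequality <= 1 (no anti-aliasing), so
#' noise-free pupil centroids can be checked exactly. Coordinates are
#' 0-based with origin at the top-left, x = column, y = row.
#'
#' Rendering order: sclera background, iris disc, pupil ellipse, additive
#' illumination gradient, optional glint disc overlapping the pupil,
#' optional occluder band across the top, Gaussian noise; the result is
#' clipped to \[0, 255\] and rounded to integer gray levels.
#'
#' @param config an [eye_config()].
#' @param seed optional integer; the sample is a pure function of
#'   (config, seed).
#' @param center optional length-2 numeric `(x, y)` overriding the random
#'   pupil center (used by tests; must respect the margin).
#' @return object of class `eye_sample`: list with `pixels` (height x width
#'   integer matrix, gray levels 0-255), `center_x`, `center_y` (pixels),
#'   and `metadata` (the parameters actually drawn).
#' @export
generate_eye_image <- function(config, seed = NULL, center = NULL) {
  validate_eye_config(config)
  with_seed(seed, {
    w <- config$image_width; h <- config$image_height
    if (is.null(center)) {
      cx <- runif(1, config$margin, w - 1 - config$margin)
      cy <- runif(1, config$margin, h - 1 - config$margin)
    } else {
      cx <- center[1L]; cy <- center[2L]
    }
    a <- runif(1, config$pupil_radius_range[1L], config$pupil_radius_range[2L])
    ecc <- runif(1, config$pupil_eccentricity_range[1L],
                 config$pupil_eccentricity_range[2L])
    b <- a * ecc
    theta <- runif(1, 0, pi)
    has_glint <- runif(1) < config$glint_probability
    has_occluder <- runif(1) < config$occluder_probability
    grad_angle <- runif(1, 0, 2 * pi)
    glint_frac <- runif(1, 0, 0.5)      # glint offset as fraction of a
    glint_angle <- runif(1, 0, 2 * pi)
    occ_frac <- runif(1, 0.05, 0.15)    # occluder band height fraction

    xg <- matrix(rep(0:(w - 1), each = h), h, w)   # x of each pixel center
    yg <- matrix(rep(0:(h - 1), times = w), h, w)  # y of each pixel center
    dx <- xg - cx; dy <- yg - cy

    px <- matrix(config$sclera_intensity, h, w)
    iris_r <- config$iris_radius_factor * a
    px[dx^2 + dy^2 <= iris_r^2] <- config$iris_intensity
    # Rotated-ellipse inequality at pixel centers.
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    pupil_mask <- (u / a)^2 + (v / b)^2 <= 1
    px[pupil_mask] <- config$pupil_intensity

    if (config$illumination_gradient_amplitude > 0) {
      # Linear ramp through the frame center along grad_angle, zero mean.
      proj <- (xg - (w - 1) / 2) * cos(grad_angle) +
        (yg - (h - 1) / 2) * sin(grad_angle)
      ramp <- proj / max(abs(range(proj)))
      px <- px + config$illumination_gradient_amplitude * ramp
    }
    if (has_glint) {
      gx <- cx + glint_frac * a * cos(glint_angle)
      gy <- cy + glint_frac * a * sin(glint_angle)
      px[(xg - gx)^2 + (yg - gy)^2 <= config$glint_radius^2] <- 255
    }
    if (has_occluder) {
      band <- max(1L, round(occ_frac * h))
      px[seq_len(band), ] <- config$pupil_intensity + 20
    }
    if (config$noise_std > 0) {
      px <- px + matrix(rnorm(h * w, sd = config$noise_std), h, w)
    }
    px <- round(pmin(pmax(px, 0), 255))
    structure(list(
      pixels = px, center_x = cx, center_y = cy,
      metadata = list(pupil_a = a, pupil_b = b, pupil_angle = theta,
                      has_glint = has_glint, has_occluder = has_occluder,
                      gradient_angle = grad_angle)
    ), class = "eye_sample")
  })
}

#' Generate a labeled synthetic dataset
#'
#' @param config an [eye_config()].
#' @param n number of samples, >= 1.
#' @param seed optional integer; the dataset is a pure function of
#'   (config, n, seed).
#' @param out_dir optional directory; when given, each sample is written as
#'   an 8-bit grayscale PNG plus one `labels.csv`
#'   (`filename,center_x,center_y`).
#' @return list with `samples` (list of `eye_sample`) and `labels`
#'   (data.frame `filename, center_x, center_y`, one row per sample).
#' @export
generate_dataset <- function(config, n, seed = NULL, out_dir = NULL) {
  if (!is_count(n)) stop("generate_dataset: n must be a positive integer")
  with_seed(seed, {
    samples <- vector("list", n)
    fn <- sprintf("eye_%05d.png", seq_len(n))
    for (i in seq_len(n)) samples[[i]] <- generate_eye_image(config)
    labels <- data.frame(
      filename = fn,
      center_x = vapply(samples, `[[`, numeric(1), "center_x"),
      center_y = vapply(samples, `[[`, numeric(1), "center_y"),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n)) samples[[i]]$filename <- fn[i]
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      for (i in seq_len(n)) {
        write_eye_image(samples[[i]]$pixels, file.path(out_dir, fn[i]))
      }
      write_labels(labels, file.path(out_dir, "labels.csv"))
    }
    list(samples = samples, labels = labels)
  })
}

#' Preprocess an eye image to the standard 320 x 240 frame
#'
#' Applies the standardization rule used throughout the package: inputs
#' whose width and height are the same exact integer multiple of the target
#' (e.g. 640 x 480 for a 320 x 240 target) are downscaled proportionally by
#' area-averaging k x k blocks and the label coordinates are divided by k;
#' all other inputs at least as large as the target are center-cropped and
#' the labels translated by the crop offset. If a translated label falls
#' outside the target frame the sample is flagged `discarded` rather than
#' clamped (clamping would corrupt the regression target).
#'
#' @param sample an `eye_sample` (or list with `pixels`, `center_x`,
#'   `center_y`).
#' @param target_w,target_h target frame size, default 320 x 240.
#' @return the transformed sample, with `discarded = TRUE` when the label
#'   left the frame.
#' @export
preprocess_image <- function(sample, target_w = 320, target_h = 240) {
  px <- sample$pixels
  h <- nrow(px); w <- ncol(px)
  if (h < target_h || w < target_w) {
    stop(sprintf("preprocess_image: input %d x %d smaller than target %d x %d",
                 w, h, target_w, target_h))
  }
  out <- sample
  if (h == target_h && w == target_w) {
    out$discarded <- FALSE
    return(out)
  }
  if (w %% target_w == 0 && h %% target_h == 0 &&
      w %/% target_w == h %/% target_h) {
    k <- w %/% target_w
    # Area averaging over exact k x k blocks.
    a <- array(px, dim = c(k, target_h, w))
    m1 <- apply(a, c(2L, 3L), mean)                  # target_h x w
    a2 <- array(t(m1), dim = c(k, target_w, target_h))
    out$pixels <- t(apply(a2, c(2L, 3L), mean))      # target_h x target_w
    out$center_x <- sample$center_x / k
    out$center_y <- sample$center_y / k
    out$scale <- k
    out$offset <- c(0, 0)
  } else {
    ox <- (w - target_w) %/% 2L
    oy <- (h - target_h) %/% 2L
    out$pixels <- px[(oy + 1L):(oy + target_h), (ox + 1L):(ox + target_w)]
    out$center_x <- sample$center_x - ox
    out$center_y <- sample$center_y - oy
    out$scale <- 1
    out$offset <- c(ox, oy)
  }
  out$discarded <- out$center_x < 0 || out$center_x >= target_w ||
    out$center_y < 0 || out$center_y >= target_h
  out
}

#' Split a dataset into training and test sets
#'
#' Random disjoint, exhaustive partition with `round(n * train_fraction)`
#' training samples; deterministic given `seed`.
#'
#' @param samples list of samples (any list; split by index).
#' @param train_fraction fraction in (0, 1), default 0.85.
#' @param seed optional integer seed.
#' @return list with `train`, `test` (sub-lists) and `train_idx`,
#'   `test_idx` (integer index vectors into `samples`).
#' @export
split_dataset <- function(samples, train_fraction = 0.85, seed = NULL) {
  n <- length(samples)
  if (n < 1L) stop("split_dataset: empty input")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("split_dataset: train_fraction must lie in (0, 1)")
  }
  with_seed(seed, {
    n_train <- floor(n * train_fraction + 0.5)
    perm <- sample.int(n)
    train_idx <- sort(perm[seq_len(n_train)])
    test_idx <- sort(setdiff(seq_len(n), train_idx))
    if (length(test_idx) == 0L) {
      warning("split_dataset: test set is empty at this n and train_fraction")
    }
    list(train = samples[train_idx], test = samples[test_idx],
         train_idx = train_idx, test_idx = test_idx)
  })
}

#' Noise-free pupil centroid recomputed from pixels
#'
#' Centroid of the darkest-pixel mask (pixels within `tol` gray levels of
#' the image minimum); on noise-free, gradient-free renders this recovers
#' the pupil center and serves as the label-consistency oracle.
#'
#' @param pixels height x width gray-level matrix.
#' @param tol gray-level tolerance above the minimum, default 0.
#' @return numeric `(x, y)` centroid in pixel coordinates.
#' @export
pupil_centroid <- function(pixels, tol = 0) {
  mask <- pixels <= min(pixels) + tol
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
}

# ---- Image and label I/O -------------------------------------------------

#' Write an 8-bit grayscale PNG
#'
#' @param pixels height x width matrix of gray levels 0-255.
#' @param path output file path.
#' @export
write_eye_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels, 0), 255) / 255, path)
  invisible(path)
}

#' Read a grayscale image (PNG or PGM)
#'
#' PNGs are read with the png package (first channel taken if the file has
#' several); PGM files (P2 ASCII or P5 binary, maxval <= 255) are parsed
#' directly. Values are returned as gray levels 0-255.
#'
#' @param path image file path.
#' @return height x width numeric matrix of gray levels.
#' @export
read_eye_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_eye_image: no such file: %s", path))
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * 255)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("read_pgm: not a PGM file (P2/P5)")
  # Header tokens (width, height, maxval), skipping whitespace and comments.
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- paste0(buf, ch)
    } else if (nzchar(buf)) {
      tokens <- c(tokens, buf); buf <- ""
    }
  }
  dims <- as.integer(tokens)
  w <- dims[1L]; h <- dims[2L]; maxval <- dims[3L]
  if (maxval > 255) stop("read_pgm: only 8-bit PGM supported")
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", w * h))
  } else {
    scan(con, integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' Write a label table
#'
#' Comma-separated, header `filename,center_x,center_y`, UTF-8, `.` decimal
#' separator.
#'
#' @param labels data.frame with columns `filename`, `center_x`, `center_y`.
#' @param path output CSV path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("filename", "center_x", "center_y") %in% names(labels)))
  utils::write.csv(labels[, c("filename", "center_x", "center_y")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a label table written by [write_labels()]
#'
#' @param path CSV path.
#' @return data.frame with `filename`, `center_x`, `center_y`.
#' @export
read_labels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Load a dataset directory (images + labels.csv) as samples
#'
#' @param dir directory containing images and a `labels.csv`.
#' @return list of `eye_sample` objects.
#' @export
read_dataset <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.csv"))
  lapply(seq_len(nrow(labels)), function(i) {
    structure(list(pixels = read_eye_image(file.path(dir, labels$filename[i])),
                   center_x = labels$center_x[i],
                   center_y = labels$center_y[i],
                   filename = labels$filename[i],
                   metadata = list()), class = "eye_sample")
  })
}
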