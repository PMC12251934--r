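#' Root-mean-square center error (pixels)
#'
#' `sqrt(mean((x' - x)^2 + (y' - y)^2))` over prediction/truth pairs; the
#' Euclidean RMSE in pixels. This is both the evaluation metric and the
#' training loss (applied per mini-batch with N = batch size).
#'
#' @param predictions,truths N x 2 matrices (columns x, y).
#' @return non-negative scalar, pixels.
#' @export
#' @examples
#' rmse(matrix(c(3, 4), 1), matrix(c(0, 0), 1))  # 5
rmse <- function(predictions, truths) {
  predictions <- as.matrix(predictions); truths <- as.matrix(truths)
  if (nrow(predictions) < 1L || nrow(predictions) != nrow(truths)) {
    stop("rmse: need equal, non-zero numbers of predictions and truths")
  }
  d <- predictions - truths
  sqrt(mean(rowSums(d * d)))
}

#' Detection rate at a pixel tolerance
#'
#' `DR = C / N * 100`, where a prediction is correct iff its Euclidean
#' distance to the ground truth is <= `tolerance` (boundary inclusive).
#'
#' @param predictions,truths N x 2 matrices (columns x, y).
#' @param tolerance pixel tolerance, default 5 (the DR5 convention).
#' @return percentage in \[0, 100\].
#' @export
detection_rate <- function(predictions, truths, tolerance = 5) {
  predictions <- as.matrix(predictions); truths <- as.matrix(truths)
  if (nrow(predictions) < 1L || nrow(predictions) != nrow(truths)) {
    stop("detection_rate: need equal, non-zero numbers of predictions and truths")
  }
  d <- predictions - truths
  dist <- sqrt(rowSums(d * d))
  mean(dist <= tolerance) * 100
}

#' Training configuration
#'
#' The selected protocol: batch size 4, AdamW, cosine learning-rate decay
#' from 1e-3 to 1e-5 over a 100-epoch cycle. All alternatives evaluated in
#' the ablation (fixed / step / exponential schedules; SGD family,
#' AdaGrad, RMSProp, Adam) are available.
#'
#' @param batch_size mini-batch size, >= 1.
#' @param optimizer one of `"sgd"`, `"sgd_momentum"`, `"adagrad"`,
#'   `"rmsprop"`, `"adam"`, `"adamw"`.
#' @param lr_schedule one of `"fixed"`, `"step"`, `"exponential"`,
#'   `"cosine"`.
#' @param lr_init,lr_min initial and minimum learning rates.
#' @param cosine_cycle cosine decay cycle length, epochs.
#' @param step_breaks,step_rates step schedule: rate `step_rates[i]` for
#'   epochs in `[step_breaks[i-1], step_breaks[i])` (defaults: 1e-3 for the
#'   first 40 epochs, 1e-4 for the next 40, 1e-5 thereafter).
#' @param exp_gamma exponential decay factor per epoch.
#' @param epochs training epochs.
#' @param weight_decay decoupled weight decay (AdamW only).
#' @param momentum momentum coefficient (sgd_momentum).
#' @param beta1,beta2,adam_eps Adam/AdamW moment coefficients.
#' @param seed integer seed controlling initialization-independent
#'   stochasticity of training (data order).
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 4,
                         optimizer = c("adamw", "adam", "sgd", "sgd_momentum",
                                       "adagrad", "rmsprop"),
                         lr_schedule = c("cosine", "fixed", "step", "exponential"),
                         lr_init = 1e-3, lr_min = 1e-5, cosine_cycle = 100,
                         step_breaks = c(40, 80), step_rates = c(1e-3, 1e-4, 1e-5),
                         exp_gamma = 0.95,
                         epochs = 100, weight_decay = 0.01, momentum = 0.9,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  lr_schedule <- match.arg(lr_schedule)
  if (lr_min > lr_init) stop("train_config: lr_min must not exceed lr_init")
  if (!is_count(batch_size)) stop("train_config: batch_size must be >= 1")
  structure(list(batch_size = batch_size, optimizer = optimizer,
                 lr_schedule = lr_schedule, lr_init = lr_init, lr_min = lr_min,
                 cosine_cycle = cosine_cycle, step_breaks = step_breaks,
                 step_rates = step_rates, exp_gamma = exp_gamma,
                 epochs = epochs, weight_decay = weight_decay,
                 momentum = momentum, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Cosine: `lr_min + (lr_init - lr_min)/2 * (1 + cos(pi * min(e, cycle)
#' / cycle))` — exactly `lr_init` at epoch 0 and `lr_min` from the end of
#' the cycle on. Step: the configured piecewise-constant rates (defaults
#' 1e-3 / 1e-4 / 1e-5 with breaks at 40 and 80 epochs). Exponential:
#' `lr_init * gamma^e`. Fixed: `lr_init`.
#'
#' @param epoch epoch index, 0-based, >= 0.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(epoch, config) {
  if (any(epoch < 0)) stop("lr_at: epoch must be >= 0")
  switch(config$lr_schedule,
    fixed = rep(config$lr_init, length(epoch)),
    cosine = {
      e <- pmin(epoch, config$cosine_cycle)
      config$lr_min + 0.5 * (config$lr_init - config$lr_min) *
        (1 + cos(pi * e / config$cosine_cycle))
    },
    step = config$step_rates[findInterval(epoch, config$step_breaks) + 1L],
    exponential = config$lr_init * config$exp_gamma^epoch
  )
}

# One optimizer step over the parameter tree. state carries slot trees.
optim_step <- function(params, grads, state, lr, tc) {
  switch(tc$optimizer,
    sgd = {
      list(params = tree_map2(function(p, g) p - lr * g, params, grads),
           state = state)
    },
    sgd_momentum = {
      state$v <- tree_map2(function(v, g) tc$momentum * v + g, state$v, grads)
      list(params = tree_map2(function(p, v) p - lr * v, params, state$v),
           state = state)
    },
    adagrad = {
      state$v <- tree_map2(function(v, g) v + g * g, state$v, grads)
      list(params = tree_map3(function(p, v, g) p - lr * g / (sqrt(v) + 1e-10),
                              params, state$v, grads),
           state = state)
    },
    rmsprop = {
      state$v <- tree_map2(function(v, g) 0.99 * v + 0.01 * g * g,
                           state$v, grads)
      list(params = tree_map3(function(p, v, g) p - lr * g / (sqrt(v) + 1e-8),
                              params, state$v, grads),
           state = state)
    },
    adam = ,
    adamw = {
      state$t <- state$t + 1L
      state$m <- tree_map2(function(m, g) tc$beta1 * m + (1 - tc$beta1) * g,
                           state$m, grads)
      state$v <- tree_map2(function(v, g) tc$beta2 * v + (1 - tc$beta2) * g * g,
                           state$v, grads)
      bc1 <- 1 - tc$beta1^state$t
      bc2 <- 1 - tc$beta2^state$t
      wd <- if (tc$optimizer == "adamw") tc$weight_decay else 0
      params <- tree_map3(function(p, m, v) {
        p - lr * ((m / bc1) / (sqrt(v / bc2) + tc$adam_eps) + wd * p)
      }, params, state$m, state$v)
      list(params = params, state = state)
    }
  )
}

init_optim_state <- function(params, tc) {
  switch(tc$optimizer,
    sgd = list(),
    sgd_momentum = list(v = tree_zero(params)),
    adagrad = ,
    rmsprop = list(v = tree_zero(params)),
    adam = ,
    adamw = list(m = tree_zero(params), v = tree_zero(params), t = 0L)
  )
}

samples_to_batch <- function(samples) {
  list(images = lapply(samples, `[[`, "pixels"),
       truths = cbind(vapply(samples, `[[`, numeric(1), "center_x"),
                      vapply(samples, `[[`, numeric(1), "center_y")))
}

#' Train a detector
#'
#' Mini-batch gradient descent on the Euclidean RMSE loss with the
#' configured optimizer and epoch-granularity learning-rate schedule.
#' Deterministic given `config$seed` (shuffling order); gradients are
#' evaluated through the dense attention product, which agrees with the
#' FFT route to floating tolerance.
#'
#' @param model a [vimsa_model()].
#' @param train_set list of `eye_sample` objects at the model frame size.
#' @param config a [train_config()].
#' @param verbose print one line per `verbose` epochs (0 = silent).
#' @return list with `model` (trained) and `history` (data.frame
#'   `epoch, loss, lr`, one row per epoch; loss is the mean batch RMSE).
#' @export
vimsa_train <- function(model, train_set, config = train_config(),
                        verbose = 0) {
  n <- length(train_set)
  if (n < 1L) stop("vimsa_train: empty training set")
  params <- model$params
  state <- init_optim_state(params, config)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  # Tile every training image into its patch matrix once, up front.
  Plist <- lapply(train_set, function(s) {
    arr3_to_mat(extract_patches(s$pixels, model$config$patch_size)$values) / 255
  })
  truth_all <- cbind(vapply(train_set, `[[`, numeric(1), "center_x"),
                     vapply(train_set, `[[`, numeric(1), "center_y"))
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at(epoch - 1L, config)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        lg <- model_loss_grad(params, model$config, images = NULL,
                              truth_all[idx, , drop = FALSE],
                              P = do.call(rbind, Plist[idx]))
        if (!is.finite(lg$loss)) {
          stop(sprintf("vimsa_train: non-finite loss at epoch %d", epoch))
        }
        st <- optim_step(params, lg$grads, state, lr, config)
        params <- st$params
        state <- st$state
        losses <- c(losses, lg$loss)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(losses), lr = lr))
      if (verbose > 0 && epoch %% verbose == 0) {
        message(sprintf("epoch %4d  loss %8.4f  lr %.2e", epoch,
                        mean(losses), lr))
      }
    }
  })
  model$params <- params
  list(model = model, history = history)
}

#' Evaluate a detector
#'
#' RMSE and detection rate at each tolerance on a held-out set; no
#' parameter updates. Optionally dumps per-sample predictions
#' (`filename,x_true,y_true,x_pred,y_pred,distance`) to CSV.
#'
#' @param model a `vimsa_model`.
#' @param test_set list of `eye_sample` objects.
#' @param tolerances DR tolerances in pixels.
#' @param impl attention route (default: the model's configured one).
#' @param dump_csv optional path for the per-sample prediction dump.
#' @param batch_size forward-pass batch size.
#' @return list with `rmse` (pixels), `dr` (named vector, percent per
#'   tolerance), `n`, and `predictions` (data.frame).
#' @export
vimsa_evaluate <- function(model, test_set, tolerances = 1:5, impl = NULL,
                           dump_csv = NULL, batch_size = 8) {
  n <- length(test_set)
  if (n < 1L) stop("vimsa_evaluate: empty test set")
  preds <- matrix(0, n, 2)
  truths <- matrix(0, n, 2)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- samples_to_batch(test_set[idx])
    preds[idx, ] <- vimsa_forward(model, batch$images, impl = impl)
    truths[idx, ] <- batch$truths
  }
  dist <- sqrt(rowSums((preds - truths)^2))
  dr <- vapply(tolerances, function(k) detection_rate(preds, truths, k),
               numeric(1))
  names(dr) <- paste0("DR", tolerances)
  fns <- vapply(seq_len(n), function(i) test_set[[i]]$filename %||%
                  sprintf("sample_%05d", i), character(1))
  pred_df <- data.frame(filename = fns,
                        x_true = truths[, 1], y_true = truths[, 2],
                        x_pred = preds[, 1], y_pred = preds[, 2],
                        distance = dist, stringsAsFactors = FALSE)
  if (!is.null(dump_csv)) {
    utils::write.csv(pred_df, dump_csv, row.names = FALSE, quote = FALSE)
  }
  list(rmse = rmse(preds, truths), dr = dr, n = n, predictions = pred_df)
}

#' Predict the pupil center for one image file
#'
#' Reads the image, applies the standard preprocessing (proportional
#' downscale or center crop to the model frame), runs the forward pass,
#' and reports the center in preprocessed-frame pixels and — when the
#' preprocessing scaled or cropped — also in original-frame pixels via the
#' inverse transform.
#'
#' @param object a `vimsa_model`.
#' @param image path to a grayscale PNG/PGM file, or a pixel matrix.
#' @param ... unused.
#' @return list with `x`, `y` (model frame) and `x_orig`, `y_orig`
#'   (original frame).
#' @export
predict.vimsa_model <- function(object, image, ...) {
  px <- if (is.character(image)) read_eye_image(image) else image
  sample <- list(pixels = px, center_x = 0, center_y = 0)
  pre <- preprocess_image(sample, target_w = object$config$image_width,
                          target_h = object$config$image_height)
  p <- vimsa_forward(object, list(pre$pixels))
  scale <- pre$scale %||% 1
  offset <- pre$offset %||% c(0, 0)
  list(x = p[1, 1], y = p[1, 2],
       x_orig = p[1, 1] * scale + offset[1],
       y_orig = p[1, 2] * scale + offset[2])
}
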