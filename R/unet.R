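# Convolutional encoder-decoder segmenter (U-Net family): parameter
# construction, forward/backward passes over the Rcpp layer kernels,
# loss functions, the 1-cycle learning-rate policy, Adam and
# RAdam+Lookahead optimizers, training with validation-based early
# stopping on the mean Jaccard distance, and inference to probability
# maps.
#
# Parameters live in a flat named list of matrices/vectors
# ("enc1.conv1.w", ..., "final.w"), which keeps optimizer state
# handling trivial.  A 3x3 kernel bank for C_in -> C_out channels is a
# (C_in * 9) x C_out matrix (see src/layers.cpp for the row ordering).

#' Build an encoder-decoder segmentation model
#'
#' A plain U-Net-style network: `depth` encoder stages of two 3x3
#' convolutions + ReLU followed by 2x2 max pooling, a bottleneck, and a
#' mirrored decoder with nearest-neighbour upsampling and skip
#' concatenation at every stage.  The final 1x1 convolution emits
#' two-class scores turned into per-pixel probabilities by softmax.
#' Channel width doubles per stage starting from `base_channels`.
#'
#' @param depth number of pooling stages (>= 2); input dimensions must
#'   be divisible by `2^depth`.
#' @param base_channels channels of the first stage.
#' @param input_size c(rows, cols) of the training input.
#' @param in_channels input channels (1 for gray-scale).
#' @param encoder_id encoder variant; only the built-in `"plain"`
#'   encoder is available without external weight files.
#' @param pretrained must be `FALSE` unless pretrained weights for the
#'   chosen encoder are locally available.
#' @param seed seed for He-normal weight initialization.
#' @return Object of class `unet_model` with elements `config`, `par`
#'   (flat named parameter list) and `trained` flag.
#' @export
build_model <- function(depth = 3, base_channels = 8,
                        input_size = c(128, 128), in_channels = 1,
                        encoder_id = "plain", pretrained = FALSE,
                        seed = 1) {
  stopifnot(depth >= 2, base_channels >= 1)
  if (any(input_size %% 2^depth != 0))
    stop("input dimensions must be divisible by 2^depth")
  if (encoder_id != "plain")
    stop("encoder '", encoder_id, "' requires locally provided weights; ",
         "only the built-in 'plain' encoder is available")
  if (pretrained)
    stop("no pretrained weights are bundled; set pretrained = FALSE")
  ch <- base_channels * 2^(seq_len(depth) - 1)
  chb <- base_channels * 2^depth
  par <- list()
  he <- function(cin, cout)
    matrix(rnorm(cin * 9 * cout) * sqrt(2 / (cin * 9)), cin * 9, cout)
  with_seed(seed, {
    cin <- in_channels
    for (i in seq_len(depth)) {
      par[[sprintf("enc%d.conv1.w", i)]] <- he(cin, ch[i])
      par[[sprintf("enc%d.conv1.b", i)]] <- numeric(ch[i])
      par[[sprintf("enc%d.conv2.w", i)]] <- he(ch[i], ch[i])
      par[[sprintf("enc%d.conv2.b", i)]] <- numeric(ch[i])
      cin <- ch[i]
    }
    par[["bot.conv1.w"]] <- he(ch[depth], chb)
    par[["bot.conv1.b"]] <- numeric(chb)
    par[["bot.conv2.w"]] <- he(chb, chb)
    par[["bot.conv2.b"]] <- numeric(chb)
    for (i in seq_len(depth)) {
      below <- if (i == depth) chb else ch[i + 1]
      par[[sprintf("dec%d.up.w", i)]] <- he(below, ch[i])
      par[[sprintf("dec%d.up.b", i)]] <- numeric(ch[i])
      par[[sprintf("dec%d.conv.w", i)]] <- he(2 * ch[i], ch[i])
      par[[sprintf("dec%d.conv.b", i)]] <- numeric(ch[i])
    }
    par[["final.w"]] <- matrix(rnorm(ch[1] * 2) * sqrt(2 / ch[1]), ch[1], 2)
    par[["final.b"]] <- numeric(2)
  })
  structure(list(
    config = list(depth = depth, base_channels = base_channels,
                  input_size = input_size, in_channels = in_channels,
                  encoder_id = encoder_id, pretrained = pretrained),
    par = par, trained = FALSE), class = "unet_model")
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$par, length, 0L))

relu <- function(x) { x[x < 0] <- 0; x }

# Forward pass.  x: H x W (x C) array normalized to [0,1].
# Returns list(prob = H x W matrix, cache = activations for backprop).
unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$par
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (any(dim(x)[1:2] %% 2^cfg$depth != 0))
    stop("input dimensions must be divisible by 2^depth")
  cache <- list(enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth))
  skips <- vector("list", cfg$depth)
  a <- x
  for (i in seq_len(cfg$depth)) {
    a0 <- a
    z1 <- conv3_fw(a0, p[[sprintf("enc%d.conv1.w", i)]],
                   p[[sprintf("enc%d.conv1.b", i)]])
    a1 <- relu(z1)
    z2 <- conv3_fw(a1, p[[sprintf("enc%d.conv2.w", i)]],
                   p[[sprintf("enc%d.conv2.b", i)]])
    a2 <- relu(z2)
    mp <- maxpool2_fw(a2)
    skips[[i]] <- a2
    if (keep_cache)
      cache$enc[[i]] <- list(a0 = a0, a1 = a1, m1 = z1 > 0, m2 = z2 > 0,
                             arg = mp$arg, hw = dim(a2)[1:2])
    a <- mp$out
  }
  zb1 <- conv3_fw(a, p[["bot.conv1.w"]], p[["bot.conv1.b"]])
  ab1 <- relu(zb1)
  zb2 <- conv3_fw(ab1, p[["bot.conv2.w"]], p[["bot.conv2.b"]])
  ab2 <- relu(zb2)
  if (keep_cache)
    cache$bot <- list(a0 = a, a1 = ab1, m1 = zb1 > 0, m2 = zb2 > 0)
  a <- ab2
  for (i in rev(seq_len(cfg$depth))) {
    u <- upsample2_fw(a)
    zu <- conv3_fw(u, p[[sprintf("dec%d.up.w", i)]],
                   p[[sprintf("dec%d.up.b", i)]])
    au <- relu(zu)
    cat2 <- array(c(au, skips[[i]]),
                  c(dim(au)[1:2], dim(au)[3] + dim(skips[[i]])[3]))
    zc <- conv3_fw(cat2, p[[sprintf("dec%d.conv.w", i)]],
                   p[[sprintf("dec%d.conv.b", i)]])
    a <- relu(zc)
    if (keep_cache)
      cache$dec[[i]] <- list(u = u, mu = zu > 0, cat = cat2, mc = zc > 0,
                             nch = dim(au)[3])
  }
  hw <- dim(a)[1:2]
  amat <- matrix(a, prod(hw), dim(a)[3])
  z <- amat %*% p[["final.w"]]
  z <- sweep(z, 2, p[["final.b"]], "+")
  prob <- matrix(stats::plogis(z[, 2] - z[, 1]), hw[1], hw[2])
  if (keep_cache) {
    cache$amat <- amat
    cache$hw <- hw
    cache$prob <- prob
  }
  list(prob = prob, cache = cache)
}

# Backward pass: dprob is dLoss/dprob (H x W).  Returns flat grad list.
unet_backward <- function(model, cache, dprob) {
  cfg <- model$config
  p <- model$par
  g <- list()
  prob <- cache$prob
  # softmax over 2 classes == sigmoid of (z2 - z1)
  dzd <- as.vector(dprob * prob * (1 - prob))
  dZ <- cbind(-dzd, dzd)
  g[["final.w"]] <- crossprod(cache$amat, dZ)
  g[["final.b"]] <- colSums(dZ)
  dA <- array(dZ %*% t(p[["final.w"]]), c(cache$hw, nrow(p[["final.w"]])))
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {  # decoder stages, last applied first
    dc <- cache$dec[[i]]
    dzc <- dA * dc$mc
    bw <- conv3_bw(dc$cat, p[[sprintf("dec%d.conv.w", i)]], dzc)
    g[[sprintf("dec%d.conv.w", i)]] <- bw$dw
    g[[sprintf("dec%d.conv.b", i)]] <- as.vector(bw$db)
    nch <- dc$nch
    dau <- bw$dx[, , seq_len(nch), drop = FALSE]
    dskips[[i]] <- bw$dx[, , nch + seq_len(dim(bw$dx)[3] - nch),
                         drop = FALSE]
    dzu <- dau * dc$mu
    bwu <- conv3_bw(dc$u, p[[sprintf("dec%d.up.w", i)]], dzu)
    g[[sprintf("dec%d.up.w", i)]] <- bwu$dw
    g[[sprintf("dec%d.up.b", i)]] <- as.vector(bwu$db)
    dA <- upsample2_bw(bwu$dx)
  }
  bc <- cache$bot
  dz <- dA * bc$m2
  bw <- conv3_bw(bc$a1, p[["bot.conv2.w"]], dz)
  g[["bot.conv2.w"]] <- bw$dw; g[["bot.conv2.b"]] <- as.vector(bw$db)
  dz <- bw$dx * bc$m1
  bw <- conv3_bw(bc$a0, p[["bot.conv1.w"]], dz)
  g[["bot.conv1.w"]] <- bw$dw; g[["bot.conv1.b"]] <- as.vector(bw$db)
  dA <- bw$dx
  for (i in rev(seq_len(cfg$depth))) {  # encoder stages, deepest first
    ec <- cache$enc[[i]]
    da2 <- maxpool2_bw(ec$arg, dA, ec$hw[1], ec$hw[2]) + dskips[[i]]
    dz <- da2 * ec$m2
    bw <- conv3_bw(ec$a1, p[[sprintf("enc%d.conv2.w", i)]], dz)
    g[[sprintf("enc%d.conv2.w", i)]] <- bw$dw
    g[[sprintf("enc%d.conv2.b", i)]] <- as.vector(bw$db)
    dz <- bw$dx * ec$m1
    bw <- conv3_bw(ec$a0, p[[sprintf("enc%d.conv1.w", i)]], dz)
    g[[sprintf("enc%d.conv1.w", i)]] <- bw$dw
    g[[sprintf("enc%d.conv1.b", i)]] <- as.vector(bw$db)
    dA <- bw$dx
  }
  g
}

#' Segmentation loss functions
#'
#' `dice_loss` is the region-based loss
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)` with smoothing
#' `eps = 1` (in pixel-count units).  `cross_entropy_loss` is the mean
#' per-pixel negative log probability of the true class, and
#' `focal_loss` its focusing variant
#' `mean((1 - p_true)^gamma * (-log p_true))`; `gamma = 0` recovers
#' cross-entropy.  Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param prob numeric matrix of foreground probabilities in [0, 1] (or
#'   a `prob_map`).
#' @param target logical mask of the same shape.
#' @param gamma focusing exponent (>= 0).
#' @return Scalar loss value.
#' @export
dice_loss <- function(prob, target) {
  prob <- prob_values(prob); target <- as_mask(target)
  stopifnot_shape(prob, target)
  t <- as.numeric(target)
  1 - (2 * sum(prob * t) + 1) / (sum(prob) + sum(t) + 1)
}

#' @rdname dice_loss
#' @export
cross_entropy_loss <- function(prob, target) focal_loss(prob, target, 0)

#' @rdname dice_loss
#' @export
focal_loss <- function(prob, target, gamma = 2) {
  prob <- prob_values(prob); target <- as_mask(target)
  stopifnot_shape(prob, target)
  stopifnot(gamma >= 0)
  pt <- ifelse(target, prob, 1 - prob)
  pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
  mean((1 - pt)^gamma * (-log(pt)))
}

# loss + gradient wrt prob, used by the training loop
loss_with_grad <- function(kind, prob, target, gamma = 2) {
  t <- as.numeric(target)
  n <- length(prob)
  if (kind == "dice") {
    num <- 2 * sum(prob * t) + 1
    den <- sum(prob) + sum(t) + 1
    loss <- 1 - num / den
    dp <- -(2 * t * den - num) / den^2
  } else {
    g <- if (kind == "focal") gamma else 0
    pt <- ifelse(t > 0, prob, 1 - prob)
    pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
    if (g == 0) {
      loss <- mean(-log(pt))
      dpt <- -1 / (pt * n)
    } else {
      loss <- mean((1 - pt)^g * (-log(pt)))
      dpt <- (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt) / n
    }
    dp <- ifelse(t > 0, dpt, -dpt)
  }
  list(loss = loss, dprob = matrix(dp, nrow(target), ncol(target)))
}

#' 1-cycle learning-rate schedule
#'
#' The learning rate is cycled once between two bounds over the whole
#' run: a linear ramp from `lr_bounds[1]` up to `lr_bounds[2]` over the
#' first half of the steps, then a linear ramp back down over the
#' second half.
#'
#' @param lr_bounds c(min, max) learning rates.
#' @param total_steps total optimizer step count (>= 2).
#' @return Function `lr(step)` for step in [0, total_steps].
#' @export
one_cycle_schedule <- function(lr_bounds, total_steps) {
  stopifnot(total_steps >= 2, lr_bounds[1] < lr_bounds[2])
  lo <- lr_bounds[1]; hi <- lr_bounds[2]; half <- total_steps / 2
  function(step) {
    s <- pmin(pmax(step, 0), total_steps)
    ifelse(s <= half, lo + (hi - lo) * s / half,
           hi - (hi - lo) * (s - half) / half)
  }
}

#' Training configuration
#'
#' @param loss `"dice"` (default, region-based), `"ce"` or `"focal"`.
#' @param focal_gamma focusing exponent of the focal loss.
#' @param optimizer `"adam"` or `"radam_lookahead"`.
#' @param lr_bounds c(min, max) bounds of the 1-cycle schedule.
#' @param epochs maximum epoch count.
#' @param patience early-stopping patience in epochs (default 10).
#' @param batch_size mini-batch size (default 2).
#' @param seed training seed.
#' @param augment double the training set with one random
#'   flip/rotation per image.
#' @param resize_factor working resolution relative to the input
#'   images; probability maps are upscaled back before evaluation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(loss = c("dice", "ce", "focal"),
                         focal_gamma = 2,
                         optimizer = c("adam", "radam_lookahead"),
                         lr_bounds = c(1e-4, 1e-2), epochs = 40,
                         patience = 10, batch_size = 2, seed = 1,
                         augment = TRUE, resize_factor = 1) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  stopifnot(lr_bounds[1] < lr_bounds[2], patience <= epochs,
            batch_size >= 1, resize_factor > 0, resize_factor <= 1)
  structure(as.list(environment()), class = "train_config")
}

# --- optimizers -----------------------------------------------------------

make_optimizer <- function(kind, par) {
  zeros <- lapply(par, function(x) x * 0)
  st <- list(kind = kind, t = 0, m = zeros, v = zeros,
             slow = if (kind == "radam_lookahead") par else NULL,
             la_k = 6, la_alpha = 0.5, b1 = 0.9, b2 = 0.999, eps = 1e-8)
  st
}

optimizer_step <- function(st, par, grads, lr) {
  st$t <- st$t + 1
  b1 <- st$b1; b2 <- st$b2; t <- st$t
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  for (nm in names(par)) {
    gn <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * gn
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * gn^2
    mhat <- st$m[[nm]] / (1 - b1^t)
    if (st$kind == "adam") {
      vhat <- st$v[[nm]] / (1 - b2^t)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + st$eps)
    } else {  # RAdam with variance rectification
      if (rho_t > 4) {
        r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        vhat <- sqrt(st$v[[nm]] / (1 - b2^t))
        par[[nm]] <- par[[nm]] - lr * r * mhat / (vhat + st$eps)
      } else {
        par[[nm]] <- par[[nm]] - lr * mhat
      }
    }
  }
  if (st$kind == "radam_lookahead" && st$t %% st$la_k == 0) {
    for (nm in names(par)) {
      st$slow[[nm]] <- st$slow[[nm]] +
        st$la_alpha * (par[[nm]] - st$slow[[nm]])
      par[[nm]] <- st$slow[[nm]]
    }
  }
  list(state = st, par = par)
}

# --- training -------------------------------------------------------------

# Prepare one sample for the network: 8-bit conversion, optional
# resize, [0,1] normalization.  Keeps the native-resolution target for
# validation metrics.
prep_sample <- function(s, resize_factor) {
  img <- if (inherits(s$image, "gray_image")) to_8bit(s$image)
         else gray_image(s$image, 8)
  x <- img$values
  t <- s$target
  if (resize_factor != 1) {
    x <- resize(x, resize_factor, "bilinear")
    t <- resize(t, resize_factor, "nearest")
  }
  list(x = x / 255, t = t, target_native = s$target,
       image = img, spheroid_id = s$spheroid_id)
}

val_jcd_metric <- function(model, val_prepped, pixel_size = 1) {
  js <- vapply(val_prepped, function(v) {
    fw <- unet_forward(model, v$x)
    prob <- resize_to(fw$prob, dim(v$target_native))
    seg <- extract_spheroid(prob_map(prob, dim(v$target_native)))
    jcd(seg$spheroid_mask, v$target_native)
  }, 0)
  mean(js)
}

#' Train the segmenter
#'
#' Mini-batch gradient descent with the 1-cycle learning-rate policy
#' and validation-based early stopping: after every epoch the mean
#' Jaccard distance over the validation set (computed through the full
#' probability-map -> largest-component postprocessing chain at native
#' resolution) is monitored, and training stops once it has not
#' improved for `patience` epochs; the best-scoring weights are
#' restored.  Training refuses to start when a spheroid ID occurs in
#' both sets (data leakage).
#'
#' @param model a `unet_model` from [build_model()].
#' @param train_set,val_set lists of samples (`image`, `target`,
#'   `spheroid_id`), e.g. from [generate_dataset()].
#' @param config a [train_config()].
#' @param val_metric_fn optional override of the validation metric,
#'   `function(model, epoch) -> numeric` (lower is better); used mainly
#'   for testing the early-stopping contract.
#' @param verbose print per-epoch progress.
#' @return The trained model; `$history` holds per-epoch training loss
#'   and validation JCD, `$best_epoch` the restored epoch.
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  val_metric_fn = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"),
            inherits(config, "train_config"),
            length(train_set) > 0, length(val_set) > 0)
  tr_ids <- unique(vapply(train_set, `[[`, "", "spheroid_id"))
  va_ids <- unique(vapply(val_set, `[[`, "", "spheroid_id"))
  shared <- intersect(tr_ids, va_ids)
  if (length(shared) > 0)
    stop("data leakage: spheroid IDs in both train and val sets: ",
         paste(shared, collapse = ", "))

  if (config$augment)
    train_set <- build_training_set(train_set, seed = config$seed)
  tr <- lapply(train_set, prep_sample, resize_factor = config$resize_factor)
  va <- lapply(val_set, prep_sample, resize_factor = config$resize_factor)

  n <- length(tr)
  steps_per_epoch <- ceiling(n / config$batch_size)
  sched <- one_cycle_schedule(config$lr_bounds,
                              config$epochs * steps_per_epoch)
  opt <- make_optimizer(config$optimizer, model$par)
  if (is.null(val_metric_fn))
    val_metric_fn <- function(model, epoch) val_jcd_metric(model, va)

  best <- Inf; best_par <- model$par; best_epoch <- 0L
  hist_loss <- numeric(0); hist_val <- numeric(0)
  step <- 0
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1) * config$batch_size + 1):
                     min(b * config$batch_size, n)]
        grads <- NULL
        bl <- 0
        for (i in idx) {
          fw <- unet_forward(model, tr[[i]]$x, keep_cache = TRUE)
          lw <- loss_with_grad(config$loss, fw$prob, tr[[i]]$t,
                               config$focal_gamma)
          bl <- bl + lw$loss
          gi <- unet_backward(model, fw$cache, lw$dprob)
          grads <- if (is.null(grads)) gi
                   else mapply(`+`, grads, gi, SIMPLIFY = FALSE)
        }
        grads <- lapply(grads, `/`, length(idx))
        res <- optimizer_step(opt, model$par, grads, sched(step))
        opt <- res$state
        model$par <- res$par
        step <- step + 1
        ep_loss <- ep_loss + bl / length(idx)
      }
      vj <- val_metric_fn(model, epoch)
      hist_loss <- c(hist_loss, ep_loss / steps_per_epoch)
      hist_val <- c(hist_val, vj)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_jcd %.4f", epoch,
                        hist_loss[epoch], vj))
      if (vj < best - 1e-12) {
        best <- vj; best_par <- model$par; best_epoch <- epoch
      } else if (epoch - best_epoch >= config$patience) {
        break
      }
    }
  })
  model$par <- best_par
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  model$history <- data.frame(epoch = seq_along(hist_loss),
                              train_loss = hist_loss, val_jcd = hist_val)
  model
}

#' Probability map container
#' @param values numeric matrix in [0, 1].
#' @param source_size c(rows, cols) of the native image the map refers
#'   to.
#' @return Object of class `prob_map`.
#' @export
prob_map <- function(values, source_size = dim(values)) {
  stopifnot(is.matrix(values), min(values) >= 0, max(values) <= 1)
  structure(list(values = values, source_size = as.integer(source_size)),
            class = "prob_map")
}

prob_values <- function(p) if (inherits(p, "prob_map")) p$values else p

#' Predict a spheroid probability map for one image
#'
#' The image is converted to 8 bit, optionally downscaled by
#' `resize_factor` for the forward pass (with reflection padding to the
#' next multiple of `2^depth`), and the probability map is upscaled
#' back to the native resolution so that all downstream metrics live on
#' the native pixel grid.
#'
#' @param model a trained `unet_model`.
#' @param image `gray_image` or 8-bit matrix.
#' @param resize_factor working-resolution factor in (0, 1].
#' @return A `prob_map` at the native image size.  If the model has
#'   never been trained a warning is issued and recorded in the
#'   `untrained` attribute.
#' @export
predict_probmap <- function(model, image, resize_factor = 1) {
  stopifnot(inherits(model, "unet_model"))
  untrained <- !isTRUE(model$trained)
  if (untrained)
    warning("model has not been trained; probabilities are arbitrary")
  img <- if (inherits(image, "gray_image")) to_8bit(image)
         else gray_image(image, 8)
  native <- dim(img$values)
  x <- if (resize_factor != 1) resize(img$values, resize_factor,
                                      "bilinear") else img$values
  x <- x / 255
  # reflection-pad to a multiple of 2^depth
  m <- 2^model$config$depth
  pad <- (m - dim(x) %% m) %% m
  if (any(pad > 0)) {
    if (pad[1] > 0) x <- rbind(x, x[nrow(x):(nrow(x) - pad[1] + 1), ,
                                    drop = FALSE])
    if (pad[2] > 0) x <- cbind(x, x[, ncol(x):(ncol(x) - pad[2] + 1),
                                    drop = FALSE])
  }
  prob <- unet_forward(model, x)$prob
  if (any(pad > 0))
    prob <- prob[seq_len(nrow(prob) - pad[1]),
                 seq_len(ncol(prob) - pad[2]), drop = FALSE]
  prob <- resize_to(prob, native)
  out <- prob_map(prob, native)
  attr(out, "untrained") <- untrained
  out
}

#' Save / load a model checkpoint
#' @param model a `unet_model`.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
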