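#' @title Trainable encoder-decoder segmenter (ASPP + sub-pixel decoder)
#' @name segnet
#' @description
#' A small convolutional encoder-decoder for per-pixel root probability,
#' implemented directly on the package's own convolution kernels. The
#' encoder stacks 3x3 convolution + ReLU + 2x2 average-pool stages; at the
#' bottleneck an atrous spatial pyramid pooling (ASPP) block runs parallel
#' 3x3 convolutions at several dilation rates and fuses them with a 1x1
#' convolution, capturing context at multiple scales around thin roots. The
#' decoder upsamples exclusively by sub-pixel convolution (pixel shuffle): a
#' 1x1 convolution expands channels to `r^2 x C` which are reshaped into an
#' `r`-fold larger grid, avoiding interpolation blur on fine root edges;
#' every decoder stage uses it, so the product of upsampling factors equals
#' the encoder's total downsampling. Training minimises pixel-wise binary
#' cross-entropy plus a Dice term with Adam, on seeded, foreground-balanced
#' patches with flip/rotation augmentation.
NULL

#' Configuration of the trainable segmenter
#'
#' @param in_channels input channels (3 for RGB).
#' @param enc_channels channel width per encoder stage; each stage halves
#'   resolution, so the decoder applies one x2 pixel-shuffle per stage.
#' @param aspp_rates dilation rates of the parallel ASPP branches (>= 3
#'   distinct positive integers).
#' @param aspp_channels channels per ASPP branch.
#' @param dec_channels channels of the intermediate decoder stages.
#' @param patch_px square patch size for training and tiled inference; must
#'   be divisible by the total downsampling factor.
#' @param epochs,batch_size,batches_per_epoch training schedule.
#' @param lr Adam learning rate.
#' @param dice_weight weight of the Dice loss term added to cross-entropy.
#' @param seed seed controlling weight init, patch sampling and
#'   augmentation.
#' @export
seg_model_config <- function(in_channels = 3L, enc_channels = c(8L, 16L),
                             aspp_rates = c(1L, 2L, 4L), aspp_channels = 8L,
                             dec_channels = 8L, patch_px = 64L,
                             epochs = 10L, batch_size = 8L,
                             batches_per_epoch = 48L, lr = 0.01,
                             dice_weight = 1, seed = 1L) {
  if (length(aspp_rates) < 3L || anyDuplicated(aspp_rates) ||
      any(aspp_rates < 1))
    stop("aspp_rates must be >= 3 distinct positive integers")
  down <- 2L^length(enc_channels)
  if (patch_px %% down != 0L)
    stop("patch_px must be divisible by the total downsampling factor ", down)
  structure(as.list(environment()), class = "seg_model_config")
}

relu <- function(x) { x[x < 0] <- 0; x }

conv_layer <- function(k, cin, cout, dil = 1L, fan_scale = 2) {
  w <- array(rnorm(k * k * cin * cout, 0, sqrt(fan_scale / (k * k * cin))),
             c(k, k, cin, cout))
  list(w = w, b = numeric(cout), k = k, cin = cin, cout = cout, dil = dil)
}

conv_fw <- function(layer, x) {
  d <- dim(x)
  conv2d_fw(x, layer$w, layer$b, d[1], d[2], layer$cin, layer$cout,
            layer$k, layer$dil)
}

conv_bw <- function(layer, x, gy) {
  d <- dim(x)
  conv2d_bw(x, layer$w, gy, d[1], d[2], layer$cin, layer$cout,
            layer$k, layer$dil)
}

# sub-pixel upsample: (H, W, r^2*C) -> (rH, rW, C)
pixel_shuffle <- function(x, r) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3] / (r * r)
  a <- array(x, c(H, W, r, r, C))
  a <- aperm(a, c(3, 1, 4, 2, 5))       # (dr, H, dc, W, C)
  array(a, c(r * H, r * W, C))
}

pixel_unshuffle <- function(y, r) {
  d <- dim(y); H <- d[1] / r; W <- d[2] / r; C <- d[3]
  a <- array(y, c(r, H, r, W, C))
  a <- aperm(a, c(2, 4, 1, 3, 5))       # (H, W, dr, dc, C)
  array(a, c(H, W, r * r * C))
}

init_seg_model <- function(config) {
  cfg <- config
  n <- length(cfg$enc_channels)
  layers <- list(enc = list(), aspp = list(), fuse = NULL,
                 up = list(), dec = list())
  cin <- cfg$in_channels
  for (i in seq_len(n)) {
    layers$enc[[i]] <- conv_layer(3L, cin, cfg$enc_channels[i])
    cin <- cfg$enc_channels[i]
  }
  for (j in seq_along(cfg$aspp_rates))
    layers$aspp[[j]] <- conv_layer(3L, cin, cfg$aspp_channels,
                                   dil = as.integer(cfg$aspp_rates[j]))
  layers$fuse <- conv_layer(1L, cfg$aspp_channels * length(cfg$aspp_rates), cin)
  # decoder: one x2 sub-pixel stage per encoder stage
  dc <- cin
  for (i in seq_len(n)) {
    cnext <- if (i < n) cfg$dec_channels else 1L   # last stage emits logits
    layers$up[[i]] <- conv_layer(1L, dc, 4L * cnext)
    if (i < n) layers$dec[[i]] <- conv_layer(3L, cnext, cfg$dec_channels)
    dc <- if (i < n) cfg$dec_channels else 1L
  }
  structure(list(config = cfg, layers = layers, trained = FALSE,
                 epoch_loss = numeric(0)), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "seg_model: encoder %s, ASPP rates (%s) x %d ch, sub-pixel decoder, patch %d px%s\n",
    paste(cfg$enc_channels, collapse = "-"),
    paste(cfg$aspp_rates, collapse = ","), cfg$aspp_channels, cfg$patch_px,
    if (x$trained) sprintf(", trained %d epochs (final loss %.4f)",
                           length(x$epoch_loss), tail(x$epoch_loss, 1))
    else " (untrained)"))
  invisible(x)
}

# forward pass; returns logits and the activation cache for backprop
seg_forward <- function(model, x, keep_cache = TRUE) {
  L <- model$layers
  n <- length(L$enc)
  cache <- list(x = x, enc_in = list(), enc_pre = list(), pool_in = list())
  h <- x
  for (i in seq_len(n)) {
    cache$enc_in[[i]] <- h
    z <- conv_fw(L$enc[[i]], h)
    cache$enc_pre[[i]] <- z
    a <- relu(z)
    cache$pool_in[[i]] <- a
    d <- dim(a)
    h <- avgpool2_fw(a, d[1], d[2], d[3])
  }
  cache$bottleneck <- h
  az <- lapply(L$aspp, conv_fw, x = h)
  cache$aspp_pre <- az
  aa <- lapply(az, relu)
  cat_ <- array(unlist(aa), c(dim(h)[1], dim(h)[2],
                              length(aa) * dim(aa[[1]])[3]))
  cache$cat <- cat_
  fz <- conv_fw(L$fuse, cat_)
  cache$fuse_pre <- fz
  d <- relu(fz)
  for (i in seq_len(n)) {
    cache[[paste0("up_in", i)]] <- d
    u <- conv_fw(L$up[[i]], d)
    cache[[paste0("shuf_in", i)]] <- u
    s <- pixel_shuffle(u, 2L)
    if (i < n) {
      cache[[paste0("dec_in", i)]] <- s
      z <- conv_fw(L$dec[[i]], s)
      cache[[paste0("dec_pre", i)]] <- z
      d <- relu(z)
    } else d <- s
  }
  list(logits = d[, , 1], cache = if (keep_cache) cache else NULL)
}

# loss and gradient wrt logits: mean BCE + dice_weight * (1 - Dice)
seg_loss_grad <- function(logits, target, dice_weight) {
  p <- 1 / (1 + exp(-logits))
  N <- length(p)
  eps <- 1e-6
  bce <- -mean(target * log(p + 1e-12) + (1 - target) * log(1 - p + 1e-12))
  sp <- sum(p); sg <- sum(target); spg <- sum(p * target)
  dice <- (2 * spg + eps) / (sp + sg + eps)
  loss <- bce + dice_weight * (1 - dice)
  g_bce <- (p - target) / N
  g_dice_p <- -(2 * target * (sp + sg + eps) - (2 * spg + eps)) / (sp + sg + eps)^2
  g <- g_bce + dice_weight * g_dice_p * p * (1 - p)
  list(loss = loss, grad = g)
}

# backward pass; returns list of gradients shaped like the layer list
seg_backward <- function(model, cache, g_logits) {
  L <- model$layers
  n <- length(L$enc)
  gr <- list(enc = vector("list", n), aspp = vector("list", length(L$aspp)),
             fuse = NULL, up = vector("list", n),
             dec = vector("list", max(n - 1L, 0L)))
  g <- array(g_logits, c(dim(g_logits), 1L))
  for (i in rev(seq_len(n))) {
    if (i < n) {
      g <- g * (cache[[paste0("dec_pre", i)]] > 0)
      bw <- conv_bw(L$dec[[i]], cache[[paste0("dec_in", i)]], g)
      gr$dec[[i]] <- list(gw = bw$gw, gb = bw$gb)
      g <- bw$gx
    }
    g <- pixel_unshuffle(g, 2L)
    bw <- conv_bw(L$up[[i]], cache[[paste0("up_in", i)]], g)
    gr$up[[i]] <- list(gw = bw$gw, gb = bw$gb)
    g <- bw$gx
  }
  g <- g * (cache$fuse_pre > 0)
  bw <- conv_bw(L$fuse, cache$cat, g)
  gr$fuse <- list(gw = bw$gw, gb = bw$gb)
  g <- bw$gx
  cb <- model$config$aspp_channels
  gb_sum <- 0
  for (j in seq_along(L$aspp)) {
    gj <- g[, , ((j - 1L) * cb + 1L):(j * cb), drop = FALSE]
    gj <- gj * (cache$aspp_pre[[j]] > 0)
    bw <- conv_bw(L$aspp[[j]], cache$bottleneck, gj)
    gr$aspp[[j]] <- list(gw = bw$gw, gb = bw$gb)
    gb_sum <- gb_sum + bw$gx
  }
  g <- gb_sum
  for (i in rev(seq_len(n))) {
    d <- dim(cache$pool_in[[i]])
    g <- avgpool2_bw(g, d[1], d[2], d[3])
    g <- g * (cache$enc_pre[[i]] > 0)
    bw <- conv_bw(L$enc[[i]], cache$enc_in[[i]], g)
    gr$enc[[i]] <- list(gw = bw$gw, gb = bw$gb)
    g <- bw$gx
  }
  gr
}

# flatten layer tree to a named list of parameter arrays (for Adam)
walk_params <- function(layers, fn) {
  for (grp in c("enc", "aspp", "up", "dec"))
    for (i in seq_along(layers[[grp]]))
      if (!is.null(layers[[grp]][[i]]))
        fn(paste0(grp, i), layers[[grp]][[i]])
  fn("fuse", layers$fuse)
  invisible(NULL)
}

adam_update <- function(model, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  keys <- list(list(grp = "fuse", i = 0L))
  for (grp in c("enc", "aspp", "up", "dec"))
    for (i in seq_along(model$layers[[grp]]))
      keys[[length(keys) + 1L]] <- list(grp = grp, i = i)
  for (kk in keys) {
    grp <- kk$grp; i <- kk$i
    lay <- if (grp == "fuse") model$layers$fuse else model$layers[[grp]][[i]]
    g <- if (grp == "fuse") grads$fuse else grads[[grp]][[i]]
    if (is.null(lay) || is.null(g)) next
    for (pn in c("w", "b")) {
      gv <- if (pn == "w") g$gw else g$gb
      k <- paste0(grp, i, ".", pn)
      if (is.null(state$m[[k]])) { state$m[[k]] <- gv * 0; state$v[[k]] <- gv * 0 }
      state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gv
      state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gv^2
      mhat <- state$m[[k]] / (1 - beta1^t)
      vhat <- state$v[[k]] / (1 - beta2^t)
      lay[[pn]] <- lay[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (grp == "fuse") model$layers$fuse <- lay
    else model$layers[[grp]][[i]] <- lay
  }
  list(model = model, state = state)
}

# accumulate b into a, layer-wise (both gradient trees)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (grp in c("enc", "aspp", "up", "dec"))
    for (i in seq_along(b[[grp]]))
      if (!is.null(b[[grp]][[i]])) {
        a[[grp]][[i]]$gw <- a[[grp]][[i]]$gw + b[[grp]][[i]]$gw
        a[[grp]][[i]]$gb <- a[[grp]][[i]]$gb + b[[grp]][[i]]$gb
      }
  a$fuse$gw <- a$fuse$gw + b$fuse$gw
  a$fuse$gb <- a$fuse$gb + b$fuse$gb
  a
}

grads_scale <- function(a, s) {
  for (grp in c("enc", "aspp", "up", "dec"))
    for (i in seq_along(a[[grp]]))
      if (!is.null(a[[grp]][[i]])) {
        a[[grp]][[i]]$gw <- a[[grp]][[i]]$gw * s
        a[[grp]][[i]]$gb <- a[[grp]][[i]]$gb * s
      }
  a$fuse$gw <- a$fuse$gw * s
  a$fuse$gb <- a$fuse$gb * s
  a
}

# sample one training patch (image + mask), foreground-balanced, augmented
sample_patch <- function(frames, masks, P, balanced = TRUE) {
  f <- sample.int(length(frames), 1L)
  img <- frames[[f]]; msk <- masks[[f]]
  nr <- dim(img)[1]; nc <- dim(img)[2]
  use_fg <- balanced && runif(1) < 0.5 && sum(msk) > 0
  if (use_fg) {
    on <- which(msk == 1L)
    ctr <- on[sample.int(length(on), 1L)]
    r0 <- ((ctr - 1L) %% nr) + 1L - P %/% 2L
    c0 <- ((ctr - 1L) %/% nr) + 1L - P %/% 2L
  } else {
    r0 <- sample.int(max(nr - P + 1L, 1L), 1L)
    c0 <- sample.int(max(nc - P + 1L, 1L), 1L)
  }
  r0 <- min(max(r0, 1L), nr - P + 1L)
  c0 <- min(max(c0, 1L), nc - P + 1L)
  xi <- img[r0:(r0 + P - 1L), c0:(c0 + P - 1L), , drop = FALSE]
  yi <- msk[r0:(r0 + P - 1L), c0:(c0 + P - 1L)]
  # augmentation: flips and 90-degree rotations only
  if (runif(1) < 0.5) { xi <- xi[P:1, , , drop = FALSE]; yi <- yi[P:1, ] }
  if (runif(1) < 0.5) { xi <- xi[, P:1, , drop = FALSE]; yi <- yi[, P:1] }
  if (runif(1) < 0.5) {
    xi <- aperm(xi, c(2, 1, 3)); yi <- t(yi)
  }
  list(x = xi, y = yi)
}

#' Train the encoder-decoder segmenter on paired frames and masks
#'
#' @param frames list of RGB arrays (or an `image_series`, whose frames are
#'   read on the fly).
#' @param masks list of binary truth masks matching `frames`.
#' @param config a [seg_model_config()].
#' @return a trained `seg_model`; `$epoch_loss` holds the mean training loss
#'   per epoch (finite and decreasing from first to last epoch on any
#'   learnable problem).
#' @export
train_seg_model <- function(frames, masks, config = seg_model_config()) {
  if (inherits(frames, "image_series")) frames <- lapply(frames$records, read_frame)
  if (length(frames) == 0L) stop("empty training set")
  if (length(frames) != length(masks)) stop("frames and masks must be paired")
  for (i in seq_along(frames)) {
    masks[[i]] <- as_binary_mask(masks[[i]])
    if (!identical(dim(frames[[i]])[1:2], dim(masks[[i]])[1:2]))
      stop("frame/mask shape mismatch at pair ", i)
  }
  cfg <- config
  P <- cfg$patch_px
  if (any(vapply(frames, function(f) dim(f)[1] < P || dim(f)[2] < P, logical(1))))
    stop("all frames must be at least patch_px on each side")
  with_seed(cfg$seed, {
    model <- init_seg_model(cfg)
    state <- list(m = list(), v = list())
    t_step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ep_losses <- numeric(cfg$batches_per_epoch)
      for (bt in seq_len(cfg$batches_per_epoch)) {
        acc <- NULL; loss_sum <- 0
        for (s in seq_len(cfg$batch_size)) {
          pa <- sample_patch(frames, masks, P)
          fw <- seg_forward(model, pa$x)
          lg <- seg_loss_grad(fw$logits, pa$y, cfg$dice_weight)
          loss_sum <- loss_sum + lg$loss
          acc <- grads_add(acc, seg_backward(model, fw$cache, lg$grad))
        }
        acc <- grads_scale(acc, 1 / cfg$batch_size)
        t_step <- t_step + 1L
        st <- adam_update(model, acc, state, cfg$lr, t_step)
        model <- st$model; state <- st$state
        ep_losses[bt] <- loss_sum / cfg$batch_size
      }
      model$epoch_loss <- c(model$epoch_loss, mean(ep_losses))
    }
    model$trained <- TRUE
    model
  })
}

#' Predict a root mask with a trained segmenter
#'
#' Frames larger than the training patch are tiled with 25% overlap and
#' stitched from tile centres; the probability map is thresholded.
#'
#' @param model a trained `seg_model`.
#' @param image RGB array.
#' @param threshold probability cut; lowering it can only grow the mask.
#' @return binary mask with provenance `"model"` and attribute `prob`
#'   (the probability map).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (!inherits(model, "seg_model") || !isTRUE(model$trained))
    stop("model is not trained")
  prob <- predict_prob(model, image)
  m <- root_mask((prob > threshold) + 0L, "model")
  attr(m, "prob") <- prob
  m
}

predict_prob <- function(model, image) {
  if (length(dim(image)) == 2L) image <- array(rep(image, 3L), c(dim(image), 3L))
  P <- model$config$patch_px
  nr <- dim(image)[1]; nc <- dim(image)[2]
  margin <- P %/% 8L                       # 25% tile overlap
  stride <- P - 2L * margin
  # reflect-pad so that tiling covers the frame
  nr_p <- max(P, stride * ceiling((nr - P) / stride + 1e-9) + P)
  nc_p <- max(P, stride * ceiling((nc - P) / stride + 1e-9) + P)
  pr <- reflect_pad(image, nr_p, nc_p)
  out <- matrix(NA_real_, nr_p, nc_p)
  r_starts <- seq(1L, nr_p - P + 1L, by = stride)
  c_starts <- seq(1L, nc_p - P + 1L, by = stride)
  for (r0 in r_starts) for (c0 in c_starts) {
    tile <- pr[r0:(r0 + P - 1L), c0:(c0 + P - 1L), , drop = FALSE]
    lg <- seg_forward(model, tile, keep_cache = FALSE)$logits
    p <- 1 / (1 + exp(-lg))
    # centre crop, extended to the frame edge for border tiles
    rlo <- if (r0 == 1L) 1L else margin + 1L
    rhi <- if (r0 == max(r_starts)) P else P - margin
    clo <- if (c0 == 1L) 1L else margin + 1L
    chi <- if (c0 == max(c_starts)) P else P - margin
    out[(r0 + rlo - 1L):(r0 + rhi - 1L), (c0 + clo - 1L):(c0 + chi - 1L)] <-
      p[rlo:rhi, clo:chi]
  }
  out[1:nr, 1:nc]
}

reflect_pad <- function(image, nr_p, nc_p) {
  nr <- dim(image)[1]; nc <- dim(image)[2]
  ri <- c(seq_len(nr), rev(seq_len(nr)))[((seq_len(nr_p) - 1L) %% (2L * nr)) + 1L]
  ci <- c(seq_len(nc), rev(seq_len(nc)))[((seq_len(nc_p) - 1L) %% (2L * nc)) + 1L]
  image[ri, ci, , drop = FALSE]
}

#' Save / load a segmenter checkpoint
#'
#' The checkpoint is a single serialized file with the configuration
#' embedded.
#' @param model a `seg_model`.
#' @param path checkpoint path.
#' @export
save_seg_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "seg_model")) stop("not a seg_model checkpoint")
  m
}
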