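#' Three-channel slice triplets
#'
#' The indirect model sees each axial slice together with its two
#' neighbours as a three-channel input, which restores some through-plane
#' context to the 2D model. At the volume boundaries the missing
#' neighbour is the replicated edge slice, so an N-slice study yields
#' exactly N triplets.
#'
#' @param study a [dwi_study()] (or bare 3D array).
#' @return A list of `slice_triplet` objects, each with `channels`
#'   (array 3 x H x W: previous, current, next) and `index`.
#' @export
make_triplets <- function(study) {
  vol <- if (inherits(study, "dwi_study")) study$voxels else study
  n <- dim(vol)[1]
  lapply(seq_len(n), function(k) {
    ks <- c(max(1L, k - 1L), k, min(n, k + 1L))
    structure(list(channels = vol[ks, , , drop = FALSE], index = k),
              class = "slice_triplet")
  })
}

# triplet tensor for the network: (H, W, N, 3)
triplet_tensor <- function(vol) {
  n <- dim(vol)[1]
  out <- array(0, dim = c(dim(vol)[2], dim(vol)[3], n, 3L))
  for (k in seq_len(n)) {
    ks <- c(max(1L, k - 1L), k, min(n, k + 1L))
    for (c in 1:3) out[, , k, c] <- vol[ks[c], , ]
  }
  out
}

#' Random flip / right-angle rotation augmentation
#'
#' Draws a transform (independent horizontal flip, vertical flip, and
#' k x 90-degree rotation) and applies the *same* transform to the image
#' and its mask, so the pair stays aligned and the mask stays binary.
#' These transforms permute pixels, leaving the foreground count
#' unchanged. `invert_transform()` gives the inverse draw.
#'
#' @param image 2D matrix (or H x W x C array, transformed per channel).
#' @param mask 2D binary matrix aligned with `image`.
#' @param transform a draw from [draw_transform()]; a fresh draw from the
#'   current RNG by default.
#' @return List with transformed `image`, `mask`, and the `transform`
#'   applied.
#' @export
augment <- function(image, mask, transform = draw_transform()) {
  di <- dim(image); dm <- dim(mask)
  if (!identical(di[1:2], dm[1:2]))
    stop("image and mask are misaligned: ", paste(di[1:2], collapse = "x"),
         " vs ", paste(dm[1:2], collapse = "x"), call. = FALSE)
  list(image = apply_transform(image, transform),
       mask = apply_transform(mask, transform),
       transform = transform)
}

#' @rdname augment
#' @export
draw_transform <- function() {
  list(hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
       rot = sample(0:3, 1L))
}

rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_plane <- function(m, tr) {
  r <- tr$rot %% 4L
  if (r > 0 && nrow(m) != ncol(m))
    stop("right-angle rotation requires square slices", call. = FALSE)
  for (i in seq_len(r)) m <- rot90ccw(m)
  if (tr$hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (tr$vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' @param x image or mask to transform.
#' @rdname augment
#' @export
apply_transform <- function(x, transform) {
  if (is.matrix(x)) return(apply_plane(x, transform))
  d <- dim(x)
  if (length(d) == 3L) {           # H x W x C: per channel
    for (c in seq_len(d[3])) x[, , c] <- apply_plane(x[, , c], transform)
    return(x)
  }
  stop("cannot transform an array with ", length(d), " dims", call. = FALSE)
}

#' @param transform the draw to invert.
#' @rdname augment
#' @export
invert_transform <- function(transform) {
  # inverse applies the flips first (self-inverse), then the opposite
  # rotation; encoded as a sequence of two elementary draws
  structure(list(list(hflip = transform$hflip, vflip = transform$vflip, rot = 0L),
                 list(hflip = FALSE, vflip = FALSE, rot = (4L - transform$rot) %% 4L)),
            class = "transform_sequence")
}

#' @param seq a `transform_sequence` from [invert_transform()].
#' @rdname augment
#' @export
apply_transform_sequence <- function(x, seq) {
  for (tr in seq) x <- apply_transform(x, tr)
  x
}

#' Tile a volume into overlapping 3D patches and stitch predictions back
#'
#' The direct model is trained and run on fixed-size sub-volumes. The
#' volume is zero-padded up to the patch size where needed, tiled with
#' the given stride (a final patch is added per axis so every voxel is
#' covered), and per-patch probability maps are averaged where patches
#' overlap before cropping the padding away. Stitching the unchanged
#' patches of a constant field reproduces that constant everywhere.
#'
#' @param volume 3D numeric array (slices, H, W).
#' @param patch_shape integer triple (slices, H, W).
#' @param stride integer triple of positive strides, componentwise
#'   `<= patch_shape`.
#' @return For `extract_patches`: list of `patch3d` objects
#'   (`voxels`, `origin`) with the padded shape as an attribute.
#' @export
extract_patches <- function(volume, patch_shape, stride = pmax(1L, patch_shape %/% 2L)) {
  d <- dim(volume)
  patch_shape <- as.integer(patch_shape); stride <- as.integer(stride)
  if (any(stride <= 0L)) stop("stride components must be positive", call. = FALSE)
  if (any(stride > patch_shape)) stop("stride must not exceed patch shape", call. = FALSE)
  dp <- pmax(d, patch_shape)
  padded <- array(0, dim = dp)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- volume
  starts <- lapply(1:3, function(a) {
    s <- seq(1L, dp[a] - patch_shape[a] + 1L, by = stride[a])
    if (tail(s, 1L) + patch_shape[a] - 1L < dp[a]) s <- c(s, dp[a] - patch_shape[a] + 1L)
    s
  })
  grid <- expand.grid(starts[[1]], starts[[2]], starts[[3]], KEEP.OUT.ATTRS = FALSE)
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    o <- as.integer(grid[i, ])
    structure(list(voxels = padded[o[1] + seq_len(patch_shape[1]) - 1L,
                                   o[2] + seq_len(patch_shape[2]) - 1L,
                                   o[3] + seq_len(patch_shape[3]) - 1L, drop = FALSE],
                   origin = o),
              class = "patch3d")
  })
  attr(patches, "padded_shape") <- dp
  attr(patches, "volume_shape") <- d
  patches
}

#' @param patches list of `patch3d` objects carrying probability voxels.
#' @param volume_shape integer triple to crop the stitched result to
#'   (defaults to the shape recorded at extraction).
#' @rdname extract_patches
#' @export
stitch_patches <- function(patches, volume_shape = attr(patches, "volume_shape")) {
  dp <- attr(patches, "padded_shape")
  if (is.null(dp)) {
    ps <- dim(patches[[1]]$voxels)
    dp <- volume_shape
    for (p in patches) dp <- pmax(dp, p$origin + ps - 1L)
  }
  # online mean: m <- m + (v - m)/n is exactly constant-preserving
  # (identical contributions leave the mean bit-identical), unlike
  # sum-then-divide
  mean_arr <- array(0, dim = dp); cnt <- array(0, dim = dp)
  for (p in patches) {
    ps <- dim(p$voxels); o <- p$origin
    iz <- o[1] + seq_len(ps[1]) - 1L; iy <- o[2] + seq_len(ps[2]) - 1L
    ix <- o[3] + seq_len(ps[3]) - 1L
    n <- cnt[iz, iy, ix] + 1
    cnt[iz, iy, ix] <- n
    m <- mean_arr[iz, iy, ix]
    mean_arr[iz, iy, ix] <- m + (p$voxels - m) / n
  }
  if (any(cnt == 0)) stop("patches do not cover the volume", call. = FALSE)
  mean_arr[seq_len(volume_shape[1]), seq_len(volume_shape[2]),
           seq_len(volume_shape[3]), drop = FALSE]
}

#' Training configuration
#'
#' @param epochs maximum training epochs.
#' @param batch_size items per gradient step.
#' @param learning_rate Adam step size.
#' @param split_ratios positive train:validation:test fractions summing
#'   to 1.
#' @param threshold probability cutoff in (0, 1) for binarizing predicted
#'   maps.
#' @param seed integer seed driving the split, shuffling, augmentation
#'   draws and initialization.
#' @param augment_data apply random flip/rotation augmentation to
#'   training items.
#' @param normalize z-score each volume's intensities before the network.
#' @param target_size in-plane (height, width) the model works at.
#' @param patch_shape,patch_stride (slices, H, W) patch geometry for the
#'   direct path; `patch_stride` is the *inference* stride and defaults
#'   to 50% overlap (overlapping probability maps are averaged when
#'   stitching).
#' @param patch_train_stride stride used when tiling training volumes
#'   into patch items; defaults to `patch_shape` (non-overlapping
#'   training tiles, the usual trade of sample redundancy for epoch
#'   time).
#' @param oversample_foreground bias direct-path patch sampling toward
#'   lesion-containing patches (off by default: the class imbalance of
#'   uniform patches is part of the direct path's characterization).
#' @param eps Dice-loss denominator stabilizer.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, learning_rate = 1e-3,
                         split_ratios = c(0.8, 0.1, 0.1), threshold = 0.5,
                         seed = 1L, augment_data = TRUE, normalize = TRUE,
                         target_size = c(256L, 256L),
                         patch_shape = c(16L, 64L, 64L),
                         patch_stride = NULL,
                         patch_train_stride = NULL,
                         oversample_foreground = FALSE,
                         eps = 1e-6) {
  if (any(split_ratios <= 0) || abs(sum(split_ratios) - 1) > 1e-8)
    stop("`split_ratios` must be positive and sum to 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  if (is.null(patch_stride)) patch_stride <- pmax(1L, as.integer(patch_shape) %/% 2L)
  if (is.null(patch_train_stride)) patch_train_stride <- as.integer(patch_shape)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, split_ratios = split_ratios,
                 threshold = threshold, seed = as.integer(seed),
                 augment_data = augment_data, normalize = normalize,
                 target_size = as.integer(target_size),
                 patch_shape = as.integer(patch_shape),
                 patch_stride = as.integer(patch_stride),
                 patch_train_stride = as.integer(patch_train_stride),
                 oversample_foreground = oversample_foreground,
                 eps = eps),
            class = "train_config")
}

#' Split a cohort into train/validation/test by patient
#'
#' Patients (not slices) are shuffled with the given seed and partitioned
#' by the ratios, so adjacent slices of one patient never leak across
#' splits. Sizes are `floor(r * n)` for train and validation with the
#' remainder in test; every part must be nonempty.
#'
#' @param patient_ids character vector of unique ids.
#' @param split_ratios train:validation:test fractions.
#' @param seed integer shuffle seed.
#' @return List of character vectors `train`, `validation`, `test`.
#' @export
split_cohort <- function(patient_ids, split_ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(patient_ids)
  n_train <- floor(split_ratios[1] * n)
  n_val <- floor(split_ratios[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("cohort of ", n, " patients is too small for a nonempty ",
         paste(split_ratios, collapse = ":"), " split", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ord <- sample(patient_ids)
  list(train = sort(ord[seq_len(n_train)]),
       validation = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[n_train + n_val + seq_len(n_test)]))
}

normalize_volume <- function(vol) {
  s <- stats::sd(vol)
  if (s == 0) vol - mean(vol) else (vol - mean(vol)) / s
}

# preprocess one study+mask to model geometry; returns list(vol, mask_vol)
preprocess_pair <- function(study, mask, cfg) {
  st <- study_to_model_geometry(study, cfg$target_size)
  mk <- mask_to_model_geometry(mask, cfg$target_size)
  vol <- st$voxels
  if (cfg$normalize) vol <- normalize_volume(vol)
  list(vol = vol, mask_vol = mk$voxels)
}

# assemble indirect training items: list of (x: H x W x 3, y: H x W)
indirect_items <- function(vol, mask_vol) {
  tt <- triplet_tensor(vol)
  n <- dim(vol)[1]
  lapply(seq_len(n), function(k)
    list(x = tt[, , k, ], y = mask_vol[k, , ]))
}

# assemble direct training items: list of (x: D x H x W, y: same)
direct_items <- function(vol, mask_vol, cfg) {
  px <- extract_patches(vol, cfg$patch_shape, cfg$patch_train_stride)
  py <- extract_patches(array(as.numeric(mask_vol), dim = dim(mask_vol)),
                        cfg$patch_shape, cfg$patch_train_stride)
  Map(function(a, b) list(x = a$voxels, y = b$voxels), px, py)
}

batch_tensor_2d <- function(items, augmenting) {
  H <- nrow(items[[1]]$x); W <- ncol(items[[1]]$x)
  B <- length(items)
  x <- array(0, dim = c(H, W, B, 3L)); y <- array(0, dim = c(H, W, B))
  for (b in seq_len(B)) {
    xi <- items[[b]]$x; yi <- items[[b]]$y
    if (augmenting) {
      tr <- draw_transform()
      xi <- apply_transform(xi, tr); yi <- apply_transform(yi, tr)
    }
    x[, , b, ] <- xi; y[, , b] <- yi
  }
  list(x = x, y = y)
}

batch_tensor_3d <- function(items, augmenting) {
  d <- dim(items[[1]]$x); B <- length(items)
  x <- array(0, dim = c(d, B, 1L)); y <- array(0, dim = c(d, B))
  for (b in seq_len(B)) {
    xi <- items[[b]]$x; yi <- items[[b]]$y
    if (augmenting && d[2] == d[3]) {
      tr <- draw_transform()
      for (k in seq_len(d[1])) {
        xi[k, , ] <- apply_plane(xi[k, , ], tr)
        yi[k, , ] <- apply_plane(yi[k, , ], tr)
      }
    }
    x[, , , b, 1L] <- xi; y[, , , b] <- yi
  }
  list(x = x, y = y)
}

run_epoch <- function(model, items, cfg, state, training) {
  nd <- model$config$dimensionality
  B <- cfg$batch_size
  order <- if (training) sample(length(items)) else seq_along(items)
  losses <- numeric(0)
  i <- 1L
  while (i <= length(items)) {
    take <- order[i:min(i + B - 1L, length(items))]
    bt <- if (nd == 2L) batch_tensor_2d(items[take], training && cfg$augment_data)
          else batch_tensor_3d(items[take], training && cfg$augment_data)
    fw <- unet_forward_full(model, bt$x, training = training)
    model <- fw$model
    nb <- length(take)
    probs <- array(fw$probs, dim = c(dim(bt$x)[seq_len(nd)], nb))
    lg <- dice_loss_grad(probs, bt$y, eps = cfg$eps)
    losses <- c(losses, rep(lg$loss, nb))
    if (training) {
      dprobs <- array(lg$dprobs, dim = c(dim(bt$x)[seq_len(nd)], nb, 1L))
      grads <- unet_backward_full(model, fw$caches, dprobs)
      st <- adam_step(model$params, grads, state, lr = cfg$learning_rate)
      model$params <- st$params; state <- st$state
    }
    i <- i + B
  }
  list(model = model, state = state, loss = mean(losses))
}

#' Train a segmentation model on a cohort
#'
#' Splits the cohort by patient ([split_cohort()]), prepares training
#' items for the model's dimensionality (slice triplets for 2D, tiled 3D
#' patches for 3D), and minimizes the Dice loss with Adam, recording the
#' training and validation loss per epoch. The returned fit carries the
#' parameters of the epoch with the lowest validation loss. All
#' randomness (split, shuffling, augmentation, initialization) flows from
#' the configured seeds.
#'
#' @param model_config a [unet_config()].
#' @param config a [train_config()].
#' @param cohort list of `list(study, mask)` pairs (>= 3 patients, so
#'   every split part can be nonempty).
#' @return A `trained_unet`: list with `model`, `history` (tibble of
#'   epoch, train_loss, val_loss), `split`, `model_config`, `train_config`,
#'   `best_epoch`.
#' @export
train_model <- function(model_config, config, cohort) {
  ids <- vapply(cohort, function(p) p$study$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  split <- split_cohort(ids, config$split_ratios, config$seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  prep <- function(which_ids) {
    items <- list()
    for (id in which_ids) {
      p <- cohort[[match(id, ids)]]
      pp <- preprocess_pair(p$study, p$mask, config)
      new <- if (model_config$dimensionality == 2L) indirect_items(pp$vol, pp$mask_vol)
             else direct_items(pp$vol, pp$mask_vol, config)
      items <- c(items, new)
    }
    items
  }
  train_items <- prep(split$train)
  val_items <- prep(split$validation)
  if (model_config$dimensionality == 3L && config$oversample_foreground) {
    fg <- vapply(train_items, function(it) sum(it$y) > 0, logical(1))
    if (any(fg) && any(!fg)) train_items <- c(train_items, train_items[fg])
  }
  model <- unet_init(model_config)
  state <- adam_init(model$params)
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, params = model$params, running = model$running, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    tr <- run_epoch(model, train_items, config, state, training = TRUE)
    model <- tr$model; state <- tr$state
    vl <- run_epoch(model, val_items, config, state, training = FALSE)
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr$loss, val_loss = vl$loss)
    if (vl$loss < best$loss)
      best <- list(loss = vl$loss, params = model$params, running = model$running,
                   epoch = ep)
  }
  model$params <- best$params; model$running <- best$running
  structure(list(model = model, history = do.call(rbind, history),
                 split = split, model_config = model_config,
                 train_config = config, best_epoch = best$epoch),
            class = "trained_unet")
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("<trained_unet> %dD, %d epochs (best %d, val loss %.4f)\n",
              x$model_config$dimensionality, nrow(x$history), x$best_epoch,
              min(x$history$val_loss)))
  cat(sprintf("  split: %d train / %d validation / %d test patients\n",
              length(x$split$train), length(x$split$validation), length(x$split$test)))
  invisible(x)
}

#' @export
tidy.trained_unet <- function(x, ...) x$history

#' @export
glance.trained_unet <- function(x, ...) {
  tibble::tibble(dimensionality = x$model_config$dimensionality,
                 depth = x$model_config$depth,
                 base_channels = x$model_config$base_channels,
                 epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_loss = min(x$history$val_loss),
                 final_train_loss = tail(x$history$train_loss, 1L))
}

#' @export
autoplot.trained_unet <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$train_loss, set = "train"),
              data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(y = "Dice loss", colour = NULL)
}

preprocess_for_predict <- function(fit, study) {
  cfg <- fit$train_config
  st <- study_to_model_geometry(study, cfg$target_size)
  vol <- st$voxels
  if (cfg$normalize) vol <- normalize_volume(vol)
  vol
}

finalize_mask <- function(prob_vol, fit, study) {
  bin <- array(as.integer(prob_vol >= fit$train_config$threshold), dim = dim(prob_vol))
  native <- all(dim(bin)[2:3] == study$original_size)
  lesion_mask(bin, alignment = if (native) "native" else "resized")
}

#' Predict a lesion mask for a study
#'
#' `predict_indirect` runs every slice triplet through a trained 2D model
#' and restacks the binarized per-slice probability maps into a volume
#' mask. `predict_direct` tiles the volume into patches, runs the 3D
#' model, averages overlapping probabilities and binarizes. Both return a
#' mask in the model's resized geometry (tagged `"native"` when that
#' coincides with the acquisition matrix), ready for [estimate_volume()].
#'
#' @param fit a `trained_unet` from [train_model()].
#' @param study a [dwi_study()].
#' @return A [lesion_mask()].
#' @export
predict_indirect <- function(fit, study) {
  if (fit$model_config$dimensionality != 2L)
    stop("predict_indirect needs a 2D model", call. = FALSE)
  vol <- preprocess_for_predict(fit, study)
  tt <- triplet_tensor(vol)                     # H x W x N x 3
  probs <- unet_forward(fit$model, tt)          # H x W x N
  n <- dim(vol)[1]
  out <- array(0, dim = dim(vol))
  for (k in seq_len(n)) out[k, , ] <- probs[, , k]
  finalize_mask(out, fit, study)
}

#' @rdname predict_indirect
#' @export
predict_direct <- function(fit, study) {
  if (fit$model_config$dimensionality != 3L)
    stop("predict_direct needs a 3D model", call. = FALSE)
  cfg <- fit$train_config
  vol <- preprocess_for_predict(fit, study)
  patches <- extract_patches(vol, cfg$patch_shape, cfg$patch_stride)
  preds <- lapply(patches, function(p) {
    x <- array(p$voxels, dim = c(dim(p$voxels), 1L, 1L))
    pr <- unet_forward_full(fit$model, x, training = FALSE)$probs
    structure(list(voxels = array(pr, dim = dim(p$voxels)), origin = p$origin),
              class = "patch3d")
  })
  attr(preds, "padded_shape") <- attr(patches, "padded_shape")
  attr(preds, "volume_shape") <- attr(patches, "volume_shape")
  prob_vol <- stitch_patches(preds)
  finalize_mask(prob_vol, fit, study)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single serialized file embedding the parameters,
#' batch-norm statistics, both configurations (including their seeds),
#' the split membership and the training history.
#'
#' @param fit a `trained_unet`.
#' @param path checkpoint filename.
#' @return `load_checkpoint` returns the `trained_unet`.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "trained_unet")
}

#' Load externally trained weights into a model
#'
#' Hook for transfer learning: replaces any subset of the parameter
#' arrays by name (shapes must match). Weight files produced elsewhere
#' can thus initialize the encoder/decoder before fine-tuning.
#'
#' @param model a `unet_model`.
#' @param weights named list of arrays matching entries of
#'   `model$params`.
#' @return The model with the given parameters replaced.
#' @export
load_pretrained_weights <- function(model, weights) {
  for (nm in names(weights)) {
    if (!nm %in% names(model$params))
      stop("unknown parameter: ", nm, call. = FALSE)
    if (!identical(dim(model$params[[nm]]) %||% length(model$params[[nm]]),
                   dim(weights[[nm]]) %||% length(weights[[nm]])))
      stop("shape mismatch for parameter ", nm, call. = FALSE)
    model$params[[nm]] <- weights[[nm]]
  }
  model
}
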