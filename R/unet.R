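#' Configure an encoder-decoder segmentation network
#'
#' A symmetric U-shaped network: `depth` encoder levels of two
#' (convolution, batch normalization, ReLU) units with 3-voxel kernels,
#' each non-bottleneck level followed by 2x max pooling; a mirrored
#' decoder of 2x up-convolutions with skip concatenation from the matching
#' encoder level; and a final 1x1 convolution with a sigmoid, so the
#' output is a per-voxel probability map of the same spatial shape as the
#' input. The 2D variant takes three-channel slice triplets (the slice
#' plus its two neighbours); the 3D variant takes single-channel
#' sub-volume patches.
#'
#' @param dimensionality 2 or 3.
#' @param depth number of encoder levels including the bottleneck (>= 2);
#'   spatial input sizes must be divisible by `2^(depth - 1)`.
#' @param base_channels feature channels at the first level (>= 4),
#'   doubled at each deeper level.
#' @param input_channels 3 for the slice-triplet (indirect) model, 1 for
#'   the patch (direct) model.
#' @param seed integer seed for parameter initialization.
#' @return A `unet_config` object.
#' @export
unet_config <- function(dimensionality = 2L, depth = 3L, base_channels = 8L,
                        input_channels = if (dimensionality == 2) 3L else 1L,
                        seed = 1L) {
  if (!dimensionality %in% c(2L, 3L)) stop("`dimensionality` must be 2 or 3", call. = FALSE)
  if (depth < 2L) stop("`depth` must be >= 2", call. = FALSE)
  if (base_channels < 4L) stop("`base_channels` must be >= 4", call. = FALSE)
  structure(list(dimensionality = as.integer(dimensionality),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 input_channels = as.integer(input_channels),
                 seed = as.integer(seed)),
            class = "unet_config")
}

unet_channels <- function(config) config$base_channels * 2L^(seq_len(config$depth) - 1L)

he_init <- function(nin, nout, fan_in) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / fan_in)), nrow = nin, ncol = nout)
}

#' Initialize network parameters
#'
#' He-normal weights, zero biases, unit batch-norm scale; fully
#' determined by `config$seed`.
#'
#' @param config a [unet_config()].
#' @return A `unet_model`: list with `config`, `params` (flat named list)
#'   and `running` (batch-norm running statistics).
#' @export
unet_init <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  nd <- config$dimensionality
  K <- 3L^nd
  ch <- unet_channels(config)
  params <- list(); running <- list()
  add_conv <- function(name, cin, cout, k = K) {
    params[[paste0(name, ".W")]] <<- he_init(k * cin, cout, k * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
    params[[paste0(name, ".gamma")]] <<- rep(1, cout)
    params[[paste0(name, ".beta")]] <<- numeric(cout)
    running[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
  }
  for (l in seq_len(config$depth)) {
    cin <- if (l == 1L) config$input_channels else ch[l - 1L]
    add_conv(sprintf("e%dc1", l), cin, ch[l])
    add_conv(sprintf("e%dc2", l), ch[l], ch[l])
  }
  for (l in rev(seq_len(config$depth - 1L))) {
    noff <- 2L^nd
    params[[sprintf("u%d.W", l)]] <- he_init(ch[l + 1L], noff * ch[l], ch[l + 1L])
    params[[sprintf("u%d.b", l)]] <- numeric(ch[l])
    add_conv(sprintf("d%dc1", l), 2L * ch[l], ch[l])
    add_conv(sprintf("d%dc2", l), ch[l], ch[l])
  }
  params[["out.W"]] <- he_init(ch[1L], 1L, ch[1L])
  params[["out.b"]] <- numeric(1L)
  structure(list(config = config, params = params, running = running),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet_model> %dD, depth %d, base %d channels, %d input channel(s), %s parameters\n",
              x$config$dimensionality, x$config$depth, x$config$base_channels,
              x$config$input_channels, format(npar, big.mark = ",")))
  invisible(x)
}

check_divisible <- function(spatial, depth) {
  f <- 2L^(depth - 1L)
  if (any(spatial %% f != 0L))
    stop("spatial input size ", paste(spatial, collapse = "x"),
         " is not divisible by 2^(depth-1) = ", f, call. = FALSE)
}

conv_unit_forward <- function(model, name, x, training, caches) {
  p <- model$params
  k <- rep(3L, model$config$dimensionality)
  if (nrow(p[[paste0(name, ".W")]]) == dim(x)[length(dim(x))]) k <- rep(1L, model$config$dimensionality)
  cv <- conv_forward(x, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]], k)
  bn <- bn_forward(cv$out, p[[paste0(name, ".gamma")]], p[[paste0(name, ".beta")]],
                   model$running[[name]], training)
  model$running[[name]] <- bn$running
  rl <- relu_forward(bn$out)
  caches[[name]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  list(model = model, out = rl$out, caches = caches)
}

conv_unit_backward <- function(model, name, dout, caches, grads) {
  p <- model$params; cc <- caches[[name]]
  d1 <- relu_backward(dout, cc$relu)
  d2 <- bn_backward(d1, p[[paste0(name, ".gamma")]], cc$bn)
  grads[[paste0(name, ".gamma")]] <- d2$dgamma
  grads[[paste0(name, ".beta")]] <- d2$dbeta
  d3 <- conv_backward(d2$dx, p[[paste0(name, ".W")]], cc$conv)
  grads[[paste0(name, ".W")]] <- d3$dW
  grads[[paste0(name, ".b")]] <- d3$db
  list(dx = d3$dx, grads = grads)
}

# Full forward pass. x: (spatial..., batch, channel). Returns
# probabilities with a single output channel, plus caches for backward
# and the (possibly updated) model when training.
unet_forward_full <- function(model, x, training = FALSE) {
  cfg <- model$config
  nd <- cfg$dimensionality
  d <- dim(x)
  if (length(d) != nd + 2L)
    stop("input must have dims (spatial x ", nd, ", batch, channel)", call. = FALSE)
  if (d[nd + 2L] != cfg$input_channels)
    stop("expected ", cfg$input_channels, " input channel(s), got ", d[nd + 2L], call. = FALSE)
  check_divisible(d[seq_len(nd)], cfg$depth)
  caches <- list(); skips <- list()
  h <- x
  for (l in seq_len(cfg$depth)) {
    r <- conv_unit_forward(model, sprintf("e%dc1", l), h, training, caches)
    model <- r$model; caches <- r$caches
    r <- conv_unit_forward(model, sprintf("e%dc2", l), r$out, training, caches)
    model <- r$model; caches <- r$caches; h <- r$out
    if (l < cfg$depth) {
      skips[[l]] <- h
      pl <- pool_forward(h)
      caches[[sprintf("pool%d", l)]] <- pl$cache
      h <- pl$out
    }
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    up <- upconv_forward(h, model$params[[sprintf("u%d.W", l)]],
                         model$params[[sprintf("u%d.b", l)]])
    caches[[sprintf("up%d", l)]] <- up$cache
    h <- concat_channels(skips[[l]], up$out)
    caches[[sprintf("cat%d", l)]] <- dim(skips[[l]])[nd + 2L]
    r <- conv_unit_forward(model, sprintf("d%dc1", l), h, training, caches)
    model <- r$model; caches <- r$caches
    r <- conv_unit_forward(model, sprintf("d%dc2", l), r$out, training, caches)
    model <- r$model; caches <- r$caches; h <- r$out
  }
  fin <- conv_forward(h, model$params[["out.W"]], model$params[["out.b"]], rep(1L, nd))
  caches[["out"]] <- fin$cache
  probs <- sigmoid(fin$out)
  caches[["probs"]] <- probs
  list(model = model, probs = probs, caches = caches)
}

# Backward pass from d(loss)/d(probs); returns flat named gradient list.
unet_backward_full <- function(model, caches, dprobs) {
  cfg <- model$config
  p <- caches[["probs"]]
  dz <- dprobs * p * (1 - p)
  grads <- list()
  d3 <- conv_backward(dz, model$params[["out.W"]], caches[["out"]])
  grads[["out.W"]] <- d3$dW; grads[["out.b"]] <- d3$db
  dh <- d3$dx
  for (l in seq_len(cfg$depth - 1L)) {
    r <- conv_unit_backward(model, sprintf("d%dc2", l), dh, caches, grads)
    grads <- r$grads
    r <- conv_unit_backward(model, sprintf("d%dc1", l), r$dx, caches, grads)
    grads <- r$grads
    sp <- split_channels(r$dx, caches[[sprintf("cat%d", l)]])
    du <- upconv_backward(sp$second, model$params[[sprintf("u%d.W", l)]],
                          caches[[sprintf("up%d", l)]])
    grads[[sprintf("u%d.W", l)]] <- du$dW
    grads[[sprintf("u%d.b", l)]] <- du$db
    # gradient flowing into encoder level l: skip path + pooled path
    dskip <- sp$first
    dh <- du$dx   # gradient at bottom of level l+1 path, to be backed up later
    # back up through encoder level l now (skip contribution), pooled
    # contribution is added when the deeper levels finish; handled by the
    # ordering below
    caches[[sprintf("dskip%d", l)]] <- dskip
  }
  # encoder backward, deepest level first
  dh_deep <- dh
  for (l in rev(seq_len(cfg$depth))) {
    if (l == cfg$depth) {
      dcur <- dh_deep
    } else {
      dpool <- pool_backward(dnext, caches[[sprintf("pool%d", l)]])
      dcur <- dpool + caches[[sprintf("dskip%d", l)]]
    }
    r <- conv_unit_backward(model, sprintf("e%dc2", l), dcur, caches, grads)
    grads <- r$grads
    r <- conv_unit_backward(model, sprintf("e%dc1", l), r$dx, caches, grads)
    grads <- r$grads
    dnext <- r$dx
  }
  grads
}

#' Forward pass of a segmentation network
#'
#' Runs the network in inference mode on a batch and returns per-voxel
#' probabilities in \[0, 1\] with the same spatial shape as the input.
#'
#' @param model a `unet_model` from [unet_init()] or [train_model()].
#' @param input array of dims (spatial..., batch, channel), or
#'   (spatial..., channel) for a single item.
#' @return Probability array of dims (spatial..., batch).
#' @export
unet_forward <- function(model, input) {
  nd <- model$config$dimensionality
  if (length(dim(input)) == nd + 1L)
    dim(input) <- c(dim(input)[seq_len(nd)], 1L, dim(input)[nd + 1L])
  out <- unet_forward_full(model, input, training = FALSE)$probs
  array(out, dim = dim(out)[seq_len(nd + 1L)])
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(y * p) / (sum(y^2) + sum(p^2) + eps)`, computed over all
#' elements of each batch item and averaged over the batch. With binary
#' predictions and `eps = 0` the loss is 0 exactly on perfect overlap and
#' 1 on disjoint masks. The stabilizer `eps` is added to the denominator
#' only, so empty-mask items do not divide by zero; set `eps = 0` for the
#' analytic cases.
#'
#' @param pred_probs numeric array of probabilities in \[0, 1\].
#' @param labels binary array of the same shape.
#' @param eps nonnegative denominator stabilizer.
#' @param batch_dim optional dimension indexing batch items; `NULL`
#'   treats the whole array as one item.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred_probs, labels, eps = 1e-6, batch_dim = NULL) {
  if (!identical(dim(pred_probs) %||% length(pred_probs),
                 dim(labels) %||% length(labels)))
    stop("prediction and label shapes differ", call. = FALSE)
  if (any(pred_probs < 0 | pred_probs > 1)) stop("predictions must lie in [0, 1]", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  if (is.null(batch_dim)) {
    num <- 2 * sum(labels * pred_probs)
    den <- sum(labels^2) + sum(pred_probs^2) + eps
    return(if (den == 0) 0 else 1 - num / den)
  }
  B <- dim(pred_probs)[batch_dim]
  per <- vapply(seq_len(B), function(b) {
    ix <- lapply(dim(pred_probs), seq_len); ix[[batch_dim]] <- b
    p <- do.call(`[`, c(list(pred_probs), ix))
    y <- do.call(`[`, c(list(labels), ix))
    num <- 2 * sum(y * p); den <- sum(y^2) + sum(p^2) + eps
    if (den == 0) 0 else 1 - num / den
  }, numeric(1))
  mean(per)
}

# Loss and gradient wrt probabilities for training; probs/labels laid out
# (spatial..., B) with batch last.
dice_loss_grad <- function(probs, labels, eps = 1e-6) {
  d <- dim(probs); B <- d[length(d)]
  pm <- matrix(probs, ncol = B); ym <- matrix(labels, ncol = B)
  num <- 2 * colSums(ym * pm)
  den <- colSums(ym^2) + colSums(pm^2) + eps
  loss <- mean(1 - num / den)
  # d/dp_b of (1 - num_b/den_b): -(2 y den - num * 2 p) / den^2, / B
  dp <- -(sweep(2 * ym, 2L, den, `*`) - sweep(2 * pm, 2L, num, `*`))
  dp <- sweep(dp, 2L, den^2, `/`) / B
  list(loss = loss, dprobs = array(dp, dim = d))
}
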