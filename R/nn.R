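# Vectorized CPU building blocks for small encoder-decoder networks.
# Tensor layout: (spatial dims ..., batch, channel), column-major, so the
# channel is the slowest-varying dimension. Convolutions are evaluated as
# one im2col gather plus a BLAS matrix product; gather index matrices are
# cached per shape. Sizes here are tiny U-Nets at <=256^2 / <=64^3, where
# this is fast enough on one CPU core.

.conv_cache <- new.env(parent = emptyenv())

# im2col spatial index for 'same' stride-1 convolution on the padded grid:
# rows enumerate output positions in array-linear order, columns kernel
# offsets; entries are linear indices into the padded spatial block.
conv_sp_idx <- function(spatial, kernel) {
  nd <- length(spatial)
  padded <- spatial + kernel - 1L
  pos <- lapply(spatial, seq_len)
  grid <- as.matrix(expand.grid(pos, KEEP.OUT.ATTRS = FALSE))  # out positions, dim1 fastest
  offs <- as.matrix(expand.grid(lapply(kernel, function(k) 0:(k - 1L)),
                                KEEP.OUT.ATTRS = FALSE))
  mult <- cumprod(c(1, padded[-nd]))
  P <- nrow(grid); K <- nrow(offs)
  idx <- matrix(0L, P, K)
  for (k in seq_len(K)) {
    lin <- 1L
    for (d in seq_len(nd)) lin <- lin + (grid[, d] + offs[k, d] - 1L) * mult[d]
    idx[, k] <- as.integer(lin)
  }
  idx
}

# gather index for im2col, cached as a flat integer vector in the
# column-major order of the (P*B) x (K*C) cols matrix
conv_idx_full <- function(spatial, kernel, B, C) {
  key <- paste(c(spatial, kernel, B, C), collapse = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  sp <- conv_sp_idx(spatial, kernel)
  S <- prod(spatial + kernel - 1L)
  P <- nrow(sp); K <- ncol(sp)
  idx <- sp[rep(seq_len(P), times = B), rep(seq_len(K), times = C), drop = FALSE]
  idx <- idx + rep((seq_len(B) - 1L) * S, each = P)
  idx <- idx + matrix(rep((seq_len(C) - 1L) * S * B, each = K), nrow = P * B,
                      ncol = K * C, byrow = TRUE)
  out <- list(vec = as.integer(idx), nrow = P * B, ncol = K * C)
  .conv_cache[[key]] <- out
  out
}

pad_spatial <- function(x, pad) {
  if (all(pad == 0L)) return(x)
  d <- dim(x); nd <- length(d) - 2L
  dp <- c(d[seq_len(nd)] + 2L * pad, d[nd + 1L], d[nd + 2L])
  xp <- array(0, dim = dp)
  ix <- c(lapply(seq_len(nd), function(i) pad[i] + seq_len(d[i])),
          list(seq_len(d[nd + 1L]), seq_len(d[nd + 2L])))
  do.call(`[<-`, c(list(xp), ix, list(value = x)))
}

unpad_spatial <- function(xp, pad, spatial) {
  if (all(pad == 0L)) return(xp)
  d <- dim(xp); nd <- length(spatial)
  ix <- c(lapply(seq_len(nd), function(i) pad[i] + seq_len(spatial[i])),
          list(seq_len(d[nd + 1L]), seq_len(d[nd + 2L])))
  do.call(`[`, c(list(xp), ix, list(drop = FALSE)))
}

# Convolution, stride 1, 'same' padding for odd kernels. W: (K*C_in) x
# C_out matrix whose rows follow the im2col column order (kernel offsets
# fastest, then input channel); b: length C_out.
conv_forward <- function(x, W, b, kernel) {
  d <- dim(x); nd <- length(d) - 2L
  spatial <- d[seq_len(nd)]; B <- d[nd + 1L]; C <- d[nd + 2L]
  pad <- (kernel - 1L) %/% 2L
  xp <- pad_spatial(x, pad)
  idx <- conv_idx_full(spatial, kernel, B, C)
  cols <- xp[idx$vec]
  dim(cols) <- c(idx$nrow, idx$ncol)
  out <- cols %*% W
  out <- sweep(out, 2L, b, `+`)
  list(out = array(out, dim = c(spatial, B, ncol(W))),
       cache = list(cols = cols, idx = idx, spatial = spatial, pad = pad,
                    B = B, C = C, kernel = kernel,
                    padded = spatial + 2L * pad))
}

conv_backward <- function(dout, W, cache) {
  P <- prod(cache$spatial) * cache$B
  dmat <- matrix(dout, nrow = P)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, W)
  dxp <- numeric(prod(cache$padded) * cache$B * cache$C)
  idx <- cache$idx
  n <- idx$nrow
  for (k in seq_len(idx$ncol)) {
    ik <- idx$vec[(k - 1L) * n + seq_len(n)]
    dxp[ik] <- dxp[ik] + dcols[, k]
  }
  dxp <- array(dxp, dim = c(cache$padded, cache$B, cache$C))
  list(dx = unpad_spatial(dxp, cache$pad, cache$spatial), dW = dW, db = db)
}

relu_forward <- function(x) {
  m <- x > 0
  list(out = x * m, cache = m)
}
relu_backward <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalization per channel over all spatial positions and batch
# items. Population variance; running statistics for inference.
bn_forward <- function(x, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[length(d)]
  xm <- matrix(x, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean; v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu, `-`), 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = array(y, dim = d), running = running,
       cache = list(xhat = xhat, inv = inv, dim = d))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dim; C <- d[length(d)]
  dy <- matrix(dout, ncol = C)
  N <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  # dx = inv/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / N, `-`)
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / N, `*`)
  dx <- sweep(t1 - t2, 2L, cache$inv, `*`)
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# 2x (2x2x2) max pooling over every spatial dimension.
pool_offsets <- function(nd) as.matrix(expand.grid(rep(list(0:1), nd), KEEP.OUT.ATTRS = FALSE))

pool_slice_ix <- function(spatial, off) {
  lapply(seq_along(spatial), function(d) seq(1L + off[d], spatial[d], by = 2L))
}

pool_forward <- function(x) {
  d <- dim(x); nd <- length(d) - 2L
  spatial <- d[seq_len(nd)]
  if (any(spatial %% 2L != 0L))
    stop("spatial dims must be even for 2x pooling: ", paste(spatial, collapse = "x"),
         call. = FALSE)
  offs <- pool_offsets(nd)
  out <- NULL; arg <- NULL
  for (o in seq_len(nrow(offs))) {
    ix <- c(pool_slice_ix(spatial, offs[o, ]), list(seq_len(d[nd + 1L]), seq_len(d[nd + 2L])))
    cand <- do.call(`[`, c(list(x), ix, list(drop = FALSE)))
    if (is.null(out)) {
      out <- cand; arg <- array(1L, dim = dim(cand))
    } else {
      better <- cand > out
      out[better] <- cand[better]
      arg[better] <- o
    }
  }
  list(out = out, cache = list(arg = arg, spatial = spatial, dim_in = d))
}

pool_backward <- function(dout, cache) {
  d <- cache$dim_in; nd <- length(cache$spatial)
  offs <- pool_offsets(nd)
  dx <- array(0, dim = d)
  for (o in seq_len(nrow(offs))) {
    ix <- c(pool_slice_ix(cache$spatial, offs[o, ]),
            list(seq_len(d[nd + 1L]), seq_len(d[nd + 2L])))
    contrib <- dout * (cache$arg == o)
    cur <- do.call(`[`, c(list(dx), ix, list(drop = FALSE)))
    dx <- do.call(`[<-`, c(list(dx), ix, list(value = cur + contrib)))
  }
  dx
}

# Transposed convolution, kernel 2, stride 2 (non-overlapping 2x
# upsampling). W: C_in x (2^nd * C_out), columns ordered offset-fastest
# within each output channel; b: length C_out.
upconv_forward <- function(x, W, b) {
  d <- dim(x); nd <- length(d) - 2L
  spatial <- d[seq_len(nd)]; B <- d[nd + 1L]; Cin <- d[nd + 2L]
  noff <- 2L^nd
  Cout <- ncol(W) / noff
  M <- matrix(x, ncol = Cin)
  out_cols <- M %*% W
  out <- array(0, dim = c(2L * spatial, B, Cout))
  offs <- pool_offsets(nd)
  for (o in seq_len(noff)) {
    ix <- c(pool_slice_ix(2L * spatial, offs[o, ]), list(seq_len(B), seq_len(Cout)))
    block <- array(out_cols[, seq(o, by = noff, length.out = Cout)],
                   dim = c(spatial, B, Cout))
    out <- do.call(`[<-`, c(list(out), ix, list(value = block)))
  }
  out <- sweep(out, nd + 2L, b, `+`)
  list(out = out, cache = list(M = M, spatial = spatial, B = B,
                               Cin = Cin, Cout = Cout, nd = nd))
}

upconv_backward <- function(dout, W, cache) {
  nd <- cache$nd; noff <- 2L^nd
  offs <- pool_offsets(nd)
  dcols <- matrix(0, nrow = nrow(cache$M), ncol = noff * cache$Cout)
  for (o in seq_len(noff)) {
    ix <- c(pool_slice_ix(2L * cache$spatial, offs[o, ]),
            list(seq_len(cache$B), seq_len(cache$Cout)))
    block <- do.call(`[`, c(list(dout), ix, list(drop = FALSE)))
    dcols[, seq(o, by = noff, length.out = cache$Cout)] <- matrix(block, ncol = cache$Cout)
  }
  db <- colSums(matrix(dout, ncol = cache$Cout))
  dW <- crossprod(cache$M, dcols)
  dM <- tcrossprod(dcols, W)
  list(dx = array(dM, dim = c(cache$spatial, cache$B, cache$Cin)), dW = dW, db = db)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b); n <- length(da)
  stopifnot(identical(da[-n], db[-n]))
  array(c(a, b), dim = c(da[-n], da[n] + db[n]))
}

split_channels <- function(d, n_first) {
  nd <- length(dim(d))
  Ctot <- dim(d)[nd]
  ixa <- c(lapply(dim(d)[-nd], seq_len), list(seq_len(n_first)))
  ixb <- c(lapply(dim(d)[-nd], seq_len), list((n_first + 1L):Ctot))
  list(first = do.call(`[`, c(list(d), ixa, list(drop = FALSE))),
       second = do.call(`[`, c(list(d), ixb, list(drop = FALSE))))
}

# Adam first-order optimizer over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
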