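test_that("config invariants are enforced", {
  expect_error(unet_config(dimensionality = 4), "2 or 3")
  expect_error(unet_config(depth = 1), "depth")
  expect_error(unet_config(base_channels = 2), "base_channels")
})

test_that("outputs are probabilities with the input's spatial shape", {
  for (nd in c(2L, 3L)) {
    cfg <- unet_config(dimensionality = nd, depth = 3, base_channels = 4,
                       input_channels = if (nd == 2) 3L else 1L, seed = 2)
    model <- unet_init(cfg)
    spd <- if (nd == 2) c(64L, 64L) else c(8L, 16L, 16L)
    x <- array(rnorm(prod(spd) * cfg$input_channels), c(spd, cfg$input_channels))
    p <- unet_forward(model, x)
    expect_equal(dim(p), c(spd, 1L))
    expect_true(all(p >= 0 & p <= 1))
  }
  # 2D at a second size: shape preservation is not tied to 64
  cfg <- unet_config(dimensionality = 2, depth = 2, base_channels = 4, seed = 2)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  expect_equal(dim(unet_forward(unet_init(cfg), x)), c(32L, 32L, 1L))
})

test_that("indivisible input sizes raise a shape error", {
  cfg <- unet_config(dimensionality = 2, depth = 3, base_channels = 4, seed = 1)
  model <- unet_init(cfg)
  x <- array(rnorm(30 * 30 * 3), c(30, 30, 3))
  expect_error(unet_forward(model, x), "divisible")
})

test_that("initialization and inference are deterministic under fixed seeds", {
  cfg <- unet_config(dimensionality = 2, depth = 2, base_channels = 4, seed = 31)
  m1 <- unet_init(cfg); m2 <- unet_init(cfg)
  expect_identical(m1$params, m2$params)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  expect_identical(unet_forward(m1, x), unet_forward(m1, x))
})

test_that("backpropagated gradients match finite differences", {
  sv <- asNamespace("strokevol")
  set.seed(42)
  for (nd in c(2L, 3L)) {
    cfg <- unet_config(dimensionality = nd, depth = 2, base_channels = 4,
                       input_channels = if (nd == 2) 3L else 1L, seed = 7)
    model <- unet_init(cfg)
    spd <- if (nd == 2) c(8L, 8L) else c(4L, 8L, 8L)
    B <- 2L
    x <- array(rnorm(prod(spd) * B * cfg$input_channels),
               c(spd, B, cfg$input_channels))
    y <- array(rbinom(prod(spd) * B, 1, 0.3), c(spd, B))
    lossfun <- function(m) {
      fw <- sv$unet_forward_full(m, x, training = TRUE)
      sv$dice_loss_grad(array(fw$probs, c(spd, B)), y, eps = 1e-6)$loss
    }
    fw <- sv$unet_forward_full(model, x, training = TRUE)
    lg <- sv$dice_loss_grad(array(fw$probs, c(spd, B)), y, eps = 1e-6)
    grads <- sv$unet_backward_full(fw$model, fw$caches,
                                   array(lg$dprobs, c(spd, B, 1L)))
    h <- 1e-6
    for (nm in sample(names(model$params), 6)) {
      i <- sample(length(model$params[[nm]]), 1)
      m2 <- model
      m2$params[[nm]][i] <- model$params[[nm]][i] + h
      l1 <- lossfun(m2)
      m2$params[[nm]][i] <- model$params[[nm]][i] - h
      l0 <- lossfun(m2)
      num <- (l1 - l0) / (2 * h)
      expect_equal(grads[[nm]][i], num, tolerance = 5e-3,
                   label = sprintf("%dD grad %s[%d]", nd, nm, i))
    }
  }
})

test_that("pretrained weight loading replaces parameters by name", {
  cfg <- unet_config(dimensionality = 2, depth = 2, base_channels = 4, seed = 1)
  model <- unet_init(cfg)
  w <- model$params[["e1c1.W"]] * 0 + 0.5
  m2 <- load_pretrained_weights(model, list(e1c1.W = w))
  expect_true(all(m2$params[["e1c1.W"]] == 0.5))
  expect_error(load_pretrained_weights(model, list(nope = w)), "unknown")
  expect_error(load_pretrained_weights(model, list(e1c1.W = matrix(0, 2, 2))),
               "shape")
})
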