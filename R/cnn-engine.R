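# Internal training engine for the 2D CNN classifier.
#
# Activations are R arrays of dim (H, W, C, B); convolutions run through the
# compiled im2col/GEMM kernels. Batch normalisation is per output channel
# over (H, W, B) with running statistics for inference; max-pooling spans the
# full remaining channel axis with a width-2, stride-2 temporal window;
# dropout is the inverted variant on the flattened feature vector.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

init_cnn_params <- function(config, input_shape, n_classes) {
  kh <- config$kernel[1]; kw <- config$kernel[2]
  shapes <- cnn_shapes(input_shape, config)
  conv <- vector("list", config$n_conv_modules)
  cin <- 1L
  for (k in seq_len(config$n_conv_modules)) {
    f <- config$filters[k]
    fan_in <- kh * kw * cin
    conv[[k]] <- list(
      W = array(rnorm(kh * kw * cin * f, 0, sqrt(2 / fan_in)),
                dim = c(kh, kw, cin, f)),
      b = numeric(f),
      gamma = rep(1, f), beta = numeric(f),
      run_mean = numeric(f), run_var = rep(1, f))
    cin <- f
  }
  pooled_w <- shapes$width[config$n_conv_modules] %/% 2L
  n_feat <- cin * pooled_w
  fc <- list(W = matrix(rnorm(n_classes * n_feat, 0, sqrt(2 / n_feat)),
                        n_classes, n_feat),
             b = numeric(n_classes))
  list(conv = conv, fc = fc, n_feat = n_feat, pooled_w = pooled_w)
}

# per-module feature-map sizes for valid kernels; errors name the module
cnn_shapes <- function(input_shape, config) {
  kh <- config$kernel[1]; kw <- config$kernel[2]
  h <- input_shape[1]; w <- input_shape[2]
  hs <- ws <- integer(config$n_conv_modules)
  for (k in seq_len(config$n_conv_modules)) {
    h <- h - (kh - 1L); w <- w - (kw - 1L)
    if (h < 1 || w < 1) {
      abort(sprintf(
        "input %d x %d is too small for conv module %d (feature map %d x %d)",
        input_shape[1], input_shape[2], k, h, w), class = "har_shape_error")
    }
    hs[k] <- h; ws[k] <- w
  }
  if (ws[config$n_conv_modules] < 2) {
    abort("final feature map too narrow for stride-2 temporal pooling",
          class = "har_shape_error")
  }
  tibble(module = seq_len(config$n_conv_modules), height = hs, width = ws)
}

cnn_n_params <- function(config, input_shape, n_classes) {
  kh <- config$kernel[1]; kw <- config$kernel[2]
  cin <- 1L; total <- 0L
  for (k in seq_len(config$n_conv_modules)) {
    f <- config$filters[k]
    total <- total + kh * kw * cin * f + f + 2L * f  # W, b, gamma, beta
    cin <- f
  }
  shapes <- cnn_shapes(input_shape, config)
  n_feat <- cin * (shapes$width[config$n_conv_modules] %/% 2L)
  total + n_feat * n_classes + n_classes
}

bn_forward <- function(x, p, train) {
  d <- dim(x)  # (H, W, C, B)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*B) x C
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- p$run_mean; v <- p$run_var
  }
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, sqrt(v + BN_EPS), "/")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  out <- aperm(array(y, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(y = out, xhat = xhat, mu = mu, var = v)
}

bn_backward <- function(dy, cache, p) {
  d <- dim(dy)
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  n <- nrow(dym)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  inv_sd <- 1 / sqrt(cache$var + BN_EPS)
  dxhat <- sweep(dym, 2, p$gamma, "*")
  dxm <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dym), byrow = TRUE) -
                 sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
               2, inv_sd, "*")
  dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# max pool over the full channel-axis extent and width-2/stride-2 in time
pool_forward <- function(x) {
  d <- dim(x)  # (H, W, C, B)
  wo <- d[2] %/% 2L
  xs <- x[, seq_len(2L * wo), , , drop = FALSE]
  # regions: (H*2) values per output cell
  xr <- array(aperm(xs, c(1, 2, 3, 4)), dim = c(d[1], 2L, wo, d[3], d[4]))
  rm <- matrix(xr, nrow = d[1] * 2L)
  best <- rm[1, ]; arg <- rep(1L, ncol(rm))
  if (nrow(rm) > 1) {
    for (r in 2:nrow(rm)) {
      upd <- rm[r, ] > best
      best[upd] <- rm[r, upd]
      arg[upd] <- r
    }
  }
  y <- array(best, dim = c(1L, wo, d[3], d[4]))
  list(y = y, arg = arg, in_dim = d, wo = wo)
}

pool_backward <- function(dy, cache) {
  d <- cache$in_dim
  wo <- cache$wo
  rm <- matrix(0, d[1] * 2L, wo * d[3] * d[4])
  rm[cbind(cache$arg, seq_len(ncol(rm)))] <- as.vector(dy)
  dxs <- array(rm, dim = c(d[1], 2L, wo, d[3], d[4]))
  dx <- array(0, dim = d)
  dx[, seq_len(2L * wo), , ] <- array(dxs, dim = c(d[1], 2L * wo, d[3], d[4]))
  dx
}

cnn_forward <- function(params, config, x, train = FALSE, drop_mask = NULL) {
  nmod <- config$n_conv_modules
  caches <- vector("list", nmod)
  a <- x
  for (k in seq_len(nmod)) {
    p <- params$conv[[k]]
    z <- conv2d_fwd(a, dim(a), p$W, dim(p$W), p$b)
    bn <- bn_forward(z, p, train)
    relu_mask <- bn$y > 0
    h <- bn$y * relu_mask
    caches[[k]] <- list(a_in = a, z = z, bn = bn, relu_mask = relu_mask)
    a <- h
  }
  pool <- pool_forward(a)
  B <- dim(x)[4]
  feat <- matrix(pool$y, nrow = params$n_feat, ncol = B)
  if (train && !is.null(drop_mask)) {
    feat <- feat * drop_mask / (1 - config$dropout)
  }
  logits <- params$fc$W %*% feat + params$fc$b
  # stable softmax
  shifted <- sweep(logits, 2, apply(logits, 2, max), "-")
  expv <- exp(shifted)
  probs <- sweep(expv, 2, colSums(expv), "/")
  list(probs = probs, logits = logits, feat = feat, pool = pool,
       caches = caches)
}

cnn_backward <- function(params, config, fwd, y_index, drop_mask) {
  B <- ncol(fwd$probs)
  dlogits <- fwd$probs
  dlogits[cbind(y_index, seq_len(B))] <-
    dlogits[cbind(y_index, seq_len(B))] - 1
  dlogits <- dlogits / B

  grads <- list(fc = list(W = dlogits %*% t(fwd$feat),
                          b = rowSums(dlogits)),
                conv = vector("list", config$n_conv_modules))
  dfeat <- t(params$fc$W) %*% dlogits
  if (!is.null(drop_mask)) dfeat <- dfeat * drop_mask / (1 - config$dropout)
  dpool <- array(dfeat, dim = dim(fwd$pool$y))
  da <- pool_backward(dpool, fwd$pool)

  for (k in rev(seq_len(config$n_conv_modules))) {
    cache <- fwd$caches[[k]]
    p <- params$conv[[k]]
    dh <- da * cache$relu_mask
    bnb <- bn_backward(dh, cache$bn, p)
    cb <- conv2d_bwd(cache$a_in, dim(cache$a_in), p$W, dim(p$W), bnb$dx)
    grads$conv[[k]] <- list(W = cb$dw, b = cb$db,
                            gamma = bnb$dgamma, beta = bnb$dbeta)
    da <- cb$dx
  }
  grads
}

cnn_loss <- function(probs, y_index) {
  p <- probs[cbind(y_index, seq_len(ncol(probs)))]
  -mean(log(pmax(p, 1e-12)))
}

# Adam over the flat list of trainable tensors
adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  trainable <- cnn_trainable(params)
  list(m = zeros(trainable), v = zeros(trainable), t = 0L)
}

cnn_trainable <- function(params) {
  c(lapply(params$conv, function(p) p[c("W", "b", "gamma", "beta")]),
    list(fc = params$fc))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  glist <- c(grads$conv, list(fc = grads$fc))
  nmod <- length(params$conv)
  for (k in seq_len(nmod + 1L)) {
    names_k <- if (k <= nmod) c("W", "b", "gamma", "beta") else c("W", "b")
    for (nm in names_k) {
      g <- glist[[k]][[nm]]
      state$m[[k]][[nm]] <- beta1 * state$m[[k]][[nm]] + (1 - beta1) * g
      state$v[[k]][[nm]] <- beta2 * state$v[[k]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[k]][[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[k]][[nm]] / (1 - beta2^state$t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (k <= nmod) {
        params$conv[[k]][[nm]] <- params$conv[[k]][[nm]] - upd
      } else {
        params$fc[[nm]] <- params$fc[[nm]] - upd
      }
    }
  }
  list(params = params, state = state)
}

update_running_stats <- function(params, k, bn) {
  p <- params$conv[[k]]
  p$run_mean <- (1 - BN_MOMENTUM) * p$run_mean + BN_MOMENTUM * bn$mu
  p$run_var <- (1 - BN_MOMENTUM) * p$run_var + BN_MOMENTUM * bn$var
  params$conv[[k]] <- p
  params
}
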