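# Minimal neural-network engine used by the vitals regressors, the
# contrastive PPG-caption encoders, and the PPG-to-ECG feed-forward
# network. Layers are mutable environments holding parameters, gradients
# and Adam state; shapes are (batch, features) for dense paths and
# (batch, length, channels) for convolutional paths. Everything is plain
# matrix arithmetic, deterministic under a fixed seed in a single thread.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  e$children <- list()
  class(e) <- "nn_layer"
  e
}

xavier_init <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# reshape (B,T,D) to (B*T, D) rows; D is the slowest-varying dim so a plain
# dim<- is the correct row mapping
as_rows <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    matrix(x, d[1] * d[2], d[3])
  } else {
    x
  }
}

#' Dense (fully connected) layer
#'
#' Applies `x %*% W + b` to the last dimension of a 2-D `(batch, d)` or
#' 3-D `(batch, tokens, d)` input. Weights are Xavier-initialized from the
#' R random stream at construction time.
#'
#' @param n_in,n_out input/output widths.
#' @param l1 L1 penalty coefficient added to the weight gradient.
#' @return An `nn_layer`.
#' @export
layer_dense <- function(n_in, n_out, l1 = 0) {
  e <- new_layer("dense")
  e$params$W <- xavier_init(n_in, n_out)
  e$params$b <- numeric(n_out)
  e$l1 <- l1
  e$fwd <- function(x, training = FALSE) {
    e$in_dim <- dim(x)
    x2 <- as_rows(x)
    e$cache <- x2
    y2 <- x2 %*% e$params$W
    y2 <- y2 + rep(e$params$b, each = nrow(y2))
    if (length(e$in_dim) == 3L) {
      array(y2, dim = c(e$in_dim[1], e$in_dim[2], ncol(y2)))
    } else y2
  }
  e$bwd <- function(dout) {
    d2 <- as_rows(dout)
    e$grads$W <- crossprod(e$cache, d2)
    if (e$l1 > 0) e$grads$W <- e$grads$W + e$l1 * sign(e$params$W)
    e$grads$b <- colSums(d2)
    dx2 <- tcrossprod(d2, e$params$W)
    if (length(e$in_dim) == 3L) {
      array(dx2, dim = e$in_dim)
    } else dx2
  }
  e
}

selu_lambda <- 1.0507009873554805
selu_alpha <- 1.6732632423543772

#' Elementwise activation layer
#'
#' @param name one of `"relu"`, `"selu"`, `"gelu"`, `"tanh"`, `"linear"`.
#' @return An `nn_layer`.
#' @export
layer_activation <- function(name = "relu") {
  e <- new_layer(paste0("act_", name))
  act <- switch(name,
    relu = list(
      f = function(x) x * (x > 0),
      df = function(x, y) (x > 0) * 1
    ),
    selu = list(
      f = function(x) selu_lambda * ifelse(x > 0, x, selu_alpha * (exp(x) - 1)),
      df = function(x, y) selu_lambda * ifelse(x > 0, 1, selu_alpha * exp(x))
    ),
    gelu = list(
      f = function(x) {
        inner <- sqrt(2 / pi) * (x + 0.044715 * x^3)
        0.5 * x * (1 + tanh(inner))
      },
      df = function(x, y) {
        inner <- sqrt(2 / pi) * (x + 0.044715 * x^3)
        th <- tanh(inner)
        0.5 * (1 + th) +
          0.5 * x * (1 - th^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
      }
    ),
    tanh = list(
      f = function(x) tanh(x),
      df = function(x, y) 1 - y^2
    ),
    linear = list(
      f = function(x) x,
      df = function(x, y) 1
    ),
    stop("unknown activation: ", name, call. = FALSE)
  )
  e$fwd <- function(x, training = FALSE) {
    e$cache_x <- x
    y <- act$f(x)
    if (name == "tanh") e$cache_y <- y
    y
  }
  e$bwd <- function(dout) {
    dout * act$df(e$cache_x, if (name == "tanh") e$cache_y else NULL)
  }
  e
}

#' Batch normalization layer
#'
#' Normalizes over the batch for dense inputs `(batch, d)` or over batch
#' and position for convolutional inputs `(batch, length, channels)`, with
#' learnable scale and shift and exponential running statistics used at
#' inference.
#'
#' @param dim number of features/channels normalized.
#' @param momentum running-statistics momentum.
#' @param eps numerical floor for the variance.
#' @return An `nn_layer`.
#' @export
layer_batchnorm <- function(dim, momentum = 0.9, eps = 1e-5) {
  e <- new_layer("batchnorm")
  e$params$gamma <- rep(1, dim)
  e$params$beta <- rep(0, dim)
  e$run_mean <- rep(0, dim)
  e$run_var <- rep(1, dim)
  e$fwd <- function(x, training = FALSE) {
    e$in_dim <- dim(x)
    x2 <- as_rows(x)
    if (training) {
      mu <- colMeans(x2)
      v <- colMeans(sweep(x2, 2, mu)^2)
      e$run_mean <- momentum * e$run_mean + (1 - momentum) * mu
      e$run_var <- momentum * e$run_var + (1 - momentum) * v
    } else {
      mu <- e$run_mean
      v <- e$run_var
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(x2, 2, mu), 2, inv, "*")
    e$cache <- list(xhat = xhat, inv = inv)
    y2 <- sweep(sweep(xhat, 2, e$params$gamma, "*"), 2, e$params$beta, "+")
    if (length(e$in_dim) == 3L) array(y2, e$in_dim) else y2
  }
  e$bwd <- function(dout) {
    d2 <- as_rows(dout)
    xhat <- e$cache$xhat
    inv <- e$cache$inv
    m <- nrow(d2)
    e$grads$gamma <- colSums(d2 * xhat)
    e$grads$beta <- colSums(d2)
    dxhat <- sweep(d2, 2, e$params$gamma, "*")
    dx2 <- sweep(
      dxhat - matrix(colMeans(dxhat), m, ncol(d2), byrow = TRUE) -
        xhat * matrix(colMeans(dxhat * xhat), m, ncol(d2), byrow = TRUE),
      2, inv, "*"
    )
    if (length(e$in_dim) == 3L) array(dx2, e$in_dim) else dx2
  }
  e
}

#' Layer normalization over the last dimension
#'
#' @param dim normalized width.
#' @param eps numerical floor.
#' @return An `nn_layer`.
#' @export
layer_layernorm <- function(dim, eps = 1e-5) {
  e <- new_layer("layernorm")
  e$params$gamma <- rep(1, dim)
  e$params$beta <- rep(0, dim)
  e$fwd <- function(x, training = FALSE) {
    e$in_dim <- dim(x)
    x2 <- as_rows(x)
    mu <- rowMeans(x2)
    xc <- x2 - mu
    v <- rowMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    e$cache <- list(xhat = xhat, inv = inv)
    y2 <- sweep(sweep(xhat, 2, e$params$gamma, "*"), 2, e$params$beta, "+")
    if (length(e$in_dim) == 3L) array(y2, e$in_dim) else y2
  }
  e$bwd <- function(dout) {
    d2 <- as_rows(dout)
    xhat <- e$cache$xhat
    inv <- e$cache$inv
    D <- ncol(d2)
    e$grads$gamma <- colSums(d2 * xhat)
    e$grads$beta <- colSums(d2)
    dxhat <- sweep(d2, 2, e$params$gamma, "*")
    dx2 <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    if (length(e$in_dim) == 3L) array(dx2, e$in_dim) else dx2
  }
  e
}

#' Inverted dropout layer
#'
#' @param rate drop probability in `[0, 1)`.
#' @return An `nn_layer`.
#' @export
layer_dropout <- function(rate = 0.2) {
  stopifnot(rate >= 0, rate < 1)
  e <- new_layer("dropout")
  e$fwd <- function(x, training = FALSE) {
    if (!training || rate == 0) {
      e$mask <- NULL
      return(x)
    }
    m <- array(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate), dim = dim(x))
    e$mask <- m
    x * m
  }
  e$bwd <- function(dout) {
    if (is.null(e$mask)) dout else dout * e$mask
  }
  e
}

#' 1-D convolution layer (valid padding)
#'
#' Input `(batch, length, in_ch)`, output
#' `(batch, floor((length - kernel) / stride) + 1, filters)`. Implemented
#' by im2col and a single matrix product.
#'
#' @param in_ch,filters input/output channel counts.
#' @param kernel kernel size in samples.
#' @param stride stride in samples.
#' @param l1 L1 penalty coefficient on the kernel weights.
#' @return An `nn_layer`.
#' @export
layer_conv1d <- function(in_ch, filters, kernel, stride = 1, l1 = 0) {
  e <- new_layer("conv1d")
  e$params$W <- xavier_init(kernel * in_ch, filters)
  e$params$b <- numeric(filters)
  e$kernel <- kernel
  e$stride <- stride
  e$in_ch <- in_ch
  e$l1 <- l1
  e$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    B <- d[1]; L <- d[2]; C <- d[3]
    stopifnot(C == in_ch)
    L_out <- (L - kernel) %/% stride + 1
    if (L_out < 1) stop("conv1d: input shorter than kernel", call. = FALSE)
    starts <- seq(1L, by = stride, length.out = L_out)
    X2 <- matrix(0, B * L_out, kernel * in_ch)
    for (c in seq_len(C)) {
      xc <- x[, , c, drop = FALSE]
      dim(xc) <- c(B, L)
      for (k in seq_len(kernel)) {
        X2[, (c - 1) * kernel + k] <- xc[, starts + k - 1L]
      }
    }
    e$cache <- list(X2 = X2, dims = d, L_out = L_out, starts = starts)
    Y2 <- X2 %*% e$params$W
    Y2 <- Y2 + rep(e$params$b, each = nrow(Y2))
    array(Y2, dim = c(B, L_out, filters))
  }
  e$bwd <- function(dout) {
    cc <- e$cache
    B <- cc$dims[1]; L <- cc$dims[2]; C <- cc$dims[3]
    d2 <- matrix(dout, B * cc$L_out, filters)
    e$grads$W <- crossprod(cc$X2, d2)
    if (e$l1 > 0) e$grads$W <- e$grads$W + e$l1 * sign(e$params$W)
    e$grads$b <- colSums(d2)
    dX2 <- tcrossprod(d2, e$params$W)
    dx <- array(0, dim = cc$dims)
    for (c in seq_len(C)) {
      dxc <- matrix(0, B, L)
      for (k in seq_len(e$kernel)) {
        cols <- cc$starts + k - 1L
        dxc[, cols] <- dxc[, cols] +
          matrix(dX2[, (c - 1) * e$kernel + k], B, cc$L_out)
      }
      dx[, , c] <- dxc
    }
    dx
  }
  e
}

#' 1-D max pooling layer
#'
#' Non-overlapping pooling; trailing samples that do not fill a window are
#' dropped.
#'
#' @param size pooling window in samples.
#' @return An `nn_layer`.
#' @export
layer_maxpool1d <- function(size = 2) {
  e <- new_layer("maxpool1d")
  e$size <- size
  e$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    B <- d[1]; L <- d[2]; C <- d[3]
    L_out <- L %/% size
    x2 <- x[, seq_len(L_out * size), , drop = FALSE]
    dim(x2) <- c(B, size, L_out, C)
    y <- x2[, 1, , , drop = FALSE]
    dim(y) <- c(B, L_out, C)
    amax <- array(1L, dim = c(B, L_out, C))
    if (size > 1) {
      for (s in 2:size) {
        xs <- x2[, s, , , drop = FALSE]
        dim(xs) <- c(B, L_out, C)
        upd <- xs > y
        y[upd] <- xs[upd]
        amax[upd] <- s
      }
    }
    e$cache <- list(dims = d, L_out = L_out, amax = amax)
    y
  }
  e$bwd <- function(dout) {
    cc <- e$cache
    B <- cc$dims[1]; L <- cc$dims[2]; C <- cc$dims[3]
    dx2 <- array(0, dim = c(B, e$size, cc$L_out, C))
    for (s in seq_len(e$size)) {
      mask <- cc$amax == s
      slab <- array(0, dim = c(B, cc$L_out, C))
      slab[mask] <- dout[mask]
      dx2[, s, , ] <- slab
    }
    dim(dx2) <- c(B, e$size * cc$L_out, C)
    if (L > e$size * cc$L_out) {
      pad <- array(0, dim = c(B, L - e$size * cc$L_out, C))
      dx <- array(0, dim = c(B, L, C))
      dx[, seq_len(e$size * cc$L_out), ] <- dx2
      dx
    } else dx2
  }
  e
}

#' Flatten layer
#'
#' `(batch, length, channels)` to `(batch, length * channels)`.
#' @return An `nn_layer`.
#' @export
layer_flatten <- function() {
  e <- new_layer("flatten")
  e$fwd <- function(x, training = FALSE) {
    e$in_dim <- dim(x)
    matrix(x, e$in_dim[1], prod(e$in_dim[-1]))
  }
  e$bwd <- function(dout) array(dout, dim = e$in_dim)
  e
}

#' Mean pooling over the token dimension
#'
#' `(batch, tokens, d)` to `(batch, d)`.
#' @return An `nn_layer`.
#' @export
layer_meanpool_tokens <- function() {
  e <- new_layer("meanpool_tokens")
  e$fwd <- function(x, training = FALSE) {
    e$in_dim <- dim(x)
    d <- e$in_dim
    y <- matrix(0, d[1], d[3])
    for (tt in seq_len(d[2])) y <- y + x[, tt, ]
    y / d[2]
  }
  e$bwd <- function(dout) {
    d <- e$in_dim
    dx <- array(0, dim = d)
    for (tt in seq_len(d[2])) dx[, tt, ] <- dout / d[2]
    dx
  }
  e
}

#' Residual wrapper
#'
#' Computes `x + f(x)` where `f` is the sequential composition of
#' `sublayers` (shapes must match).
#'
#' @param sublayers list of `nn_layer`s.
#' @return An `nn_layer`.
#' @export
layer_residual <- function(sublayers) {
  e <- new_layer("residual")
  e$children <- sublayers
  e$fwd <- function(x, training = FALSE) {
    h <- x
    for (l in e$children) h <- l$fwd(h, training)
    x + h
  }
  e$bwd <- function(dout) {
    dh <- dout
    for (l in rev(e$children)) dh <- l$bwd(dh)
    dout + dh
  }
  e
}

#' Single-head self-attention layer
#'
#' Scaled dot-product self-attention over token inputs
#' `(batch, tokens, d)` with learned query/key/value/output projections.
#'
#' @param d model width.
#' @return An `nn_layer`.
#' @export
layer_attention <- function(d) {
  e <- new_layer("attention")
  e$params$Wq <- xavier_init(d, d)
  e$params$Wk <- xavier_init(d, d)
  e$params$Wv <- xavier_init(d, d)
  e$params$Wo <- xavier_init(d, d)
  e$d <- d
  e$fwd <- function(x, training = FALSE) {
    dm <- dim(x)
    B <- dm[1]; Tn <- dm[2]
    x2 <- matrix(x, B * Tn, d)
    Q <- x2 %*% e$params$Wq
    K <- x2 %*% e$params$Wk
    V <- x2 %*% e$params$Wv
    A <- vector("list", B)
    O2 <- matrix(0, B * Tn, d)
    rowsb <- function(b) b + (seq_len(Tn) - 1) * B
    for (b in seq_len(B)) {
      rb <- rowsb(b)
      S <- tcrossprod(Q[rb, , drop = FALSE], K[rb, , drop = FALSE]) / sqrt(d)
      S <- S - apply(S, 1, max)
      Ab <- exp(S)
      Ab <- Ab / rowSums(Ab)
      A[[b]] <- Ab
      O2[rb, ] <- Ab %*% V[rb, , drop = FALSE]
    }
    e$cache <- list(x2 = x2, Q = Q, K = K, V = V, A = A, dm = dm)
    y2 <- O2 %*% e$params$Wo
    e$cache$O2 <- O2
    array(y2, dim = dm)
  }
  e$bwd <- function(dout) {
    cc <- e$cache
    dm <- cc$dm
    B <- dm[1]; Tn <- dm[2]
    d2 <- matrix(dout, B * Tn, d)
    e$grads$Wo <- crossprod(cc$O2, d2)
    dO2 <- tcrossprod(d2, e$params$Wo)
    dQ <- matrix(0, B * Tn, d)
    dK <- matrix(0, B * Tn, d)
    dV <- matrix(0, B * Tn, d)
    rowsb <- function(b) b + (seq_len(Tn) - 1) * B
    for (b in seq_len(B)) {
      rb <- rowsb(b)
      Ab <- cc$A[[b]]
      dOb <- dO2[rb, , drop = FALSE]
      Vb <- cc$V[rb, , drop = FALSE]
      dV[rb, ] <- crossprod(Ab, dOb)
      dA <- tcrossprod(dOb, Vb)
      dS <- Ab * (dA - rowSums(dA * Ab))
      dQ[rb, ] <- dS %*% cc$K[rb, , drop = FALSE] / sqrt(d)
      dK[rb, ] <- crossprod(dS, cc$Q[rb, , drop = FALSE]) / sqrt(d)
    }
    e$grads$Wq <- crossprod(cc$x2, dQ)
    e$grads$Wk <- crossprod(cc$x2, dK)
    e$grads$Wv <- crossprod(cc$x2, dV)
    dx2 <- tcrossprod(dQ, e$params$Wq) + tcrossprod(dK, e$params$Wk) +
      tcrossprod(dV, e$params$Wv)
    array(dx2, dim = dm)
  }
  e
}

#' Group a sequence into a fixed number of token patches
#'
#' Splits the length axis of `(batch, length, channels)` input into
#' `n_tokens` contiguous patches (truncating any remainder) and flattens
#' each patch, yielding `(batch, n_tokens, patch_len * channels)`.
#'
#' @param n_tokens number of patches.
#' @return An `nn_layer`.
#' @export
layer_patchify <- function(n_tokens) {
  e <- new_layer("patchify")
  e$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    B <- d[1]; L <- d[2]; C <- d[3]
    P <- L %/% n_tokens
    e$cache <- list(dims = d, P = P)
    y <- array(0, dim = c(B, n_tokens, P * C))
    for (tt in seq_len(n_tokens)) {
      patch <- x[, ((tt - 1) * P + 1):(tt * P), , drop = FALSE]
      y[, tt, ] <- matrix(patch, B, P * C)
    }
    y
  }
  e$bwd <- function(dout) {
    cc <- e$cache
    d <- cc$dims
    dx <- array(0, dim = d)
    for (tt in seq_len(n_tokens)) {
      slab <- array(dout[, tt, ], dim = c(d[1], cc$P, d[3]))
      dx[, ((tt - 1) * cc$P + 1):(tt * cc$P), ] <- slab
    }
    dx
  }
  e
}

# --- model plumbing ---------------------------------------------------------

#' Sequential model container
#'
#' @param layers list of `nn_layer`s applied in order.
#' @return An object of class `nn_model`.
#' @export
nn_sequential <- function(layers) {
  structure(list(layers = layers), class = "nn_model")
}

flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    out <- c(out, list(l))
    if (length(l$children)) out <- c(out, flatten_layers(l$children))
  }
  out
}

#' Forward pass through a sequential model
#'
#' @param model an `nn_model`.
#' @param x input array.
#' @param training `TRUE` during training (enables dropout and batch
#'   statistics).
#' @return Output of the final layer.
#' @export
nn_forward <- function(model, x, training = FALSE) {
  for (l in model$layers) x <- l$fwd(x, training)
  x
}

#' Backward pass through a sequential model
#'
#' @param model an `nn_model`.
#' @param dout gradient of the loss w.r.t. the model output.
#' @return Gradient w.r.t. the input (invisibly useful for composites).
#' @export
nn_backward <- function(model, dout) {
  for (l in rev(model$layers)) dout <- l$bwd(dout)
  dout
}

#' Number of trainable parameters
#'
#' @param model an `nn_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(flatten_layers(model$layers),
             function(l) sum(vapply(l$params, length, integer(1))),
             numeric(1)))
}

nn_get_weights <- function(model) {
  lapply(flatten_layers(model$layers), function(l) {
    list(params = l$params, run_mean = l$run_mean, run_var = l$run_var)
  })
}

nn_set_weights <- function(model, w) {
  ls <- flatten_layers(model$layers)
  stopifnot(length(ls) == length(w))
  for (i in seq_along(ls)) {
    ls[[i]]$params <- w[[i]]$params
    if (!is.null(w[[i]]$run_mean)) ls[[i]]$run_mean <- w[[i]]$run_mean
    if (!is.null(w[[i]]$run_var)) ls[[i]]$run_var <- w[[i]]$run_var
  }
  invisible(model)
}

adam_update <- function(layers, lr, step, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (l in layers) {
    if (!length(l$params)) next
    if (is.null(l$adam_m)) {
      l$adam_m <- lapply(l$params, function(p) p * 0)
      l$adam_v <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g^2
      mhat <- l$adam_m[[nm]] / (1 - beta1^step)
      vhat <- l$adam_v[[nm]] / (1 - beta2^step)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
}

#' Mean absolute error and its subgradient
#'
#' The training criterion of all regressors in the package: the mean of
#' `|y - yhat|` over batch elements and output dimensions (for scalar
#' labels this is the plain batch-mean absolute error).
#'
#' @param y_pred,y_true matrices `(batch, n_out)`.
#' @return `loss_mae()` returns a scalar; `loss_mae_grad()` the gradient
#'   w.r.t. `y_pred`.
#' @export
loss_mae <- function(y_pred, y_true) mean(abs(y_pred - y_true))

#' @rdname loss_mae
#' @export
loss_mae_grad <- function(y_pred, y_true) {
  sign(y_pred - y_true) / length(y_pred)
}

#' Learning-rate schedules
#'
#' `lr_schedule_staircase()` multiplies the initial rate by
#' `factor^floor(epoch / every)` (staircase exponential decay);
#' `lr_schedule_plateau()` multiplies the current rate by `factor`
#' whenever the validation loss has not improved for `patience` epochs.
#'
#' @param factor multiplicative decay factor.
#' @param every epochs per staircase step.
#' @param patience epochs without improvement before decaying.
#' @param min_lr lower bound on the learning rate.
#' @return A schedule description consumed by [nn_train()].
#' @export
lr_schedule_staircase <- function(factor = exp(-0.1), every = 50) {
  list(type = "staircase", factor = factor, every = every)
}

#' @rdname lr_schedule_staircase
#' @export
lr_schedule_plateau <- function(factor = 0.1, patience = 10, min_lr = 1e-5) {
  list(type = "plateau", factor = factor, patience = patience, min_lr = min_lr)
}

#' Train a model with Adam under the MAE criterion
#'
#' Mini-batch training with shuffling, optional validation split, early
#' stopping on the validation MAE with best-weight restoration, and a
#' configurable learning-rate schedule. Runs are reproducible for a fixed
#' `seed` in single-threaded execution.
#'
#' @param model an `nn_model` (modified in place; also returned).
#' @param x input array `(n, ...)`.
#' @param y label matrix `(n, n_out)` (vectors are promoted).
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param val_frac fraction of rows held out for validation (ignored when
#'   `x_val` is given).
#' @param x_val,y_val explicit validation data.
#' @param patience early-stopping patience (epochs) on validation MAE.
#' @param schedule `NULL`, [lr_schedule_staircase()] or
#'   [lr_schedule_plateau()].
#' @param seed RNG seed controlling shuffling, dropout and the validation
#'   split.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return List with `model` and `history` (data.frame: epoch, train_mae,
#'   val_mae, lr).
#' @export
nn_train <- function(model, x, y, epochs = 100, batch_size = 32,
                     lr = 1e-3, val_frac = 0.15, x_val = NULL, y_val = NULL,
                     patience = 20, schedule = NULL, seed = 1L,
                     verbose = 0) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  n <- dim(x)[1]
  if (n == 0) stop("empty dataset", call. = FALSE)
  set.seed(seed)
  if (is.null(x_val) && val_frac > 0) {
    vi <- sample.int(n, max(1L, round(val_frac * n)))
    x_val <- index_rows(x, vi)
    y_val <- y[vi, , drop = FALSE]
    x <- index_rows(x, setdiff(seq_len(n), vi))
    y <- y[setdiff(seq_len(n), vi), , drop = FALSE]
    n <- dim(x)[1]
  }
  layers <- flatten_layers(model$layers)
  best_val <- Inf
  best_w <- NULL
  wait <- 0
  plateau_wait <- 0
  cur_lr <- lr
  hist <- data.frame(epoch = integer(0), train_mae = numeric(0),
                     val_mae = numeric(0), lr = numeric(0))
  step <- 0
  for (ep in seq_len(epochs)) {
    if (!is.null(schedule) && schedule$type == "staircase") {
      cur_lr <- lr * schedule$factor^((ep - 1) %/% schedule$every)
    }
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, n)]
      if (length(bi) < 2 && n > 1) next # skip degenerate 1-sample batch
      xb <- index_rows(x, bi)
      yb <- y[bi, , drop = FALSE]
      pred <- nn_forward(model, xb, training = TRUE)
      l <- loss_mae(pred, yb)
      if (!is.finite(l)) {
        stop(sprintf("NaN/Inf loss at epoch %d (lr %.2g); try a lower lr",
                     ep, cur_lr), call. = FALSE)
      }
      ep_loss <- ep_loss + l
      nb <- nb + 1
      nn_backward(model, loss_mae_grad(pred, yb))
      step <- step + 1
      adam_update(layers, cur_lr, step)
    }
    train_mae <- ep_loss / max(nb, 1)
    val_mae <- NA_real_
    if (!is.null(x_val)) {
      val_pred <- nn_forward(model, x_val, training = FALSE)
      val_mae <- loss_mae(val_pred, y_val)
      if (val_mae < best_val - 1e-9) {
        best_val <- val_mae
        best_w <- nn_get_weights(model)
        wait <- 0
        plateau_wait <- 0
      } else {
        wait <- wait + 1
        plateau_wait <- plateau_wait + 1
      }
      if (!is.null(schedule) && schedule$type == "plateau" &&
          plateau_wait >= schedule$patience) {
        cur_lr <- max(cur_lr * schedule$factor, schedule$min_lr)
        plateau_wait <- 0
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_mae = train_mae,
                                   val_mae = val_mae, lr = cur_lr))
    if (verbose > 0 && ep %% verbose == 0) {
      message(sprintf("epoch %d: train %.4f val %.4f lr %.2g",
                      ep, train_mae, val_mae, cur_lr))
    }
    if (!is.null(x_val) && wait >= patience) break
  }
  if (!is.null(best_w)) nn_set_weights(model, best_w)
  list(model = model, history = hist)
}

# row-subset an array along its first dimension
index_rows <- function(x, i) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    x[i, , drop = FALSE]
  } else if (length(d) == 3L) {
    x[i, , , drop = FALSE]
  } else {
    stop("unsupported array rank", call. = FALSE)
  }
}

#' Predict from a trained model
#'
#' @param model an `nn_model`.
#' @param x input array.
#' @param batch_size evaluation batch size.
#' @return Output matrix.
#' @export
nn_predict <- function(model, x, batch_size = 256) {
  n <- dim(x)[1]
  out <- NULL
  for (b0 in seq(1, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, n)
    pred <- nn_forward(model, index_rows(x, bi), training = FALSE)
    out <- rbind(out, pred)
  }
  out
}
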