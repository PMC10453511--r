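# Minimal feed-forward / convolutional / recurrent network engine.
#
# Only what the three agent architectures need: dense, elementwise
# activation, inverted dropout, Conv1D (kernel along the time axis, genes as
# channels), MaxPool1D, LSTM (last hidden state), and an Adam optimizer on a
# full-batch MSE objective. Batches are (B x features) matrices; the
# convolutional/recurrent path reshapes them to (B, m timesteps, n genes)
# arrays. Gradients are hand-derived and checked against finite differences
# in the test suite.

ACTIVATIONS <- c("relu", "tanh", "sigmoid", "linear")

act_apply <- function(x, fun) {
  switch(fun,
    relu = pmax(x, 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    linear = x,
    stop(sprintf("unknown activation '%s'", fun)))
}

# derivative expressed through the activation's output
act_grad <- function(dout, out, fun) {
  switch(fun,
    relu = dout * (out > 0),
    tanh = dout * (1 - out^2),
    sigmoid = dout * out * (1 - out),
    linear = dout)
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

layer_dense <- function(in_dim, out_dim) {
  list(type = "dense",
       W = glorot(in_dim, out_dim, c(in_dim, out_dim)),
       b = numeric(out_dim))
}
layer_act <- function(fun) {
  if (!fun %in% ACTIVATIONS) stop(sprintf("unknown activation '%s'", fun))
  list(type = "act", fun = fun)
}
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}
layer_reshape3d <- function(m, n) list(type = "reshape3d", m = m, n = n)
layer_conv1d <- function(in_ch, filters, kernel) {
  list(type = "conv1d", kernel = kernel, in_ch = in_ch, filters = filters,
       W = glorot(kernel * in_ch, filters, c(kernel, in_ch, filters)),
       b = numeric(filters))
}
layer_maxpool1d <- function(pool) list(type = "maxpool1d", pool = pool)
# zero-pads `left` steps at the start of the time axis, so a kernel-2
# convolution preserves the sequence length
layer_pad1d <- function(left) list(type = "pad1d", left = left)
layer_flatten <- function() list(type = "flatten")
layer_lstm <- function(in_ch, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias
  list(type = "lstm", units = units,
       Wx = glorot(in_ch, units, c(in_ch, 4 * units)),
       Wh = glorot(units, units, c(units, 4 * units)),
       b = b)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$W
      out <- sweep(out, 2L, layer$b, "+")
      list(out = out, cache = list(x = x))
    },
    act = {
      out <- act_apply(x, layer$fun)
      list(out = out, cache = list(out = out))
    },
    dropout = {
      if (!training || layer$rate == 0) {
        list(out = x, cache = list(mask = NULL))
      } else {
        mask <- array(stats::runif(length(x)) >= layer$rate, dim = dim(x))
        list(out = x * mask / (1 - layer$rate),
             cache = list(mask = mask))
      }
    },
    reshape3d = {
      # column j = (gene-1)*m + step, so a plain column-major refold gives
      # out[b, step, gene]
      list(out = array(x, c(nrow(x), layer$m, layer$n)), cache = NULL)
    },
    conv1d = {
      d <- dim(x); B <- d[1L]; Tt <- d[2L]; C <- d[3L]
      K <- layer$kernel; Tout <- Tt - K + 1L
      if (Tout < 1L) stop("conv1d: window shorter than kernel")
      U <- matrix(0, B * Tout, K * C)
      for (c in seq_len(C)) for (k in seq_len(K))
        U[, k + (c - 1L) * K] <- as.vector(x[, k:(k + Tout - 1L), c])
      W2 <- matrix(layer$W, K * C, layer$filters)
      out2 <- U %*% W2
      out2 <- sweep(out2, 2L, layer$b, "+")
      list(out = array(out2, c(B, Tout, layer$filters)),
           cache = list(U = U, dims = d))
    },
    pad1d = {
      d <- dim(x)
      out <- array(0, c(d[1L], d[2L] + layer$left, d[3L]))
      out[, (layer$left + 1L):(d[2L] + layer$left), ] <- x
      list(out = out, cache = list(dims = d))
    },
    maxpool1d = {
      d <- dim(x); B <- d[1L]; Tt <- d[2L]; C <- d[3L]
      P <- Tt %/% layer$pool
      out <- array(0, c(B, P, C))
      first_wins <- array(FALSE, c(B, P, C))
      for (p in seq_len(P)) {
        a <- x[, 2L * p - 1L, , drop = FALSE]
        bb <- x[, 2L * p, , drop = FALSE]
        take <- a >= bb  # ties go to the earlier step
        out[, p, ] <- ifelse(take, a, bb)
        first_wins[, p, ] <- take
      }
      list(out = out, cache = list(first_wins = first_wins, dims = d))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1L], d[2L] * d[3L]), cache = list(dims = d))
    },
    lstm = {
      d <- dim(x); B <- d[1L]; Tt <- d[2L]
      U <- layer$units
      h <- matrix(0, B, U); cc <- matrix(0, B, U)
      steps <- vector("list", Tt)
      for (t in seq_len(Tt)) {
        xt <- matrix(x[, t, ], B)
        z <- xt %*% layer$Wx + h %*% layer$Wh
        z <- sweep(z, 2L, layer$b, "+")
        ig <- 1 / (1 + exp(-z[, 1:U, drop = FALSE]))
        fg <- 1 / (1 + exp(-z[, (U + 1):(2 * U), drop = FALSE]))
        gg <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
        og <- 1 / (1 + exp(-z[, (3 * U + 1):(4 * U), drop = FALSE]))
        c_new <- fg * cc + ig * gg
        steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc,
                           i = ig, f = fg, g = gg, o = og, tc = tanh(c_new))
        cc <- c_new
        h <- og * steps[[t]]$tc
      }
      list(out = h, cache = list(steps = steps, dims = d))
    },
    stop(sprintf("unknown layer type '%s'", layer$type)))
}

# returns list(dx = ..., grads = named list or NULL)
layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    dense = {
      list(dx = dout %*% t(layer$W),
           grads = list(W = t(cache$x) %*% dout, b = colSums(dout)))
    },
    act = list(dx = act_grad(dout, cache$out, layer$fun), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask / (1 - layer$rate), grads = NULL)
    },
    reshape3d = {
      dx <- dout
      dim(dx) <- c(dim(dout)[1L], layer$m * layer$n)
      list(dx = dx, grads = NULL)
    },
    conv1d = {
      d <- cache$dims; B <- d[1L]; Tt <- d[2L]; C <- d[3L]
      K <- layer$kernel; Tout <- Tt - K + 1L
      dout2 <- matrix(dout, B * Tout, layer$filters)
      W2 <- matrix(layer$W, K * C, layer$filters)
      dU <- dout2 %*% t(W2)
      dx <- array(0, d)
      for (c in seq_len(C)) for (k in seq_len(K))
        dx[, k:(k + Tout - 1L), c] <- dx[, k:(k + Tout - 1L), c] +
          matrix(dU[, k + (c - 1L) * K], B, Tout)
      dW <- t(cache$U) %*% dout2
      dim(dW) <- dim(layer$W)
      list(dx = dx, grads = list(W = dW, b = colSums(dout2)))
    },
    pad1d = {
      d <- cache$dims
      list(dx = dout[, (layer$left + 1L):(d[2L] + layer$left), , drop = FALSE],
           grads = NULL)
    },
    maxpool1d = {
      d <- cache$dims; B <- d[1L]; P <- dim(dout)[2L]
      dx <- array(0, d)
      for (p in seq_len(P)) {
        g <- matrix(dout[, p, ], B)
        take <- matrix(cache$first_wins[, p, ], B)
        dx[, 2L * p - 1L, ] <- g * take
        dx[, 2L * p, ] <- g * !take
      }
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache$dims
      list(dx = dx, grads = NULL)
    },
    lstm = {
      d <- cache$dims; B <- d[1L]; Tt <- d[2L]; U <- layer$units
      dWx <- array(0, dim(layer$Wx)); dWh <- array(0, dim(layer$Wh))
      db <- numeric(4 * U)
      dh <- dout; dc <- matrix(0, B, U)
      dx <- array(0, d)
      for (t in rev(seq_len(Tt))) {
        s <- cache$steps[[t]]
        do_ <- dh * s$tc
        dc <- dc + dh * s$o * (1 - s$tc^2)
        di <- dc * s$g; df <- dc * s$c_prev; dg <- dc * s$i
        dz <- cbind(di * s$i * (1 - s$i),
                    df * s$f * (1 - s$f),
                    dg * (1 - s$g^2),
                    do_ * s$o * (1 - s$o))
        dWx <- dWx + t(s$xt) %*% dz
        dWh <- dWh + t(s$h_prev) %*% dz
        db <- db + colSums(dz)
        dx[, t, ] <- dz %*% t(layer$Wx)
        dh <- dz %*% t(layer$Wh)
        dc <- dc * s$f
      }
      list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    stop(sprintf("unknown layer type '%s'", layer$type)))
}

nn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  out <- X
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], out, training = training)
    out <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = out, caches = caches)
}

nn_predict <- function(model, X) {
  as.numeric(nn_forward(model, X, training = FALSE)$out)
}

# Full-batch MSE loss + gradient of every parameter.
nn_loss_grads <- function(model, X, y, training = TRUE) {
  fw <- nn_forward(model, X, training = training)
  pred <- as.numeric(fw$out)
  B <- length(y)
  loss <- mean((pred - y)^2)
  dout <- matrix(2 * (pred - y) / B, B, 1L)
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], dout, fw$caches[[i]])
    grads[i] <- list(bw$grads)  # keep NULL slots for parameter-free layers
    dout <- bw$dx
  }
  list(loss = loss, grads = grads)
}

PARAM_NAMES <- c("W", "b", "Wx", "Wh")

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    ps <- intersect(PARAM_NAMES, names(l))
    if (!length(ps)) return(NULL)
    stats::setNames(lapply(ps, function(p)
      list(m = array(0, dim = dim(l[[p]]) %||% length(l[[p]])),
           v = array(0, dim = dim(l[[p]]) %||% length(l[[p]])))), ps)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(model = model, state = state)
}
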