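# Minimal neural-network engine: fully connected and GRU regressors trained
# with Adam on mean-squared error. Pure matrix code; networks here are small
# (tens of inputs, <=128 hidden units) so base R linear algebra is adequate.
# All stochastic steps (init, shuffling) draw from the session RNG; callers
# seed it for reproducibility.

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

mlp_init <- function(input_dim, hidden, y_mean = 0) {
  dims <- c(input_dim, hidden, 1L)
  params <- list()
  for (l in seq_len(length(dims) - 1L)) {
    fan_in <- dims[l]
    params[[paste0("W", l)]] <- matrix(rnorm(fan_in * dims[l + 1L],
                                             sd = sqrt(2 / fan_in)),
                                       fan_in, dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  # start forecasts at the operating point instead of zero saturation
  params[[paste0("b", length(dims) - 1L)]] <- y_mean
  list(kind = "mlp", params = params, n_layers = length(dims) - 1L,
       input_dim = input_dim)
}

mlp_forward <- function(net, X) {
  p <- net$params
  L <- net$n_layers
  Z <- vector("list", L); A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- add_bias(A[[l]] %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    A[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(Z = Z, A = A, pred = drop(A[[L + 1L]]))
}

mlp_grad <- function(net, X, y) {
  fw <- mlp_forward(net, X)
  L <- net$n_layers
  n <- nrow(X)
  err <- fw$pred - y
  loss <- mean(err^2)
  grads <- vector("list", 2L * L)
  names(grads) <- names(net$params)
  dZ <- matrix(2 * err / n, n, 1L)
  for (l in L:1) {
    grads[[paste0("W", l)]] <- crossprod(fw$A[[l]], dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(net$params[[paste0("W", l)]])
      dZ <- dA * (fw$Z[[l - 1L]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init <- function(n_channels, units, w, y_mean = 0) {
  gm <- function(nr, nc, fan) matrix(rnorm(nr * nc, sd = sqrt(1 / fan)), nr, nc)
  params <- list(
    Wz = gm(n_channels, units, n_channels), Uz = gm(units, units, units),
    bz = numeric(units),
    Wr = gm(n_channels, units, n_channels), Ur = gm(units, units, units),
    br = numeric(units),
    Wh = gm(n_channels, units, n_channels), Uh = gm(units, units, units),
    bh = numeric(units),
    V = gm(units, 1L, units), c0 = y_mean)
  list(kind = "gru", params = params, units = units,
       n_channels = n_channels, w = w, input_dim = n_channels * w)
}

# rows are laid out channel-blocked: w spo2 columns, then w hr columns;
# timestep t feeds the t-th column of each block
gru_steps <- function(net, X) {
  lapply(seq_len(net$w), function(t) {
    X[, t + net$w * (seq_len(net$n_channels) - 1L), drop = FALSE]
  })
}

gru_forward <- function(net, X) {
  p <- net$params
  n <- nrow(X); H <- net$units; Tn <- net$w
  xs <- gru_steps(net, X)
  zs <- rs <- hhs <- hs <- vector("list", Tn)
  h <- matrix(0, n, H)
  for (t in seq_len(Tn)) {
    x <- xs[[t]]
    z <- sigmoid(add_bias(x %*% p$Wz + h %*% p$Uz, p$bz))
    r <- sigmoid(add_bias(x %*% p$Wr + h %*% p$Ur, p$br))
    hh <- tanh(add_bias(x %*% p$Wh + (r * h) %*% p$Uh, p$bh))
    h_new <- (1 - z) * h + z * hh
    zs[[t]] <- z; rs[[t]] <- r; hhs[[t]] <- hh; hs[[t]] <- h_new
    h <- h_new
  }
  pred <- drop(h %*% p$V) + p$c0
  list(xs = xs, zs = zs, rs = rs, hhs = hhs, hs = hs, pred = pred)
}

gru_grad <- function(net, X, y) {
  p <- net$params
  fw <- gru_forward(net, X)
  n <- nrow(X); H <- net$units; Tn <- net$w
  err <- fw$pred - y
  loss <- mean(err^2)
  dpred <- 2 * err / n
  g <- lapply(p, function(q) if (is.matrix(q)) matrix(0, nrow(q), ncol(q)) else q * 0)
  hT <- fw$hs[[Tn]]
  g$V <- crossprod(hT, matrix(dpred, n, 1L))
  g$c0 <- sum(dpred)
  dh <- matrix(dpred, n, 1L) %*% t(p$V)
  for (t in Tn:1) {
    z <- fw$zs[[t]]; r <- fw$rs[[t]]; hh <- fw$hhs[[t]]
    h_prev <- if (t > 1L) fw$hs[[t - 1L]] else matrix(0, n, H)
    x <- fw$xs[[t]]
    dz <- dh * (hh - h_prev) * z * (1 - z)
    dhh <- dh * z * (1 - hh^2)
    dr <- (dhh %*% t(p$Uh)) * h_prev * r * (1 - r)
    g$Wz <- g$Wz + crossprod(x, dz); g$Uz <- g$Uz + crossprod(h_prev, dz)
    g$bz <- g$bz + colSums(dz)
    g$Wr <- g$Wr + crossprod(x, dr); g$Ur <- g$Ur + crossprod(h_prev, dr)
    g$br <- g$br + colSums(dr)
    g$Wh <- g$Wh + crossprod(x, dhh); g$Uh <- g$Uh + crossprod(r * h_prev, dhh)
    g$bh <- g$bh + colSums(dhh)
    dh <- dh * (1 - z) + dz %*% t(p$Uz) + dr %*% t(p$Ur) + (dhh %*% t(p$Uh)) * r
  }
  list(loss = loss, grads = g)
}

net_predict <- function(net, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$input_dim) {
    stop(sprintf("input has %d columns; network expects %d", ncol(X), net$input_dim),
         call. = FALSE)
  }
  if (net$kind == "mlp") mlp_forward(net, X)$pred else gru_forward(net, X)$pred
}

net_grad <- function(net, X, y) {
  if (net$kind == "mlp") mlp_grad(net, X, y) else gru_grad(net, X, y)
}

adam_init <- function(params) {
  zero <- lapply(params, function(q) if (is.matrix(q)) matrix(0, nrow(q), ncol(q)) else q * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# mini-batch training with early stopping on validation MSE; restores the
# best-validation weights
train_network <- function(net, X_train, y_train, X_val, y_val,
                          learning_rate = 1e-3, batch_size = 32L,
                          max_epochs = 200L, patience = 10L) {
  n <- nrow(X_train)
  state <- adam_init(net$params)
  best <- net$params
  best_val <- Inf
  wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (b in starts) {
      rows <- perm[b:min(b + batch_size - 1L, n)]
      gr <- net_grad(net, X_train[rows, , drop = FALSE], y_train[rows])
      upd <- adam_step(net$params, gr$grads, state, lr = learning_rate)
      net$params <- upd$params
      state <- upd$state
    }
    val_mse <- mean((net_predict(net, X_val) - y_val)^2)
    history <- c(history, val_mse)
    if (val_mse < best_val - 1e-10) {
      best_val <- val_mse
      best <- net$params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
    if (best_val < 1e-10) break
  }
  net$params <- best
  net$val_mse <- best_val
  net$history <- history
  net
}
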