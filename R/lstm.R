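# Minimal single-layer LSTM sequence regressor: gated recurrence, a linear
# readout of the final hidden state, mean-squared-error loss, Adam updates
# and full backpropagation through time. Written in base R matrix ops;
# gate order in the stacked pre-activation is [input, forget, output, cell].

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init_params <- function(hidden) {
  s <- 1 / sqrt(hidden)
  H4 <- 4L * hidden
  b <- numeric(H4)
  b[(hidden + 1L):(2L * hidden)] <- 1   # forget-gate bias starts open
  list(Wx = stats::runif(H4, -s, s),
       Wh = matrix(stats::runif(H4 * hidden, -s, s), H4, hidden),
       b = b,
       Wy = stats::runif(hidden, -s, s),
       by = 0)
}

# X: [B, T] matrix of (normalized) scalar inputs. Returns prediction and,
# when cache = TRUE, everything backprop needs.
lstm_forward <- function(params, X, cache = FALSE, dropout_mask = NULL) {
  H <- length(params$Wy)
  B <- nrow(X); Tn <- ncol(X)
  ii <- 1:H; ff <- (H + 1L):(2L * H)
  oo <- (2L * H + 1L):(3L * H); gg <- (3L * H + 1L):(4L * H)
  h <- matrix(0, H, B); c <- matrix(0, H, B)
  if (cache) {
    Ia <- array(0, c(H, B, Tn)); Fa <- Ia; Oa <- Ia; Ga <- Ia; Ca <- Ia
    Ha <- array(0, c(H, B, Tn + 1L))
  }
  for (t in seq_len(Tn)) {
    zpre <- outer(params$Wx, X[, t]) + params$Wh %*% h + params$b
    gi <- sigmoid(zpre[ii, , drop = FALSE])
    gf <- sigmoid(zpre[ff, , drop = FALSE])
    go <- sigmoid(zpre[oo, , drop = FALSE])
    gg_ <- tanh(zpre[gg, , drop = FALSE])
    c <- gf * c + gi * gg_
    h <- go * tanh(c)
    if (cache) {
      Ia[, , t] <- gi; Fa[, , t] <- gf; Oa[, , t] <- go; Ga[, , t] <- gg_
      Ca[, , t] <- c; Ha[, , t + 1L] <- h
    }
  }
  h_out <- if (is.null(dropout_mask)) h else h * dropout_mask
  yhat <- as.numeric(crossprod(h_out, params$Wy)) + params$by
  if (!cache) return(list(yhat = yhat))
  list(yhat = yhat, I = Ia, F = Fa, O = Oa, G = Ga, C = Ca, H = Ha,
       h_out = h_out, X = X)
}

lstm_backward <- function(params, fw, y, dropout_mask = NULL) {
  H <- length(params$Wy)
  B <- nrow(fw$X); Tn <- ncol(fw$X)
  dyhat <- 2 * (fw$yhat - y) / B
  grads <- list(Wx = numeric(4L * H),
                Wh = matrix(0, 4L * H, H),
                b = numeric(4L * H),
                Wy = as.numeric(fw$h_out %*% dyhat),
                by = sum(dyhat))
  dh <- outer(params$Wy, dyhat)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  dc <- matrix(0, H, B)
  for (t in rev(seq_len(Tn))) {
    gi <- fw$I[, , t, drop = FALSE]; dim(gi) <- c(H, B)
    gf <- fw$F[, , t, drop = FALSE]; dim(gf) <- c(H, B)
    go <- fw$O[, , t, drop = FALSE]; dim(go) <- c(H, B)
    gg_ <- fw$G[, , t, drop = FALSE]; dim(gg_) <- c(H, B)
    ct <- fw$C[, , t, drop = FALSE]; dim(ct) <- c(H, B)
    c_prev <- if (t > 1L) { x <- fw$C[, , t - 1L, drop = FALSE]
                            dim(x) <- c(H, B); x } else matrix(0, H, B)
    h_prev <- fw$H[, , t, drop = FALSE]; dim(h_prev) <- c(H, B)
    tc <- tanh(ct)
    do_ <- dh * tc
    dc <- dc + dh * go * (1 - tc^2)
    di <- dc * gg_
    df <- dc * c_prev
    dg <- dc * gi
    dz <- rbind(di * gi * (1 - gi),
                df * gf * (1 - gf),
                do_ * go * (1 - go),
                dg * (1 - gg_^2))
    grads$Wx <- grads$Wx + as.numeric(dz %*% fw$X[, t])
    grads$Wh <- grads$Wh + dz %*% t(h_prev)
    grads$b <- grads$b + rowSums(dz)
    dh <- crossprod(params$Wh, dz)
    dc <- dc * gf
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

lstm_mse <- function(params, X, y) {
  mean((lstm_forward(params, X)$yhat - y)^2)
}
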