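# Training machinery shared by the two streams: Adam, softmax cross-entropy,
# and an LSTM with full backpropagation through time. Convolution and pooling
# kernels live in src/kernels.cpp; everything else runs on BLAS matrix
# multiplication. All randomness flows through R's RNG so one set.seed()
# makes a fit bit-reproducible.

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    st <- state[[nm]]
    upd <- cpp_adam_fused(params[[nm]], grads[[nm]], st$m, st$v,
                          lr, t, b1, b2, eps)
    attributes(upd$p) <- attributes(params[[nm]])
    params[[nm]] <- upd$p
    state[[nm]] <- list(m = upd$m, v = upd$v)
  }
  list(params = params, state = state)
}

# ---- softmax / cross-entropy ---------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# logits: K x B; labels: integer vector in 1..K.
softmax_ce <- function(logits, labels) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  at <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(p[at], 1e-300)))
  d <- p
  d[at] <- d[at] - 1
  list(loss = loss, dlogits = d / B, probs = p)
}

# ---- LSTM ----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init_params <- function(input_dim, hidden, n_layers, n_classes) {
  params <- list()
  for (l in seq_len(n_layers)) {
    d <- if (l == 1L) input_dim else hidden
    s <- 1 / sqrt(hidden)
    params[[paste0("Wg", l)]] <- matrix(stats::runif(4L * hidden * (d + hidden), -s, s),
                                        4L * hidden, d + hidden)
    bg <- numeric(4L * hidden)
    bg[hidden + seq_len(hidden)] <- 1  # forget-gate bias 1: standard stabiliser
    params[[paste0("bg", l)]] <- bg
  }
  s <- 1 / sqrt(hidden)
  params$Wo <- matrix(stats::runif(n_classes * hidden, -s, s), n_classes, hidden)
  params$bo <- numeric(n_classes)
  params
}

# Forward pass. X: (n x T x D) array; lens: true lengths — the class readout
# uses the hidden state at t = len, so zero padding beyond a clip's true
# length never influences the prediction.
lstm_forward <- function(params, X, lens, hidden, n_layers) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  caches <- vector("list", n_layers)
  inp_seq <- X
  for (l in seq_len(n_layers)) {
    D <- dim(inp_seq)[3]
    Wg <- params[[paste0("Wg", l)]]; bg <- params[[paste0("bg", l)]]
    Hs <- array(0, c(n, Tt, hidden)); Cs <- array(0, c(n, Tt, hidden))
    gates <- array(0, c(n, Tt, 4L * hidden))
    hprev <- matrix(0, n, hidden); cprev <- matrix(0, n, hidden)
    for (t in seq_len(Tt)) {
      xt <- matrix(inp_seq[, t, ], n, D)
      z <- cbind(xt, hprev) %*% t(Wg)
      z <- sweep(z, 2L, bg, "+")
      i <- sigmoid(z[, seq_len(hidden), drop = FALSE])
      f <- sigmoid(z[, hidden + seq_len(hidden), drop = FALSE])
      g <- tanh(z[, 2L * hidden + seq_len(hidden), drop = FALSE])
      o <- sigmoid(z[, 3L * hidden + seq_len(hidden), drop = FALSE])
      cprev <- f * cprev + i * g
      hprev <- o * tanh(cprev)
      gates[, t, ] <- cbind(i, f, g, o)
      Cs[, t, ] <- cprev; Hs[, t, ] <- hprev
    }
    caches[[l]] <- list(inp = inp_seq, H = Hs, C = Cs, gates = gates)
    inp_seq <- Hs
  }
  Hlast <- matrix(0, n, hidden)
  top <- caches[[n_layers]]$H
  for (s in seq_len(n)) Hlast[s, ] <- top[s, lens[s], ]
  logits <- sweep(Hlast %*% t(params$Wo), 2L, params$bo, "+")
  list(caches = caches, Hlast = Hlast, logits = logits)
}

lstm_backward <- function(params, fwd, X, lens, labels, hidden, n_layers) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  ce <- softmax_ce(t(fwd$logits), labels)   # expects K x n
  dlog <- t(ce$dlogits)                     # n x K
  grads <- list(Wo = t(dlog) %*% fwd$Hlast, bo = colSums(dlog))
  dHlast <- dlog %*% params$Wo
  dH_inject <- array(0, c(n, Tt, hidden))
  for (s in seq_len(n)) dH_inject[s, lens[s], ] <- dHlast[s, ]
  for (l in rev(seq_len(n_layers))) {
    cache <- fwd$caches[[l]]
    D <- dim(cache$inp)[3]
    Wg <- params[[paste0("Wg", l)]]
    dWg <- Wg * 0; dbg <- numeric(4L * hidden)
    dh_next <- matrix(0, n, hidden); dc_next <- matrix(0, n, hidden)
    dInp <- array(0, c(n, Tt, D))
    for (t in rev(seq_len(Tt))) {
      dh <- dh_next + matrix(dH_inject[, t, ], n, hidden)
      i <- matrix(cache$gates[, t, seq_len(hidden)], n, hidden)
      f <- matrix(cache$gates[, t, hidden + seq_len(hidden)], n, hidden)
      g <- matrix(cache$gates[, t, 2L * hidden + seq_len(hidden)], n, hidden)
      o <- matrix(cache$gates[, t, 3L * hidden + seq_len(hidden)], n, hidden)
      ct <- matrix(cache$C[, t, ], n, hidden)
      tc <- tanh(ct)
      dc <- dc_next + dh * o * (1 - tc * tc)
      cm1 <- if (t > 1L) matrix(cache$C[, t - 1L, ], n, hidden) else matrix(0, n, hidden)
      di <- dc * g * i * (1 - i)
      df <- dc * cm1 * f * (1 - f)
      dg <- dc * i * (1 - g * g)
      do_ <- dh * tc * o * (1 - o)
      dz <- cbind(di, df, dg, do_)
      xt <- matrix(cache$inp[, t, ], n, D)
      hm1 <- if (t > 1L) matrix(cache$H[, t - 1L, ], n, hidden) else matrix(0, n, hidden)
      dWg <- dWg + t(dz) %*% cbind(xt, hm1)
      dbg <- dbg + colSums(dz)
      dinp_full <- dz %*% Wg
      dInp[, t, ] <- dinp_full[, seq_len(D)]
      dh_next <- dinp_full[, D + seq_len(hidden), drop = FALSE]
      dc_next <- dc * f
    }
    grads[[paste0("Wg", l)]] <- dWg
    grads[[paste0("bg", l)]] <- dbg
    dH_inject <- dInp   # feeds the layer below as its dH sequence
  }
  list(grads = grads, loss = ce$loss)
}

clip_grads <- function(grads, max_norm = 5) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(tot) && tot > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / tot))
  }
  grads
}
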