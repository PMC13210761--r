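# Internal neural-network primitives: forward/backward passes for the
# temporal-convolution -> spatial-fusion -> BiLSTM architecture and its
# ablation variants, written against BLAS matrix products. Feature maps are
# stored column-major as (B, T, C[, F]) arrays; a matrix view with rows
# (b, t[, c]) and columns F is obtained directly via matrix() because F is
# the trailing dimension.

sigm <- function(x) 1 / (1 + exp(-x))

# fast column-wise broadcast ops (sweep() is too slow on these hot paths)
addcol <- function(x, v) x + rep(v, each = nrow(x))
mulcol <- function(x, v) x * rep(v, each = nrow(x))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' @noRd
bn_forward <- function(x, gamma, beta, running, train) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    running$mean <- (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * mu
    running$var <- (1 - BN_MOMENTUM) * running$var + BN_MOMENTUM * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_std <- 1 / sqrt(v + BN_EPS)
  xhat <- addcol(mulcol(x, inv_std), -mu * inv_std)
  out <- addcol(mulcol(xhat, gamma), beta)
  list(out = out, cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma),
       running = running)
}

#' @noRd
bn_backward <- function(dout, cache) {
  m <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- mulcol(dout, cache$gamma)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- mulcol(addcol(dxhat, -s1 / m) - mulcol(xhat, s2 / m), cache$inv_std)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Temporal convolution: kernel (K, 1) slid over time, weights shared across
# channels. X is (B, T, C); output matrix (B*T*C, F) with same-padding.
#' @noRd
convt_forward <- function(x, w, b) {
  d <- dim(x); B <- d[1]; T_ <- d[2]; C <- d[3]
  k <- nrow(w)
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(B, T_ + k - 1L, C))
  xp[, (pad + 1L):(pad + T_), ] <- x
  p <- matrix(0, B * T_ * C, k)
  for (j in seq_len(k)) p[, j] <- as.vector(xp[, j:(j + T_ - 1L), , drop = FALSE])
  z <- addcol(p %*% w, b)
  list(out = z, cache = list(p = p, w = w, dims = c(B, T_, C), k = k, pad = pad))
}

#' @noRd
convt_backward <- function(dz, cache) {
  B <- cache$dims[1]; T_ <- cache$dims[2]; C <- cache$dims[3]
  k <- cache$k; pad <- cache$pad
  dw <- crossprod(cache$p, dz)
  db <- colSums(dz)
  dp <- tcrossprod(dz, cache$w)
  dxp <- array(0, c(B, T_ + k - 1L, C))
  for (j in seq_len(k)) {
    dxp[, j:(j + T_ - 1L), ] <- dxp[, j:(j + T_ - 1L), , drop = FALSE] +
      array(dp[, j], c(B, T_, C))
  }
  list(dx = dxp[, (pad + 1L):(pad + T_), , drop = FALSE], dw = dw, db = db)
}

# Max pooling over time with span 2; input/output (B, T, C, F) arrays.
#' @noRd
pool_forward <- function(x) {
  d <- dim(x); T_ <- d[2]
  odd <- x[, seq(1L, T_, 2L), , , drop = FALSE]
  even <- x[, seq(2L, T_, 2L), , , drop = FALSE]
  m <- odd >= even
  list(out = pmax(odd, even), cache = list(m = m, dims = d))
}

#' @noRd
pool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  dx[, seq(1L, d[2], 2L), , ] <- dout * cache$m
  dx[, seq(2L, d[2], 2L), , ] <- dout * !cache$m
  dx
}

# LSTM over a (B*T, D) matrix whose rows are grouped by time step
# (rows ((t-1)B+1):(tB) are time t). Returns the final hidden state.
#' @noRd
lstm_forward <- function(h_in, wx, wh, b, B, T_) {
  u <- nrow(wh)
  xw <- h_in %*% wx
  h <- matrix(0, B, u); cc <- matrix(0, B, u)
  gi <- array(0, c(B, u, T_)); gf <- gi; gg <- gi; go <- gi
  cs <- gi; tcs <- gi; hps <- gi; cps <- gi
  iu <- 1:u; fu <- u + iu; gu <- 2L * u + iu; ou <- 3L * u + iu
  for (t in seq_len(T_)) {
    rt <- ((t - 1L) * B + 1L):(t * B)
    z <- addcol(xw[rt, , drop = FALSE] + h %*% wh, b)
    i_g <- sigm(z[, iu, drop = FALSE]); f_g <- sigm(z[, fu, drop = FALSE])
    g_g <- tanh(z[, gu, drop = FALSE]); o_g <- sigm(z[, ou, drop = FALSE])
    hps[, , t] <- h; cps[, , t] <- cc
    cc <- f_g * cc + i_g * g_g
    tc <- tanh(cc)
    h <- o_g * tc
    gi[, , t] <- i_g; gf[, , t] <- f_g; gg[, , t] <- g_g; go[, , t] <- o_g
    cs[, , t] <- cc; tcs[, , t] <- tc
  }
  list(h = h, cache = list(gi = gi, gf = gf, gg = gg, go = go, cs = cs,
                           tcs = tcs, hps = hps, cps = cps, h_in = h_in,
                           wx = wx, wh = wh, B = B, T_ = T_, u = u))
}

#' @noRd
lstm_backward <- function(dh_final, cache) {
  B <- cache$B; T_ <- cache$T_; u <- cache$u
  wh <- cache$wh
  dxw <- matrix(0, B * T_, 4L * u)
  dwh <- matrix(0, u, 4L * u)
  db <- numeric(4L * u)
  dh <- dh_final
  dc <- matrix(0, B, u)
  for (t in rev(seq_len(T_))) {
    i_g <- cache$gi[, , t, drop = FALSE]; dim(i_g) <- c(B, u)
    f_g <- cache$gf[, , t, drop = FALSE]; dim(f_g) <- c(B, u)
    g_g <- cache$gg[, , t, drop = FALSE]; dim(g_g) <- c(B, u)
    o_g <- cache$go[, , t, drop = FALSE]; dim(o_g) <- c(B, u)
    tc <- cache$tcs[, , t, drop = FALSE]; dim(tc) <- c(B, u)
    cp <- cache$cps[, , t, drop = FALSE]; dim(cp) <- c(B, u)
    hp <- cache$hps[, , t, drop = FALSE]; dim(hp) <- c(B, u)
    do_ <- dh * tc
    dc <- dc + dh * o_g * (1 - tc^2)
    di <- dc * g_g; dg <- dc * i_g; df <- dc * cp
    dz <- cbind(di * i_g * (1 - i_g), df * f_g * (1 - f_g),
                dg * (1 - g_g^2), do_ * o_g * (1 - o_g))
    rt <- ((t - 1L) * B + 1L):(t * B)
    dxw[rt, ] <- dz
    dwh <- dwh + crossprod(hp, dz)
    db <- db + colSums(dz)
    dh <- tcrossprod(dz, wh)
    dc <- dc * f_g
  }
  list(dx = tcrossprod(dxw, cache$wx), dwx = crossprod(cache$h_in, dxw),
       dwh = dwh, db = db)
}

# GRU with the usual reset/update/candidate gating; same row layout as LSTM.
#' @noRd
gru_forward <- function(h_in, wx, wh, b, B, T_) {
  u <- nrow(wh)
  xw <- h_in %*% wx
  h <- matrix(0, B, u)
  gr <- array(0, c(B, u, T_)); gz <- gr; gn <- gr; hps <- gr; hun <- gr
  ru <- 1:u; zu <- u + ru; nu <- 2L * u + ru
  for (t in seq_len(T_)) {
    rt <- ((t - 1L) * B + 1L):(t * B)
    hu <- h %*% wh
    r_g <- sigm(addcol(xw[rt, ru, drop = FALSE] + hu[, ru, drop = FALSE], b[ru]))
    z_g <- sigm(addcol(xw[rt, zu, drop = FALSE] + hu[, zu, drop = FALSE], b[zu]))
    n_g <- tanh(addcol(xw[rt, nu, drop = FALSE] + r_g * hu[, nu, drop = FALSE],
                       b[nu]))
    hps[, , t] <- h; hun[, , t] <- hu[, nu, drop = FALSE]
    h <- (1 - z_g) * n_g + z_g * h
    gr[, , t] <- r_g; gz[, , t] <- z_g; gn[, , t] <- n_g
  }
  list(h = h, cache = list(gr = gr, gz = gz, gn = gn, hps = hps, hun = hun,
                           h_in = h_in, wx = wx, wh = wh, B = B, T_ = T_,
                           u = u))
}

#' @noRd
gru_backward <- function(dh_final, cache) {
  B <- cache$B; T_ <- cache$T_; u <- cache$u
  wh <- cache$wh
  ru <- 1:u; zu <- u + ru; nu <- 2L * u + ru
  dxw <- matrix(0, B * T_, 3L * u)
  dwh <- matrix(0, u, 3L * u)
  db <- numeric(3L * u)
  dh <- dh_final
  for (t in rev(seq_len(T_))) {
    r_g <- cache$gr[, , t, drop = FALSE]; dim(r_g) <- c(B, u)
    z_g <- cache$gz[, , t, drop = FALSE]; dim(z_g) <- c(B, u)
    n_g <- cache$gn[, , t, drop = FALSE]; dim(n_g) <- c(B, u)
    hp <- cache$hps[, , t, drop = FALSE]; dim(hp) <- c(B, u)
    hu_n <- cache$hun[, , t, drop = FALSE]; dim(hu_n) <- c(B, u)
    dz_g <- dh * (hp - n_g)
    dn <- dh * (1 - z_g)
    dhp <- dh * z_g
    dnpre <- dn * (1 - n_g^2)
    dr <- dnpre * hu_n
    dhu_n <- dnpre * r_g
    dzpre <- dz_g * z_g * (1 - z_g)
    drpre <- dr * r_g * (1 - r_g)
    dhp <- dhp + tcrossprod(drpre, wh[, ru, drop = FALSE]) +
      tcrossprod(dzpre, wh[, zu, drop = FALSE]) +
      tcrossprod(dhu_n, wh[, nu, drop = FALSE])
    dz_all <- cbind(drpre, dzpre, dnpre)
    rt <- ((t - 1L) * B + 1L):(t * B)
    dxw[rt, ] <- dz_all
    dwh[, ru] <- dwh[, ru] + crossprod(hp, drpre)
    dwh[, zu] <- dwh[, zu] + crossprod(hp, dzpre)
    dwh[, nu] <- dwh[, nu] + crossprod(hp, dhu_n)
    db <- db + colSums(dz_all)
    dh <- dhp
  }
  list(dx = tcrossprod(dxw, cache$wx), dwx = crossprod(cache$h_in, dxw),
       dwh = dwh, db = db)
}

#' @noRd
init_params <- function(arch, n_channels = 12L) {
  f1 <- arch$temporal_filters; f2 <- arch$spatial_filters
  u <- arch$bilstm_units; k <- arch$temporal_kernel
  nc <- arch$n_classes
  he <- function(nr, nc_, fan) matrix(rnorm(nr * nc_, 0, sqrt(2 / fan)), nr, nc_)
  uni <- function(nr, nc_, u_) matrix(runif(nr * nc_, -1 / sqrt(u_), 1 / sqrt(u_)),
                                      nr, nc_)
  p <- list()
  if (arch$variant %in% c("cnn_bilstm", "cnn_only")) {
    p$wc1 <- he(k, f1, k)
    p$bc1 <- numeric(f1)
    p$g1 <- rep(1, f1); p$be1 <- numeric(f1)
    p$wc2 <- he(n_channels * f1, f2, n_channels * f1)
    p$bc2 <- numeric(f2)
    p$g2 <- rep(1, f2); p$be2 <- numeric(f2)
    rnn_d <- f2
  } else {
    rnn_d <- n_channels
  }
  if (arch$variant %in% c("cnn_bilstm", "bilstm_only")) {
    for (dir in c("f", "b")) {
      p[[paste0("wx_", dir)]] <- uni(rnn_d, 4L * u, u)
      p[[paste0("wh_", dir)]] <- uni(u, 4L * u, u)
      bb <- numeric(4L * u); bb[(u + 1L):(2L * u)] <- 1  # forget-gate bias
      p[[paste0("b_", dir)]] <- bb
    }
    emb_d <- 2L * u
  } else if (arch$variant == "gru_only") {
    for (dir in c("f", "b")) {
      p[[paste0("wx_", dir)]] <- uni(rnn_d, 3L * u, u)
      p[[paste0("wh_", dir)]] <- uni(u, 3L * u, u)
      p[[paste0("b_", dir)]] <- numeric(3L * u)
    }
    emb_d <- 2L * u
  } else {
    emb_d <- f2
  }
  p$wd <- he(emb_d, nc, emb_d)
  p$bd <- numeric(nc)
  p
}

#' @noRd
init_bn_state <- function(arch) {
  if (!arch$variant %in% c("cnn_bilstm", "cnn_only")) return(list())
  list(bn1 = list(mean = numeric(arch$temporal_filters),
                  var = rep(1, arch$temporal_filters)),
       bn2 = list(mean = numeric(arch$spatial_filters),
                  var = rep(1, arch$spatial_filters)))
}

# Reverse the time axis of a (B*T, D) time-grouped matrix.
#' @noRd
time_reverse <- function(m, B, T_) {
  idx <- as.vector(outer(1:B, (rev(seq_len(T_)) - 1L) * B, "+"))
  m[idx, , drop = FALSE]
}

# Full forward pass. Returns embeddings (penultimate), logits, caches.
#' @noRd
net_forward <- function(params, x, arch, bn_state, train = FALSE,
                        drop_mask = NULL) {
  d <- dim(x); B <- d[1]; T_ <- d[2]; C <- d[3]
  cache <- list(B = B, T_ = T_, C = C)
  if (arch$variant %in% c("cnn_bilstm", "cnn_only")) {
    cv1 <- convt_forward(x, params$wc1, params$bc1)
    bn1 <- bn_forward(cv1$out, params$g1, params$be1, bn_state$bn1, train)
    bn_state$bn1 <- bn1$running
    r1 <- pmax(bn1$out, 0)
    f1 <- arch$temporal_filters
    a1 <- array(r1, c(B, T_, C, f1))
    pl <- pool_forward(a1)
    t2 <- dim(pl$out)[2]
    # column-major vec order of (B, t2, C, F1) is (b, t) fastest, so this
    # view has rows (b, t) and columns (c, f) — exactly the spatial-fusion
    # input that merges all channels at each time step
    m2 <- matrix(pl$out, nrow = B * t2)
    cv2 <- list(z = addcol(m2 %*% params$wc2, params$bc2))
    bn2 <- bn_forward(cv2$z, params$g2, params$be2, bn_state$bn2, train)
    bn_state$bn2 <- bn2$running
    h_seq <- pmax(bn2$out, 0)                      # (B*t2, f2), rows (b,t)
    cache$cv1 <- cv1$cache; cache$bn1 <- bn1$cache; cache$relu1 <- bn1$out > 0
    cache$pool <- pl$cache; cache$m2 <- m2; cache$bn2 <- bn2$cache
    cache$relu2 <- bn2$out > 0; cache$t2 <- t2
    seq_mat <- h_seq; seq_t <- t2
  } else {
    seq_mat <- matrix(x, nrow = B * T_)            # rows (b,t), cols channels
    seq_t <- T_
  }
  cache$seq_mat <- seq_mat; cache$seq_t <- seq_t
  if (arch$variant == "cnn_only") {
    # global average pooling over time
    emb <- matrix(0, B, ncol(seq_mat))
    for (t in seq_len(seq_t)) {
      rt <- ((t - 1L) * B + 1L):(t * B)
      emb <- emb + seq_mat[rt, , drop = FALSE]
    }
    emb <- emb / seq_t
  } else {
    rnn_fun <- if (arch$variant == "gru_only") gru_forward else lstm_forward
    fw <- rnn_fun(seq_mat, params$wx_f, params$wh_f, params$b_f, B, seq_t)
    rev_mat <- time_reverse(seq_mat, B, seq_t)
    bw <- rnn_fun(rev_mat, params$wx_b, params$wh_b, params$b_b, B, seq_t)
    cache$fw <- fw$cache; cache$bw <- bw$cache
    emb <- cbind(fw$h, bw$h)
  }
  cache$emb <- emb
  h_drop <- emb
  if (train && arch$dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(runif(length(emb)) >= arch$dropout,
                          nrow(emb), ncol(emb)) / (1 - arch$dropout)
    }
    h_drop <- emb * drop_mask
  }
  cache$drop_mask <- drop_mask
  logits <- addcol(h_drop %*% params$wd, params$bd)
  cache$h_drop <- h_drop
  list(logits = logits, emb = emb, cache = cache, bn_state = bn_state)
}

#' @noRd
net_backward <- function(params, dlogits, arch, cache) {
  g <- list()
  g$wd <- crossprod(cache$h_drop, dlogits)
  g$bd <- colSums(dlogits)
  demb <- tcrossprod(dlogits, params$wd)
  if (!is.null(cache$drop_mask)) demb <- demb * cache$drop_mask
  B <- cache$B; seq_t <- cache$seq_t
  if (arch$variant == "cnn_only") {
    dseq <- matrix(0, B * seq_t, ncol(cache$seq_mat))
    for (t in seq_len(seq_t)) {
      rt <- ((t - 1L) * B + 1L):(t * B)
      dseq[rt, ] <- demb / seq_t
    }
  } else {
    u <- arch$bilstm_units
    rnn_back <- if (arch$variant == "gru_only") gru_backward else lstm_backward
    bf <- rnn_back(demb[, 1:u, drop = FALSE], cache$fw)
    bb <- rnn_back(demb[, (u + 1L):(2L * u), drop = FALSE], cache$bw)
    g$wx_f <- bf$dwx; g$wh_f <- bf$dwh; g$b_f <- bf$db
    g$wx_b <- bb$dwx; g$wh_b <- bb$dwh; g$b_b <- bb$db
    dseq <- bf$dx + time_reverse(bb$dx, B, seq_t)
  }
  if (arch$variant %in% c("cnn_bilstm", "cnn_only")) {
    dseq <- dseq * cache$relu2
    bn2b <- bn_backward(dseq, cache$bn2)
    g$g2 <- bn2b$dgamma; g$be2 <- bn2b$dbeta
    g$wc2 <- crossprod(cache$m2, bn2b$dx)
    g$bc2 <- colSums(bn2b$dx)
    dm2 <- tcrossprod(bn2b$dx, params$wc2)
    t2 <- cache$t2; C <- cache$C; f1 <- arch$temporal_filters
    dpool <- array(dm2, c(B, t2, C, f1))
    dr1 <- pool_backward(dpool, cache$pool)
    dr1 <- matrix(dr1, nrow = B * cache$T_ * C) * cache$relu1
    bn1b <- bn_backward(dr1, cache$bn1)
    g$g1 <- bn1b$dgamma; g$be1 <- bn1b$dbeta
    cb <- convt_backward(bn1b$dx, cache$cv1)
    g$wc1 <- cb$dw; g$bc1 <- cb$db
  }
  g
}

# Softmax cross-entropy; y is an integer class vector (1-based).
#' @noRd
softmax_ce <- function(logits, y) {
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

#' @noRd
adam_update <- function(params, grads, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decoupled weight decay on weight matrices only
    if (grepl("^w", nm)) step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
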