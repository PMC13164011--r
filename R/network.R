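# Dual-branch single-block Transformer fusion classifier, single-modality
# ablations, and RNN/CNN/LSTM baselines.
#
# Forward and backward passes are written directly in vectorised base R.
# A mini-batch of B sequences of length T is stored as a (B*T) x d matrix
# whose rows are grouped by sample (sample b occupies rows (b-1)*T + 1..T),
# so linear projections and layer statistics are single matrix operations;
# only the T x T attention products loop over samples and heads.
#
# Each Transformer branch computes, in pre-LN residual form,
#   Y = Dropout(LN2(X + MHA(LN1(X)))),
# with fixed sinusoidal positional encoding added to the (already
# normalised) modality input before the branch. Layer-norm statistics are
# taken over the feature axis when the modality width is > 1 and over the
# time axis for the width-1 vibration branch, where feature-axis
# normalisation would be degenerate (every time step would collapse to the
# shift parameter).

.LN_EPS <- 1e-5

#' Network architecture configuration
#'
#' Defaults follow the studied architecture: sequence length 50, pressure
#' width 36, vibration width 1, one self-attention block per branch with two
#' heads of key dimension 32, dropout 0.3, and a dense 64 / dropout /
#' dense 64 / softmax-2 classification head.
#'
#' @param T Sequence length.
#' @param d_p,d_v Pressure and vibration feature widths.
#' @param H Number of attention heads.
#' @param d_k Per-head key/query/value dimension.
#' @param L Self-attention blocks per branch (1 for this architecture).
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param head_units Widths of the two dense head layers.
#' @param n_classes Number of output classes.
#' @param pe_base Base of the sinusoidal positional encoding.
#' @return An object of class `network_config`.
#' @export
network_config <- function(T = 50L, d_p = 36L, d_v = 1L, H = 2L, d_k = 32L,
                           L = 1L, dropout_rate = 0.3,
                           head_units = c(64L, 64L), n_classes = 2L,
                           pe_base = 10000) {
  if (H < 1L || d_k < 1L) stop("H and d_k must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (length(head_units) != 2L) stop("head_units must have length 2")
  structure(list(T = as.integer(T), d_p = as.integer(d_p),
                 d_v = as.integer(d_v), H = as.integer(H),
                 d_k = as.integer(d_k), L = as.integer(L),
                 dropout_rate = dropout_rate,
                 head_units = as.integer(head_units),
                 n_classes = as.integer(n_classes), pe_base = pe_base),
            class = "network_config")
}

#' Fixed sinusoidal positional encoding
#'
#' `PE[t, 2i] = sin(t / base^(2i/d))`, `PE[t, 2i+1] = cos(t / base^(2i/d))`
#' with 0-based time index; for odd `d` the trailing unpaired column uses
#' the sine term.
#'
#' @param T Sequence length.
#' @param d Feature width.
#' @param base Encoding base.
#' @return `T` x `d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(T, d, base = 10000) {
  if (T < 1L || d < 1L) stop("T and d must be >= 1", call. = FALSE)
  t <- 0:(T - 1L)
  pe <- matrix(0, T, d)
  for (j in seq_len(d)) {
    i <- (j - 1L) %/% 2L
    ang <- t / base^(2 * i / d)
    pe[, j] <- if (j %% 2L == 1L) sin(ang) else cos(ang)
  }
  pe
}

## ---- parameter initialisation ------------------------------------------

.glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

.init_branch <- function(prefix, d, cfg) {
  hk <- cfg$H * cfg$d_k
  p <- list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = .glorot(d, hk), bq = rep(0, hk),
    Wk = .glorot(d, hk), bk = rep(0, hk),
    Wv = .glorot(d, hk), bv = rep(0, hk),
    Wo = .glorot(hk, d), bo = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d))
  names(p) <- paste0(prefix, "_", names(p))
  p
}

.init_head <- function(n_flat, cfg) {
  u <- cfg$head_units
  list(W1 = .glorot(n_flat, u[1]), b1 = rep(0, u[1]),
       W2 = .glorot(u[1], u[2]), b2 = rep(0, u[2]),
       W3 = .glorot(u[2], cfg$n_classes), b3 = rep(0, cfg$n_classes))
}

.init_rnn <- function(prefix, d, units = 32L) {
  p <- list(Wx = .glorot(d, units), Wh = .glorot(units, units),
            b = rep(0, units))
  names(p) <- paste0(prefix, "_", names(p))
  p
}

.init_lstm <- function(prefix, d, units = 32L) {
  # gate order in the 4*units columns: input, forget, output, candidate;
  # forget-gate bias starts at 1
  b <- rep(0, 4L * units)
  b[(units + 1L):(2L * units)] <- 1
  p <- list(Wx = .glorot(d, 4L * units), Wh = .glorot(units, 4L * units),
            b = b)
  names(p) <- paste0(prefix, "_", names(p))
  p
}

.init_cnn <- function(prefix, d, filters = 32L, kernel = 5L) {
  p <- list(W = .glorot(kernel * d, filters), b = rep(0, filters))
  names(p) <- paste0(prefix, "_", names(p))
  p
}

.model_kinds <- c("fusion", "pressure_only", "vibration_only",
                  "rnn", "cnn", "lstm")
.ENC_UNITS <- 32L

#' Initialise a model of a given kind
#'
#' `fusion` is the dual-branch Transformer; `pressure_only` and
#' `vibration_only` keep one branch and attach the same head to that
#' branch's flattened output; `rnn`, `cnn` and `lstm` use a per-modality
#' encoder (simple recurrent 32 units / 1-D convolution with 32 filters of
#' kernel 5 and global average pooling / LSTM 32 units) feeding the
#' identical dense-64/dropout/dense-64/softmax head. Initialisation draws
#' from the current RNG stream; seed it for reproducible parameters.
#'
#' @param kind One of `"fusion"`, `"pressure_only"`, `"vibration_only"`,
#'   `"rnn"`, `"cnn"`, `"lstm"`.
#' @param cfg A [network_config()].
#' @return An object of class `graspnet_model` with elements `kind`, `cfg`,
#'   `params` and `n_params`.
#' @export
build_model <- function(kind, cfg = network_config()) {
  kind <- match.arg(kind, .model_kinds)
  params <- switch(kind,
    fusion = c(.init_branch("p", cfg$d_p, cfg), .init_branch("v", cfg$d_v, cfg),
               .init_head(cfg$T * (cfg$d_p + cfg$d_v), cfg)),
    pressure_only = c(.init_branch("p", cfg$d_p, cfg),
                      .init_head(cfg$T * cfg$d_p, cfg)),
    vibration_only = c(.init_branch("v", cfg$d_v, cfg),
                       .init_head(cfg$T * cfg$d_v, cfg)),
    rnn = c(.init_rnn("p", cfg$d_p), .init_rnn("v", cfg$d_v),
            .init_head(2L * .ENC_UNITS, cfg)),
    lstm = c(.init_lstm("p", cfg$d_p), .init_lstm("v", cfg$d_v),
             .init_head(2L * .ENC_UNITS, cfg)),
    cnn = c(.init_cnn("p", cfg$d_p), .init_cnn("v", cfg$d_v),
            .init_head(2L * .ENC_UNITS, cfg)))
  structure(list(kind = kind, cfg = cfg, params = params,
                 n_params = sum(vapply(params, length, 0L))),
            class = "graspnet_model")
}

## ---- layer primitives ---------------------------------------------------

# Layer normalisation over the feature axis (rows of the stacked matrix) or,
# for width-1 inputs, over the time axis within each sample.
.ln_forward <- function(X, g, b, axis, T) {
  if (axis == "feature") {
    mu <- rowMeans(X)
    xc <- X - mu
    inv <- 1 / sqrt(rowMeans(xc^2) + .LN_EPS)
    xhat <- xc * inv
    Y <- sweep(xhat, 2L, g, `*`)
    Y <- sweep(Y, 2L, b, `+`)
  } else {
    xm <- matrix(X, nrow = T)                 # T x B, one column per sample
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    inv <- 1 / sqrt(colMeans(xc^2) + .LN_EPS)
    xhat_m <- sweep(xc, 2L, inv, `*`)
    xhat <- matrix(as.vector(xhat_m), ncol = 1L)
    Y <- xhat * g + b
  }
  list(Y = Y, cache = list(xhat = xhat, inv = inv, g = g, axis = axis, T = T))
}

.ln_backward <- function(dY, cache) {
  g <- cache$g
  if (cache$axis == "feature") {
    xhat <- cache$xhat
    dxhat <- sweep(dY, 2L, g, `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dX <- cache$inv * (dxhat - m1 - xhat * m2)
    list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
  } else {
    T <- cache$T
    xhat_m <- matrix(cache$xhat, nrow = T)
    dxhat_m <- matrix(dY * g, nrow = T)
    m1 <- colMeans(dxhat_m)
    m2 <- colMeans(dxhat_m * xhat_m)
    dXm <- sweep(dxhat_m, 2L, m1) - sweep(xhat_m, 2L, m2, `*`)
    dXm <- sweep(dXm, 2L, cache$inv, `*`)
    list(dX = matrix(as.vector(dXm), ncol = 1L),
         dg = sum(dY * cache$xhat), db = sum(dY))
  }
}

.sample_rows <- function(b, T) ((b - 1L) * T + 1L):(b * T)

# Multi-head self-attention over a stacked (B*T) x d input.
.mha_forward <- function(Z, p, prefix, cfg, B) {
  T <- cfg$T; H <- cfg$H; dk <- cfg$d_k
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  Qa <- sweep(Z %*% g("Wq"), 2L, g("bq"), `+`)
  Ka <- sweep(Z %*% g("Wk"), 2L, g("bk"), `+`)
  Va <- sweep(Z %*% g("Wv"), 2L, g("bv"), `+`)
  A <- array(0, c(T, T, H, B))
  O <- matrix(0, nrow(Z), H * dk)
  sc <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rows <- .sample_rows(b, T)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Ah <- softmax_rows(tcrossprod(Qa[rows, cols, drop = FALSE],
                                    Ka[rows, cols, drop = FALSE]) * sc)
      A[, , h, b] <- Ah
      O[rows, cols] <- Ah %*% Va[rows, cols, drop = FALSE]
    }
  }
  list(O = O, cache = list(Z = Z, Qa = Qa, Ka = Ka, Va = Va, A = A))
}

.mha_backward <- function(dO, cache, p, prefix, cfg, B) {
  T <- cfg$T; H <- cfg$H; dk <- cfg$d_k
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  Qa <- cache$Qa; Ka <- cache$Ka; Va <- cache$Va; A <- cache$A
  dQa <- matrix(0, nrow(Qa), ncol(Qa))
  dKa <- dQa; dVa <- dQa
  sc <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rows <- .sample_rows(b, T)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Ah <- A[, , h, b]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- Va[rows, cols, drop = FALSE]
      dAh <- tcrossprod(dOh, Vh)
      dVa[rows, cols] <- crossprod(Ah, dOh)
      dS <- Ah * (dAh - rowSums(dAh * Ah))
      dQa[rows, cols] <- sc * dS %*% Ka[rows, cols, drop = FALSE]
      dKa[rows, cols] <- sc * crossprod(dS, Qa[rows, cols, drop = FALSE])
    }
  }
  Z <- cache$Z
  grads <- list(Wq = crossprod(Z, dQa), bq = colSums(dQa),
                Wk = crossprod(Z, dKa), bk = colSums(dKa),
                Wv = crossprod(Z, dVa), bv = colSums(dVa))
  names(grads) <- paste0(prefix, "_", names(grads))
  dZ <- dQa %*% t(g("Wq")) + dKa %*% t(g("Wk")) + dVa %*% t(g("Wv"))
  list(dZ = dZ, grads = grads)
}

.dropout_mask <- function(dim1, dim2, rate, train) {
  if (!train || rate <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= rate) / (1 - rate), dim1, dim2)
}

# One Transformer branch: Y = Dropout(LN2(X + MHA(LN1(X)))).
.branch_forward <- function(X, p, prefix, cfg, B, train) {
  d <- ncol(X)
  axis <- if (d > 1L) "feature" else "time"
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  ln1 <- .ln_forward(X, g("ln1_g"), g("ln1_b"), axis, cfg$T)
  mha <- .mha_forward(ln1$Y, p, prefix, cfg, B)
  M <- sweep(mha$O %*% g("Wo"), 2L, g("bo"), `+`)
  U <- X + M
  ln2 <- .ln_forward(U, g("ln2_g"), g("ln2_b"), axis, cfg$T)
  mask <- .dropout_mask(nrow(X), d, cfg$dropout_rate, train)
  Y <- if (is.null(mask)) ln2$Y else ln2$Y * mask
  list(Y = Y, cache = list(ln1 = ln1$cache, mha = mha$cache, O = mha$O,
                           ln2 = ln2$cache, mask = mask, A = mha$cache$A))
}

# Backward through a branch; the gradient w.r.t. the branch input is not
# needed (inputs and positional encoding are fixed), so only parameter
# gradients are returned.
.branch_backward <- function(dY, cache, p, prefix, cfg, B) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  l2 <- .ln_backward(dY, cache$ln2)
  dU <- l2$dX
  dWo <- crossprod(cache$O, dU)
  dbo <- colSums(dU)
  dO <- dU %*% t(g("Wo"))
  mb <- .mha_backward(dO, cache$mha, p, prefix, cfg, B)
  l1 <- .ln_backward(mb$dZ, cache$ln1)
  grads <- c(mb$grads,
             stats::setNames(list(l1$dg, l1$db, dWo, dbo, l2$dg, l2$db),
                             paste0(prefix, "_",
                                    c("ln1_g", "ln1_b", "Wo", "bo",
                                      "ln2_g", "ln2_b"))))
  grads
}

# Flatten stacked branch outputs ((B*T) x C) into per-sample rows (B x T*C),
# column-major within a sample: feature c of time t lands at (c-1)*T + t.
.flatten_batch <- function(Y, B, T) {
  out <- matrix(0, B, T * ncol(Y))
  for (b in seq_len(B)) out[b, ] <- as.vector(Y[.sample_rows(b, T), ])
  out
}

.unflatten_batch <- function(dF, B, T, C) {
  out <- matrix(0, B * T, C)
  for (b in seq_len(B)) out[.sample_rows(b, T), ] <- matrix(dF[b, ], T, C)
  out
}

.head_forward <- function(Fm, p, cfg, train) {
  H1p <- sweep(Fm %*% p$W1, 2L, p$b1, `+`)
  H1 <- relu(H1p)
  mask <- .dropout_mask(nrow(H1), ncol(H1), cfg$dropout_rate, train)
  D <- if (is.null(mask)) H1 else H1 * mask
  H2p <- sweep(D %*% p$W2, 2L, p$b2, `+`)
  H2 <- relu(H2p)
  logits <- sweep(H2 %*% p$W3, 2L, p$b3, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(Fm = Fm, H1p = H1p, mask = mask, D = D, H2p = H2p, H2 = H2))
}

.head_backward <- function(dlogits, cache, p) {
  dW3 <- crossprod(cache$H2, dlogits)
  db3 <- colSums(dlogits)
  dH2 <- dlogits %*% t(p$W3)
  dH2p <- dH2 * (cache$H2p > 0)
  dW2 <- crossprod(cache$D, dH2p)
  db2 <- colSums(dH2p)
  dD <- dH2p %*% t(p$W2)
  dH1 <- if (is.null(cache$mask)) dD else dD * cache$mask
  dH1p <- dH1 * (cache$H1p > 0)
  dW1 <- crossprod(cache$Fm, dH1p)
  db1 <- colSums(dH1p)
  dF <- dH1p %*% t(p$W1)
  list(dF = dF, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                             W3 = dW3, b3 = db3))
}

## ---- baseline encoders ---------------------------------------------------

.rnn_forward <- function(X, p, prefix, B, T) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  units <- ncol(g("Wh"))
  Hs <- vector("list", T)
  Hprev <- matrix(0, B, units)
  XW <- sweep(X %*% g("Wx"), 2L, g("b"), `+`)
  for (t in seq_len(T)) {
    rows <- (0:(B - 1L)) * T + t
    Hprev <- tanh(XW[rows, , drop = FALSE] + Hprev %*% g("Wh"))
    Hs[[t]] <- Hprev
  }
  list(out = Hs[[T]], cache = list(Hs = Hs, X = X))
}

.rnn_backward <- function(dOut, cache, p, prefix, B, T) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  Hs <- cache$Hs; X <- cache$X
  units <- ncol(dOut)
  dWx <- matrix(0, ncol(X), units)
  dWh <- matrix(0, units, units)
  db <- rep(0, units)
  dH <- dOut
  for (t in rev(seq_len(T))) {
    rows <- (0:(B - 1L)) * T + t
    dA <- dH * (1 - Hs[[t]]^2)
    dWx <- dWx + crossprod(X[rows, , drop = FALSE], dA)
    Hprev <- if (t > 1L) Hs[[t - 1L]] else matrix(0, B, units)
    dWh <- dWh + crossprod(Hprev, dA)
    db <- db + colSums(dA)
    dH <- dA %*% t(g("Wh"))
  }
  grads <- list(Wx = dWx, Wh = dWh, b = db)
  names(grads) <- paste0(prefix, "_", names(grads))
  grads
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.lstm_forward <- function(X, p, prefix, B, T) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  units <- nrow(g("Wh"))
  Hprev <- matrix(0, B, units)
  Cprev <- matrix(0, B, units)
  XW <- sweep(X %*% g("Wx"), 2L, g("b"), `+`)
  st <- vector("list", T)
  i1 <- seq_len(units); i2 <- units + i1; i3 <- 2L * units + i1
  i4 <- 3L * units + i1
  for (t in seq_len(T)) {
    rows <- (0:(B - 1L)) * T + t
    Z <- XW[rows, , drop = FALSE] + Hprev %*% g("Wh")
    ig <- .sigmoid(Z[, i1, drop = FALSE])
    fg <- .sigmoid(Z[, i2, drop = FALSE])
    og <- .sigmoid(Z[, i3, drop = FALSE])
    cc <- tanh(Z[, i4, drop = FALSE])
    Cn <- fg * Cprev + ig * cc
    tc <- tanh(Cn)
    Hn <- og * tc
    st[[t]] <- list(ig = ig, fg = fg, og = og, cc = cc, C = Cn, tc = tc,
                    Hprev = Hprev, Cprev = Cprev)
    Hprev <- Hn; Cprev <- Cn
  }
  list(out = Hprev, cache = list(st = st, X = X, units = units))
}

.lstm_backward <- function(dOut, cache, p, prefix, B, T) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  X <- cache$X; st <- cache$st; units <- cache$units
  dWx <- matrix(0, ncol(X), 4L * units)
  dWh <- matrix(0, units, 4L * units)
  db <- rep(0, 4L * units)
  dH <- dOut
  dC <- matrix(0, nrow(dOut), units)
  i1 <- seq_len(units); i2 <- units + i1; i3 <- 2L * units + i1
  i4 <- 3L * units + i1
  for (t in rev(seq_len(T))) {
    s <- st[[t]]
    dog <- dH * s$tc
    dC <- dC + dH * s$og * (1 - s$tc^2)
    dig <- dC * s$cc
    dfg <- dC * s$Cprev
    dcc <- dC * s$ig
    dZ <- matrix(0, nrow(dH), 4L * units)
    dZ[, i1] <- dig * s$ig * (1 - s$ig)
    dZ[, i2] <- dfg * s$fg * (1 - s$fg)
    dZ[, i3] <- dog * s$og * (1 - s$og)
    dZ[, i4] <- dcc * (1 - s$cc^2)
    rows <- (0:(nrow(dH) - 1L)) * T + t
    dWx <- dWx + crossprod(X[rows, , drop = FALSE], dZ)
    dWh <- dWh + crossprod(s$Hprev, dZ)
    db <- db + colSums(dZ)
    dH <- dZ %*% t(g("Wh"))
    dC <- dC * s$fg
  }
  grads <- list(Wx = dWx, Wh = dWh, b = db)
  names(grads) <- paste0(prefix, "_", names(grads))
  grads
}

# Zero-padded within-sample time shift of a stacked (B*T) x d matrix.
.shift_rows <- function(X, o, B, T) {
  Y <- matrix(0, nrow(X), ncol(X))
  t_dest <- which(seq_len(T) + o >= 1L & seq_len(T) + o <= T)
  if (!length(t_dest)) return(Y)
  base <- rep((0:(B - 1L)) * T, each = length(t_dest))
  Y[base + t_dest, ] <- X[base + t_dest + o, ]
  Y
}

.cnn_forward <- function(X, p, prefix, B, T, kernel = 5L) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  d <- ncol(X)
  half <- (kernel - 1L) %/% 2L
  Unf <- matrix(0, nrow(X), kernel * d)
  for (k in seq_len(kernel))
    Unf[, ((k - 1L) * d + 1L):(k * d)] <- .shift_rows(X, k - 1L - half, B, T)
  Pre <- sweep(Unf %*% g("W"), 2L, g("b"), `+`)
  C <- relu(Pre)
  G <- rowsum(C, rep(seq_len(B), each = T)) / T
  list(out = G, cache = list(Unf = Unf, Pre = Pre))
}

.cnn_backward <- function(dOut, cache, p, prefix, B, T) {
  dC <- (cache$Pre > 0) * dOut[rep(seq_len(B), each = T), , drop = FALSE] / T
  grads <- list(W = crossprod(cache$Unf, dC), b = colSums(dC))
  names(grads) <- paste0(prefix, "_", names(grads))
  grads
}

## ---- full model forward / backward --------------------------------------

# Xp: (B*T) x d_p, Xv: (B*T) x d_v stacked inputs (raw model inputs;
# positional encoding is added here for Transformer kinds).
.nn_forward <- function(kind, params, cfg, Xp, Xv, B, train = FALSE) {
  T <- cfg$T
  cache <- list(kind = kind)
  if (kind %in% c("fusion", "pressure_only", "vibration_only")) {
    if (kind != "vibration_only") {
      if (is.null(Xp) || ncol(Xp) != cfg$d_p || nrow(Xp) != B * T)
        stop("pressure input must be ", T, "x", cfg$d_p, " per sample",
             call. = FALSE)
      Xp <- Xp + positional_encoding(T, cfg$d_p, cfg$pe_base)[rep(seq_len(T), B), ]
      bp <- .branch_forward(Xp, params, "p", cfg, B, train)
      cache$bp <- bp$cache
    }
    if (kind != "pressure_only") {
      if (is.null(Xv) || ncol(Xv) != cfg$d_v || nrow(Xv) != B * T)
        stop("vibration input must be ", T, "x", cfg$d_v, " per sample",
             call. = FALSE)
      Xv <- Xv + positional_encoding(T, cfg$d_v, cfg$pe_base)[rep(seq_len(T), B), , drop = FALSE]
      bv <- .branch_forward(Xv, params, "v", cfg, B, train)
      cache$bv <- bv$cache
    }
    Ycat <- switch(kind,
      fusion = cbind(bp$Y, bv$Y),
      pressure_only = bp$Y,
      vibration_only = bv$Y)
    cache$C <- ncol(Ycat)
    Fm <- .flatten_batch(Ycat, B, T)
  } else {
    if (is.null(Xp) || is.null(Xv) || ncol(Xp) != cfg$d_p || ncol(Xv) != cfg$d_v)
      stop("baseline models need both modalities at their configured widths",
           call. = FALSE)
    enc <- switch(kind,
      rnn = list(.rnn_forward(Xp, params, "p", B, T),
                 .rnn_forward(Xv, params, "v", B, T)),
      lstm = list(.lstm_forward(Xp, params, "p", B, T),
                  .lstm_forward(Xv, params, "v", B, T)),
      cnn = list(.cnn_forward(Xp, params, "p", B, T),
                 .cnn_forward(Xv, params, "v", B, T)))
    cache$enc <- list(p = enc[[1]]$cache, v = enc[[2]]$cache)
    Fm <- cbind(enc[[1]]$out, enc[[2]]$out)
  }
  hd <- .head_forward(Fm, params, cfg, train)
  cache$head <- hd$cache
  list(probs = hd$probs, cache = cache)
}

.nn_backward <- function(dlogits, cache, kind, params, cfg, B) {
  T <- cfg$T
  hb <- .head_backward(dlogits, cache$head, params)
  grads <- hb$grads
  if (kind %in% c("fusion", "pressure_only", "vibration_only")) {
    dY <- .unflatten_batch(hb$dF, B, T, cache$C)
    if (kind == "fusion") {
      grads <- c(grads,
                 .branch_backward(dY[, seq_len(cfg$d_p), drop = FALSE],
                                  cache$bp, params, "p", cfg, B),
                 .branch_backward(dY[, cfg$d_p + seq_len(cfg$d_v), drop = FALSE],
                                  cache$bv, params, "v", cfg, B))
    } else if (kind == "pressure_only") {
      grads <- c(grads, .branch_backward(dY, cache$bp, params, "p", cfg, B))
    } else {
      grads <- c(grads, .branch_backward(dY, cache$bv, params, "v", cfg, B))
    }
  } else {
    dFp <- hb$dF[, seq_len(.ENC_UNITS), drop = FALSE]
    dFv <- hb$dF[, .ENC_UNITS + seq_len(.ENC_UNITS), drop = FALSE]
    grads <- c(grads, switch(kind,
      rnn = c(.rnn_backward(dFp, cache$enc$p, params, "p", B, T),
              .rnn_backward(dFv, cache$enc$v, params, "v", B, T)),
      lstm = c(.lstm_backward(dFp, cache$enc$p, params, "p", B, T),
               .lstm_backward(dFv, cache$enc$v, params, "v", B, T)),
      cnn = c(.cnn_backward(dFp, cache$enc$p, params, "p", B, T),
              .cnn_backward(dFv, cache$enc$v, params, "v", B, T))))
  }
  grads
}

## ---- input stacking ------------------------------------------------------

# Stack a list of model_input objects into (N*T) x d matrices plus one-hot
# labels.
.stack_inputs <- function(inputs, cfg) {
  n <- length(inputs)
  if (n == 0L) stop("empty input set", call. = FALSE)
  for (x in inputs) {
    if (!all(dim(x$pressure_seq) == c(cfg$T, cfg$d_p)) ||
        !all(dim(x$vibration_seq) == c(cfg$T, cfg$d_v)))
      stop("model inputs must be ", cfg$T, "x", cfg$d_p, " and ",
           cfg$T, "x", cfg$d_v, call. = FALSE)
  }
  list(P = do.call(rbind, lapply(inputs, `[[`, "pressure_seq")),
       V = do.call(rbind, lapply(inputs, `[[`, "vibration_seq")),
       Y = do.call(rbind, lapply(inputs, `[[`, "label_onehot")),
       ids = vapply(inputs, `[[`, "", "trial_id"))
}

#' Extract per-head self-attention maps for one sample
#'
#' Runs an inference-mode forward pass (dropout disabled) and returns the
#' post-softmax attention maps of every head in every branch present in the
#' model; deterministic for fixed parameters.
#'
#' @param model A fitted [graspnet()] object or a [build_model()] result.
#' @param input A single `model_input`.
#' @return Object of class `attention_maps`: named list (per branch
#'   `pressure` / `vibration`) of lists of `T` x `T` row-stochastic
#'   matrices, one per head.
#' @export
extract_attention_maps <- function(model, input) {
  kind <- model$kind
  if (!kind %in% c("fusion", "pressure_only", "vibration_only"))
    stop("attention maps exist only for Transformer kinds", call. = FALSE)
  cfg <- model$cfg %||% model$net
  fw <- .nn_forward(kind, model$params, cfg,
                    input$pressure_seq, input$vibration_seq, 1L, train = FALSE)
  per_head <- function(A) lapply(seq_len(cfg$H), function(h) A[, , h, 1L])
  maps <- list()
  if (!is.null(fw$cache$bp)) maps$pressure <- per_head(fw$cache$bp$A)
  if (!is.null(fw$cache$bv)) maps$vibration <- per_head(fw$cache$bv$A)
  structure(maps, class = "attention_maps")
}
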