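# Minimal tape-based reverse-mode automatic differentiation on matrices.
#
# Every operation appends a node (value + parent ids + backward closure) to a
# tape; nodes are created in topological order, so the backward pass is a single
# reverse sweep.  Backward closures capture the forward intermediates they need
# (softmax weights, gate activations, dropout masks), which keeps each layer a
# single node and the R-level overhead per training step small; the heavy
# lifting is BLAS matrix products.  Gradients reach all the way back to the
# input node, which is what the saliency module differentiates.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- vector("list", 512L)
  tp
}

ad_node <- function(tp, value, parents = integer(0), backfn = NULL) {
  # force the arguments first: evaluating them may itself append nodes (ops
  # written inline as arguments), and this node must come after all of them
  force(value); force(parents); force(backfn)
  n <- tp$n + 1L
  if (n > length(tp$nodes))
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(value = value, parents = parents, backfn = backfn)
  tp$n <- n
  list(tp = tp, id = n)
}

ad_value <- function(x) x$tp$nodes[[x$id]]$value

# Reverse sweep from a scalar (1x1) root node.  Returns the full gradient list
# indexed by node id; leaf gradients are read off by id.
ad_backward <- function(root) {
  tp <- root$tp
  grads <- vector("list", tp$n)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tp$nodes[[i]]
    if (is.null(node$backfn)) next
    pg <- node$backfn(g)
    ps <- node$parents
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

ad_matmul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(a$tp, A %*% B, c(a$id, b$id),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

ad_add <- function(a, b) {
  ad_node(a$tp, ad_value(a) + ad_value(b), c(a$id, b$id),
          function(g) list(g, g))
}

# a (n x d) + bias (1 x d) broadcast over rows
ad_add_bias <- function(a, bias) {
  A <- ad_value(a); bv <- ad_value(bias)
  v <- A + rep(bv, each = nrow(A))
  ad_node(a$tp, v, c(a$id, bias$id),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_add_const <- function(a, const) {
  ad_node(a$tp, ad_value(a) + const, a$id, function(g) list(g))
}

ad_scale <- function(a, s) {
  ad_node(a$tp, ad_value(a) * s, a$id, function(g) list(g * s))
}

# a + s * b (used to combine the cross-entropy and MFCC loss terms)
ad_axpy <- function(a, b, s) {
  ad_node(a$tp, ad_value(a) + s * ad_value(b), c(a$id, b$id),
          function(g) list(g, g * s))
}

ad_relu <- function(a) {
  A <- ad_value(a)
  mask <- A > 0
  ad_node(a$tp, A * mask, a$id, function(g) list(g * mask))
}

ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_node(a$tp, v, a$id, function(g) list(g * (1 - v^2)))
}

# Inverted dropout; identity when not training or p == 0.  Consumes the R RNG,
# so training seeds make masks reproducible.
ad_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  A <- ad_value(a)
  mask <- (matrix(stats::runif(length(A)), nrow(A)) >= p) / (1 - p)
  ad_node(a$tp, A * mask, a$id, function(g) list(g * mask))
}

# Row-wise layer normalization with learned gain/offset (1 x d each).
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  A <- ad_value(a); gm <- ad_value(gamma); bt <- ad_value(beta)
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  gmr <- matrix(gm, nrow(A), d, byrow = TRUE)
  v <- xhat * gmr + matrix(bt, nrow(A), d, byrow = TRUE)
  ad_node(a$tp, v, c(a$id, gamma$id, beta$id), function(g) {
    dxhat <- g * gmr
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# Embedding lookup: rows of E (vocab x d) selected by 1-based indices.
ad_embed <- function(E, rows) {
  Ev <- ad_value(E)
  ad_node(E$tp, Ev[rows, , drop = FALSE], E$id, function(g) {
    gE <- matrix(0, nrow(Ev), ncol(Ev))
    for (k in seq_along(rows))
      gE[rows[k], ] <- gE[rows[k], ] + g[k, ]
    list(gE)
  })
}

ad_concat_cols <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  na <- ncol(A)
  ad_node(a$tp, cbind(A, B), c(a$id, b$id),
          function(g) list(g[, seq_len(na), drop = FALSE],
                           g[, -seq_len(na), drop = FALSE]))
}

# Per-block column means: a holds n_blocks equal contiguous row blocks
# (stacked segments); returns an n_blocks x d matrix of block means.
ad_block_mean <- function(a, n_blocks = 1L) {
  A <- ad_value(a)
  n <- nrow(A) %/% n_blocks
  v <- do.call(rbind, lapply(seq_len(n_blocks), function(s)
    colMeans(A[((s - 1L) * n + 1L):(s * n), , drop = FALSE])))
  ad_node(a$tp, v, a$id, function(g) {
    list(g[rep(seq_len(n_blocks), each = n), , drop = FALSE] / n)
  })
}

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - mx)
  e / rowSums(e)
}

# Multi-head attention, one fused node.  q_in provides queries; kv_in provides
# keys and values.  wq (dq x d), wk/wv (dk x d), wo (d x d); d must divide by
# n_heads.  When `n_blocks > 1`, q_in and kv_in each hold that many equal
# contiguous row blocks (stacked segments) and attention is block-diagonal:
# queries of block s attend only to keys of block s.  `causal = TRUE` adds a
# strictly-upper-triangular mask within each block (masked self-attention;
# requires equal per-block query/key counts).
ad_mha <- function(q_in, kv_in, wq, wk, wv, wo, n_heads, causal = FALSE,
                   n_blocks = 1L) {
  Xq <- ad_value(q_in); Xkv <- ad_value(kv_in)
  Wq <- ad_value(wq); Wk <- ad_value(wk)
  Wv <- ad_value(wv); Wo <- ad_value(wo)
  d <- ncol(Wq)
  stopifnot(d %% n_heads == 0L,
            nrow(Xq) %% n_blocks == 0L, nrow(Xkv) %% n_blocks == 0L)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  Mb <- nrow(Xq) %/% n_blocks; Nb <- nrow(Xkv) %/% n_blocks
  mask <- if (causal) {
    stopifnot(Mb == Nb)
    mk <- matrix(0, Mb, Nb)
    mk[upper.tri(mk)] <- -1e30
    mk
  } else NULL
  Q <- Xq %*% Wq; K <- Xkv %*% Wk; V <- Xkv %*% Wv
  att <- vector("list", n_heads * n_blocks)
  O <- matrix(0, nrow(Xq), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    for (s in seq_len(n_blocks)) {
      qr <- ((s - 1L) * Mb + 1L):(s * Mb)
      kr <- ((s - 1L) * Nb + 1L):(s * Nb)
      S <- tcrossprod(Q[qr, idx, drop = FALSE],
                      K[kr, idx, drop = FALSE]) * scale
      if (!is.null(mask)) S <- S + mask
      A <- softmax_rows(S)
      O[qr, idx] <- A %*% V[kr, idx, drop = FALSE]
      att[[(h - 1L) * n_blocks + s]] <- A
    }
  }
  out <- O %*% Wo
  ad_node(q_in$tp, out, c(q_in$id, kv_in$id, wq$id, wk$id, wv$id, wo$id),
          function(g) {
    gO <- tcrossprod(g, Wo)
    gWo <- crossprod(O, g)
    gQ <- matrix(0, nrow(Xq), d); gK <- matrix(0, nrow(Xkv), d)
    gV <- matrix(0, nrow(Xkv), d)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      for (s in seq_len(n_blocks)) {
        qr <- ((s - 1L) * Mb + 1L):(s * Mb)
        kr <- ((s - 1L) * Nb + 1L):(s * Nb)
        A <- att[[(h - 1L) * n_blocks + s]]
        gOh <- gO[qr, idx, drop = FALSE]
        gA <- tcrossprod(gOh, V[kr, idx, drop = FALSE])
        gS <- A * (gA - rowSums(gA * A))        # softmax backward, then scale
        gQ[qr, idx] <- gS %*% K[kr, idx, drop = FALSE] * scale
        gK[kr, idx] <- crossprod(gS, Q[qr, idx, drop = FALSE]) * scale
        gV[kr, idx] <- crossprod(A, gOh)
      }
    }
    list(tcrossprod(gQ, Wq),
         tcrossprod(gK, Wk) + tcrossprod(gV, Wv),
         crossprod(Xq, gQ),
         crossprod(Xkv, gK),
         crossprod(Xkv, gV),
         gWo)
  })
}

# Strided temporal convolution over the time axis with non-overlapping
# windows (kernel width == stride, as in the (12, K) kernel / (12, 1) stride
# front end).  x holds `n_seg` equal contiguous segments of length L stacked
# row-wise; each segment is zero-padded on the right so that width divides L.
# Output is (n_seg * N) x C with N = ceil(L / width), segment-major.
ad_conv_time <- function(x, w, b, width, n_seg = 1L) {
  X <- ad_value(x); W <- ad_value(w); bv <- ad_value(b)
  stopifnot(nrow(X) %% n_seg == 0L)
  L <- nrow(X) %/% n_seg; K <- ncol(X)
  stopifnot(nrow(W) == width * K)
  if (L < width) stop("input length ", L, " shorter than kernel width ", width,
                      call. = FALSE)
  N <- as.integer(ceiling(L / width))
  Lp <- N * width
  arr <- array(0, c(Lp, n_seg, K))
  arr[seq_len(L), , ] <- array(X, c(L, n_seg, K))
  # unfold: U[(s-1)*N + i, (k-1)*width + t] = segment s, sample (i-1)*width+t,
  # electrode k
  U <- matrix(aperm(array(arr, c(width, N, n_seg, K)), c(2L, 3L, 1L, 4L)),
              N * n_seg)
  out <- U %*% W + matrix(bv, N * n_seg, ncol(W), byrow = TRUE)
  ad_node(x$tp, out, c(x$id, w$id, b$id), function(g) {
    gU <- tcrossprod(g, W)
    gArr <- aperm(array(gU, c(N, n_seg, width, K)), c(3L, 1L, 2L, 4L))
    gX <- matrix(array(gArr, c(Lp, n_seg, K))[seq_len(L), , , drop = FALSE],
                 L * n_seg)
    list(gX, crossprod(U, g), matrix(colSums(g), 1L))
  })
}

# Single-layer LSTM with hidden width H over `n_seg` stacked equal-length
# sequences (x is (n_seg * T) x D, segment-major); the recurrence runs all
# segments in lockstep, one (n_seg x D) slice per time step.
# wx (D x 4H), wh (H x 4H), b (1 x 4H); gate column blocks [i | f | g | o].
# h0/c0 are optional n_seg x H nodes (e.g. an encoder summary); `reverse` runs
# the recurrence backward in time but returns outputs in forward time order.
ad_lstm <- function(x, wx, wh, b, h0 = NULL, c0 = NULL, reverse = FALSE,
                    n_seg = 1L) {
  X <- ad_value(x); Wx <- ad_value(wx); Wh <- ad_value(wh); bv <- ad_value(b)
  stopifnot(nrow(X) %% n_seg == 0L)
  Tn <- nrow(X) %/% n_seg; H <- nrow(Wh)
  row_of <- function(t) (seq_len(n_seg) - 1L) * Tn + t
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  bmat <- matrix(bv, n_seg, 4L * H, byrow = TRUE)
  h_prev <- if (is.null(h0)) matrix(0, n_seg, H) else ad_value(h0)
  c_prev <- if (is.null(c0)) matrix(0, n_seg, H) else ad_value(c0)
  Hout <- matrix(0, nrow(X), H)
  cache <- vector("list", Tn)
  for (s in seq_len(Tn)) {
    t <- steps[s]
    rw <- row_of(t)
    z <- X[rw, , drop = FALSE] %*% Wx + h_prev %*% Wh + bmat
    i_g <- 1 / (1 + exp(-z[, ii, drop = FALSE]))
    f_g <- 1 / (1 + exp(-z[, ff, drop = FALSE]))
    g_g <- tanh(z[, gg, drop = FALSE])
    o_g <- 1 / (1 + exp(-z[, oo, drop = FALSE]))
    c_t <- f_g * c_prev + i_g * g_g
    tc <- tanh(c_t)
    h_t <- o_g * tc
    Hout[rw, ] <- h_t
    cache[[s]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev, t = t)
    h_prev <- h_t; c_prev <- c_t
  }
  parents <- c(x$id, wx$id, wh$id, b$id,
               if (!is.null(h0)) h0$id, if (!is.null(c0)) c0$id)
  ad_node(x$tp, Hout, parents, function(g) {
    gX <- matrix(0, nrow(X), ncol(X))
    gWx <- matrix(0, nrow(Wx), ncol(Wx))
    gWh <- matrix(0, H, 4L * H)
    gb <- matrix(0, 1L, 4L * H)
    dh <- matrix(0, n_seg, H); dc <- matrix(0, n_seg, H)
    for (s in rev(seq_len(Tn))) {
      cc <- cache[[s]]
      rw <- row_of(cc$t)
      dht <- g[rw, , drop = FALSE] + dh
      do <- dht * cc$tc
      dct <- dht * cc$o * (1 - cc$tc^2) + dc
      di <- dct * cc$g
      df <- dct * cc$c_prev
      dg <- dct * cc$i
      dz <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do * cc$o * (1 - cc$o))
      gWx <- gWx + crossprod(X[rw, , drop = FALSE], dz)
      gWh <- gWh + crossprod(cc$h_prev, dz)
      gb <- gb + colSums(dz)
      gX[rw, ] <- dz %*% t(Wx)
      dh <- dz %*% t(Wh)
      dc <- dct * cc$f
    }
    out <- list(gX, gWx, gWh, gb)
    if (!is.null(h0)) out <- c(out, list(dh))
    if (!is.null(c0)) out <- c(out, list(dc))
    out
  })
}

# Mean categorical cross-entropy of row-wise logits against 1-based class ids.
ad_ce <- function(logits, targets) {
  Z <- ad_value(logits)
  M <- nrow(Z)
  stopifnot(length(targets) == M)
  P <- softmax_rows(Z)
  picked <- P[cbind(seq_len(M), targets)]
  v <- matrix(-mean(log(pmax(picked, 1e-12))), 1L, 1L)
  ad_node(logits$tp, v, logits$id, function(g) {
    G <- P
    G[cbind(seq_len(M), targets)] <- G[cbind(seq_len(M), targets)] - 1
    list(G * (g[1L] / M))
  })
}

# Summed log-probability of the target tokens (the scalar the saliency module
# differentiates with respect to the input features).
ad_logprob_sum <- function(logits, targets) {
  Z <- ad_value(logits)
  M <- nrow(Z)
  P <- softmax_rows(Z)
  picked <- P[cbind(seq_len(M), targets)]
  v <- matrix(sum(log(pmax(picked, 1e-12))), 1L, 1L)
  ad_node(logits$tp, v, logits$id, function(g) {
    G <- -P
    G[cbind(seq_len(M), targets)] <- G[cbind(seq_len(M), targets)] + 1
    list(G * g[1L])
  })
}

# Mean squared error against a constant target matrix.
ad_mse <- function(pred, target) {
  Pv <- ad_value(pred)
  stopifnot(all(dim(Pv) == dim(target)))
  diff <- Pv - target
  v <- matrix(mean(diff^2), 1L, 1L)
  ad_node(pred$tp, v, pred$id,
          function(g) list(diff * (2 * g[1L] / length(diff))))
}
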