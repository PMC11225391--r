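# Minimal GRU language-model core: parameter init, teacher-forced forward,
# backpropagation through time, and Adam. Written against base-R matrix
# algebra; batch-major (B x H) states.
#
# Gate layout in the fused 3H matrices: [reset | update | candidate].
# Recurrence (per layer):
#   a_r = x W_r + b_r + h U_r          r = sigmoid(a_r)
#   a_z = x W_z + b_z + h U_z          z = sigmoid(a_z)
#   a_n = x W_n + b_n + r * (h U_n)    n = tanh(a_n)
#   h'  = (1 - z) * n + z * h
# The bias sits on the input side only; gradients are verified against
# numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init <- function(vocab_size, emb = 64L, hidden = 128L, layers = 1L) {
  rmat <- function(nr, nc) {
    a <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -a, a), nr, nc)
  }
  P <- list(
    Emb = rmat(vocab_size, emb),
    Wout = rmat(hidden, vocab_size),
    bout = numeric(vocab_size),
    layers = lapply(seq_len(layers), function(l) {
      ind <- if (l == 1L) emb else hidden
      list(W = rmat(ind, 3L * hidden), U = rmat(hidden, 3L * hidden),
           b = numeric(3L * hidden))
    })
  )
  attr(P, "arch") <- list(vocab_size = vocab_size, emb = emb,
                          hidden = hidden, layers = layers)
  P
}

# one recurrent step for a batch of token ids; hs: list of B x H states.
# Returns list(hs, logits, cache) — cache only when requested.
nn_step <- function(P, tok, hs, want_cache = FALSE) {
  H <- ncol(hs[[1]])
  ri <- seq_len(H); zi <- H + ri; ni <- 2L * H + ri
  x <- P$Emb[tok, , drop = FALSE]
  caches <- if (want_cache) vector("list", length(P$layers)) else NULL
  for (l in seq_along(P$layers)) {
    L <- P$layers[[l]]
    h <- hs[[l]]
    gx <- x %*% L$W
    gx <- sweep(gx, 2L, L$b, "+")
    gh <- h %*% L$U
    r <- sigmoid(gx[, ri, drop = FALSE] + gh[, ri, drop = FALSE])
    z <- sigmoid(gx[, zi, drop = FALSE] + gh[, zi, drop = FALSE])
    ghn <- gh[, ni, drop = FALSE]
    n <- tanh(gx[, ni, drop = FALSE] + r * ghn)
    hnew <- (1 - z) * n + z * h
    if (want_cache) caches[[l]] <- list(x = x, h_prev = h, r = r, z = z,
                                        n = n, ghn = ghn)
    hs[[l]] <- hnew
    x <- hnew
  }
  logits <- sweep(x %*% P$Wout, 2L, P$bout, "+")
  list(hs = hs, logits = logits, cache = caches)
}

row_log_softmax <- function(logits) {
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  sh <- logits - mx
  sh - log(rowSums(exp(sh)))
}

# Teacher-forced pass over batch matrix X (B x T of ids, PAD-padded).
# mask[, t] marks a real prediction target at X[, t + 1].
# Returns per-sequence NLL (nats) and, optionally, the BPTT caches.
nn_forward <- function(P, X, pad_id, want_cache = FALSE) {
  B <- nrow(X); Tm <- ncol(X)
  H <- attr(P, "arch")$hidden
  hs <- rep(list(matrix(0, B, H)), length(P$layers))
  nll <- numeric(B)
  steps <- vector("list", if (want_cache) Tm - 1L else 0L)
  tok_lp <- matrix(0, B, max(Tm - 1L, 0L))
  for (t in seq_len(Tm - 1L)) {
    tok <- X[, t]
    tgt <- X[, t + 1L]
    m <- tgt != pad_id & tok != pad_id
    st <- nn_step(P, tok, hs, want_cache = want_cache)
    hs <- st$hs
    lp <- row_log_softmax(st$logits)
    lpt <- lp[cbind(seq_len(B), tgt)]
    nll <- nll - ifelse(m, lpt, 0)
    tok_lp[, t] <- ifelse(m, lpt, 0)
    if (want_cache) {
      steps[[t]] <- list(cache = st$cache, logp = lp, tok = tok, tgt = tgt, mask = m)
    }
  }
  list(nll = nll, steps = steps, tok_logp = tok_lp)
}

zeros_like <- function(P) {
  G <- list(Emb = P$Emb * 0, Wout = P$Wout * 0, bout = P$bout * 0,
            layers = lapply(P$layers, function(L)
              list(W = L$W * 0, U = L$U * 0, b = L$b * 0)))
  attr(G, "arch") <- attr(P, "arch")
  G
}

# BPTT. seq_w: per-sequence weight on its token NLL terms (use 1/B/ntok for
# mean-CE pre-training; use the REINVENT residual weights for RL).
# tok_w: optional B x (T-1) extra per-token weights (prompt masking).
nn_backward <- function(P, fw, X, pad_id, seq_w, tok_w = NULL) {
  B <- nrow(X); Tm <- ncol(X)
  arch <- attr(P, "arch")
  H <- arch$hidden
  nl <- length(P$layers)
  ri <- seq_len(H); zi <- H + ri; ni <- 2L * H + ri
  G <- zeros_like(P)
  dh_next <- rep(list(matrix(0, B, H)), nl)
  for (t in (Tm - 1L):1L) {
    st <- fw$steps[[t]]
    w <- seq_w * st$mask
    if (!is.null(tok_w)) w <- w * tok_w[, t]
    probs <- exp(st$logp)
    dlogits <- probs * w
    dlogits[cbind(seq_len(B), st$tgt)] <- dlogits[cbind(seq_len(B), st$tgt)] - w
    # top state gradient
    htop <- st$cache[[nl]]
    h_top_val <- (1 - htop$z) * htop$n + htop$z * htop$h_prev
    G$Wout <- G$Wout + crossprod(h_top_val, dlogits)
    G$bout <- G$bout + colSums(dlogits)
    dx_above <- dlogits %*% t(P$Wout)
    for (l in nl:1L) {
      cc <- st$cache[[l]]
      dh <- dh_next[[l]] + dx_above
      dn <- dh * (1 - cc$z)
      dz <- dh * (cc$h_prev - cc$n)
      dhp <- dh * cc$z
      dan <- dn * (1 - cc$n^2)
      dr <- dan * cc$ghn
      dghn <- dan * cc$r
      dar <- dr * cc$r * (1 - cc$r)
      daz <- dz * cc$z * (1 - cc$z)
      dgx <- cbind(dar, daz, dan)
      dgh <- cbind(dar, daz, dghn)
      L <- P$layers[[l]]
      G$layers[[l]]$W <- G$layers[[l]]$W + crossprod(cc$x, dgx)
      G$layers[[l]]$U <- G$layers[[l]]$U + crossprod(cc$h_prev, dgh)
      G$layers[[l]]$b <- G$layers[[l]]$b + colSums(dgx)
      dhp <- dhp + dgh %*% t(L$U)
      dx <- dgx %*% t(L$W)
      dh_next[[l]] <- dhp
      dx_above <- dx  # feeds layer below (or the embedding at l == 1)
    }
    # scatter-add embedding gradients for this step
    ids <- st$tok
    agg <- rowsum(dx_above, group = ids)
    uid <- as.integer(rownames(agg))
    G$Emb[uid, ] <- G$Emb[uid, ] + agg
  }
  G
}

adam_init <- function(P) list(m = zeros_like(P), v = zeros_like(P), t = 0L)

adam_update <- function(P, G, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (nm in c("Emb", "Wout", "bout")) {
    u <- upd(P[[nm]], G[[nm]], state$m[[nm]], state$v[[nm]])
    P[[nm]] <- u$p; state$m[[nm]] <- u$m; state$v[[nm]] <- u$v
  }
  for (l in seq_along(P$layers)) {
    for (nm in c("W", "U", "b")) {
      u <- upd(P$layers[[l]][[nm]], G$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      P$layers[[l]][[nm]] <- u$p
      state$m$layers[[l]][[nm]] <- u$m
      state$v$layers[[l]][[nm]] <- u$v
    }
  }
  list(P = P, state = state)
}
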