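# E(3)-equivariant graph network noise predictor.
#
# Rotation equivariance of the coordinate head comes from predicting each
# cloud node's coordinate noise as a sum of scaled difference vectors
# (x_i - x_j) over its graph neighbours, with scalar edge weights computed
# from rotation-invariant quantities (squared distances, node features,
# time). Translation is handled by expressing all coordinates in the
# pocket-centered frame. Gradients are derived analytically and verified
# against numerical differentiation in the test suite.

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' Denoiser hyperparameter configuration
#'
#' @param cutoff Radius-graph cutoff in Angstrom for cloud-pocket edges
#'   (default 6); cloud-cloud nodes are always fully connected.
#' @param hidden_dim Hidden width (default 256).
#' @param n_layers Number of message-passing layers (default 5).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 16).
#' @param grad_clip Global gradient-norm bound (default 1).
#' @param seed Integer seed controlling initialization and training order.
#' @return An object of class `denoiser_config`.
#' @export
denoiser_config <- function(cutoff = 6, hidden_dim = 256, n_layers = 5,
                            lr = 1e-4, batch_size = 16, grad_clip = 1,
                            seed = 1) {
  stopifnot(cutoff > 0, hidden_dim > 0, n_layers > 0, lr > 0,
            batch_size > 0, grad_clip > 0)
  structure(list(cutoff = cutoff, hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers), lr = lr,
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 seed = as.integer(seed)), class = "denoiser_config")
}

# parameter initialization (He-style scaling), deterministic under the
# caller's RNG state
egnn_init <- function(din, h, L) {
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
  layers <- lapply(seq_len(L), function(l) list(
    W1 = mk(2 * h + 1, h), b1 = numeric(h),
    W2 = mk(h, h),         b2 = numeric(h),
    wx = mk(h, 1) * 0.1,   bx = 0,
    Wh = mk(2 * h, h),     bh = numeric(h)
  ))
  list(W_emb = mk(din, h), b_emb = numeric(h),
       W_out = mk(h, 8), b_out = numeric(8),
       layers = layers)
}

# Build the edge list for one graph: every ordered cloud-cloud pair plus
# pocket sources within `cutoff` of each cloud node. Pocket edges carry a
# smooth cosine envelope that vanishes at the cutoff, so the model's output
# is a continuous function of geometry (an edge entering or leaving the
# radius graph contributes nothing at the boundary).
egnn_edges <- function(Xc, Xp, cutoff) {
  nc <- nrow(Xc); np <- nrow(Xp)
  dst <- integer(0); src <- integer(0)
  if (nc > 1) {
    g <- expand.grid(i = seq_len(nc), j = seq_len(nc))
    g <- g[g$i != g$j, ]
    dst <- g$i; src <- g$j
  }
  if (np > 0) {
    d2 <- outer(rowSums(Xc^2), rowSums(Xp^2), `+`) - 2 * Xc %*% t(Xp)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      dst <- c(dst, hit[, 1])
      src <- c(src, nc + hit[, 2])
    }
  }
  E <- length(dst)
  Xall <- rbind(Xc, Xp)
  if (E > 0) {
    diff <- Xall[dst, , drop = FALSE] - Xall[src, , drop = FALSE]
    d2 <- rowSums(diff^2)
    u <- diff / (sqrt(d2) + 1)
    env <- rep(1, E)
    pe <- src > nc  # pocket-source edges are the cutoff-selected ones
    if (any(pe)) {
      # smooth switch active only over the outer quarter of the radius:
      # full weight below 0.75*cutoff, cosine decay to zero at the cutoff
      x <- pmin(sqrt(d2[pe]) / cutoff, 1)
      s <- pmax((x - 0.75) / 0.25, 0)
      env[pe] <- ((cos(pi * s) + 1) / 2)^2
    }
  } else {
    diff <- matrix(0, 0, 3); d2 <- numeric(0); u <- matrix(0, 0, 3)
    env <- numeric(0)
  }
  agg_dst <- matrix(0, nc, E)
  if (E > 0) agg_dst[cbind(dst, seq_len(E))] <- 1
  agg_all <- matrix(0, nc + np, E)
  if (E > 0) agg_all[cbind(src, seq_len(E))] <- 1
  list(dst = dst, src = src, E = E, d2 = d2, u = u, env = env,
       agg_dst = agg_dst, agg_src = agg_all)
}

# Forward pass. Xc: cloud coords (Angstrom, pocket-centered), Hc_in: n_c x 8
# noisy features; Xp/Fp: pocket coords and one-hot features; tt in [0,1].
# Returns eps_x (n_c x 3), eps_h (n_c x 8) and, if cache=TRUE, the
# intermediate activations needed for the backward pass.
egnn_forward <- function(params, Xc, Hc_in, Xp, Fp, tt, cutoff,
                         cache = FALSE) {
  nc <- nrow(Xc); np <- nrow(Xp)
  h <- ncol(params$W_emb)
  In_c <- cbind(Hc_in, matrix(0, nc, ncol(Fp)), 1, 0, tt)
  In_p <- cbind(matrix(0, np, 8), Fp, 0, 1, tt)
  H0c <- In_c %*% params$W_emb +
    matrix(params$b_emb, nc, h, byrow = TRUE)
  H0p <- In_p %*% params$W_emb +
    matrix(params$b_emb, np, h, byrow = TRUE)

  ed <- egnn_edges(Xc, Xp, cutoff)
  Hc <- H0c
  eps_x <- matrix(0, nc, 3)
  caches <- if (cache) vector("list", length(params$layers)) else NULL

  for (l in seq_along(params$layers)) {
    P <- params$layers[[l]]
    Hall <- rbind(Hc, H0p)
    if (ed$E > 0) {
      e_in <- cbind(Hall[ed$dst, , drop = FALSE],
                    Hall[ed$src, , drop = FALSE], ed$d2 / cutoff^2)
      pre1 <- e_in %*% P$W1 + matrix(P$b1, ed$E, h, byrow = TRUE)
      a1 <- silu(pre1)
      pre2 <- a1 %*% P$W2 + matrix(P$b2, ed$E, h, byrow = TRUE)
      M <- silu(pre2)
      wpre <- as.numeric(M %*% P$wx) + P$bx
      w <- tanh(wpre)
      eps_x <- eps_x + ed$agg_dst %*% (ed$u * (w * ed$env))
      A <- ed$agg_dst %*% (M * ed$env)
    } else {
      e_in <- pre1 <- a1 <- pre2 <- M <- matrix(0, 0, h)
      wpre <- w <- numeric(0)
      A <- matrix(0, nc, h)
    }
    cat_ <- cbind(Hc, A)
    hpre <- cat_ %*% P$Wh + matrix(P$bh, nc, h, byrow = TRUE)
    Hc_new <- Hc + silu(hpre)
    if (cache) {
      caches[[l]] <- list(e_in = e_in, pre1 = pre1, a1 = a1, pre2 = pre2,
                          M = M, wpre = wpre, w = w, cat_ = cat_,
                          hpre = hpre, Hc_entry = Hc)
    }
    Hc <- Hc_new
  }
  eps_h <- Hc %*% params$W_out + matrix(params$b_out, nc, 8, byrow = TRUE)
  out <- list(eps_x = eps_x, eps_h = eps_h)
  if (cache) {
    out$cache <- list(layers = caches, edges = ed, In_c = In_c, In_p = In_p,
                      Hc_final = Hc, nc = nc, np = np)
  }
  out
}

# Backward pass: gradients of a scalar loss wrt all parameters, given the
# loss gradients wrt the two heads. Returns a params-shaped list.
egnn_backward <- function(params, fwd, d_eps_x, d_eps_h) {
  ck <- fwd$cache
  ed <- ck$edges
  h <- ncol(params$W_emb)
  nc <- ck$nc; np <- ck$np
  L <- length(params$layers)

  g <- list(W_emb = matrix(0, nrow(params$W_emb), h), b_emb = numeric(h),
            W_out = t(ck$Hc_final) %*% d_eps_h,
            b_out = colSums(d_eps_h),
            layers = vector("list", L))
  dHc <- d_eps_h %*% t(params$W_out)
  dH0p <- matrix(0, np, h)

  for (l in rev(seq_len(L))) {
    P <- params$layers[[l]]
    C <- ck$layers[[l]]
    dhpre <- silu_grad(C$hpre) * dHc
    gWh <- t(C$cat_) %*% dhpre
    gbh <- colSums(dhpre)
    dcat <- dhpre %*% t(P$Wh)
    dHc_prev <- dHc + dcat[, seq_len(h), drop = FALSE]
    dA <- dcat[, h + seq_len(h), drop = FALSE]

    if (ed$E > 0) {
      dM <- (t(ed$agg_dst) %*% dA) * ed$env
      # coordinate path
      dw <- rowSums(ed$u * d_eps_x[ed$dst, , drop = FALSE]) * ed$env
      dwpre <- (1 - C$w^2) * dw
      gwx <- t(C$M) %*% matrix(dwpre, ncol = 1)
      gbx <- sum(dwpre)
      dM <- dM + matrix(dwpre, ncol = 1) %*% t(P$wx)
      # message MLP
      dpre2 <- silu_grad(C$pre2) * dM
      gW2 <- t(C$a1) %*% dpre2
      gb2 <- colSums(dpre2)
      da1 <- dpre2 %*% t(P$W2)
      dpre1 <- silu_grad(C$pre1) * da1
      gW1 <- t(C$e_in) %*% dpre1
      gb1 <- colSums(dpre1)
      de_in <- dpre1 %*% t(P$W1)
      # scatter edge-input grads back to entry node embeddings
      d_by_dst <- ed$agg_dst %*% de_in[, seq_len(h), drop = FALSE]
      d_by_src <- ed$agg_src %*% de_in[, h + seq_len(h), drop = FALSE]
      dHc_prev <- dHc_prev + d_by_dst + d_by_src[seq_len(nc), , drop = FALSE]
      if (np > 0)
        dH0p <- dH0p + d_by_src[nc + seq_len(np), , drop = FALSE]
    } else {
      gwx <- matrix(0, h, 1); gbx <- 0
      gW1 <- matrix(0, 2 * h + 1, h); gb1 <- numeric(h)
      gW2 <- matrix(0, h, h); gb2 <- numeric(h)
    }
    g$layers[[l]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                          wx = gwx, bx = gbx, Wh = gWh, bh = gbh)
    dHc <- dHc_prev
  }
  g$W_emb <- t(ck$In_c) %*% dHc + t(ck$In_p) %*% dH0p
  g$b_emb <- colSums(dHc) + colSums(dH0p)
  g
}

# --- flat parameter utilities (Adam, clipping, determinism checks) -------

params_flatten <- function(p) {
  unlist(list(p$W_emb, p$b_emb, p$W_out, p$b_out,
              lapply(p$layers, function(l)
                list(l$W1, l$b1, l$W2, l$b2, l$wx, l$bx, l$Wh, l$bh))),
         use.names = FALSE)
}

params_map2 <- function(a, b, f) {
  # elementwise combine two params-shaped lists
  out <- a
  out$W_emb <- f(a$W_emb, b$W_emb); out$b_emb <- f(a$b_emb, b$b_emb)
  out$W_out <- f(a$W_out, b$W_out); out$b_out <- f(a$b_out, b$b_out)
  for (l in seq_along(a$layers)) {
    for (nm in names(a$layers[[l]])) {
      out$layers[[l]][[nm]] <- f(a$layers[[l]][[nm]], b$layers[[l]][[nm]])
    }
  }
  out
}

params_map <- function(a, f) params_map2(a, a, function(x, y) f(x))

params_zero <- function(p) params_map(p, function(x) x * 0)

grad_global_norm <- function(g) sqrt(sum(params_flatten(g)^2))

# one Adam update; state holds first/second moments and step count
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m +
                           (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v +
                           (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = params_map2(params, upd, `-`), state = state)
}

adam_init <- function(params) {
  list(m = params_zero(params), v = params_zero(params), t = 0)
}
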