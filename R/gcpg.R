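# Pharmacophore-conditioned, property-gated SMILES generator.
#
# A latent-variable conditional sequence model: a pharmacophore-graph
# encoder and a per-property gating embedding form the combined condition
# c_com; a recognition network q(z | c_com, x) gives a Gaussian posterior
# over the latent z (prior N(0, I)); an autoregressive decoder with a
# sliding token-context window predicts the next SMILES token from
# (context, z, c_com); and a mapping head predicts which decoder position
# realizes each pharmacophore node. Training minimizes KL + language-model
# + mapping losses. All gradients are analytic (verified numerically in the
# test suite) and updates use Adam with decoupled weight decay and cyclic
# cosine annealing.

.gate_channels <- c("MW", "LogP", "QED", "SAS", "RotBonds", "TPSA",
                    "DockScore")

#' Generator hyperparameter configuration
#'
#' @param hidden_dim Decoder/recognition hidden width (default 384).
#' @param n_blocks Number of decoder blocks; blocks beyond the first are
#'   residual (default 8).
#' @param latent_dim Latent dimension (default 32).
#' @param emb_dim Token/pharmacophore embedding dimension (default 64).
#' @param lr Adam learning rate (default 3e-4).
#' @param weight_decay Decoupled weight decay (default 1e-6).
#' @param batch_size Minibatch size (default 32).
#' @param seed RNG seed.
#' @param infill_rate Feature-subset noise rate for training hypotheses
#'   (default 0.5; 0 = deterministic full feature set).
#' @param gate_open_prob Probability that each property gate is open for a
#'   training example (default 0.5).
#' @param max_len Maximum decode length in tokens (default 128).
#' @param temperature Sampling temperature (default 1).
#' @param kl_warmup Fraction of training steps over which the KL weight
#'   ramps linearly from 0 to 1 (default 0.1).
#' @param context Length of the decoder's token-context window (default 8).
#' @return Object of class `gcpg_config`.
#' @export
gcpg_config <- function(hidden_dim = 384, n_blocks = 8, latent_dim = 32,
                        emb_dim = 64, lr = 3e-4, weight_decay = 1e-6,
                        batch_size = 32, seed = 1, infill_rate = 0.5,
                        gate_open_prob = 0.5, max_len = 128,
                        temperature = 1, kl_warmup = 0.1, context = 8) {
  stopifnot(hidden_dim > 0, n_blocks > 0, latent_dim > 0, emb_dim > 0,
            lr > 0, infill_rate >= 0, infill_rate <= 1, context >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_blocks = as.integer(n_blocks),
                 latent_dim = as.integer(latent_dim),
                 emb_dim = as.integer(emb_dim), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), infill_rate = infill_rate,
                 gate_open_prob = gate_open_prob,
                 max_len = as.integer(max_len), temperature = temperature,
                 kl_warmup = kl_warmup, context = as.integer(context)),
            class = "gcpg_config")
}

#' Construct a gating condition
#'
#' The per-property conditioning channels of the generator. Channels named
#' in `...` are open and carry the given target value; all other channels
#' are closed (the model then uses a learned unconditional embedding for
#' them).
#'
#' @param ... Named numeric values for open channels, e.g. `MW = 400,
#'   QED = 0.6`. Valid names: MW, LogP, QED, SAS, RotBonds, TPSA, DockScore.
#' @return Object of class `gating_condition`.
#' @export
#' @examples
#' gating_condition(MW = 400, LogP = 3, QED = 0.6, SAS = 2)
gating_condition <- function(...) {
  vals <- list(...)
  if (length(vals) > 0 &&
      (is.null(names(vals)) || any(names(vals) == "")))
    stop("All open channels must be named")
  bad <- setdiff(names(vals), .gate_channels)
  if (length(bad) > 0)
    stop("Unknown gating channel(s): ", paste(bad, collapse = ", "),
         ". Valid channels: ", paste(.gate_channels, collapse = ", "))
  gate <- stats::setNames(rep("closed", length(.gate_channels)),
                          .gate_channels)
  value <- stats::setNames(rep(NA_real_, length(.gate_channels)),
                           .gate_channels)
  for (nm in names(vals)) {
    gate[nm] <- "open"
    value[nm] <- as.numeric(vals[[nm]])
  }
  structure(list(gate = gate, value = value), class = "gating_condition")
}

#' @export
print.gating_condition <- function(x, ...) {
  open <- names(x$gate)[x$gate == "open"]
  if (length(open) == 0) {
    cat("<gating_condition> all channels closed\n")
  } else {
    cat("<gating_condition>",
        paste(sprintf("%s=%g", open, x$value[open]), collapse = ", "),
        "| closed:", paste(setdiff(.gate_channels, open), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# ---- parameter initialization -------------------------------------------

gcpg_init <- function(V, cfg) {
  E <- cfg$emb_dim; H <- cfg$hidden_dim; Z <- cfg$latent_dim
  K <- cfg$context; C <- length(.gate_channels)
  Din <- K * E + Z + 2 * E
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
  dec <- vector("list", cfg$n_blocks)
  dec[[1]] <- list(W = mk(Din, H), b = numeric(H))
  if (cfg$n_blocks > 1) {
    for (l in 2:cfg$n_blocks) dec[[l]] <- list(W = mk(H, H), b = numeric(H))
  }
  list(
    Temb = mk(V, E),
    Wp1 = mk(11, E), bp1 = numeric(E), Wp2 = mk(E, E), bp2 = numeric(E),
    Wv = mk(C, E), Bv = mk(C, E) * 0, Nv = mk(C, E),
    Wr1 = mk(3 * E + 1, H), br1 = numeric(H),
    Wmu = mk(H, Z), bmu = numeric(Z),
    Wlv = mk(H, Z) * 0.1, blv = numeric(Z),
    dec = dec,
    Wout = mk(H, V), bout = numeric(V),
    Wmap = mk(H, E), none_vec = stats::rnorm(E, 0, 0.1),
    empty_node = stats::rnorm(E, 0, 0.1)
  )
}

# flatten/zero/map2 over the gcpg parameter tree (named recursive walk)
.walk2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- .walk2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}
gcpg_zero <- function(p) .walk2(p, p, function(x, y) x * 0)
gcpg_flat <- function(p) unlist(p, use.names = FALSE)

gcpg_adam_init <- function(p) list(m = gcpg_zero(p), v = gcpg_zero(p), t = 0)

gcpg_adam_step <- function(params, grads, state, lr, wd = 0,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- .walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .walk2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- .walk2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .walk2(params, upd, `-`)
  if (wd > 0) params <- .walk2(params, params, function(x, y) x - lr * wd * x)
  list(params = params, state = state)
}

# ---- condition encoders --------------------------------------------------

# pharm-graph node features: one-hot category + (mean, min, max)/10 of the
# node's distances to the other nodes
.phar_node_feats <- function(phar) {
  k <- length(phar$nodes)
  oh <- matrix(0, k, 8)
  oh[cbind(seq_len(k), category_index(phar$nodes) + 1L)] <- 1
  if (k > 1) {
    ds <- t(vapply(seq_len(k), function(i) {
      d <- phar$edge_dist[i, -i]
      c(mean(d), min(d), max(d)) / 10
    }, numeric(3)))
  } else ds <- matrix(0, 1, 3)
  cbind(oh, ds)
}

# forward the condition path; returns cache for backward
.cond_forward <- function(params, phar, gating, prop_stats) {
  nf <- .phar_node_feats(phar)
  pre1 <- nf %*% params$Wp1 +
    matrix(params$bp1, nrow(nf), ncol(params$Wp1), byrow = TRUE)
  a1 <- silu(pre1)
  node_emb <- a1 %*% params$Wp2 +
    matrix(params$bp2, nrow(nf), ncol(params$Wp2), byrow = TRUE)
  m_phar <- colMeans(node_emb)
  C <- length(.gate_channels)
  vnorm <- numeric(C)
  open <- gating$gate == "open"
  for (c in which(open)) {
    st <- prop_stats[[.gate_channels[c]]]
    vnorm[c] <- (gating$value[c] - st["mean"]) / st["sd"]
  }
  gmat <- params$Nv
  for (c in which(open))
    gmat[c, ] <- params$Wv[c, ] * vnorm[c] + params$Bv[c, ]
  c_gate <- colSums(gmat)
  list(nf = nf, pre1 = pre1, a1 = a1, node_emb = node_emb,
       m_phar = m_phar, c_gate = c_gate, c_com = c(m_phar, c_gate),
       open = open, vnorm = vnorm, k = nrow(nf))
}

# backward through the condition path; d_m_phar, d_c_gate, d_node_emb are
# accumulated grads; writes into g (params-shaped gradient tree)
.cond_backward <- function(params, cc, g, d_m_phar, d_c_gate,
                           d_node_emb = NULL) {
  k <- cc$k
  dne <- matrix(d_m_phar / k, k, length(d_m_phar), byrow = TRUE)
  if (!is.null(d_node_emb)) dne <- dne + d_node_emb
  g$Wp2 <- g$Wp2 + t(cc$a1) %*% dne
  g$bp2 <- g$bp2 + colSums(dne)
  da1 <- dne %*% t(params$Wp2)
  dpre1 <- silu_grad(cc$pre1) * da1
  g$Wp1 <- g$Wp1 + t(cc$nf) %*% dpre1
  g$bp1 <- g$bp1 + colSums(dpre1)
  for (c in seq_along(cc$open)) {
    if (cc$open[c]) {
      g$Wv[c, ] <- g$Wv[c, ] + d_c_gate * cc$vnorm[c]
      g$Bv[c, ] <- g$Bv[c, ] + d_c_gate
    } else {
      g$Nv[c, ] <- g$Nv[c, ] + d_c_gate
    }
  }
  g
}

# ---- example preparation -------------------------------------------------

# is a token an atom token?
.is_atom_token <- function(tok) {
  grepl("^(\\[|Cl$|Br$|[BCNOPSFIbcnops]$)", tok)
}

# Prepare one training example: hypothesis graph, encoded target sequence,
# gating condition, mapping targets. `props` is the molecule's property row.
gcpg_prepare <- function(smiles, vocab, cfg, props, open_mask = NULL,
                         dock_score = NA_real_) {
  tp <- mol_to_training_pair(smiles, infill_rate = cfg$infill_rate)
  if (is.null(tp)) return(NULL)
  ids <- encode_tokens(tp$tokens, vocab)
  if (length(ids) + 1 > cfg$max_len) return(NULL)
  C <- length(.gate_channels)
  if (is.null(open_mask))
    open_mask <- stats::runif(C) < cfg$gate_open_prob
  vals <- c(props$MW, props$LogP, props$QED, props$SAS, props$RotBonds,
            props$TPSA, dock_score)
  open_mask[is.na(vals)] <- FALSE
  args <- as.list(vals[open_mask])
  names(args) <- .gate_channels[open_mask]
  gating <- do.call(gating_condition, args)
  atom_pos <- which(.is_atom_token(tp$tokens))
  if (length(atom_pos) != tp$n_atoms) {
    message("Skipping molecule with token/atom order mismatch: ", smiles)
    return(NULL)
  }
  list(phar = tp$phar, ids = ids, gating = gating, mapping = tp$mapping,
       n_atoms = tp$n_atoms, atom_pos = atom_pos)
}

# ---- forward / backward over one example ---------------------------------

# softmax rows
.softmax <- function(x) {
  x <- x - apply(x, 1, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

# forward pass; z_eps: latent noise draw (Z). Returns losses and cache.
gcpg_forward <- function(params, ex, z_eps, cfg, vocab, prop_stats,
                         kl_weight = 1) {
  E <- cfg$emb_dim; Z <- cfg$latent_dim; K <- cfg$context
  V <- vocab$size
  bos <- match("<bos>", vocab$tokens); eos <- match("<eos>", vocab$tokens)
  cc <- .cond_forward(params, ex$phar, ex$gating, prop_stats)

  ids <- ex$ids
  target <- c(ids, eos)
  T1 <- length(target)
  hist <- c(rep(bos, K), ids)
  Ctx <- t(vapply(seq_len(T1), function(t) hist[t:(t + K - 1)], integer(K)))

  # recognition
  bag <- colMeans(params$Temb[ids, , drop = FALSE])
  rin <- c(bag, length(ids) / cfg$max_len, cc$c_com)
  rpre <- as.numeric(rin %*% params$Wr1) + params$br1
  ra <- silu(rpre)
  mu <- as.numeric(ra %*% params$Wmu) + params$bmu
  lv <- as.numeric(ra %*% params$Wlv) + params$blv
  lv <- pmin(pmax(lv, -8), 8)
  z <- mu + exp(0.5 * lv) * z_eps
  kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv)

  # decoder
  Din <- cbind(
    do.call(cbind, lapply(seq_len(K), function(k)
      params$Temb[Ctx[, k], , drop = FALSE])),
    matrix(z, T1, Z, byrow = TRUE),
    matrix(cc$c_com, T1, 2 * E, byrow = TRUE))
  hs <- vector("list", cfg$n_blocks)
  pres <- vector("list", cfg$n_blocks)
  pres[[1]] <- Din %*% params$dec[[1]]$W +
    matrix(params$dec[[1]]$b, T1, cfg$hidden_dim, byrow = TRUE)
  hs[[1]] <- silu(pres[[1]])
  if (cfg$n_blocks > 1) {
    for (l in 2:cfg$n_blocks) {
      pres[[l]] <- hs[[l - 1]] %*% params$dec[[l]]$W +
        matrix(params$dec[[l]]$b, T1, cfg$hidden_dim, byrow = TRUE)
      hs[[l]] <- hs[[l - 1]] + silu(pres[[l]])
    }
  }
  hB <- hs[[cfg$n_blocks]]
  logits <- hB %*% params$Wout + matrix(params$bout, T1, V, byrow = TRUE)
  probs <- .softmax(logits)
  lm <- -mean(log(pmax(probs[cbind(seq_len(T1), target)], 1e-12)))

  # mapping head: node embeddings vs decoder hiddens at atom positions
  np <- nrow(ex$mapping)
  k <- cc$k
  node_mat <- if (np > k) {
    rbind(cc$node_emb, matrix(params$empty_node, np - k, E, byrow = TRUE))
  } else cc$node_emb
  hm <- hB[ex$atom_pos, , drop = FALSE] %*% params$Wmap  # n_atoms x E
  mlogits <- cbind(node_mat %*% t(hm),
                   as.numeric(node_mat %*% params$none_vec))
  mprobs <- .softmax(mlogits)
  # mapping targets: column index in (atoms..., none)
  tcol <- apply(ex$mapping, 1, which.max)
  tcol_red <- ifelse(tcol > ex$n_atoms, ncol(mlogits), NA)
  # map atom index -> atom order (atom_pos is ordered by atom index)
  for (i in seq_len(np)) {
    if (is.na(tcol_red[i])) tcol_red[i] <- match(tcol[i], seq_len(ex$n_atoms))
  }
  mapl <- -mean(log(pmax(mprobs[cbind(seq_len(np), tcol_red)], 1e-12)))

  total <- kl_weight * kl + lm + mapl
  list(kl = kl, lm = lm, mapping = mapl, total = total,
       cache = list(cc = cc, ids = ids, target = target, T1 = T1, Ctx = Ctx,
                    bag = bag, rin = rin, rpre = rpre, ra = ra, mu = mu,
                    lv = lv, z = z, z_eps = z_eps, Din = Din, pres = pres,
                    hs = hs, probs = probs, node_mat = node_mat, hm = hm,
                    mprobs = mprobs, tcol_red = tcol_red, k = k, np = np))
}

gcpg_backward <- function(params, ex, fw, cfg, vocab, kl_weight = 1) {
  ck <- fw$cache
  E <- cfg$emb_dim; Z <- cfg$latent_dim; K <- cfg$context
  H <- cfg$hidden_dim
  T1 <- ck$T1
  g <- gcpg_zero(params)

  # LM head
  dlogits <- ck$probs
  dlogits[cbind(seq_len(T1), ck$target)] <-
    dlogits[cbind(seq_len(T1), ck$target)] - 1
  dlogits <- dlogits / T1
  g$Wout <- t(ck$hs[[cfg$n_blocks]]) %*% dlogits
  g$bout <- colSums(dlogits)
  dhB <- dlogits %*% t(params$Wout)

  # mapping head
  np <- ck$np; k <- ck$k
  dml <- ck$mprobs
  dml[cbind(seq_len(np), ck$tcol_red)] <-
    dml[cbind(seq_len(np), ck$tcol_red)] - 1
  dml <- dml / np
  n_at <- ncol(ck$mprobs) - 1L
  dnode <- dml[, seq_len(n_at), drop = FALSE] %*% ck$hm +
    matrix(dml[, n_at + 1L], np, 1) %*% matrix(params$none_vec, 1, E)
  g$none_vec <- as.numeric(t(ck$node_mat) %*% dml[, n_at + 1L])
  dhm <- t(dml[, seq_len(n_at), drop = FALSE]) %*% ck$node_mat  # n_at x E
  g$Wmap <- t(ck$hs[[cfg$n_blocks]][ex$atom_pos, , drop = FALSE]) %*% dhm
  dhB[ex$atom_pos, ] <- dhB[ex$atom_pos, ] + dhm %*% t(params$Wmap)
  d_node_emb <- dnode[seq_len(k), , drop = FALSE]
  if (np > k)
    g$empty_node <- colSums(dnode[(k + 1):np, , drop = FALSE])

  # decoder stack
  dh <- dhB
  if (cfg$n_blocks > 1) {
    for (l in cfg$n_blocks:2) {
      dpre <- silu_grad(ck$pres[[l]]) * dh
      g$dec[[l]]$W <- t(ck$hs[[l - 1]]) %*% dpre
      g$dec[[l]]$b <- colSums(dpre)
      dh <- dh + dpre %*% t(params$dec[[l]]$W)
    }
  }
  dpre1 <- silu_grad(ck$pres[[1]]) * dh
  g$dec[[1]]$W <- t(ck$Din) %*% dpre1
  g$dec[[1]]$b <- colSums(dpre1)
  dDin <- dpre1 %*% t(params$dec[[1]]$W)

  # split decoder-input grads
  for (kk in seq_len(K)) {
    dctx <- dDin[, ((kk - 1) * E + 1):(kk * E), drop = FALSE]
    for (t in seq_len(T1)) {
      id <- ck$Ctx[t, kk]
      g$Temb[id, ] <- g$Temb[id, ] + dctx[t, ]
    }
  }
  dz <- colSums(dDin[, (K * E + 1):(K * E + Z), drop = FALSE])
  dccom_dec <- colSums(dDin[, (K * E + Z + 1):(K * E + Z + 2 * E),
                            drop = FALSE])

  # latent + KL
  dmu <- dz + kl_weight * ck$mu
  dlv <- dz * ck$z_eps * 0.5 * exp(0.5 * ck$lv) +
    kl_weight * 0.5 * (exp(ck$lv) - 1)
  g$Wmu <- outer(ck$ra, dmu); g$bmu <- dmu
  g$Wlv <- outer(ck$ra, dlv); g$blv <- dlv
  dra <- as.numeric(params$Wmu %*% dmu) + as.numeric(params$Wlv %*% dlv)
  drpre <- silu_grad(ck$rpre) * dra
  g$Wr1 <- outer(ck$rin, drpre); g$br1 <- drpre
  drin <- as.numeric(params$Wr1 %*% drpre)
  dbag <- drin[seq_len(E)]
  dccom_rec <- drin[(E + 2):(E + 1 + 2 * E)]
  nid <- length(ck$ids)
  for (id in ck$ids) g$Temb[id, ] <- g$Temb[id, ] + dbag / nid

  # condition path
  dccom <- dccom_dec + dccom_rec
  g <- .cond_backward(params, ck$cc, g,
                      d_m_phar = dccom[seq_len(E)],
                      d_c_gate = dccom[(E + 1):(2 * E)],
                      d_node_emb = d_node_emb)
  g
}

# ---- losses, training, generation ---------------------------------------

#' Compute generator losses on a prepared batch
#'
#' Evaluates (without updating) the three loss terms: closed-form Gaussian
#' KL of the recognition posterior against N(0, I), token cross-entropy,
#' and the node-to-atom mapping cross-entropy.
#'
#' @param model A `gcpg_model`.
#' @param smiles Character vector of molecules to score.
#' @param properties Optional [property_panel()] rows for `smiles`
#'   (computed when NULL).
#' @param seed RNG seed (infilling and latent draws are stochastic).
#' @return List with `kl`, `lm`, `mapping`, `total` (batch means).
#' @export
gcpg_loss <- function(model, smiles, properties = NULL, seed = 1) {
  if (is.null(properties)) properties <- property_panel(smiles)
  cfg <- model$config
  with_seed(seed, {
    tot <- c(kl = 0, lm = 0, mapping = 0, total = 0)
    n <- 0
    for (i in seq_along(smiles)) {
      ex <- gcpg_prepare(smiles[i], model$vocab, cfg, properties[i, ])
      if (is.null(ex)) next
      fw <- gcpg_forward(model$params, ex,
                         stats::rnorm(cfg$latent_dim), cfg, model$vocab,
                         model$prop_stats)
      tot <- tot + c(fw$kl, fw$lm, fw$mapping, fw$total)
      n <- n + 1
    }
    if (n == 0) stop("No usable molecules in batch")
    out <- as.list(tot / n)
    if (any(!is.finite(unlist(out))))
      stop("Non-finite loss term: ", paste(names(out), unlist(out),
                                           collapse = ", "))
    out
  })
}

#' Train the pharmacophore-conditioned gated generator
#'
#' Builds the token vocabulary from the corpus, computes the property panel
#' (unless supplied), and trains with randomly opened/closed property gates
#' per example, so the model learns both the conditional and unconditional
#' channel behavior. Deterministic given `config$seed`.
#'
#' @param corpus Character vector of training SMILES (>= 100 recommended).
#' @param config A [gcpg_config()].
#' @param epochs Training epochs (0 returns the initialized model).
#' @param properties Optional precomputed [property_panel()] for the corpus.
#' @return Object of class `gcpg_model`.
#' @export
train_gcpg <- function(corpus, config = gcpg_config(), epochs = 10,
                       properties = NULL) {
  if (length(corpus) == 0) stop("Empty corpus")
  if (is.null(properties)) properties <- property_panel(corpus)
  vocab <- build_vocab(corpus)
  stats_tab <- lapply(c(MW = "MW", LogP = "LogP", QED = "QED", SAS = "SAS",
                        RotBonds = "RotBonds", TPSA = "TPSA"),
                      function(cl) c(mean = mean(properties[[cl]]),
                                     sd = max(stats::sd(properties[[cl]]),
                                              1e-6)))
  stats_tab$DockScore <- c(mean = 0, sd = 1)
  cfg <- config
  with_seed(cfg$seed, {
    params <- gcpg_init(vocab$size, cfg)
    model <- structure(list(params = params, config = cfg, vocab = vocab,
                            prop_stats = stats_tab,
                            loss_trace = NULL, epochs_trained = 0L),
                       class = "gcpg_model")
    if (epochs == 0) return(model)
    opt <- gcpg_adam_init(params)
    nsteps_total <- epochs * ceiling(length(corpus) / cfg$batch_size)
    step <- 0
    trace <- matrix(NA_real_, epochs, 4,
                    dimnames = list(NULL, c("kl", "lm", "mapping", "total")))
    for (ep in seq_len(epochs)) {
      # cyclic cosine annealing with a 4-epoch period
      lr_ep <- cfg$lr * (0.1 + 0.9 * 0.5 *
                           (1 + cos(pi * ((ep - 1) %% 4) / 4)))
      ord <- sample.int(length(corpus))
      ep_loss <- c(0, 0, 0, 0); nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        step <- step + 1
        klw <- min(1, step / max(1, cfg$kl_warmup * nsteps_total))
        gsum <- gcpg_zero(params)
        bl <- c(0, 0, 0, 0); nex <- 0
        for (i in idx) {
          ex <- gcpg_prepare(corpus[i], vocab, cfg, properties[i, ])
          if (is.null(ex)) next
          fw <- gcpg_forward(params, ex, stats::rnorm(cfg$latent_dim),
                             cfg, vocab, stats_tab, klw)
          gr <- gcpg_backward(params, ex, fw, cfg, vocab, klw)
          gsum <- .walk2(gsum, gr, `+`)
          bl <- bl + c(fw$kl, fw$lm, fw$mapping, fw$total)
          nex <- nex + 1
        }
        if (nex == 0) next
        gsum <- .walk2(gsum, gsum, function(x, y) x / nex)
        st <- gcpg_adam_step(params, gsum, opt, lr_ep, cfg$weight_decay)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + bl / nex; nb <- nb + 1
      }
      trace[ep, ] <- ep_loss / nb
    }
    model$params <- params
    model$loss_trace <- trace
    model$epochs_trained <- epochs
    model
  })
}

#' @export
print.gcpg_model <- function(x, ...) {
  cat(sprintf(
    "<gcpg_model> V=%d, emb=%d, hidden=%d, blocks=%d, z=%d, %d epoch(s)\n",
    x$vocab$size, x$config$emb_dim, x$config$hidden_dim, x$config$n_blocks,
    x$config$latent_dim, x$epochs_trained))
  if (!is.null(x$loss_trace)) {
    lt <- x$loss_trace[nrow(x$loss_trace), ]
    cat(sprintf("  final losses: kl %.3f  lm %.3f  mapping %.3f\n",
                lt["kl"], lt["lm"], lt["mapping"]))
  }
  invisible(x)
}

#' Generate molecules from a pharmacophore hypothesis
#'
#' Draws `z ~ N(0, I)` per sample and decodes autoregressively under the
#' combined condition (pharmacophore graph + gating channels). Returned
#' strings are raw samples; chemical validity is not guaranteed.
#'
#' @param model A trained `gcpg_model`.
#' @param phar A [pharm_graph()] (or [pharm_cloud()], converted via
#'   [cloud_to_pharm_graph()]).
#' @param gating A [gating_condition()] (default: all channels closed).
#' @param n Number of samples.
#' @param seed RNG seed.
#' @param temperature Sampling temperature (default from config).
#' @return Character vector of `n` SMILES strings.
#' @export
gcpg_generate <- function(model, phar, gating = gating_condition(), n = 10,
                          seed = 1, temperature = NULL) {
  stopifnot(inherits(model, "gcpg_model"))
  if (model$epochs_trained == 0 && is.null(model$loss_trace))
    stop("Model is untrained; train or finetune before generating")
  if (inherits(phar, "pharm_cloud")) phar <- cloud_to_pharm_graph(phar)
  stopifnot(inherits(phar, "pharm_graph"))
  if (n == 0) return(character(0))
  cfg <- model$config
  if (is.null(temperature)) temperature <- cfg$temperature
  params <- model$params
  vocab <- model$vocab
  E <- cfg$emb_dim; Z <- cfg$latent_dim; K <- cfg$context
  bos <- match("<bos>", vocab$tokens); eos <- match("<eos>", vocab$tokens)
  cc <- .cond_forward(params, phar, gating, model$prop_stats)
  with_seed(seed, {
    out <- character(n)
    for (s in seq_len(n)) {
      z <- stats::rnorm(Z)
      ids <- integer(0)
      hist <- rep(bos, K)
      for (t in seq_len(cfg$max_len)) {
        din <- c(as.numeric(t(params$Temb[hist, , drop = FALSE])),
                 z, cc$c_com)
        h <- silu(as.numeric(din %*% params$dec[[1]]$W) + params$dec[[1]]$b)
        if (cfg$n_blocks > 1) {
          for (l in 2:cfg$n_blocks)
            h <- h + silu(as.numeric(h %*% params$dec[[l]]$W) +
                            params$dec[[l]]$b)
        }
        logit <- as.numeric(h %*% params$Wout) + params$bout
        logit[c(1, bos)] <- -Inf  # never emit padding/start
        p <- exp((logit - max(logit)) / temperature)
        p <- p / sum(p)
        id <- sample.int(vocab$size, 1, prob = p)
        if (id == eos) break
        ids <- c(ids, id)
        hist <- c(hist[-1], id)
      }
      out[s] <- detokenize(vocab$tokens[ids])
    }
    out
  })
}

#' Fine-tune the generator on externally scored molecules
#'
#' Continues training on a table of (SMILES, docking score) pairs with only
#' the DockScore gate open, so that generation can afterwards be
#' conditioned on a target score (e.g. fixing the score channel at -13
#' kcal/mol). The tokenizer and vocabulary are preserved; molecules with
#' out-of-vocabulary tokens are skipped.
#'
#' @param model A pretrained `gcpg_model`.
#' @param scored data.frame with columns `smiles` and `score_kcal_mol`.
#' @param epochs Fine-tuning epochs (0 returns the model unchanged).
#' @return The fine-tuned `gcpg_model` (score statistics stored for the
#'   DockScore channel).
#' @export
finetune_with_scores <- function(model, scored, epochs = 5) {
  stopifnot(inherits(model, "gcpg_model"))
  if (is.null(scored) || nrow(scored) == 0) stop("Empty score table")
  if (!all(c("smiles", "score_kcal_mol") %in% names(scored)))
    stop("`scored` needs columns smiles, score_kcal_mol")
  if (epochs == 0) return(model)
  cfg <- model$config
  vocab <- model$vocab
  model$prop_stats$DockScore <- c(
    mean = mean(scored$score_kcal_mol),
    sd = max(stats::sd(scored$score_kcal_mol), 1e-6))
  usable <- vapply(scored$smiles, function(s) {
    ok <- tryCatch({
      encode_tokens(tokenize(s), vocab)
      TRUE
    }, error = function(e) FALSE)
    ok
  }, logical(1))
  scored <- scored[usable, , drop = FALSE]
  if (nrow(scored) == 0) stop("No score-table molecule fits the vocabulary")
  props <- property_panel(scored$smiles)
  open_mask <- c(rep(FALSE, 6), TRUE)  # only DockScore open
  with_seed(cfg$seed + 1L, {
    params <- model$params
    opt <- gcpg_adam_init(params)
    trace <- matrix(NA_real_, epochs, 4,
                    dimnames = list(NULL, c("kl", "lm", "mapping", "total")))
    for (ep in seq_len(epochs)) {
      lr_ep <- cfg$lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * ((ep - 1) %% 4) / 4)))
      ord <- sample.int(nrow(scored))
      ep_loss <- c(0, 0, 0, 0); nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        gsum <- gcpg_zero(params); bl <- c(0, 0, 0, 0); nex <- 0
        for (i in idx) {
          ex <- gcpg_prepare(scored$smiles[i], vocab, cfg, props[i, ],
                             open_mask = open_mask,
                             dock_score = scored$score_kcal_mol[i])
          if (is.null(ex)) next
          fw <- gcpg_forward(params, ex, stats::rnorm(cfg$latent_dim),
                             cfg, vocab, model$prop_stats, 1)
          gr <- gcpg_backward(params, ex, fw, cfg, vocab, 1)
          gsum <- .walk2(gsum, gr, `+`)
          bl <- bl + c(fw$kl, fw$lm, fw$mapping, fw$total); nex <- nex + 1
        }
        if (nex == 0) next
        gsum <- .walk2(gsum, gsum, function(x, y) x / nex)
        st <- gcpg_adam_step(params, gsum, opt, lr_ep, cfg$weight_decay)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + bl / nex; nb <- nb + 1
      }
      trace[ep, ] <- ep_loss / nb
    }
    model$params <- params
    model$loss_trace <- rbind(model$loss_trace, trace)
    model$epochs_trained <- model$epochs_trained + epochs
    model
  })
}

#' Default property pre-filter ranges for score-gated generation
#'
#' The drug-likeness window applied before docking-based fine-tuning:
#' MW 325-425, LogP 1-4, QED 0.4-0.8, SAS 1-5, rotatable bonds 4-6.
#'
#' @return Named list of c(lo, hi) ranges.
#' @export
r1_prefilter_ranges <- function() {
  list(MW = c(325, 425), LogP = c(1, 4), QED = c(0.4, 0.8),
       SAS = c(1, 5), RotBonds = c(4, 6))
}
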