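# Training and sampling for the pocket-conditioned pharmacophore diffusion
# model. The pocket is noise-free context at every step; the cloud latent
# (coordinates + continuous one-hot categories) is denoised from t = T to 0.

# assemble normalized training tensors for one pair
.pair_tensors <- function(pair, alphabet, scale) {
  pbar <- colMeans(pair$pocket$xyz)
  Xp <- sweep(pair$pocket$xyz, 2, pbar)
  Fp <- pocket_onehot(pair$pocket, alphabet)
  x0 <- sweep(pair$cloud$xyz, 2, pbar) / scale
  h0 <- cloud_onehot(pair$cloud)
  list(Xp = Xp, Fp = Fp, x0 = x0, h0 = h0, pbar = pbar)
}

#' Train the pocket-conditioned diffusion denoiser
#'
#' Minimizes the simplified denoising objective
#' `L = 1/2 ||eps - phi(z_t, pocket, t)||^2` (mean over state entries) with
#' Adam, drawing one uniform timestep and one noise realization per pair and
#' minibatch. Pocket nodes are fixed, noise-free context throughout. The
#' run is fully deterministic given `config$seed`.
#'
#' @param pairs List of `list(pocket=, cloud=)` training pairs (e.g. from
#'   [make_complex_fixtures()]).
#' @param config A [denoiser_config()].
#' @param schedule A [build_schedule()] object (default T = 500 polynomial).
#' @param epochs Number of passes over the data (0 returns the freshly
#'   initialized model unchanged).
#' @return An object of class `pharm_denoiser`: parameters, config,
#'   schedule, pocket feature alphabet, coordinate scale, the training-set
#'   cloud-size histogram, and the per-epoch loss trace.
#' @export
train_denoiser <- function(pairs, config = denoiser_config(),
                           schedule = build_schedule(), epochs = 50) {
  if (length(pairs) < 1) stop("Empty training set")
  if (length(pairs) < 2 && epochs > 0)
    stop("Need at least 2 training pairs")
  alphabet <- sort(unique(unlist(lapply(pairs, function(p)
    p$pocket$feature))))
  # coordinate normalization: std of pocket-centered cloud coordinates
  allc <- do.call(rbind, lapply(pairs, function(p)
    sweep(p$cloud$xyz, 2, colMeans(p$pocket$xyz))))
  scale <- max(stats::sd(as.numeric(allc)), 0.1)
  din <- 8 + length(alphabet) + 3
  h <- config$hidden_dim

  with_seed(config$seed, {
    params <- egnn_init(din, h, config$n_layers)
    tensors <- lapply(pairs, .pair_tensors, alphabet = alphabet,
                      scale = scale)
    opt <- adam_init(params)
    trace <- numeric(0)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        # cosine learning-rate decay to 10% of the initial rate
        lr_ep <- config$lr * (0.1 + 0.45 * (1 + cos(pi * (ep - 1) / epochs)))
        ord <- sample.int(length(tensors))
        ep_loss <- 0; nb <- 0
        for (start in seq(1, length(ord), by = config$batch_size)) {
          idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
          gsum <- params_zero(params)
          bloss <- 0
          for (i in idx) {
            tn <- tensors[[i]]
            ncp <- nrow(tn$x0)
            t <- sample.int(schedule$T, 1)
            a <- sched_alpha(schedule, t); s <- sched_sigma(schedule, t)
            ex <- matrix(stats::rnorm(ncp * 3), ncp, 3)
            eh <- matrix(stats::rnorm(ncp * 8), ncp, 8)
            zx <- a * tn$x0 + s * ex
            zh <- a * tn$h0 + s * eh
            fw <- egnn_forward(params, zx * scale, zh, tn$Xp, tn$Fp,
                               t / schedule$T, config$cutoff, cache = TRUE)
            nel <- ncp * 11
            rx <- fw$eps_x - ex; rh <- fw$eps_h - eh
            bloss <- bloss + 0.5 * (sum(rx^2) + sum(rh^2)) / nel
            gr <- egnn_backward(params, fw, rx / nel, rh / nel)
            gsum <- params_map2(gsum, gr, `+`)
          }
          gsum <- params_map(gsum, function(x) x / length(idx))
          gn <- grad_global_norm(gsum)
          if (gn > config$grad_clip)
            gsum <- params_map(gsum, function(x) x * config$grad_clip / gn)
          st <- adam_step(params, gsum, opt, lr_ep)
          params <- st$params; opt <- st$state
          ep_loss <- ep_loss + bloss / length(idx); nb <- nb + 1
        }
        trace[ep] <- ep_loss / nb
      }
    }
    structure(list(params = params, config = config, schedule = schedule,
                   pocket_alphabet = alphabet, coord_scale = scale,
                   size_hist = vapply(pairs, function(p) nrow(p$cloud$xyz),
                                      1L),
                   loss_trace = trace),
              class = "pharm_denoiser")
  })
}

#' @export
print.pharm_denoiser <- function(x, ...) {
  cat(sprintf(
    "<pharm_denoiser> h=%d, L=%d, d_P=%d, trained %d epoch(s), final loss %.4f\n",
    x$config$hidden_dim, x$config$n_layers, length(x$pocket_alphabet),
    length(x$loss_trace),
    if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA))
  invisible(x)
}

#' Evaluate the denoiser on a diffusion state
#'
#' Exposes the raw noise predictor `phi(z_t, pocket, t)`; used by the
#' sampler and by the equivariance checks.
#'
#' @param model A `pharm_denoiser`.
#' @param zx n x 3 normalized cloud coordinates (pocket-centered frame / scale).
#' @param zh n x 8 continuous category features.
#' @param Xp Pocket coordinates (pocket-centered, Angstrom).
#' @param Fp Pocket one-hot features over `model$pocket_alphabet`.
#' @param t Timestep.
#' @return List with `eps_x` (n x 3) and `eps_h` (n x 8).
#' @export
denoiser_predict <- function(model, zx, zh, Xp, Fp, t) {
  egnn_forward(model$params, zx * model$coord_scale, zh, Xp, Fp,
               t / model$schedule$T, model$config$cutoff)
}

#' Sample pharmacophore clouds inside a pocket
#'
#' Runs the reverse diffusion chain from pure noise to a pharmacophore point
#' cloud, with the pocket as fixed context. Categorical features are decoded
#' by argmax over the 8 channels at the final step.
#'
#' @param pocket A [pocket_cloud()].
#' @param model A trained (or freshly initialized) `pharm_denoiser`.
#' @param n_points Number of cloud points; when NULL, drawn from the
#'   training-set size histogram.
#' @param schedule Optional override of the model's schedule.
#' @param seed Integer seed (ignored when `noise_fn` is supplied).
#' @param noise_fn Optional noise source for reproducible/transformed
#'   streams: a function `(kind, t, n)` with `kind` in `"init"`/`"step"`,
#'   returning an n x 11 standard-normal matrix (3 coordinate + 8 feature
#'   columns). Used by the equivariance tests to rotate the injected noise.
#' @return A [pharm_cloud()] with provenance `"diffusion-sampled"`.
#' @export
sample_pharmacophores <- function(pocket, model, n_points = NULL,
                                  schedule = NULL, seed = 1,
                                  noise_fn = NULL) {
  stopifnot(inherits(model, "pharm_denoiser"))
  if (is.null(schedule)) schedule <- model$schedule
  run <- function() {
    n <- n_points
    if (is.null(n)) n <- sample(model$size_hist, 1)
    if (n < 1) stop("n_points must be >= 1")
    pbar <- colMeans(pocket$xyz)
    Xp <- sweep(pocket$xyz, 2, pbar)
    Fp <- pocket_onehot(pocket, model$pocket_alphabet)
    draw <- if (is.null(noise_fn)) {
      function(kind, t, n) matrix(stats::rnorm(n * 11), n, 11)
    } else noise_fn
    e0 <- draw("init", schedule$T, n)
    z <- diffusion_state(e0[, 1:3, drop = FALSE],
                         e0[, 4:11, drop = FALSE], schedule$T)
    for (t in seq(schedule$T, 1)) {
      ep <- denoiser_predict(model, z$coords, z$feats, Xp, Fp, t)
      z0h <- predict_clean(z, diffusion_state(ep$eps_x, ep$eps_h, t),
                           schedule, t)
      # clamp the denoised estimate to the plausible data range; guards the
      # 1/alpha_t amplification of prediction error at large t. Coordinates
      # are clamped radially (per-point norm), which commutes with
      # rotations; features are clamped per channel (rotation-invariant).
      nrm <- sqrt(rowSums(z0h$coords^2))
      fac <- pmin(1, 6 / pmax(nrm, 1e-12))
      z0h$coords <- z0h$coords * fac
      z0h$feats[] <- pmin(pmax(z0h$feats, -3), 3)
      if (t > 1) {
        en <- draw("step", t - 1L, n)
        z <- posterior_step(z, z0h, t, t - 1L, schedule,
                            eps = diffusion_state(en[, 1:3, drop = FALSE],
                                                  en[, 4:11, drop = FALSE],
                                                  t - 1L))
      } else {
        z <- z0h
      }
    }
    xyz <- z$coords * model$coord_scale
    xyz <- sweep(xyz, 2, pbar, `+`)
    cats <- pharm_categories()[max.col(z$feats, ties.method = "first")]
    pharm_cloud(xyz, cats, provenance = "diffusion-sampled")
  }
  if (is.null(noise_fn)) with_seed(seed, run()) else run()
}
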