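# Shared toy study objects, trained lazily once per test run.
#
# The toy scales are the package's desk-scale study conditions (see the
# methods vignette): diffusion denoiser h=48/L=3/cutoff 16 trained 220
# epochs on 200 fixture pairs; generator h=96/2 blocks/context 8 trained 20
# epochs on a 500-molecule template corpus.

.cache <- new.env(parent = emptyenv())

quiet <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

toy_fixture_spec <- function(seed = 42) fixture_spec(n_pairs = 200, seed = seed)

toy_pairs <- function() {
  if (is.null(.cache$pairs)) .cache$pairs <- make_complex_fixtures(toy_fixture_spec())
  .cache$pairs
}

toy_denoiser_config <- function(seed = 7) {
  denoiser_config(cutoff = 16, hidden_dim = 48, n_layers = 3, lr = 3e-3,
                  batch_size = 16, seed = seed)
}

toy_denoiser <- function() {
  if (is.null(.cache$denoiser)) {
    .cache$denoiser <- train_denoiser(toy_pairs(), toy_denoiser_config(),
                                      build_schedule(500), epochs = 220)
  }
  .cache$denoiser
}

toy_corpus <- function() {
  if (is.null(.cache$corpus)) .cache$corpus <- make_smiles_corpus(500, seed = 11)
  .cache$corpus
}

toy_corpus_props <- function() {
  if (is.null(.cache$props)) .cache$props <- quiet(property_panel(toy_corpus()))
  .cache$props
}

toy_gcpg_config <- function(seed = 4) {
  gcpg_config(hidden_dim = 96, n_blocks = 2, latent_dim = 8, emb_dim = 32,
              lr = 2e-3, batch_size = 32, seed = seed, infill_rate = 0.5,
              context = 8)
}

toy_gcpg <- function() {
  if (is.null(.cache$gcpg)) {
    .cache$gcpg <- quiet(train_gcpg(toy_corpus(), toy_gcpg_config(),
                                    epochs = 20,
                                    properties = toy_corpus_props()))
  }
  .cache$gcpg
}

# deterministic reproducible noise stream for the sampler, optionally with
# coordinate rotation R applied to every draw
make_noise_fn <- function(seed, R = NULL) {
  function(kind, t, n) {
    s <- seed + t * 131L + if (kind == "init") 1000003L else 0L
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(s)
    m <- matrix(stats::rnorm(n * 11), n, 11)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    if (!is.null(R)) m[, 1:3] <- m[, 1:3] %*% t(R)
    m
  }
}

# fast molecular weights for distribution-shift tests (valid SMILES only)
mw_quick <- function(smiles) {
  sdf <- quiet(ChemmineR::smiles2sdf(
    stats::setNames(smiles, paste0("m", seq_along(smiles)))))
  as.numeric(quiet(ChemmineR::propOB(sdf))$MW)
}

# independent rigid-fit oracle: Horn's quaternion method (no SVD)
horn_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  M <- t(Ac) %*% Bc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  tr <- cb - as.numeric(R %*% ca)
  resid <- sweep(A %*% t(R), 2, tr, `+`) - B
  list(R = R, t = tr, rmsd = sqrt(mean(rowSums(resid^2))))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_pocket <- function(pocket, R) {
  pocket$xyz <- pocket$xyz %*% t(R)
  pocket$center <- as.numeric(R %*% pocket$center)
  pocket
}
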