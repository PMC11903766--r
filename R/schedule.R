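# Variance-preserving noise schedules and the closed-form diffusion algebra.
#
# The forward process is q(z_t | z_0) = N(alpha_t z_0, sigma_t^2 I) with
# alpha_t^2 + sigma_t^2 = 1. Transition quantities between steps s < t use
# alpha_{t|s} = alpha_t / alpha_s and sigma_{t|s}^2 = sigma_t^2 -
# alpha_{t|s}^2 sigma_s^2, which make the stepwise posterior exact.

# floor keeping alpha_T strictly positive (alpha_T ~ 3.2e-4)
.sched_floor <- 1e-7

#' Build a variance-preserving noise schedule
#'
#' Two closed forms are provided: a polynomial schedule (the default of the
#' equivariant-diffusion lineage), `alpha_t^2 ~ (1 - (t/T)^2)^2`, and a
#' squared-cosine schedule. Both are affinely floored so that `alpha_0^2 =
#' 1 - 1e-7` and `alpha_T^2 = 1e-7`, keeping every `alpha_t` strictly
#' positive while satisfying `alpha_t^2 + sigma_t^2 = 1` exactly.
#'
#' @param T Number of diffusion steps (default 500); arrays run t = 0..T.
#' @param kind `"polynomial"` or `"cosine"`.
#' @return An object of class `noise_schedule` with fields `T`, `alpha`,
#'   `sigma` (length `T + 1`), `kind`.
#' @export
#' @examples
#' s <- build_schedule(500)
#' max(abs(s$alpha^2 + s$sigma^2 - 1))  # < 1e-12
build_schedule <- function(T = 500, kind = c("polynomial", "cosine")) {
  kind <- match.arg(kind)
  if (!is.numeric(T) || T < 2) stop("T must be an integer >= 2")
  T <- as.integer(T)
  u <- (0:T) / T
  raw <- switch(kind,
    polynomial = (1 - u^2)^2,
    cosine = cos(u * pi / 2)^2
  )
  a2 <- raw * (1 - 2 * .sched_floor) + .sched_floor
  # enforce monotone nonincreasing (guards rounding at the flat ends)
  a2 <- rev(cummax(rev(a2)))
  structure(list(T = T, alpha = sqrt(a2), sigma = sqrt(1 - a2), kind = kind),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T=%d, alpha_0=%.6f, alpha_T=%.2e\n",
              x$kind, x$T, x$alpha[1], x$alpha[x$T + 1]))
  invisible(x)
}

# index helper: schedule arrays are 1-based over t = 0..T
sched_alpha <- function(schedule, t) schedule$alpha[t + 1L]
sched_sigma <- function(schedule, t) schedule$sigma[t + 1L]

#' Transition coefficients between two schedule steps
#'
#' @param schedule A [build_schedule()] object.
#' @param t,s Integer steps with `0 <= s < t <= T`.
#' @return List with `alpha_ts`, `sigma2_ts`, and the posterior-step
#'   quantities `coef_zt`, `coef_z0`, `var` of
#'   q(z_s | z_0, z_t) = N(coef_zt z_t + coef_z0 z_0, var I).
#' @export
schedule_coef <- function(schedule, t, s) {
  if (s >= t || s < 0 || t > schedule$T) stop("need 0 <= s < t <= T")
  a_t <- sched_alpha(schedule, t); a_s <- sched_alpha(schedule, s)
  s2_t <- sched_sigma(schedule, t)^2; s2_s <- sched_sigma(schedule, s)^2
  a_ts <- a_t / a_s
  s2_ts <- s2_t - a_ts^2 * s2_s
  list(alpha_ts = a_ts,
       sigma2_ts = s2_ts,
       coef_zt = a_ts * s2_s / s2_t,
       coef_z0 = a_s * s2_ts / s2_t,
       var = s2_ts * s2_s / s2_t)
}

#' Construct a diffusion state
#'
#' The continuous latent the sampler operates on: cloud coordinates (in the
#' pocket-centered frame, divided by the model's coordinate scale) and the
#' continuous relaxation of the one-hot category features.
#'
#' @param coords n x 3 numeric matrix.
#' @param feats n x 8 numeric matrix.
#' @param t Integer timestep.
#' @return An object of class `diffusion_state`.
#' @export
diffusion_state <- function(coords, feats, t = 0L) {
  coords <- as.matrix(coords); feats <- as.matrix(feats)
  if (ncol(coords) != 3L) stop("coords must be n x 3")
  if (ncol(feats) != 8L) stop("feats must be n x 8")
  if (nrow(coords) != nrow(feats)) stop("coords/feats row mismatch")
  structure(list(coords = unname(coords), feats = unname(feats),
                 t = as.integer(t)), class = "diffusion_state")
}

#' Apply the forward noising process
#'
#' Computes `z_t = alpha_t z_0 + sigma_t eps` exactly, jointly on
#' coordinates and features.
#'
#' @param z0 A [diffusion_state()] at its clean configuration.
#' @param t Target timestep.
#' @param eps A `diffusion_state`-shaped noise draw (same dims as `z0`),
#'   i.i.d. standard normal.
#' @param schedule A [build_schedule()] object.
#' @return A `diffusion_state` at time `t`.
#' @export
forward_noise <- function(z0, t, eps, schedule) {
  stopifnot(inherits(z0, "diffusion_state"), inherits(eps, "diffusion_state"))
  if (!all(dim(z0$coords) == dim(eps$coords)) ||
      !all(dim(z0$feats) == dim(eps$feats)))
    stop("z0 and eps shapes differ")
  a <- sched_alpha(schedule, t); s <- sched_sigma(schedule, t)
  diffusion_state(a * z0$coords + s * eps$coords,
                  a * z0$feats + s * eps$feats, t)
}

#' Reconstruct the clean state from a noise prediction
#'
#' `z0_hat = z_t / alpha_t - (sigma_t / alpha_t) eps_hat`; with the true
#' noise this inverts [forward_noise()] to machine precision.
#'
#' @param z_t A `diffusion_state` at time `t`.
#' @param eps_hat Predicted noise (same shape).
#' @param schedule A [build_schedule()] object.
#' @param t Timestep (defaults to `z_t$t`).
#' @return A `diffusion_state` estimate of the clean configuration (t = 0).
#' @export
predict_clean <- function(z_t, eps_hat, schedule, t = z_t$t) {
  a <- sched_alpha(schedule, t)
  if (!is.finite(a) || a < 1e-8)
    stop("alpha_t is (numerically) zero at t = ", t,
         "; cannot invert the forward process")
  s <- sched_sigma(schedule, t)
  diffusion_state(z_t$coords / a - (s / a) * eps_hat$coords,
                  z_t$feats / a - (s / a) * eps_hat$feats, 0L)
}

#' Draw one reverse-diffusion posterior step
#'
#' Samples z_s ~ q(z_s | z0_hat, z_t) = N(coef_zt z_t + coef_z0 z0_hat,
#' var I) for s < t.
#'
#' @param z_t State at time `t`.
#' @param z0_hat Clean-state estimate (e.g. from [predict_clean()]).
#' @param t,s Steps with `0 <= s < t`.
#' @param schedule A [build_schedule()] object.
#' @param eps Optional externally supplied standard-normal draw (same shape
#'   as the state); when NULL it is drawn from the R RNG.
#' @return A `diffusion_state` at time `s`.
#' @export
posterior_step <- function(z_t, z0_hat, t, s, schedule, eps = NULL) {
  cf <- schedule_coef(schedule, t, s)
  n <- nrow(z_t$coords)
  if (is.null(eps)) {
    eps <- diffusion_state(matrix(stats::rnorm(n * 3), n, 3),
                           matrix(stats::rnorm(n * 8), n, 8), s)
  }
  sd <- sqrt(max(cf$var, 0))
  diffusion_state(
    cf$coef_zt * z_t$coords + cf$coef_z0 * z0_hat$coords + sd * eps$coords,
    cf$coef_zt * z_t$feats + cf$coef_z0 * z0_hat$feats + sd * eps$feats,
    s)
}
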