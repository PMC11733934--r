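# Variance-preserving DDPM machinery.
#
# Conventions: alpha[t] is the *cumulative* signal coefficient (often
# written with an overbar), sigma[t] the matching noise scale with
# alpha^2 + sigma^2 = 1 at every step, t = 0..T. Latents are
# z_t = alpha_t x + sigma_t eps.

clip_alpha2_ratios <- function(alpha2, clip_value = 0.001) {
  # enforce a floor on the per-step signal ratio so beta_t stays < 1
  ratios <- alpha2[-1] / alpha2[-length(alpha2)]
  ratios <- pmax(ratios, clip_value)
  cumprod(c(alpha2[1], ratios))
}

#' Build a variance-preserving noise schedule
#'
#' `alpha` runs smoothly from ~1 at t = 0 to ~0 at t = T; `sigma` is
#' defined by the variance-preserving identity alpha^2 + sigma^2 = 1, so
#' the identity holds exactly by construction. The polynomial form is
#' alpha_bar^2(t) = (1 - (t/T)^power)^2, ratio-clipped and then shrunk
#' into [precision, 1 - precision] so both endpoints stay strictly inside
#' (0, 1); the cosine form is the standard squared-cosine profile.
#'
#' @param T number of diffusion steps (schedule has T + 1 entries, t = 0..T)
#' @param kind "polynomial" (default) or "cosine"
#' @param precision endpoint clearance, in (0, 0.1)
#' @param power polynomial power (default 2)
#' @return object of class NoiseSchedule: list(T, alpha, sigma, beta, snr)
#' @export
build_noise_schedule <- function(T, kind = c("polynomial", "cosine"),
                                 precision = 1e-4, power = 2) {
  kind <- match.arg(kind)
  stopifnot(T >= 1, precision > 0, precision < 0.1)
  t <- seq(0, T) / T
  alpha2 <- switch(kind,
    polynomial = (1 - t^power)^2,
    cosine = cos((t + 0.008) / 1.008 * pi / 2)^2 /
             cos(0.008 / 1.008 * pi / 2)^2
  )
  alpha2 <- clip_alpha2_ratios(alpha2)
  alpha2 <- precision + (1 - 2 * precision) * alpha2
  alpha <- sqrt(alpha2)
  sigma <- sqrt(1 - alpha2)
  snr <- alpha2 / (1 - alpha2)
  beta <- c(NA_real_, 1 - alpha2[-1] / alpha2[-length(alpha2)])
  if (any(diff(alpha) >= 0)) stop("internal: alpha not strictly decreasing")
  if (any(diff(snr) >= 0)) stop("internal: SNR not strictly decreasing")
  structure(list(T = as.integer(T), kind = kind, precision = precision,
                 alpha = alpha, sigma = sigma, beta = beta, snr = snr),
            class = "NoiseSchedule")
}

#' Serialize / restore a noise schedule
#' @param schedule a NoiseSchedule
#' @param path JSON file
#' @export
write_noise_schedule <- function(schedule, path) {
  jsonlite::write_json(unclass(schedule), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_noise_schedule
#' @export
read_noise_schedule <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(T = as.integer(s$T), kind = s$kind, precision = s$precision,
                 alpha = as.numeric(s$alpha), sigma = as.numeric(s$sigma),
                 beta = as.numeric(s$beta), snr = as.numeric(s$snr)),
            class = "NoiseSchedule")
}

sched_at <- function(schedule, t) {
  if (any(t < 0 | t > schedule$T)) stop("step t out of range [0, T]")
  list(alpha = schedule$alpha[t + 1], sigma = schedule$sigma[t + 1],
       snr = schedule$snr[t + 1])
}

#' Project coordinates onto the zero-centre-of-mass subspace
#'
#' Subtracts the mean of the masked rows from the masked rows; other rows
#' are untouched. Idempotent and translation-invariant on the masked set.
#'
#' @param coords n x 3 matrix
#' @param mask logical or integer subset of rows (default: all)
#' @return coords with the masked subset mean-centred
#' @export
project_zero_com <- function(coords, mask = NULL) {
  if (is.null(mask)) mask <- seq_len(nrow(coords))
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("empty mask in project_zero_com")
  mu <- colMeans(coords[mask, , drop = FALSE])
  coords[mask, ] <- sweep(coords[mask, , drop = FALSE], 2, mu, "-")
  coords
}

#' Forward-noise clean data to step t
#'
#' z_t = alpha_t x + sigma_t eps with eps standard normal (the
#' reparameterization of the closed-form forward marginal). Coordinates of
#' the ligand are expressed in the conditions-anchored frame upstream;
#' `com_free = TRUE` additionally projects the noise to zero mean over the
#' rows (the quotient-space variant).
#'
#' @param x clean data matrix (rows = nodes)
#' @param t integer step in \[1, T\]
#' @param schedule a NoiseSchedule
#' @param seed optional integer seed
#' @param com_free project the drawn noise to zero column mean
#' @return list(z = noised matrix, eps = drawn noise, t = t)
#' @export
forward_diffuse <- function(x, t, schedule, seed = NULL, com_free = FALSE) {
  if (t < 1 || t > schedule$T) stop("step t out of range [1, T]")
  x <- as.matrix(x)
  s <- sched_at(schedule, t)
  eps <- with_seed(seed, matrix(rnorm(length(x)), nrow(x), ncol(x)))
  if (com_free) eps <- project_zero_com(eps)
  list(z = s$alpha * x + s$sigma * eps, eps = eps, t = t)
}

#' Parameters of the true denoising posterior q(z_s | z_t, x)
#'
#' With alpha_ts = alpha_t / alpha_s and
#' sigma_ts^2 = sigma_t^2 - alpha_ts^2 sigma_s^2:
#' mu = (alpha_ts sigma_s^2 / sigma_t^2) z_t +
#'      (alpha_s sigma_ts^2 / sigma_t^2) x,
#' sd = sigma_ts sigma_s / sigma_t.
#'
#' @param z_t latent at step t (matrix)
#' @param x clean data (matrix, same shape)
#' @param s,t integer steps with 0 <= s < t <= T
#' @param schedule a NoiseSchedule
#' @return list(mu = matrix, sd = scalar)
#' @export
posterior_params <- function(z_t, x, s, t, schedule) {
  if (s >= t) stop("posterior requires s < t")
  if (s < 0 || t > schedule$T) stop("steps out of range")
  at <- sched_at(schedule, t); as_ <- sched_at(schedule, s)
  alpha_ts <- at$alpha / as_$alpha
  sigma_ts2 <- at$sigma^2 - alpha_ts^2 * as_$sigma^2
  mu <- (alpha_ts * as_$sigma^2 / at$sigma^2) * z_t +
        (as_$alpha * sigma_ts2 / at$sigma^2) * x
  sd <- sqrt(max(sigma_ts2, 0)) * as_$sigma / at$sigma
  list(mu = mu, sd = sd)
}

#' Predict clean data from a latent and predicted noise
#'
#' x_hat = (z_t - sigma_t eps_hat) / alpha_t — the forward
#' reparameterization solved for x with eps replaced by the network's
#' prediction.
#'
#' @param z_t latent matrix
#' @param eps_hat predicted noise, same shape
#' @param t integer step
#' @param schedule a NoiseSchedule
#' @return matrix x_hat
#' @export
predict_clean <- function(z_t, eps_hat, t, schedule) {
  s <- sched_at(schedule, t)
  if (s$alpha <= 0) stop("alpha_t is zero; cannot invert the forward map")
  stopifnot(all(dim(as.matrix(z_t)) == dim(as.matrix(eps_hat))))
  (z_t - s$sigma * eps_hat) / s$alpha
}

#' One reverse-diffusion step z_t -> z_s
#'
#' Plugs x_hat = predict_clean(z_t, eps_hat) into the true posterior and
#' samples z_s ~ N(mu, sd^2). `last_step_noiseless` (default: s == 0 adds
#' no noise) keeps decoding stable.
#'
#' @param z_t latent matrix
#' @param eps_hat predicted noise
#' @param s,t steps with s < t
#' @param schedule a NoiseSchedule
#' @param seed optional integer seed
#' @param noise optional pre-drawn standard normal matrix (overrides rng;
#'   used by the seed-matched equivariance tests)
#' @param clamp_radius optional radius: rows of the implied x_hat whose
#'   norm exceeds it are rescaled onto the ball before the posterior is
#'   formed. At high t the map eps_hat -> x_hat amplifies prediction error
#'   by sigma_t/alpha_t, and that error feeds the reverse chain's
#'   exponentially amplified centre-of-mass mode; bounding x_hat to the
#'   region the ligand can physically occupy (the pocket) removes the
#'   runaway without constraining where the ligand settles. Rotationally
#'   covariant (row norms only).
#' @return matrix z_s
#' @export
denoise_step <- function(z_t, eps_hat, s, t, schedule, seed = NULL,
                         noise = NULL, clamp_radius = NULL) {
  x_hat <- predict_clean(z_t, eps_hat, t, schedule)
  if (!is.null(clamp_radius)) {
    nr <- sqrt(rowSums(x_hat^2))
    over <- nr > clamp_radius
    if (any(over)) {
      x_hat[over, ] <- x_hat[over, , drop = FALSE] * (clamp_radius / nr[over])
    }
  }
  pp <- posterior_params(z_t, x_hat, s, t, schedule)
  if (s == 0 || pp$sd == 0) return(pp$mu)
  if (is.null(noise)) {
    noise <- with_seed(seed, matrix(rnorm(length(z_t)), nrow(z_t), ncol(z_t)))
  }
  pp$mu + pp$sd * noise
}

#' Simplified training loss
#'
#' Half the mean squared error between true and predicted noise, pooled
#' over every coordinate and feature component.
#' @param eps,eps_hat matrices (or lists of matrices) of identical shape
#' @return scalar >= 0
#' @export
simplified_loss <- function(eps, eps_hat) {
  if (is.list(eps)) {
    eps <- do.call(c, lapply(eps, as.numeric))
    eps_hat <- do.call(c, lapply(eps_hat, as.numeric))
  }
  stopifnot(length(eps) == length(eps_hat))
  0.5 * mean((as.numeric(eps) - as.numeric(eps_hat))^2)
}

#' Variational-lower-bound diagnostic terms
#'
#' L_T = KL(q(z_T | x) || N(0, I)); each L_t (t >= 1) is
#' (1/2)(SNR(t-1)/SNR(t) - 1) ||eps - eps_hat||^2 with a fresh forward
#' draw; L_0 is the Gaussian reconstruction NLL at t = 0 scale. Training
#' uses [simplified_loss()]; these are diagnostics.
#'
#' @param x clean data matrix
#' @param eps_model function(z_t, t) -> eps_hat (a trained or dummy model)
#' @param schedule a NoiseSchedule
#' @param seed optional integer seed
#' @param steps which t to evaluate (default all 1..T)
#' @return list(L_0, L_t = named numeric, L_T)
#' @export
vlb_terms <- function(x, eps_model, schedule, seed = NULL,
                      steps = seq_len(schedule$T)) {
  x <- as.matrix(x)
  d <- length(x)
  aT <- sched_at(schedule, schedule$T)
  L_T <- 0.5 * (aT$alpha^2 * sum(x^2) +
                d * (aT$sigma^2 - 1 - 2 * log(aT$sigma)))
  L_t <- with_seed(seed, vapply(steps, function(t) {
    fd <- forward_diffuse(x, t, schedule)
    eps_hat <- eps_model(fd$z, t)
    w <- schedule$snr[t] / schedule$snr[t + 1] - 1 # SNR(t-1)/SNR(t) - 1
    0.5 * w * sum((fd$eps - eps_hat)^2)
  }, numeric(1)))
  names(L_t) <- paste0("t", steps)
  a0 <- sched_at(schedule, 0)
  L_0 <- 0.5 * d * log(2 * pi * a0$sigma^2 / a0$alpha^2)
  list(L_0 = L_0, L_t = L_t, L_T = L_T)
}
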