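#' One Markov step of the forward (noising) process
#'
#' Draws \eqn{x_t \sim N(\sqrt{1-\beta_t}\, x_{t-1},\ \beta_t I)} as
#' \eqn{x_t = \sqrt{1-\beta_t}\, x_{t-1} + \sqrt{\beta_t}\, \epsilon}.
#'
#' @param x_prev array, the state at timestep `t - 1`.
#' @param t integer timestep in `1..T_steps`.
#' @param schedule a [build_cosine_schedule()] object.
#' @param eps standard-normal noise array of the same shape as `x_prev`;
#'   drawn internally when omitted.
#' @return Array `x_t` of the same shape.
#' @export
forward_step <- function(x_prev, t, schedule, eps = NULL) {
  check_timestep(schedule, t)
  if (is.null(eps)) eps <- array(stats::rnorm(length(x_prev)), arr_dim(x_prev))
  stop_if_shape_mismatch(x_prev, eps, "state and noise")
  b <- schedule$beta[t]
  sqrt(1 - b) * x_prev + sqrt(b) * eps
}

#' Closed-form forward sample at timestep t
#'
#' Jumps the forward chain directly from the clean image to timestep `t`:
#' \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#' Marginally equivalent to `t` iterations of [forward_step()].
#'
#' @param x0 clean image array, intensities in `[0, 1]`.
#' @param t integer timestep in `1..T_steps`.
#' @param schedule a [build_cosine_schedule()] object.
#' @param eps standard-normal noise array of the same shape as `x0`;
#'   drawn internally when omitted.
#' @return Array `x_t` of the same shape.
#' @export
forward_sample <- function(x0, t, schedule, eps = NULL) {
  check_timestep(schedule, t)
  if (is.null(eps)) eps <- array(stats::rnorm(length(x0)), arr_dim(x0))
  stop_if_shape_mismatch(x0, eps, "image and noise")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' One step of the learned backward (denoising) process
#'
#' Given the noise prediction \eqn{\hat\epsilon_\theta(x_t, t)}, produces
#' \deqn{x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#'   \frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\hat\epsilon\right) +
#'   \sqrt{\tilde\beta_t}\, z,}
#' where \eqn{\tilde\beta_t} is the posterior variance stored in the
#' schedule. At `t = 1` the noise term is forced to zero so the final
#' state is the posterior mean.
#'
#' @param x_t current noisy state.
#' @param t integer timestep in `1..T_steps`.
#' @param eps_hat predicted noise, same shape as `x_t`.
#' @param schedule a [build_cosine_schedule()] object.
#' @param z standard-normal noise array (ignored at `t = 1`); drawn
#'   internally when omitted.
#' @return Array `x_{t-1}` of the same shape.
#' @export
backward_step <- function(x_t, t, eps_hat, schedule, z = NULL) {
  check_timestep(schedule, t)
  stop_if_shape_mismatch(x_t, eps_hat, "state and noise prediction")
  if (!all(is.finite(eps_hat))) stop("non-finite noise prediction", call. = FALSE)
  a <- schedule$alpha[t]
  ab <- schedule$alpha_bar[t]
  mean_ <- (x_t - (1 - a) / sqrt(1 - ab) * eps_hat) / sqrt(a)
  if (t == 1L) return(mean_)
  if (is.null(z)) z <- array(stats::rnorm(length(x_t)), arr_dim(x_t))
  stop_if_shape_mismatch(x_t, z, "state and backward noise")
  mean_ + sqrt(schedule$posterior_var[t]) * z
}

#' Run the backward process from a (partially) noised state
#'
#' Iterates [backward_step()] from `t_start` down to 1, querying the
#' denoiser for a noise prediction at every step, and clips the final
#' state to the `[0, 1]` intensity range (intermediate states are left
#' unclipped, since per-step clipping biases the chain). With
#' `t_start = T_steps` and a pure-noise start this is the classic
#' unconditional diffusion sampler; with a small `t_start` and a state
#' produced by [forward_sample()] from a sketch it is the
#' sketch-conditioned generator.
#'
#' @param x_start noisy state at timestep `t_start`.
#' @param t_start integer timestep in `1..T_steps` at which to start.
#' @param denoiser a [denoiser()] (or a fitted [ddpm()] model).
#' @param schedule a [build_cosine_schedule()] object.
#' @param seed optional integer seed making the trajectory reproducible;
#'   with `NULL` the current RNG stream is used.
#' @param clip clip the final state into `[0, 1]` (default `TRUE`).
#' @return The generated image \eqn{\hat x_0}, same shape as `x_start`.
#' @export
sample_from <- function(x_start, t_start, denoiser, schedule, seed = NULL,
                        clip = TRUE) {
  check_timestep(schedule, t_start)
  denoiser <- as_denoiser(denoiser)
  with_seed(seed, {
    x <- x_start
    for (t in seq(t_start, 1L)) {
      eps_hat <- denoiser_predict(denoiser, x, t)
      stop_if_shape_mismatch(x, eps_hat, "state and denoiser output")
      x <- backward_step(x, t, eps_hat, schedule)
    }
    if (clip) clip01(x) else x
  })
}

#' Noise-prediction training loss
#'
#' The simple diffusion objective: draw a uniform timestep and a fresh
#' standard-normal noise for every image in the batch, noise the image
#' with [forward_sample()], and score the denoiser by the mean squared
#' error between the drawn and the predicted noise,
#' \eqn{E\,\lVert\epsilon - \hat\epsilon_\theta(x_t, t)\rVert^2}
#' (averaged per element).
#'
#' @param denoiser a [denoiser()] (or fitted [ddpm()] model).
#' @param x0_batch list of clean image arrays with intensities in `[0, 1]`.
#' @param schedule a [build_cosine_schedule()] object.
#' @param seed optional integer seed for the timestep/noise draws.
#' @return Non-negative scalar loss.
#' @export
training_loss <- function(denoiser, x0_batch, schedule, seed = NULL) {
  if (!is.list(x0_batch) || length(x0_batch) == 0)
    stop("x0_batch must be a non-empty list of arrays", call. = FALSE)
  denoiser <- as_denoiser(denoiser)
  with_seed(seed, {
    se <- 0; n <- 0
    for (x0 in x0_batch) {
      t <- sample.int(schedule$T_steps, 1L)
      eps <- array(stats::rnorm(length(x0)), arr_dim(x0))
      x_t <- forward_sample(x0, t, schedule, eps)
      eps_hat <- denoiser_predict(denoiser, x_t, t)
      se <- se + sum((eps - eps_hat)^2)
      n <- n + length(x0)
    }
    se / n
  })
}

#' Sinusoidal timestep embedding
#'
#' Encodes an integer timestep as `dim/2` sine and `dim/2` cosine
#' components with geometrically spaced frequencies from 1 down to
#' `1/T_max`, the conditioning signal fed to the denoiser at every step.
#' The slowest frequency completes less than a quarter period over
#' `0..T_max`, so the embedding is injective on that range.
#'
#' @param t integer timestep (scalar), `t >= 0`.
#' @param dim even embedding dimension.
#' @param T_max largest timestep the embedding must distinguish.
#' @return Numeric vector of length `dim`, values in `[-1, 1]`; sines
#'   first, cosines second.
#' @export
sinusoidal_embedding <- function(t, dim, T_max) {
  if (dim < 2 || dim %% 2 != 0) stop("dim must be a positive even integer", call. = FALSE)
  half <- dim %/% 2
  freq <- if (half == 1) 1 / T_max else T_max^(-(seq_len(half) - 1) / (half - 1))
  ang <- t * freq
  c(sin(ang), cos(ang))
}
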