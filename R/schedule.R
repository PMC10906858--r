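#' Cosine noise schedule for a denoising diffusion model
#'
#' Builds the per-timestep noise coefficients of the forward diffusion
#' process for `T_steps` steps, using the cosine schedule of Nichol &
#' Dhariwal: with \eqn{f(t) = \cos^2(((t/T + s)/(1 + s)) \cdot \pi/2)},
#' the cumulative signal fraction is \eqn{\bar\alpha_t = f(t)/f(0)} and the
#' per-step noise increment is
#' \eqn{\beta_t = 1 - \bar\alpha_t/\bar\alpha_{t-1}}, clipped at
#' `beta_clip`. After clipping, `alpha_bar` is recomputed as
#' \eqn{\prod_{s \le t}(1-\beta_s)} so all invariants hold exactly.
#'
#' Timesteps are 1-based in the mathematics (`t` in `1..T_steps`); element
#' `t` of each vector holds the coefficient for timestep `t`.
#' \eqn{\bar\alpha_0 = 1} (the clean image) is represented implicitly: use
#' [sched_alpha_bar()] with `t = 0`.
#'
#' The backward-step noise scale is the diffusion posterior variance
#' \eqn{\tilde\beta_t = \beta_t (1-\bar\alpha_{t-1})/(1-\bar\alpha_t)},
#' with \eqn{\tilde\beta_1 = \beta_1}.
#'
#' @param T_steps number of diffusion steps (positive integer).
#' @param s_offset small positive offset preventing a singular schedule at
#'   `t = 0`; default 0.008.
#' @param beta_clip upper clip for `beta` in (0,1); default 0.999.
#' @return An object of class `"diffusion_schedule"`: a list with elements
#'   `T_steps`, `beta`, `alpha`, `alpha_bar`, `posterior_var`, `s_offset`,
#'   `beta_clip` (all per-timestep vectors of length `T_steps`).
#' @examples
#' sch <- build_cosine_schedule(1000)
#' sch$alpha_bar[500]   # about 0.494
#' sch$alpha_bar[1000]  # near 0: the forward process ends in pure noise
#' @export
build_cosine_schedule <- function(T_steps, s_offset = 0.008, beta_clip = 0.999) {
  if (length(T_steps) != 1 || !is.finite(T_steps) || T_steps < 1 || T_steps != round(T_steps))
    stop("T_steps must be a positive integer", call. = FALSE)
  if (s_offset <= 0) stop("s_offset must be positive", call. = FALSE)
  if (beta_clip <= 0 || beta_clip >= 1) stop("beta_clip must be in (0,1)", call. = FALSE)
  T_steps <- as.integer(T_steps)

  f <- function(t) cos(((t / T_steps + s_offset) / (1 + s_offset)) * pi / 2)^2
  abar_raw <- f(0:T_steps) / f(0)
  beta <- 1 - abar_raw[-1] / abar_raw[-(T_steps + 1)]
  beta <- pmin(pmax(beta, .Machine$double.eps), beta_clip)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-T_steps])
  posterior_var <- beta * (1 - alpha_bar_prev) / (1 - alpha_bar)
  posterior_var[1] <- beta[1]

  structure(
    list(T_steps = T_steps, beta = beta, alpha = alpha, alpha_bar = alpha_bar,
         posterior_var = posterior_var, s_offset = s_offset, beta_clip = beta_clip),
    class = "diffusion_schedule")
}

#' Cumulative signal fraction at a timestep
#'
#' Returns \eqn{\bar\alpha_t}, with the `t = 0` boundary defined as 1
#' (the clean image, before any noise is added).
#'
#' @param schedule a [build_cosine_schedule()] object.
#' @param t integer timestep(s) in `0..T_steps`.
#' @return Numeric vector of \eqn{\bar\alpha_t} values.
#' @export
sched_alpha_bar <- function(schedule, t) {
  check_timestep(schedule, t, min_t = 0L)
  ifelse(t == 0, 1, schedule$alpha_bar[pmax(t, 1L)])
}

check_timestep <- function(schedule, t, min_t = 1L) {
  if (!inherits(schedule, "diffusion_schedule"))
    stop("not a diffusion_schedule", call. = FALSE)
  if (any(t < min_t) || any(t > schedule$T_steps) || any(t != round(t)))
    stop(sprintf("timestep out of range [%d, %d]", min_t, schedule$T_steps),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf("Cosine diffusion schedule: T = %d, s = %g, beta clip = %g\n",
              x$T_steps, x$s_offset, x$beta_clip))
  cat(sprintf("  beta in [%.3g, %.3g]; alpha_bar[T] = %.3g\n",
              min(x$beta), max(x$beta), x$alpha_bar[x$T_steps]))
  invisible(x)
}
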