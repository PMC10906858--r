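#' Fit a diffusion noise-prediction model
#'
#' Trains the denoiser of a denoising diffusion probabilistic model on a
#' batch of clean images: at every training draw an image is noised to a
#' uniformly drawn timestep with [forward_sample()] and the model learns
#' to predict the injected standard-normal noise (the simple diffusion
#' objective, mean squared error between drawn and predicted noise).
#'
#' The denoiser is a multiscale linear filter-bank model with sinusoidal
#' time conditioning: per voxel, the noise prediction is a linear
#' combination of feature maps of the noisy state (the raw state, Gaussian
#' smooths at several scales, a high-pass residual, and an intercept)
#' whose coefficients are modulated by a [sinusoidal_embedding()] of the
#' timestep,
#' \deqn{\hat\epsilon(x_t, t) = \sum_{j,k} W_{jk}\, F_j(x_t)\, e_k(t).}
#' The weights `W` are estimated in closed form by ridge-penalized least
#' squares on the accumulated training draws, which keeps CPU-only
#' training of small models in the seconds-to-minutes range while
#' honouring the denoiser contract used by [sample_from()]. Any drop-in
#' [denoiser()] can replace a fitted model everywhere in the package.
#'
#' @param x0_batch list of clean training images (arrays in `[0, 1]`),
#'   all of the same dimensionality.
#' @param schedule a [build_cosine_schedule()] object.
#' @param epochs passes over the batch, each taking one fresh
#'   (timestep, noise) draw per image; default 5000 matches the reference
#'   training budget, small fits use far fewer.
#' @param feature_sigmas Gaussian scales (pixels) of the smoothing
#'   feature maps.
#' @param embed_dim even dimension of the sinusoidal time embedding.
#' @param lambda ridge penalty per training voxel.
#' @param seed integer seed for the training draws.
#' @return An object of class `"ddpm"` with components `W` (feature by
#'   embedding coefficient matrix), `loss_initial` (loss of the
#'   zero-prediction baseline on the training draws), `loss_final`
#'   (residual training loss), `schedule`, and fit metadata. Supports
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `simulate` and
#'   `plot`.
#' @examples
#' sch <- build_cosine_schedule(50)
#' imgs <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
#' fit <- ddpm(imgs, sch, epochs = 10, seed = 1)
#' fit$loss_final < fit$loss_initial
#' @export
ddpm <- function(x0_batch, schedule, epochs = 5000, feature_sigmas = c(1, 2, 4),
                 embed_dim = 8, lambda = 1e-4, seed = NULL) {
  if (!is.list(x0_batch) || length(x0_batch) == 0)
    stop("x0_batch must be a non-empty list of arrays", call. = FALSE)
  if (epochs < 1) stop("epochs must be at least 1", call. = FALSE)
  p <- 3 + length(feature_sigmas)    # intercept, x, smooths..., high-pass
  d <- embed_dim
  A <- matrix(0, p * d, p * d)
  bvec <- numeric(p * d)
  yty <- 0
  n_total <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (x0 in x0_batch) {
        t <- sample.int(schedule$T_steps, 1L)
        eps <- array(stats::rnorm(length(x0)), arr_dim(x0))
        x_t <- forward_sample(x0, t, schedule, eps)
        F <- ddpm_features(x_t, feature_sigmas)
        e <- sinusoidal_embedding(t, d, schedule$T_steps)
        FtF <- crossprod(F)
        Fty <- crossprod(F, as.vector(eps))
        A <- A + kronecker(tcrossprod(e), FtF)
        bvec <- bvec + kronecker(e, Fty)[, 1]
        yty <- yty + sum(eps^2)
        n_total <- n_total + length(x0)
      }
    }
  })
  w <- solve(A + diag(lambda * n_total, p * d), bvec)
  W <- matrix(w, nrow = p, ncol = d)
  rownames(W) <- ddpm_feature_names(feature_sigmas)
  loss_final <- max(0, (yty - 2 * sum(w * bvec) + drop(crossprod(w, A %*% w))) / n_total)
  structure(
    list(W = W, feature_sigmas = feature_sigmas, embed_dim = d,
         schedule = schedule, epochs = epochs, n_draws = epochs * length(x0_batch),
         loss_initial = yty / n_total, loss_final = loss_final,
         shape = arr_dim(x0_batch[[1]]), x0_batch = x0_batch, seed = seed),
    class = "ddpm")
}

ddpm_feature_names <- function(sigmas) {
  c("intercept", "x", paste0("smooth_s", sigmas), "highpass")
}

# feature matrix: one row per voxel, one column per feature map
ddpm_features <- function(x_t, sigmas) {
  v <- as.vector(x_t)
  sm <- lapply(sigmas, function(s) as.vector(gaussian_filter(x_t, s)))
  cbind(1, v, do.call(cbind, sm), v - sm[[1]])
}

ddpm_denoiser <- function(fit) {
  force(fit)
  denoiser(function(x_t, t) {
    F <- ddpm_features(x_t, fit$feature_sigmas)
    e <- sinusoidal_embedding(t, fit$embed_dim, fit$schedule$T_steps)
    array(F %*% (fit$W %*% e), arr_dim(x_t))
  }, description = sprintf("fitted filter-bank denoiser (%d draws)", fit$n_draws))
}

#' @export
print.ddpm <- function(x, ...) {
  cat("Diffusion noise-prediction model (multiscale filter bank)\n")
  cat(sprintf("  schedule: T = %d (cosine); training draws: %d images x %d epochs\n",
              x$schedule$T_steps, length(x$x0_batch), x$epochs))
  cat(sprintf("  features: %s; time embedding dim %d\n",
              paste(rownames(x$W), collapse = ", "), x$embed_dim))
  cat(sprintf("  training loss: %.4f (baseline %.4f, reduction %.1f%%)\n",
              x$loss_final, x$loss_initial,
              100 * (1 - x$loss_final / x$loss_initial)))
  invisible(x)
}

#' @export
summary.ddpm <- function(object, ...) {
  structure(list(fit = object), class = "summary.ddpm")
}

#' @export
print.summary.ddpm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (feature x embedding component):\n")
  print(round(x$fit$W, 4))
  invisible(x)
}

#' @export
coef.ddpm <- function(object, ...) object$W

#' Predict the noise component (or the implied clean image)
#'
#' @param object a fitted [ddpm()] model.
#' @param x_t noisy state array.
#' @param t integer timestep the state was noised to.
#' @param type `"noise"` for \eqn{\hat\epsilon}; `"x0"` for the implied
#'   clean image \eqn{(x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/
#'   \sqrt{\bar\alpha_t}}.
#' @param ... unused.
#' @return Array of the same shape as `x_t`.
#' @export
predict.ddpm <- function(object, x_t, t, type = c("noise", "x0"), ...) {
  type <- match.arg(type)
  check_timestep(object$schedule, t)
  eps_hat <- denoiser_predict(ddpm_denoiser(object), x_t, t)
  if (type == "noise") return(eps_hat)
  ab <- object$schedule$alpha_bar[t]
  (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

#' Noise-prediction residuals on fresh diffusion draws
#'
#' Draws `(t, eps)` pairs for the stored training images exactly as the
#' training objective does and returns the per-draw residual arrays
#' `eps - eps_hat`, the quantity the fit minimizes in mean square.
#'
#' @param object a fitted [ddpm()] model.
#' @param newdata optional list of clean images; defaults to the
#'   training batch.
#' @param seed integer seed for the draws.
#' @param ... unused.
#' @return List of residual arrays, one per image.
#' @export
residuals.ddpm <- function(object, newdata = NULL, seed = 0L, ...) {
  batch <- newdata %||% object$x0_batch
  den <- ddpm_denoiser(object)
  with_seed(seed, lapply(batch, function(x0) {
    t <- sample.int(object$schedule$T_steps, 1L)
    eps <- array(stats::rnorm(length(x0)), arr_dim(x0))
    x_t <- forward_sample(x0, t, object$schedule, eps)
    eps - denoiser_predict(den, x_t, t)
  }))
}

#' Simulate images from a fitted diffusion model
#'
#' Unconditional simulation runs the full backward process from pure
#' noise (`t_start = T`). Supplying a `sketch` switches to
#' sketch-conditioned generation: the sketch is Gaussian-smoothed with
#' `sigma`, noised to the early timestep `t_start` with
#' [forward_sample()], and denoised back — the pipeline that turns a
#' coarse structural sketch into a realistic image while preserving the
#' sketched scene.
#'
#' @param object a fitted [ddpm()] model.
#' @param nsim number of images to simulate.
#' @param seed integer master seed; per-image seeds are derived from it.
#' @param sketch optional sketch array in `[0, 1]`.
#' @param t_start starting timestep; defaults to `T` (pure noise) when
#'   `sketch` is `NULL` and to `0.4 * T` otherwise.
#' @param sigma Gaussian smoothing applied to the sketch (default 1).
#' @param shape shape of unconditional simulations; defaults to the
#'   training image shape.
#' @param ... unused.
#' @return List of `nsim` generated images in `[0, 1]`.
#' @export
simulate.ddpm <- function(object, nsim = 1, seed = NULL, sketch = NULL,
                          t_start = NULL, sigma = 1, shape = NULL, ...) {
  sch <- object$schedule
  if (is.null(t_start))
    t_start <- if (is.null(sketch)) sch$T_steps else max(1L, round(0.4 * sch$T_steps))
  check_timestep(sch, t_start)
  shape <- shape %||% (if (is.null(sketch)) object$shape else arr_dim(sketch))
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), nsim)
  den <- ddpm_denoiser(object)
  lapply(seq_len(nsim), function(i) {
    with_seed(seeds[i], {
      start <- if (is.null(sketch)) {
        array(stats::rnorm(prod(shape)), shape)
      } else {
        forward_sample(gaussian_filter(sketch, sigma), t_start, sch)
      }
      sample_from(start, t_start, den, sch)
    })
  })
}

#' Diagnostic plot of a fitted diffusion model
#'
#' Left: the cosine schedule's cumulative signal fraction
#' \eqn{\bar\alpha_t}. Right: noise-prediction loss as a function of the
#' timestep, evaluated on the training batch, against the
#' zero-prediction baseline of 1.
#'
#' @param x a fitted [ddpm()] model.
#' @param n_t number of timesteps at which to evaluate the loss curve.
#' @param seed seed for the evaluation noise draws.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the data frame of the per-timestep losses.
#' @export
plot.ddpm <- function(x, n_t = 12, seed = 0L, ...) {
  sch <- x$schedule
  ts <- unique(round(seq(1, sch$T_steps, length.out = n_t)))
  den <- ddpm_denoiser(x)
  loss <- with_seed(seed, vapply(ts, function(t) {
    mean(vapply(x$x0_batch, function(x0) {
      eps <- array(stats::rnorm(length(x0)), arr_dim(x0))
      x_t <- forward_sample(x0, t, sch, eps)
      mean((eps - denoiser_predict(den, x_t, t))^2)
    }, numeric(1)))
  }, numeric(1)))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(sch$T_steps), sch$alpha_bar, type = "l",
                 xlab = "t", ylab = expression(bar(alpha)[t]),
                 main = "noise schedule", ...)
  graphics::plot(ts, loss, type = "b", xlab = "t", ylab = "noise MSE",
                 main = "denoiser loss by timestep",
                 ylim = c(0, max(1, loss)), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(data.frame(t = ts, loss = loss))
}

#' Save / load a denoiser checkpoint
#'
#' The checkpoint is a single self-describing archive (serialized list
#' with a `version` field) holding the fitted weights, feature
#' configuration, schedule and normalization convention, sufficient to
#' reproduce predictions exactly.
#'
#' @param fit a fitted [ddpm()] model.
#' @param path file path for the checkpoint.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the restored `"ddpm"` object.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ddpm"))
  obj <- unclass(fit)
  obj$x0_batch <- NULL            # weights + config only
  saveRDS(list(version = 1L, format = "sketchdiff-ddpm",
               intensity_range = c(0, 1), fit = obj), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "sketchdiff-ddpm"))
    stop("not a sketchdiff denoiser checkpoint", call. = FALSE)
  fit <- ck$fit
  fit$x0_batch <- list()
  class(fit) <- "ddpm"
  fit
}
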