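# shared fixtures and independent brute-force oracles

tiny_schedule <- function(T_steps = 20) build_cosine_schedule(T_steps)

# hand-assembled schedule with prescribed coefficients, for algebra checks
fake_schedule <- function(alpha) {
  alpha_bar <- cumprod(alpha)
  beta <- 1 - alpha
  prev <- c(1, alpha_bar[-length(alpha)])
  pv <- beta * (1 - prev) / (1 - alpha_bar)
  pv[1] <- beta[1]
  structure(list(T_steps = length(alpha), beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, posterior_var = pv,
                 s_offset = NA, beta_clip = NA),
            class = "diffusion_schedule")
}

# brute-force metric oracles, written naively with loops

bf_bhattacharyya <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + sqrt(p[i] * q[i])
  -log(s)
}

bf_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  s
}

bf_psnr <- function(x, ref, factor) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - ref[i])^2
  factor * log10(1 / (s / length(x)))
}

bf_zncc <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  sa <- sqrt(sum((a - ma)^2) / n); sb <- sqrt(sum((b - mb)^2) / n)
  s <- 0
  for (i in seq_len(n)) s <- s + (a[i] - ma) / sa * (b[i] - mb) / sb
  s / n
}

bf_iou <- function(p, g) {
  inter <- 0; uni <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0 && g[i] > 0) inter <- inter + 1
    if (p[i] > 0 || g[i] > 0) uni <- uni + 1
  }
  inter / uni
}

# brute-force ellipsoid membership over the full grid
bf_ellipsoid <- function(shape, center, r, scale, rot = NULL) {
  out <- array(FALSE, shape)
  grid <- as.matrix(expand.grid(lapply(shape, seq_len)))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ] - center
    if (!is.null(rot)) p <- as.numeric(t(rot) %*% p)
    out[matrix(grid[i, ], 1)] <- sum((p / (scale * r))^2) <= 1
  }
  out
}

small_toy <- function(n = 4, shape = c(24, 24), seed = 0L) {
  make_toy_dataset(toy_world_config(image_shape = shape, n_cells = 3,
                                    r_nuclei_range = c(2, 4), seed = seed), n)
}

# logical mask -> minimal integer label mask
finalize_mask_for_test <- function(mask) {
  array(as.integer(mask), dim(mask))
}
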