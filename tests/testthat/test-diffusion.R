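test_that("closed-form forward sample evaluates the reparameterization", {
  sch <- fake_schedule(c(0.8, 0.8))           # alpha_bar = (0.8, 0.64)
  x0 <- array(1, 1)
  expect_equal(forward_sample(x0, 2, sch, eps = array(0.5, 1)),
               array(0.8 + 0.6 * 0.5, 1))     # sqrt(.64)*1 + sqrt(.36)*.5
  expect_equal(forward_sample(x0, 2, sch, eps = array(0, 1)),
               array(sqrt(0.64), 1))
  expect_error(forward_sample(x0, 3, sch), "range")
  expect_error(forward_sample(x0, 1, sch, eps = array(0, 2)), "shape")
})

test_that("single forward step scales signal and noise correctly", {
  sch <- tiny_schedule(10)
  x <- array(runif(16), c(4, 4))
  b <- sch$beta[4]
  expect_equal(forward_step(x, 4, sch, eps = array(0, c(4, 4))),
               sqrt(1 - b) * x)
  expect_equal(forward_step(array(0, c(4, 4)), 4, sch, eps = array(1, c(4, 4))),
               array(sqrt(b), c(4, 4)))
})

test_that("closed form agrees with the iterated chain in mean and variance", {
  sch <- tiny_schedule(20)
  n_draws <- 10000
  for (case in list(list(x0 = 0.9, t = 5), list(x0 = 0.3, t = 12),
                    list(x0 = 0.6, t = 20))) {
    x0 <- rep(case$x0, n_draws)
    set.seed(101)
    closed <- forward_sample(x0, case$t, sch)
    set.seed(202)
    chain <- x0
    for (t in seq_len(case$t)) chain <- forward_step(chain, t, sch)
    ab <- sch$alpha_bar[case$t]
    se_mean <- sqrt((1 - ab) / n_draws)
    expect_lt(abs(mean(closed) - sqrt(ab) * case$x0), 4 * se_mean)
    expect_lt(abs(mean(chain) - sqrt(ab) * case$x0), 4 * se_mean)
    se_var <- (1 - ab) * sqrt(2 / (n_draws - 1))
    expect_lt(abs(var(closed) - (1 - ab)), 4 * se_var)
    expect_lt(abs(var(chain) - (1 - ab)), 4 * se_var)
  }
})

test_that("one backward step reproduces the derived closed form", {
  # alpha_t = 0.99, alpha_bar_t = 0.64 => alpha_bar_{t-1} = 0.64/0.99
  sch <- fake_schedule(c(0.64 / 0.99, 0.99))
  x0 <- 1; eps <- 0.5
  x_t <- sqrt(0.64) * x0 + sqrt(0.36) * eps   # = 1.1
  got <- backward_step(array(x_t, 1), 2, array(eps, 1), sch, z = array(0, 1))
  expect_equal(as.numeric(got), 1.0971673, tolerance = 1e-6)
  ab_prev <- 0.64 / 0.99
  ident <- sqrt(ab_prev) * x0 + sqrt(0.99) * (1 - ab_prev) / sqrt(0.36) * eps
  expect_lt(abs(as.numeric(got) - ident), 1e-10)
})

test_that("backward step with no correction just rescales", {
  sch <- tiny_schedule(10)
  x <- array(runif(9), c(3, 3))
  got <- backward_step(x, 5, array(0, c(3, 3)), sch, z = array(0, c(3, 3)))
  expect_equal(got, x / sqrt(sch$alpha[5]))
})

test_that("oracle-denoiser backward pass recovers the clean image", {
  sch <- tiny_schedule(50)
  set.seed(3)
  x0 <- matrix(runif(64), 8, 8)
  den <- oracle_denoiser(x0, sch)
  for (t_start in c(1, 10, 50)) {
    eps <- matrix(rnorm(64), 8, 8)
    x <- forward_sample(x0, t_start, sch, eps)
    for (t in seq(t_start, 1)) {
      x <- backward_step(x, t, den$fn(x, t), sch, z = array(0, dim(x)))
    }
    expect_lt(max(abs(x - x0)), 1e-4)
  }
})

test_that("sampler is deterministic under a fixed seed", {
  sch <- tiny_schedule(20)
  set.seed(9)
  x0 <- matrix(runif(36), 6, 6)
  den <- oracle_denoiser(x0, sch)
  x_start <- forward_sample(x0, 15, sch)
  a <- sample_from(x_start, 15, den, sch, seed = 42)
  b <- sample_from(x_start, 15, den, sch, seed = 42)
  expect_identical(a, b)
  # t_start = T is the classic pure-noise sampler; just exercise the path
  full <- sample_from(matrix(rnorm(36), 6, 6), sch$T_steps, den, sch, seed = 1)
  expect_true(all(full >= 0 & full <= 1))
})

test_that("training loss is zero for the oracle and ~1 for zero prediction", {
  sch <- tiny_schedule(20)
  set.seed(5)
  batch <- replicate(4, matrix(runif(256), 16, 16), simplify = FALSE)
  # oracle that reads back the drawn noise exactly
  oracle_each <- denoiser(function(x_t, t) {
    # reconstructs eps for whichever batch member produced x_t
    best <- NULL; best_err <- Inf
    for (x0 in batch) {
      ab <- sch$alpha_bar[t]
      cand <- (x_t - sqrt(ab) * x0) / sqrt(1 - ab)
      err <- sum((forward_sample(x0, t, sch, cand) - x_t)^2)
      if (err < best_err) { best <- cand; best_err <- err }
    }
    best
  })
  expect_lt(training_loss(oracle_each, batch, sch, seed = 7), 1e-6)
  l0 <- training_loss(zero_denoiser(), batch, sch, seed = 7)
  expect_gte(l0, 0)
  expect_equal(l0, 1, tolerance = 0.1)
  expect_error(training_loss(zero_denoiser(), list(), sch), "non-empty")
})

test_that("sinusoidal embeddings are bounded, injective and anchored at t = 0", {
  e0 <- sinusoidal_embedding(0, 8, 100)
  expect_equal(e0, c(rep(0, 4), rep(1, 4)))
  embs <- sapply(0:100, sinusoidal_embedding, dim = 8, T_max = 100)
  expect_equal(anyDuplicated(t(embs)), 0L)
  expect_true(all(abs(embs) <= 1))
  expect_error(sinusoidal_embedding(3, 7, 100), "even")
})
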