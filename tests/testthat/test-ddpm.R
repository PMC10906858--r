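test_that("fitting reduces the noise-prediction loss well below baseline", {
  toy <- small_toy(6)
  fit <- train_tiny_denoiser(toy, T_steps = 50, epochs = 25, seed = 0)
  expect_s3_class(fit, "ddpm")
  expect_lt(fit$loss_final, 0.7 * fit$loss_initial)
  # held-out draws, not the training accumulation
  held_out <- training_loss(fit, lapply(toy, `[[`, "image"), fit$schedule, seed = 99)
  expect_lt(held_out, 0.7)
  # a second seed trains comparably (robustness of the margin)
  fit2 <- train_tiny_denoiser(toy, T_steps = 50, epochs = 25, seed = 1)
  expect_lt(fit2$loss_final, 0.7 * fit2$loss_initial)
})

test_that("model methods expose the standard fit interface", {
  toy <- small_toy(4)
  fit <- ddpm(lapply(toy, `[[`, "image"), build_cosine_schedule(40),
              epochs = 10, seed = 2)
  W <- coef(fit)
  expect_equal(dim(W), c(6, 8))
  expect_true("highpass" %in% rownames(W))
  x_t <- forward_sample(toy[[1]]$image, 20, fit$schedule,
                        eps = array(0, dim(toy[[1]]$image)))
  eps_hat <- predict(fit, x_t, 20)
  expect_equal(dim(eps_hat), dim(x_t))
  x0_hat <- predict(fit, x_t, 20, type = "x0")
  ab <- fit$schedule$alpha_bar[20]
  expect_equal(x0_hat, (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab))
  res <- residuals(fit, seed = 1)
  expect_length(res, 4)
  expect_identical(res, residuals(fit, seed = 1))
  expect_output(print(fit), "filter bank")
  expect_output(print(summary(fit)), "Coefficients")
  grDevices::pdf(NULL)
  curve <- plot(fit, n_t = 4, seed = 0)
  grDevices::dev.off()
  expect_named(curve, c("t", "loss"))
})

test_that("simulate is reproducible and honours sketch conditioning", {
  toy <- small_toy(4)
  fit <- ddpm(lapply(toy, `[[`, "image"), build_cosine_schedule(40),
              epochs = 10, seed = 2)
  s1 <- simulate(fit, nsim = 2, seed = 7)
  s2 <- simulate(fit, nsim = 2, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1[[1]], s1[[2]]))
  cond <- simulate(fit, nsim = 1, seed = 7, sketch = toy[[1]]$sketch)[[1]]
  expect_equal(dim(cond), dim(toy[[1]]$sketch))
  expect_true(all(cond >= 0 & cond <= 1))
})

test_that("checkpoints round-trip weights and predictions exactly", {
  toy <- small_toy(3)
  fit <- ddpm(lapply(toy, `[[`, "image"), build_cosine_schedule(30),
              epochs = 8, seed = 4)
  ck <- tempfile(fileext = ".rds")
  write_checkpoint(fit, ck)
  back <- read_checkpoint(ck)
  x_t <- forward_sample(toy[[1]]$image, 10, fit$schedule)
  expect_identical(predict(fit, x_t, 10), predict(back, x_t, 10))
  expect_identical(coef(fit), coef(back))
  saveRDS(list(a = 1), ck)
  expect_error(read_checkpoint(ck), "checkpoint")
})
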