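test_that("reparameterisation trick is exact and unbiased", {
  mu <- c(1, -2)
  lv <- c(0, 0)
  expect_equal(reparameterize(mu, lv, c(0, 0)), mu)
  expect_equal(reparameterize(mu, lv, c(1, 1)), mu + 1)
  expect_equal(reparameterize(3, log(4), 2), 3 + 2 * 2)   # sigma = 2
  set.seed(6)
  z <- replicate(1e5, reparameterize(0.5, 0.3, rnorm(1)))
  se <- exp(0.3 / 2) / sqrt(1e5)
  expect_lt(abs(mean(z) - 0.5), 3 * se)
})

test_that("loss closed forms: KL at the prior and BCE of the 0.5 vector", {
  x <- matrix(0.5, 1, 14)
  l0 <- vae_loss(x, x, matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(l0$kl, 0)
  expect_equal(l0$bce, 14 * log(2))
  mu <- matrix(c(1.5, -0.5), 1, 2)
  l1 <- vae_loss(x, x, mu, matrix(0, 1, 2))
  expect_equal(l1$kl, 0.5 * sum(mu^2))
  expect_gt(l1$kl, 0)
  # KL non-negative for random parameters
  set.seed(7)
  for (i in 1:20) {
    l <- vae_loss(x, x, matrix(rnorm(2), 1), matrix(rnorm(2), 1))
    expect_gte(l$kl, -1e-12)
  }
})

test_that("loss stays finite at clamped reconstruction extremes", {
  x <- matrix(c(0, 1), 1, 14)[, 1:14, drop = FALSE]
  xh <- matrix(c(1, 0), 1, 14)[, 1:14, drop = FALSE]   # worst case
  l <- vae_loss(x, xh, matrix(0, 1, 2), matrix(0, 1, 2))
  expect_true(is.finite(l$total))
})

train_toy <- function(seed = 8, epochs = 40, n = 300) {
  set.seed(seed)
  X <- matrix(runif(n * 14, 0.2, 0.8), n, 14)
  vae_train(X, X[1:50, , drop = FALSE],
            vae_config(epochs = epochs, seed = seed))
}

test_that("training reduces the loss and is bit-reproducible", {
  f1 <- train_toy()
  h <- f1$loss_history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(is.finite(h$val_loss)))
  f2 <- train_toy()
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$par, f2$par)
})

test_that("anomaly score is deterministic, non-negative, zero at perfection", {
  fit <- train_toy(epochs = 5)
  X <- matrix(runif(20 * 14), 20, 14)
  s1 <- anomaly_score(fit, X)
  s2 <- anomaly_score(fit, X)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  expect_identical(s1[1], anomaly_score(fit, X[c(1, 1), ])[2])  # duplicated row
  # score equals the hand-computed excess BCE of the mean-path reconstruction
  fw <- pgesr:::vae_forward(fit$par, X, eps = matrix(0, 20, 2))
  bce <- -(X * log(fw$Y) + (1 - X) * log(1 - fw$Y))
  flr <- -(X * log(X) + (1 - X) * log(1 - X))
  expect_equal(s1, rowMeans(bce - flr), tolerance = 1e-10)
})

test_that("background-trained model scores suppression rows higher", {
  set.seed(9)
  n_bg <- 400
  bg <- matrix(runif(n_bg * 14, 0.3, 0.7), n_bg, 14)
  pg <- matrix(runif(60 * 14, 0, 0.05), 60, 14)       # ~10x amplitude contrast
  fit <- vae_train(bg, bg[1:80, ], vae_config(epochs = 60, seed = 9))
  expect_gt(mean(anomaly_score(fit, pg)), mean(anomaly_score(fit, bg)))
})

test_that("threshold selection maximises F1 and breaks ties low", {
  # cleanly separable: any threshold in the gap classifies perfectly
  th <- select_threshold(rep(0.01, 10), rep(0.05, 5))
  expect_gt(th$threshold, 0.01)
  expect_lte(th$threshold, 0.05)
  expect_equal(th$f1, 1)

  set.seed(10)
  for (i in 1:25) {
    bg <- round(runif(40), 2)
    pg <- round(runif(25, 0.2, 1.2), 2)
    got <- select_threshold(bg, pg)
    expect_equal(got$f1, best_f1_oracle(bg, pg), tolerance = 1e-12)
  }

  expect_warning(d <- select_threshold(rep(1, 5), rep(1, 5)), "identical")
  expect_equal(d$threshold, 1)
  expect_error(select_threshold(numeric(0), 1), "non-empty")
})

test_that("classification is strict at the threshold", {
  expect_equal(classify(c(0.03, 0.02, 0.01, 0), 0.02), c(1L, 0L, 0L, 0L))
})

test_that("broom methods and checkpoint round-trip", {
  fit <- train_toy(epochs = 4)
  td <- tidy(fit)
  expect_named(td, c("epoch", "split", "loss"))
  expect_setequal(unique(td$split), c("train", "val"))
  g <- glance(fit)
  expect_equal(g$n_parameters, 14 * 14 + 14 + 2 * (14 * 2 + 2) + 2 * 14 + 14 + 14 * 14 + 14)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
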