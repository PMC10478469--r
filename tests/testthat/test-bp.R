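test_that("scalers map feature ranges onto [-1, 1] and invert exactly", {
  X <- cbind(a = c(7000, 9500, 8250), b = c(0, 1, 0.5), c = c(1, 3, 2))
  y <- c(4833.89, 7012.88, 6000)
  sc <- fit_scalers(X, y)
  Xs <- petiolenpk:::scale_x(sc, X)
  expect_equal(Xs[, 1], c(-1, 1, 0))
  # yield is handled in t/ha
  expect_equal(sc$y_lo, 4.83389)
  expect_equal(sc$y_hi, 7.01288)
  ys <- petiolenpk:::scale_y(sc, y)
  expect_equal(petiolenpk:::unscale_y(sc, ys), y / 1000, tolerance = 1e-12)
  expect_error(fit_scalers(cbind(c(1, 1), c(1, 2)), c(1, 2)), "Constant")
})

test_that("the weight codec is a lossless length-51 round trip", {
  net <- random_net(seed = 2)
  v <- bp_encode(net)
  expect_length(v, 51) # 3*10 + 10 + 10*1 + 1
  back <- bp_decode(v, net$config, net$scalers)
  expect_identical(back$W1, net$W1)
  expect_identical(back$b1, net$b1)
  expect_identical(back$W2, net$W2)
  expect_identical(back$b2, net$b2)
  expect_error(bp_decode(v[-1], net$config, net$scalers), "length")
  zero <- bp_decode(numeric(51), net$config, net$scalers)
  expect_true(all(zero$W1 == 0) && all(zero$b2 == 0))
})

test_that("an all-zero network predicts the mid-range of the target", {
  dat <- tiny_training_data(seed = 4)
  sc <- fit_scalers(dat$X, dat$y)
  net <- bp_decode(numeric(51), bp_config(), sc)
  pred <- bp_forward(net, dat$X)
  mid <- (min(dat$y) + max(dat$y)) / 2 / 1000
  expect_equal(pred, rep(mid, nrow(dat$X)), tolerance = 1e-12)
  expect_error(bp_forward(net, dat$X[, 1:2]), "columns")
})

test_that("a single-hidden-unit network matches a hand-evaluated tanh", {
  cfg <- bp_config(n_input = 2, n_hidden = 1, seed = 1)
  X <- cbind(c(0, 1, 2), c(0, 2, 4))
  y <- c(5000, 6000, 7000)
  sc <- fit_scalers(X, y)
  # layout: W1 (2), b1 (1), W2 (1), b2 (1)
  net <- bp_decode(c(0.3, -0.2, 0.1, 0.7, 0.05), cfg, sc)
  x_raw <- c(1.5, 1.5)
  xs <- 2 * (x_raw - c(0, 0)) / (c(2, 4) - c(0, 0)) - 1 # hand min-max
  hand <- 0.7 * tanh(0.3 * xs[1] - 0.2 * xs[2] + 0.1) + 0.05
  hand_t_ha <- (hand + 1) / 2 * (7 - 5) + 5
  expect_equal(bp_forward(net, matrix(x_raw, 1)), hand_t_ha,
               tolerance = 1e-12)
})

test_that("forward output is stateless under row permutation", {
  net <- random_net(seed = 5)
  dat <- tiny_training_data(seed = 5)
  p1 <- bp_forward(net, dat$X)
  perm <- c(3, 1, 2, 4:nrow(dat$X))
  expect_equal(bp_forward(net, dat$X[perm, ]), p1[perm])
})

test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (s in 1:20) {
    dat <- tiny_training_data(seed = 100 + s, n = 8)
    cfg <- bp_config(seed = s)
    sc <- fit_scalers(dat$X, dat$y)
    net <- bp_init(cfg, sc)
    g <- bp_gradient(net, dat$X, dat$y)
    v <- bp_encode(net)
    eps <- 1e-6
    g_fd <- vapply(seq_along(v), function(j) {
      vp <- v; vp[j] <- vp[j] + eps
      vm <- v; vm[j] <- vm[j] - eps
      (bp_loss(bp_decode(vp, cfg, sc), dat$X, dat$y) -
         bp_loss(bp_decode(vm, cfg, sc), dat$X, dat$y)) / (2 * eps)
    }, numeric(1))
    rel <- sqrt(sum((g - g_fd)^2)) / max(sqrt(sum(g^2)), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("training runs exactly `epochs` updates and descends", {
  drops <- sapply(1:10, function(s) {
    dat <- tiny_training_data(seed = 200 + s, n = 30)
    cfg <- bp_config(seed = s)
    net <- bp_init(cfg, fit_scalers(dat$X, dat$y))
    fit <- bp_train(net, dat$X, dat$y, cfg)
    expect_length(fit$loss_history, 200)
    utils::tail(fit$loss_history, 1) < fit$initial_loss
  })
  expect_true(all(drops))
})

test_that("zero learning rate leaves the network untouched", {
  dat <- tiny_training_data(seed = 6)
  cfg <- bp_config(learning_rate = 0, epochs = 5, seed = 6)
  net <- bp_init(cfg, fit_scalers(dat$X, dat$y))
  fit <- bp_train(net, dat$X, dat$y, cfg)
  expect_identical(bp_encode(fit), bp_encode(net))
  expect_equal(fit$loss_history, rep(fit$initial_loss, 5))
})

test_that("loss is non-increasing at a small learning rate", {
  dat <- tiny_training_data(seed = 7, n = 40)
  cfg <- bp_config(learning_rate = 1e-4, epochs = 100, seed = 7)
  net <- bp_init(cfg, fit_scalers(dat$X, dat$y))
  fit <- bp_train(net, dat$X, dat$y, cfg)
  expect_true(all(diff(c(fit$initial_loss, fit$loss_history)) <= 1e-12))
})

test_that("training is bit-for-bit deterministic under a seed", {
  dat <- tiny_training_data(seed = 8)
  cfg <- bp_config(seed = 8, epochs = 50)
  f1 <- bp_train(bp_init(cfg, fit_scalers(dat$X, dat$y)), dat$X, dat$y, cfg)
  f2 <- bp_train(bp_init(cfg, fit_scalers(dat$X, dat$y)), dat$X, dat$y, cfg)
  expect_identical(bp_encode(f1), bp_encode(f2))
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("models survive a JSON round trip and tidy/glance behave", {
  dat <- tiny_training_data(seed = 9)
  cfg <- bp_config(seed = 9, epochs = 10)
  fit <- bp_train(bp_init(cfg, fit_scalers(dat$X, dat$y)), dat$X, dat$y, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_bp_model(fit, path)
  back <- read_bp_model(path)
  expect_equal(bp_forward(back, dat$X), bp_forward(fit, dat$X),
               tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(nrow(td), 51)
  expect_equal(sum(td$value), sum(bp_encode(fit)))
  gl <- glance(fit)
  expect_true(gl$trained)
  expect_equal(gl$final_loss, utils::tail(fit$loss_history, 1))
})
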