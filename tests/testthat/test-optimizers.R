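test_that("fitness equals an independently composed forward-pass RMSE", {
  dat <- tiny_training_data(seed = 1)
  cfg <- bp_config(seed = 1)
  sc <- fit_scalers(dat$X, dat$y)
  fitness <- make_bp_fitness(dat$X, dat$y, cfg, sc)
  set.seed(2)
  for (i in 1:5) {
    v <- runif(51, -1, 1)
    # independent composition written out by hand
    W1 <- matrix(v[1:30], nrow = 3, byrow = TRUE)
    b1 <- v[31:40]
    W2 <- v[41:50]
    b2 <- v[51]
    Xs <- sapply(1:3, function(j) {
      2 * (dat$X[, j] - min(dat$X[, j])) /
        (max(dat$X[, j]) - min(dat$X[, j])) - 1
    })
    ys <- 2 * (dat$y / 1000 - min(dat$y / 1000)) /
      (max(dat$y / 1000) - min(dat$y / 1000)) - 1
    H <- tanh(Xs %*% W1 + matrix(b1, nrow(Xs), 10, byrow = TRUE))
    yhat <- as.vector(H %*% W2) + b2
    expect_equal(fitness(v), sqrt(mean((yhat - ys)^2)), tolerance = 1e-12)
    expect_gte(fitness(v), 0)
  }
  expect_error(fitness(v[-1]), "length")
})

test_that("a crafted weight vector drives the fitness to zero", {
  X <- cbind(c(0, 1), c(5, 6), c(7, 8))
  y <- c(5000, 6000)
  cfg <- bp_config()
  v <- numeric(51)
  v[1] <- 1                 # W1[1,1]: first input to first hidden unit
  v[41] <- 1 / tanh(1)      # W2[1]: undo the tanh at x1s = +/- 1
  fitness <- make_bp_fitness(X, y, cfg)
  expect_equal(fitness(v), 0, tolerance = 1e-12)
})

test_that("both optimizers crush the sphere and keep monotone traces", {
  ratios <- sapply(1:10, function(s) {
    cfg <- optimizer_config(population = 20, iterations = 200, seed = s)
    set.seed(1000 + s)
    ref <- mean(apply(matrix(runif(20 * 51, -1, 1), 20), 1, sphere))
    sapply(list(sso = sso_optimize, gwo = gwo_optimize), function(opt) {
      tr <- opt(sphere, cfg, 51)
      expect_true(all(diff(tr$history) <= 0))
      expect_length(tr$history, 200)
      ref / tr$best_fitness
    })
  })
  expect_gte(sum(ratios["sso", ] >= 100), 9)
  expect_gte(sum(ratios["gwo", ] >= 100), 9)
})

test_that("optimizers beat random search at an equal evaluation budget", {
  wins <- sapply(1:10, function(s) {
    cfg <- optimizer_config(population = 20, iterations = 50, seed = s)
    budget <- (50 + 1) * 20
    unlist(lapply(list(sphere = sphere, rosenbrock = rosenbrock),
                  function(fn) {
      set.seed(2000 + s)
      rand_best <- min(apply(matrix(runif(budget * 20, -1, 1), budget),
                             1, fn))
      c(sso = sso_optimize(fn, cfg, 20)$best_fitness < rand_best,
        gwo = gwo_optimize(fn, cfg, 20)$best_fitness < rand_best)
    }))
  })
  expect_gte(sum(wins["sphere.sso", ]), 9)
  expect_gte(sum(wins["sphere.gwo", ]), 9)
  expect_gte(sum(wins["rosenbrock.sso", ]), 9)
  expect_gte(sum(wins["rosenbrock.gwo", ]), 9)
})

test_that("positions respect bounds and runs are seed-deterministic", {
  cfg <- optimizer_config(population = 6, iterations = 15, seed = 3,
                          bounds = c(-0.5, 0.5))
  for (opt in list(sso_optimize, gwo_optimize)) {
    t1 <- opt(sphere, cfg, 8)
    t2 <- opt(sphere, cfg, 8)
    expect_identical(t1$history, t2$history)
    expect_identical(t1$best, t2$best)
    expect_true(all(t1$best >= -0.5 & t1$best <= 0.5))
  }
})

test_that("degenerate configurations still run", {
  cfg1 <- optimizer_config(population = 20, iterations = 1, seed = 4)
  tr <- gwo_optimize(sphere, cfg1, 10)
  expect_length(tr$history, 1)
  cfg2 <- optimizer_config(population = 3, iterations = 1, seed = 4)
  tr2 <- sso_optimize(sphere, cfg2, 10)
  expect_length(tr2$history, 1)
  expect_error(gwo_optimize(function(x) NaN, cfg1, 3), "Non-finite")
})

test_that("zero optimizer iterations reduce to plain backpropagation", {
  dat <- tiny_training_data(seed = 10, n = 25)
  cfg <- bp_config(seed = 10, epochs = 30)
  plain <- optimize_then_train("none", dat$X, dat$y, cfg)
  disabled <- optimize_then_train(
    "SSO", dat$X, dat$y, cfg,
    opt_config = optimizer_config("SSO", iterations = 0, seed = 1))
  expect_identical(bp_encode(plain), bp_encode(disabled))
  expect_equal(plain$method, "BP")
  expect_equal(disabled$method, "BP")
})

test_that("optimized initial weights train to no worse a fit than random", {
  spec <- generator_spec(seed = 17)
  fields <- generate_fields(spec)
  survey <- fields[fields$split == "survey", ]
  X <- survey[paste0("full_bud_", c("NO3N", "PO4P", "KK"))]
  y <- survey$yield_kg_ha
  wins <- sapply(1:10, function(s) {
    bp_cfg <- bp_config(seed = s)
    plain <- optimize_then_train("none", X, y, bp_cfg)
    sapply(c("SSO", "GWO"), function(alg) {
      opt <- optimize_then_train(
        alg, X, y, bp_cfg, optimizer_config(alg, seed = s + 500))
      utils::tail(opt$loss_history, 1) <=
        utils::tail(plain$loss_history, 1) + 1e-12
    })
  })
  expect_gte(sum(wins["SSO", ]), 8)
  expect_gte(sum(wins["GWO", ]), 8)
})

test_that("optimize-then-train is reproducible and carries its trace", {
  dat <- tiny_training_data(seed = 11, n = 25)
  cfg <- bp_config(seed = 11, epochs = 20)
  ocfg <- optimizer_config("GWO", seed = 12)
  f1 <- optimize_then_train("GWO", dat$X, dat$y, cfg, ocfg)
  f2 <- optimize_then_train("GWO", dat$X, dat$y, cfg, ocfg)
  expect_identical(bp_encode(f1), bp_encode(f2))
  expect_equal(f1$method, "GWO-BP")
  expect_s3_class(f1$trace, "npk_trace")
  expect_equal(tidy(f1$trace)$best_fitness, f1$trace$history)
  expect_equal(glance(f1$trace)$evaluations, f1$trace$evaluations)
})
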