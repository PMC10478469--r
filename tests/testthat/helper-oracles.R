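# Independent oracles and small fixture builders shared across tests.

# truncated-normal moments by numerical integration of the truncated
# density (independent of the package's closed-form route)
tn_moments_integrate <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi,
                        rel.tol = 1e-10)$value
  m <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi,
                        rel.tol = 1e-10)$value / z
  v <- stats::integrate(function(x) (x - m)^2 * stats::dnorm(x, mean, sd),
                        lo, hi, rel.tol = 1e-10)$value / z
  c(mean = m, sd = sqrt(v))
}

# benchmark objectives for the optimizers
sphere <- function(x) sum(x^2)
rosenbrock <- function(x) {
  n <- length(x)
  sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
}

# small random regression problem on realistic scales
tiny_training_data <- function(seed = 1, n = 12) {
  set.seed(seed)
  X <- cbind(runif(n, 7000, 9500), runif(n, 85, 180), runif(n, 7000, 9000))
  y <- runif(n, 4800, 7100)
  list(X = X, y = y)
}

# a network over random scalers, for codec/gradient tests
random_net <- function(seed = 1, config = bp_config(seed = seed)) {
  dat <- tiny_training_data(seed)
  scalers <- fit_scalers(dat$X, dat$y)
  bp_init(config, scalers)
}

# the published yield-graded monitor intervals, hand-frozen
frozen_monitor_intervals <- function() {
  rows <- list(
    # stage, class, NO3N lo/hi, PO4P lo/hi, KK lo/hi
    list("full_bud", "HIGH", c(9000, 11000), c(100, 265), c(8000, 10000)),
    list("full_bloom", "HIGH", c(6500, 8500), c(270, 400), c(6000, 8500)),
    list("full_boll", "HIGH", c(5000, 7500), c(185, 300), c(4000, 6500)),
    list("full_bud", "LOW", c(7000, 9500), c(85, 180), c(7000, 9000)),
    list("full_bloom", "LOW", c(5000, 7000), c(200, 300), c(5000, 7000)),
    list("full_boll", "LOW", c(3000, 5500), c(100, 200), c(2000, 4000))
  )
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      stage = r[[1]], yield_class = r[[2]],
      analyte = c("NO3N", "PO4P", "KK"),
      lo = c(r[[3]][1], r[[4]][1], r[[5]][1]),
      hi = c(r[[3]][2], r[[4]][2], r[[5]][2])
    )
  })
}
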