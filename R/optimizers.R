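#' Configuration of the metaheuristic weight-vector optimizers
#'
#' Population settings shared by the sparrow-search (SSO) and grey-wolf
#' (GWO) optimizers used to tune the network's initial weights and
#' thresholds: population 20, 20 iterations, per-dimension bounds
#' `[-1, 1]` (the network's initialisation box). SSO additionally uses the
#' original algorithm's defaults — producer fraction 0.2, scout fraction
#' 0.1, safety threshold 0.8; GWO's control parameter decreases linearly
#' from 2 to 0 over the iterations.
#'
#' @param algorithm `"SSO"` or `"GWO"`.
#' @param population Number of agents (>= 3).
#' @param iterations Number of update sweeps (>= 1; `0` is accepted only
#'   by [optimize_then_train()] to disable optimization).
#' @param bounds Length-2 numeric, lower and upper bound per dimension.
#' @param producer_fraction,scout_fraction,safety_threshold SSO parameters,
#'   each in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("SSO", "GWO"),
                             population = 20, iterations = 20,
                             bounds = c(-1, 1),
                             producer_fraction = 0.2,
                             scout_fraction = 0.1,
                             safety_threshold = 0.8,
                             seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(population >= 3, iterations >= 0, bounds[1] < bounds[2],
            producer_fraction > 0, producer_fraction < 1,
            scout_fraction > 0, scout_fraction < 1,
            safety_threshold > 0, safety_threshold < 1)
  structure(
    list(algorithm = algorithm, population = population,
         iterations = iterations, bounds = bounds,
         producer_fraction = producer_fraction,
         scout_fraction = scout_fraction,
         safety_threshold = safety_threshold,
         seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

#' RMSE fitness of a flat weight vector
#'
#' Builds the objective the metaheuristics minimise: decode the candidate
#' vector as an (untrained) network and score it by the RMSE of its
#' predictions on the training set, in scaled space. Lower is better;
#' deterministic in the vector.
#'
#' @param X Training inputs (mg/L).
#' @param y Training yields (kg/ha).
#' @param config A [bp_config()].
#' @param scalers An `npk_scalers`; defaults to scalers fitted on `X`, `y`.
#' @return A function mapping a weight vector to a non-negative scalar.
#' @export
make_bp_fitness <- function(X, y, config = bp_config(),
                            scalers = fit_scalers(X, y)) {
  Xs <- scale_x(scalers, as.matrix(X))
  ys <- scale_y(scalers, y)
  function(vector) {
    net <- bp_decode(vector, config, scalers)
    sqrt(mean((forward_scaled(net, Xs)$yhat - ys)^2))
  }
}

new_trace <- function(algorithm, best, best_fitness, history, evaluations) {
  structure(
    list(algorithm = algorithm, best = best, best_fitness = best_fitness,
         history = history, evaluations = evaluations),
    class = "npk_trace"
  )
}

clip_bounds <- function(X, bounds) {
  X[X < bounds[1]] <- bounds[1]
  X[X > bounds[2]] <- bounds[2]
  X
}

eval_population <- function(fitness_fn, X) {
  f <- apply(X, 1, fitness_fn)
  if (any(!is.finite(f))) abort("Non-finite fitness encountered.")
  f
}

#' Grey wolf optimization of a fitness function
#'
#' Canonical grey-wolf search: the three best agents (alpha, beta, delta)
#' lead; every agent moves to the mean of three encircling updates
#' `X_leader - A * |C * X_leader - X|` with `A = 2 a r1 - a`, `C = 2 r2`
#' (`r1`, `r2` uniform per dimension) and the control parameter `a`
#' decreasing linearly from 2 to 0. Positions are clipped to the bounds.
#' The returned history is the best-so-far fitness per iteration, hence
#' non-increasing; runs are deterministic under the config seed.
#'
#' @param fitness_fn Function from a length-`dim` vector to a finite
#'   scalar (lower is better).
#' @param config An [optimizer_config()].
#' @param dim Search-space dimension (51 for the default network).
#' @return An `npk_trace`: `best` vector, `best_fitness`, per-iteration
#'   `history`, and the number of fitness `evaluations`.
#' @export
gwo_optimize <- function(fitness_fn, config, dim) {
  stopifnot(config$iterations >= 1)
  set.seed(config$seed)
  pop <- config$population
  b <- config$bounds
  X <- matrix(runif(pop * dim, b[1], b[2]), pop, dim)
  f <- eval_population(fitness_fn, X)
  best_i <- which.min(f)
  best <- X[best_i, ]
  best_f <- f[best_i]
  history <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    a <- 2 * (1 - t / config$iterations)
    ord <- order(f)
    leaders <- X[ord[1:3], , drop = FALSE]
    newX <- X
    for (i in seq_len(pop)) {
      moves <- vapply(1:3, function(k) {
        A <- 2 * a * runif(dim) - a
        C <- 2 * runif(dim)
        leaders[k, ] - A * abs(C * leaders[k, ] - X[i, ])
      }, numeric(dim))
      newX[i, ] <- rowMeans(moves)
    }
    X <- clip_bounds(newX, b)
    f <- eval_population(fitness_fn, X)
    if (min(f) < best_f) {
      best_f <- min(f)
      best <- X[which.min(f), ]
    }
    history[t] <- best_f
  }
  new_trace("GWO", best, best_f, history, (config$iterations + 1) * pop)
}

#' Sparrow search optimization of a fitness function
#'
#' Canonical sparrow search: agents are ranked by fitness each sweep. The
#' top producer fraction forages (`X * exp(-rank / (alpha * T))` under a
#' calm alarm `R2 < ST`, otherwise a unit normal step); the remaining
#' scroungers either follow the best producer or, in the worse half, flee
#' from the worst position; a random scout fraction moves toward the
#' global best when endangered or jitters relative to the worst when
#' already best. Moves are clipped to the bounds and accepted greedily
#' (only when they improve the agent's fitness), so the best-so-far
#' history is non-increasing. Deterministic under the config seed.
#'
#' @inheritParams gwo_optimize
#' @return An `npk_trace`.
#' @export
sso_optimize <- function(fitness_fn, config, dim) {
  stopifnot(config$iterations >= 1)
  set.seed(config$seed)
  pop <- config$population
  b <- config$bounds
  X <- matrix(runif(pop * dim, b[1], b[2]), pop, dim)
  f <- eval_population(fitness_fn, X)
  best_i <- which.min(f)
  gbest <- X[best_i, ]
  gbest_f <- f[best_i]
  n_prod <- max(1, round(config$producer_fraction * pop))
  n_scout <- max(1, round(config$scout_fraction * pop))
  history <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    ord <- order(f)
    worst <- X[ord[pop], ]
    worst_f <- f[ord[pop]]
    newX <- X
    r2 <- runif(1) # alarm value shared by the sweep
    for (j in seq_len(n_prod)) {
      i <- ord[j]
      if (r2 < config$safety_threshold) {
        newX[i, ] <- X[i, ] * exp(-j / (runif(1) * config$iterations))
      } else {
        newX[i, ] <- X[i, ] + rnorm(1)
      }
    }
    prod_best <- newX[ord[1], ]
    for (j in seq_len(pop - n_prod) + n_prod) {
      i <- ord[j]
      if (j > pop / 2) {
        newX[i, ] <- rnorm(1) * exp((worst - X[i, ]) / j^2)
      } else {
        A <- sample(c(-1, 1), dim, replace = TRUE)
        step <- sum(abs(X[i, ] - prod_best) * A) / dim
        newX[i, ] <- prod_best + step
      }
    }
    for (i in sample.int(pop, n_scout)) {
      if (f[i] > gbest_f) {
        newX[i, ] <- gbest + rnorm(1) * abs(X[i, ] - gbest)
      } else {
        k <- runif(1, -1, 1)
        newX[i, ] <- X[i, ] +
          k * abs(X[i, ] - worst) / (abs(f[i] - worst_f) + 1e-50)
      }
    }
    newX <- clip_bounds(newX, b)
    newf <- eval_population(fitness_fn, newX)
    improved <- newf < f
    X[improved, ] <- newX[improved, ]
    f[improved] <- newf[improved]
    if (min(f) < gbest_f) {
      gbest_f <- min(f)
      gbest <- X[which.min(f), ]
    }
    history[t] <- gbest_f
  }
  new_trace("SSO", gbest, gbest_f, history, (config$iterations + 1) * pop)
}

#' Optimize the network's initial weights, then train it
#'
#' The optimize-then-train pipeline: run the chosen metaheuristic on the
#' decoded-network RMSE fitness, take the best weight vector as the
#' network's initial state, then train by steepest descent with the
#' standard settings. With `algorithm = "none"` (or zero optimizer
#' iterations) this reduces exactly to plain backpropagation from the
#' seeded random initialisation.
#'
#' @param algorithm `"SSO"`, `"GWO"` or `"none"`.
#' @param X Training inputs (mg/L).
#' @param y Training yields (kg/ha).
#' @param bp_config A [bp_config()].
#' @param opt_config An [optimizer_config()]; ignored for `"none"`.
#' @return A trained `npk_bp` with `$method` (`"BP"`, `"SSO-BP"` or
#'   `"GWO-BP"`) and, when optimized, the optimizer `$trace`.
#' @export
#' @examples
#' spec <- generator_spec(seed = 42)
#' fields <- dplyr::filter(generate_fields(spec), split == "survey")
#' X <- fields[paste0("full_bud_", c("NO3N", "PO4P", "KK"))]
#' fit <- optimize_then_train("none", X, fields$yield_kg_ha,
#'                            bp_config(epochs = 20))
#' glance(fit)
optimize_then_train <- function(algorithm = c("SSO", "GWO", "none"),
                                X, y,
                                bp_config = petiolenpk::bp_config(),
                                opt_config = optimizer_config(algorithm)) {
  algorithm <- match.arg(algorithm)
  scalers <- fit_scalers(X, y)
  if (algorithm == "none" || opt_config$iterations == 0) {
    net <- bp_init(bp_config, scalers)
    net <- bp_train(net, X, y, bp_config)
    net$method <- "BP"
    net$trace <- NULL
    return(net)
  }
  fitness <- make_bp_fitness(X, y, bp_config, scalers)
  optimizer <- if (algorithm == "SSO") sso_optimize else gwo_optimize
  trace <- optimizer(fitness, opt_config, n_weights(bp_config))
  net <- bp_decode(trace$best, bp_config, scalers)
  net <- bp_train(net, X, y, bp_config)
  net$method <- paste0(algorithm, "-BP")
  net$trace <- trace
  net
}

#' @export
print.npk_trace <- function(x, ...) {
  cat("<npk_trace> ", x$algorithm, ": best fitness ",
      signif(x$best_fitness, 4), " after ", length(x$history),
      " iterations (", x$evaluations, " evaluations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.npk_trace <- function(x, ...) {
  tibble(algorithm = x$algorithm,
         iteration = seq_along(x$history),
         best_fitness = x$history)
}

#' @export
glance.npk_trace <- function(x, ...) {
  tibble(algorithm = x$algorithm, iterations = length(x$history),
         evaluations = x$evaluations, best_fitness = x$best_fitness)
}

#' @export
autoplot.npk_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration,
                               y = .data$best_fitness)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "Iteration", y = "Best fitness (scaled RMSE)",
      title = paste(object$algorithm, "convergence")
    ) +
    ggplot2::theme_minimal()
}
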