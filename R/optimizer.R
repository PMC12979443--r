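#' Bounded continuous search space
#'
#' Defines the box-constrained domain over which [igkso()] minimizes an
#' objective. Bounds are recycled to `dim` if given as scalars.
#'
#' @param dim Integer dimension (>= 1).
#' @param lower,upper Numeric vectors of length 1 or `dim`; must satisfy
#'   `lower < upper` elementwise and be finite.
#' @return An object of class `"search_space"` with elements `dim`, `lower`,
#'   `upper`.
#' @examples
#' search_space(2, -5, 5)
#' @export
search_space <- function(dim, lower, upper) {
  stopifnot(length(dim) == 1L, dim >= 1)
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("search space bounds must be finite")
  if (!all(lower < upper))
    stop("search space requires lower < upper elementwise")
  structure(list(dim = dim, lower = lower, upper = upper),
            class = "search_space")
}

#' One step of the Bernoulli shift map
#'
#' The piecewise-linear Bernoulli chaotic map on (0, 1):
#' `x / (1 - lambda)` when `x <= 1 - lambda`, else
#' `(x - (1 - lambda)) / lambda`. Its orbit is mixing on (0, 1) and is used
#' to seed the optimizer's initial population with a low-correlation,
#' well-spread sample.
#'
#' @param x Numeric in (0, 1) (vectorized).
#' @param lambda Map parameter in (0, 1); default 0.4.
#' @return Mapped value(s) in (0, 1).
#' @examples
#' bernoulli_map_step(0.3, 0.4)  # 0.5
#' bernoulli_map_step(0.7, 0.4)  # 0.25
#' @export
bernoulli_map_step <- function(x, lambda = 0.4) {
  if (any(x <= 0 | x >= 1)) stop("bernoulli map input must lie in (0, 1)")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  ifelse(x <= 1 - lambda, x / (1 - lambda), (x - (1 - lambda)) / lambda)
}

# Bernoulli-map orbit of length n from a random start, after burn-in.
bernoulli_orbit <- function(n, lambda, burn_in = 20L) {
  x <- runif(1, 1e-6, 1 - 1e-6)
  for (i in seq_len(burn_in)) x <- bernoulli_map_step(x, lambda)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- bernoulli_map_step(x, lambda)
    # guard against collapse onto the boundary fixed point
    if (x <= 1e-12 || x >= 1 - 1e-12) x <- runif(1, 1e-6, 1 - 1e-6)
    out[i] <- x
  }
  out
}

#' Chaotic population initialization
#'
#' Draws a `population x dim` matrix of positions inside the search box.
#' Each individual follows its own Bernoulli-map orbit (random start,
#' >= 20 burn-in steps) mapped affinely onto the bounds; with
#' `chaotic = FALSE` plain uniform sampling is used (the baseline
#' initializer).
#'
#' @param space A [search_space()].
#' @param population Number of individuals (>= 2).
#' @param lambda Bernoulli map parameter.
#' @param seed Integer seed.
#' @param chaotic Use the chaotic map (`TRUE`) or uniform draws.
#' @return Numeric matrix, rows = individuals.
#' @export
init_population <- function(space, population, lambda = 0.4, seed = 1L,
                            chaotic = TRUE) {
  stopifnot(inherits(space, "search_space"), population >= 2)
  with_seed(seed, {
    u <- if (chaotic) {
      t(vapply(seq_len(population),
               function(i) bernoulli_orbit(space$dim, lambda),
               numeric(space$dim)))
    } else {
      matrix(runif(population * space$dim), nrow = population)
    }
    sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  })
}

#' Spiral-flight mutation operator
#'
#' Moves a position along a logarithmic spiral anchored at the current best:
#' per dimension, `x' = |best - x| * exp(b * l) * cos(2 * pi * l) + best`,
#' then clamped to the bounds. `l` in \[-1, 1\] sets where on the spiral the
#' mutant lands; the caller draws it.
#'
#' @param x,best Numeric positions inside the box.
#' @param b Spiral shape constant (> 0).
#' @param l Spiral parameter in \[-1, 1\].
#' @param space A [search_space()].
#' @return Mutated, clamped position.
#' @export
spiral_flight_mutate <- function(x, best, b = 1, l, space) {
  stopifnot(b > 0, l >= -1, l <= 1)
  out <- abs(best - x) * exp(b * l) * cos(2 * pi * l) + best
  pmin(pmax(out, space$lower), space$upper)
}

clamp_rows <- function(X, space) {
  X <- pmax(X, matrix(space$lower, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(space$upper, nrow(X), ncol(X), byrow = TRUE))
}

# Evaluate objective over rows, resetting non-finite individuals uniformly
# inside the box (re-evaluated once).
eval_rows <- function(X, objective, space) {
  f <- vapply(seq_len(nrow(X)), function(i) objective(X[i, ]), numeric(1))
  bad <- !is.finite(f)
  if (any(bad)) {
    for (i in which(bad)) {
      X[i, ] <- space$lower + runif(space$dim) * (space$upper - space$lower)
      f[i] <- objective(X[i, ])
      if (!is.finite(f[i])) f[i] <- .Machine$double.xmax
    }
  }
  list(X = X, f = f)
}

# One generation of the baseline shark-predation dynamics. Each individual
# proposes one move, accepted greedily (kept only if it does not worsen its
# fitness), which also guarantees elitism of the global best:
#   1. hunting movement toward the best plus a social differential term
#      between two random peers, applied to a random subset of coordinates
#      (sparse updates keep a usable acceptance rate in high dimension);
#   2. foraging perturbation: a sparse Gaussian local search around the
#      best whose scale is the forager's own distance to it, sharpening as
#      the swarm contracts;
#   3. self-protection randomization: occasional coordinate reset inside
#      the box, more frequent early on.
gkso_step <- function(X, f, objective, space, progress) {
  pop <- nrow(X); d <- ncol(X)
  ib <- which.min(f)
  best <- X[ib, ]
  B <- matrix(best, pop, d, byrow = TRUE)
  r1 <- sample.int(pop, pop, replace = TRUE)
  r2 <- sample.int(pop, pop, replace = TRUE)
  Fw <- matrix(runif(pop, 0.4, 0.9), pop, d)  # per-individual step weight
  cross <- matrix(runif(pop * d) < 0.9, pop, d)
  # every individual updates at least one coordinate
  jrand <- cbind(seq_len(pop), sample.int(d, pop, replace = TRUE))
  cross[jrand] <- TRUE
  a <- 1 - progress                           # social term decays
  Xn <- X + cross * Fw * ((B - X) + a * (X[r1, , drop = FALSE] -
                                         X[r2, , drop = FALSE]))

  forage <- runif(pop) < 0.2                  # local search around the best
  if (any(forage)) {
    nf <- sum(forage)
    pick <- matrix(runif(nf * d) < pmax(1 / d, 2 / d), nf, d)
    Xn[forage, ] <- B[forage, , drop = FALSE] +
      pick * matrix(rnorm(nf * d), nf, d) *
        abs(X[forage, , drop = FALSE] - B[forage, , drop = FALSE])
  }

  protect <- matrix(runif(pop * d) < 0.02 * (1 - progress), pop, d)
  if (any(protect)) {
    Xn[protect] <- (matrix(space$lower, pop, d, byrow = TRUE) +
      matrix(runif(pop * d), pop, d) *
        matrix(space$upper - space$lower, pop, d, byrow = TRUE))[protect]
  }

  Xn <- clamp_rows(Xn, space)
  ev <- eval_rows(Xn, objective, space)
  improve <- ev$f <= f
  X[improve, ] <- ev$X[improve, , drop = FALSE]
  f[improve] <- ev$f[improve]
  list(X = X, f = f, evals = pop)
}

#' Minimize an objective with GKSO or IGKSO
#'
#' Population-based minimizer over a box. The baseline variant
#' (`variant = "gkso"`) uses uniform initialization and the shark-predation
#' update phases; the improved variant (`variant = "igkso"`, default) adds
#' Bernoulli chaotic-map initialization and a spiral-flight mutation applied
#' with probability `mutation_prob` per individual per iteration, accepted
#' elitistically: a mutant is kept only when it strictly improves the
#' global best, so mutation can only sharpen the search, never erode the
#' population's diversity.
#'
#' @param objective Function of a numeric vector returning a scalar to
#'   minimize.
#' @param space A [search_space()].
#' @param population Swarm size (>= 2); default 30.
#' @param iterations Number of generations (>= 1); default 200.
#' @param seed Integer seed; the run is bit-reproducible given it.
#' @param variant `"igkso"` or `"gkso"`.
#' @param bernoulli_lambda Chaotic-map parameter in (0, 1).
#' @param spiral_b Spiral shape constant (> 0).
#' @param mutation_prob Per-individual spiral-mutation probability.
#' @return Object of class `"igkso_result"`: `best_position`, `best_fitness`,
#'   `convergence` (best-so-far fitness per iteration, non-increasing),
#'   `evaluations`, and the echoed configuration.
#' @examples
#' sphere <- function(x) sum(x^2)
#' r <- igkso(sphere, search_space(2, -5, 5), population = 20,
#'            iterations = 50, seed = 1)
#' r$best_fitness
#' @export
igkso <- function(objective, space, population = 30, iterations = 200,
                  seed = 1L, variant = c("igkso", "gkso"),
                  bernoulli_lambda = 0.4, spiral_b = 1, mutation_prob = 0.2) {
  variant <- match.arg(variant)
  stopifnot(inherits(space, "search_space"))
  if (population < 2) stop("population must be >= 2")
  if (iterations < 1) stop("iterations must be >= 1")
  if (bernoulli_lambda <= 0 || bernoulli_lambda >= 1)
    stop("bernoulli_lambda must lie in (0, 1)")
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]")
  if (spiral_b <= 0) stop("spiral_b must be > 0")

  X <- init_population(space, population, bernoulli_lambda,
                       seed = derive_seed(seed, "init"),
                       chaotic = variant == "igkso")
  # the spiral mutation draws from its own substream so the baseline
  # population dynamics consume an identical random sequence in both
  # variants
  mut_state <- with_seed(derive_seed(seed, "mutation"),
                         get(".Random.seed", envir = globalenv()))
  with_seed(derive_seed(seed, "dynamics"), {
    ev <- eval_rows(X, objective, space)
    X <- ev$X; f <- ev$f
    evals <- population
    curve <- numeric(iterations)
    for (t in seq_len(iterations)) {
      st <- gkso_step(X, f, objective, space, progress = t / iterations)
      X <- st$X; f <- st$f; evals <- evals + st$evals
      if (variant == "igkso" && mutation_prob > 0) {
        dyn_state <- get(".Random.seed", envir = globalenv())
        assign(".Random.seed", mut_state, envir = globalenv())
        ib <- which.min(f)
        mut <- setdiff(which(runif(population) < mutation_prob), ib)
        for (i in mut) {
          l <- runif(1, -1, 1)
          cand <- spiral_flight_mutate(X[i, ], X[ib, ], spiral_b, l, space)
          fc <- objective(cand)
          evals <- evals + 1
          # greedy acceptance: the mutant replaces its individual only on
          # strict improvement
          if (is.finite(fc) && fc < f[i]) { X[i, ] <- cand; f[i] <- fc }
        }
        mut_state <- get(".Random.seed", envir = globalenv())
        assign(".Random.seed", dyn_state, envir = globalenv())
      }
      curve[t] <- min(f)
    }
    ib <- which.min(f)
    structure(list(
      best_position = X[ib, ],
      best_fitness = f[ib],
      convergence = cummin(curve),
      evaluations = evals,
      config = list(population = population, iterations = iterations,
                    seed = seed, variant = variant,
                    bernoulli_lambda = bernoulli_lambda,
                    spiral_b = spiral_b, mutation_prob = mutation_prob)
    ), class = "igkso_result")
  })
}

#' @export
print.igkso_result <- function(x, ...) {
  cat(sprintf("%s run: pop %d, %d iterations, %d evaluations\n",
              toupper(x$config$variant), x$config$population,
              x$config$iterations, x$evaluations))
  cat(sprintf("best fitness: %.6g\n", x$best_fitness))
  cat("best position:", format(signif(head(x$best_position, 8), 5)),
      if (length(x$best_position) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.igkso_result <- function(x, log = "y", ...) {
  y <- x$convergence
  if (grepl("y", log) && any(y <= 0)) log <- sub("y", "", log)
  plot(seq_along(y), y, type = "l", log = log,
       xlab = "iteration", ylab = "best-so-far fitness",
       main = toupper(x$config$variant), ...)
  invisible(x)
}
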