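# The classic 23-function suite (sphere through the Shekel family) used
# throughout the metaheuristics literature to compare optimizers: F1-F7
# unimodal (exploitation), F8-F13 high-dimensional multimodal, F14-F23
# fixed-dimension multimodal. Canonical dimensions and bounds; minimization
# convention; known_optimum is the global minimum value.

u_penalty <- function(x, a, k, m) {
  ifelse(x > a, k * (x - a)^m, ifelse(x < -a, k * (-x - a)^m, 0))
}

benchmark_defs <- function() {
  fox_a1 <- rep(c(-32, -16, 0, 16, 32), 5)
  fox_a2 <- rep(c(-32, -16, 0, 16, 32), each = 5)
  kow_a <- c(0.1957, 0.1947, 0.1735, 0.16, 0.0844, 0.0627,
             0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
  kow_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)
  h3_alpha <- c(1, 1.2, 3, 3.2)
  h3_A <- matrix(c(3, 10, 30, 0.1, 10, 35, 3, 10, 30, 0.1, 10, 35),
                 4, 3, byrow = TRUE)
  h3_P <- 1e-4 * matrix(c(3689, 1170, 2673, 4699, 4387, 7470,
                          1091, 8732, 5547, 381, 5743, 8828),
                        4, 3, byrow = TRUE)
  h6_A <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                   0.05, 10, 17, 0.1, 8, 14,
                   3, 3.5, 1.7, 10, 17, 8,
                   17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
  h6_P <- 1e-4 * matrix(c(1312, 1696, 5569, 124, 8283, 5886,
                          2329, 4135, 8307, 3736, 1004, 9991,
                          2348, 1451, 3522, 2883, 3047, 6650,
                          4047, 8828, 8732, 5743, 1091, 381),
                        4, 6, byrow = TRUE)
  shekel_a <- matrix(c(4, 4, 4, 4, 1, 1, 1, 1, 8, 8, 8, 8, 6, 6, 6, 6,
                       3, 7, 3, 7, 2, 9, 2, 9, 5, 5, 3, 3, 8, 1, 8, 1,
                       6, 2, 6, 2, 7, 3.6, 7, 3.6), 4, 10)
  shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)
  shekel <- function(m) {
    function(x) -sum(vapply(seq_len(m), function(j)
      1 / (sum((x - shekel_a[, j])^2) + shekel_c[j]), numeric(1)))
  }
  hart <- function(A, P) {
    function(x) -sum(h3_alpha * exp(-rowSums(A * sweep(-P, 2, -x)^2)))
  }

  list(
    F1 = list(d = 30, lo = -100, hi = 100, mod = "unimodal", opt = 0,
              f = function(x) sum(x^2)),
    F2 = list(d = 30, lo = -10, hi = 10, mod = "unimodal", opt = 0,
              f = function(x) sum(abs(x)) + prod(abs(x))),
    F3 = list(d = 30, lo = -100, hi = 100, mod = "unimodal", opt = 0,
              f = function(x) sum(cumsum(x)^2)),
    F4 = list(d = 30, lo = -100, hi = 100, mod = "unimodal", opt = 0,
              f = function(x) max(abs(x))),
    F5 = list(d = 30, lo = -30, hi = 30, mod = "unimodal", opt = 0,
              f = function(x) {
                n <- length(x)
                sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
              }),
    F6 = list(d = 30, lo = -100, hi = 100, mod = "unimodal", opt = 0,
              f = function(x) sum(floor(x + 0.5)^2)),
    F7 = list(d = 30, lo = -1.28, hi = 1.28, mod = "unimodal", opt = 0,
              # quartic with additive noise; draws from the caller's RNG
              # stream so a seeded protocol stays reproducible
              f = function(x) sum(seq_along(x) * x^4) + runif(1)),
    F8 = list(d = 30, lo = -500, hi = 500, mod = "multimodal",
              opt = -418.9828872724338 * 30,
              f = function(x) -sum(x * sin(sqrt(abs(x))))),
    F9 = list(d = 30, lo = -5.12, hi = 5.12, mod = "multimodal", opt = 0,
              f = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)),
    F10 = list(d = 30, lo = -32, hi = 32, mod = "multimodal", opt = 0,
               f = function(x) {
                 n <- length(x)
                 -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
                   exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
               }),
    F11 = list(d = 30, lo = -600, hi = 600, mod = "multimodal", opt = 0,
               f = function(x) sum(x^2) / 4000 -
                 prod(cos(x / sqrt(seq_along(x)))) + 1),
    F12 = list(d = 30, lo = -50, hi = 50, mod = "multimodal", opt = 0,
               f = function(x) {
                 n <- length(x); y <- 1 + (x + 1) / 4
                 pi / n * (10 * sin(pi * y[1])^2 +
                   sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                   (y[n] - 1)^2) + sum(u_penalty(x, 10, 100, 4))
               }),
    F13 = list(d = 30, lo = -50, hi = 50, mod = "multimodal", opt = 0,
               f = function(x) {
                 n <- length(x)
                 0.1 * (sin(3 * pi * x[1])^2 +
                   sum((x[-n] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
                   (x[n] - 1)^2 * (1 + sin(2 * pi * x[n])^2)) +
                   sum(u_penalty(x, 5, 100, 4))
               }),
    F14 = list(d = 2, lo = -65.536, hi = 65.536, mod = "multimodal",
               opt = 0.9980038377944489,
               f = function(x) {
                 s <- sum(1 / (1:25 + (x[1] - fox_a1)^6 + (x[2] - fox_a2)^6))
                 1 / (1 / 500 + s)
               }),
    F15 = list(d = 4, lo = -5, hi = 5, mod = "multimodal",
               opt = 3.0748610201479866e-4,
               f = function(x) sum((kow_a - x[1] * (kow_b^2 + kow_b * x[2]) /
                                      (kow_b^2 + kow_b * x[3] + x[4]))^2)),
    F16 = list(d = 2, lo = -5, hi = 5, mod = "multimodal",
               opt = -1.0316284534898774,
               f = function(x) 4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 +
                 x[1] * x[2] - 4 * x[2]^2 + 4 * x[2]^4),
    F17 = list(d = 2, lo = c(-5, 0), hi = c(10, 15), mod = "multimodal",
               opt = 0.39788735772973816,
               f = function(x) (x[2] - 5.1 / (4 * pi^2) * x[1]^2 +
                                  5 / pi * x[1] - 6)^2 +
                 10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10),
    F18 = list(d = 2, lo = -2, hi = 2, mod = "multimodal", opt = 3,
               f = function(x) {
                 (1 + (x[1] + x[2] + 1)^2 *
                    (19 - 14 * x[1] + 3 * x[1]^2 - 14 * x[2] +
                       6 * x[1] * x[2] + 3 * x[2]^2)) *
                 (30 + (2 * x[1] - 3 * x[2])^2 *
                    (18 - 32 * x[1] + 12 * x[1]^2 + 48 * x[2] -
                       36 * x[1] * x[2] + 27 * x[2]^2))
               }),
    F19 = list(d = 3, lo = 0, hi = 1, mod = "multimodal",
               opt = -3.862782147820756, f = hart(h3_A, h3_P)),
    F20 = list(d = 6, lo = 0, hi = 1, mod = "multimodal",
               opt = -3.322368011391339, f = hart(h6_A, h6_P)),
    F21 = list(d = 4, lo = 0, hi = 10, mod = "multimodal",
               opt = -10.153199679058231, f = shekel(5)),
    F22 = list(d = 4, lo = 0, hi = 10, mod = "multimodal",
               opt = -10.402940566818664, f = shekel(7)),
    F23 = list(d = 4, lo = 0, hi = 10, mod = "multimodal",
               opt = -10.536409816692046, f = shekel(10))
  )
}

#' Benchmark function ids
#'
#' @return Character vector `"F1"` to `"F23"`.
#' @export
benchmark_ids <- function() paste0("F", 1:23)

#' Construct a benchmark test function
#'
#' Returns one member of the classic 23-function optimizer benchmark suite
#' (sphere, Schwefel variants, Rosenbrock, step, quartic-with-noise,
#' Schwefel sine, Rastrigin, Ackley, Griewank, penalized, Shekel's foxholes,
#' Kowalik, six-hump camel, Branin, Goldstein-Price, Hartman and Shekel
#' families) with its canonical dimension, bounds, modality and known
#' global-minimum value.
#'
#' @param id Character, one of `"F1"` to `"F23"`.
#' @return Object of class `"benchmark_fn"` with fields `id`, `dim`,
#'   `space` (a [search_space()]), `modality`, `known_optimum`, and
#'   `evaluate` (position vector -> scalar).
#' @examples
#' f <- make_benchmark("F9")
#' f$evaluate(rep(0, f$dim))  # 0, the global minimum
#' @export
make_benchmark <- function(id) {
  defs <- benchmark_defs()
  if (!is.character(id) || length(id) != 1L || !id %in% names(defs))
    stop("unknown benchmark id '", id, "'; valid ids: ",
         paste(names(defs), collapse = ", "))
  d <- defs[[id]]
  structure(list(
    id = id, dim = d$d,
    space = search_space(d$d, d$lo, d$hi),
    modality = d$mod, known_optimum = d$opt, evaluate = d$f
  ), class = "benchmark_fn")
}

#' @export
print.benchmark_fn <- function(x, ...) {
  cat(sprintf("benchmark %s: %d-D %s, bounds [%g, %g], minimum %g\n",
              x$id, x$dim, x$modality, x$space$lower[1], x$space$upper[1],
              x$known_optimum))
  invisible(x)
}

#' Run the repeated-comparison protocol on a benchmark function
#'
#' Runs an optimizer on one benchmark function for a number of independent
#' repetitions (repetition `r` is seeded `base_seed + r`) and aggregates the
#' best-so-far convergence curves, the protocol under which optimizer
#' variants are compared (population 30, 200 iterations, 30 repetitions by
#' default in that comparison).
#'
#' @param optimizer Either a variant name (`"igkso"`/`"gkso"`) or a function
#'   `(objective, space, population, iterations, seed)` returning a list
#'   with `best_fitness`, `best_position` and `convergence`.
#' @param fn A [make_benchmark()] object.
#' @param population,iterations,repetitions Protocol sizes.
#' @param base_seed Integer base seed.
#' @return Object of class `"protocol_result"`: `per_rep_best` (length
#'   `repetitions`), `mean_curve` (length `iterations`, non-increasing),
#'   `failed_reps` (repetitions whose best position left the box), and
#'   `config`.
#' @export
run_protocol <- function(optimizer, fn, population = 30, iterations = 200,
                         repetitions = 30, base_seed = 1L) {
  stopifnot(inherits(fn, "benchmark_fn"),
            population >= 2, iterations >= 1, repetitions >= 1)
  if (is.character(optimizer)) {
    variant <- match.arg(optimizer, c("igkso", "gkso"))
    optimizer <- function(objective, space, population, iterations, seed)
      igkso(objective, space, population, iterations, seed, variant = variant)
  }
  curves <- matrix(NA_real_, repetitions, iterations)
  per_rep <- numeric(repetitions)
  failed <- logical(repetitions)
  for (r in seq_len(repetitions)) {
    res <- optimizer(fn$evaluate, fn$space, population, iterations,
                     base_seed + r)
    per_rep[r] <- res$best_fitness
    curves[r, ] <- res$convergence
    failed[r] <- any(res$best_position < fn$space$lower - 1e-12) ||
      any(res$best_position > fn$space$upper + 1e-12)
  }
  structure(list(
    per_rep_best = per_rep,
    mean_curve = colMeans(curves),
    failed_reps = which(failed),
    config = list(function_id = fn$id, population = population,
                  iterations = iterations, repetitions = repetitions,
                  base_seed = base_seed)
  ), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("protocol on %s: %d reps, pop %d, %d iters\n",
              x$config$function_id, x$config$repetitions,
              x$config$population, x$config$iterations))
  cat(sprintf("mean final best %.6g (sd %.3g)\n",
              mean(x$per_rep_best), sd(x$per_rep_best)))
  if (length(x$failed_reps))
    cat("out-of-bounds repetitions:", x$failed_reps, "\n")
  invisible(x)
}
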