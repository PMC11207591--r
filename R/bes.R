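# Bald eagle search (BES): a three-phase population metaheuristic for
# bounded continuous minimization.  Each iteration runs, in order:
#   1. select space  -- move toward a zone between the best and mean position,
#   2. search prey   -- spiral flight around the current positions,
#   3. swoop         -- hyperbolic (sinh/cosh) dive onto the best position.
# Candidates are clipped to the bounds and accepted greedily (only if they
# improve the eagle's own fitness), which makes the best-so-far history
# monotone.  All randomness comes from R's RNG, seeded once per run; draws
# are phase-major then eagle-major, so a seed fixes the whole trajectory.

#' BES optimizer configuration
#'
#' @param pop_size Number of eagles.
#' @param max_iter Number of iterations (each runs all three phases).
#' @param lo,hi Per-dimension lower/upper bounds (recycled to `dim`).
#' @param dim Problem dimensionality.
#' @param alpha Position-change control parameter, in (1.5, 2).
#' @param a_param Spiral angle parameter, in (5, 10).
#' @param R_param Spiral cycle parameter, in (0.5, 2).
#' @param c1,c2 Swoop intensity toward the mean / best position, in `[1, 2]`.
#' @param seed Integer seed fixing the trajectory; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `bes_config`.
#' @export
bes_config <- function(pop_size = 10L, max_iter = 30L, lo = -5, hi = 5,
                       dim = 2L, alpha = 2, a_param = 10, R_param = 1.5,
                       c1 = 2, c2 = 2, seed = NULL) {
  dim <- as.integer(dim)
  lo <- rep_len(as.numeric(lo), dim)
  hi <- rep_len(as.numeric(hi), dim)
  if (any(lo >= hi)) abort("bounds must satisfy lo < hi elementwise")
  stopifnot(pop_size >= 1L, max_iter >= 1L)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 lo = lo, hi = hi, dim = dim,
                 alpha = alpha, a_param = a_param, R_param = R_param,
                 c1 = c1, c2 = c2, seed = seed),
            class = "bes_config")
}

clip_bounds <- function(p, lo, hi) pmin(pmax(p, lo), hi)

# evaluate fitness with context on failure
eval_fitness <- function(fitness, p) {
  v <- tryCatch(fitness(p), error = function(e) {
    abort(sprintf("fitness evaluation failed at position (%s): %s",
                  paste(signif(p, 4), collapse = ", "), conditionMessage(e)))
  })
  if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
    abort("fitness must return a single non-NA number")
  }
  v
}

#' Initialize a BES swarm
#'
#' Samples `pop_size` positions uniformly within the bounds (under the
#' current RNG state), evaluates the fitness, and records the best eagle and
#' the population mean.
#'
#' @param fitness Function mapping a position vector to a single number
#'   (minimized).
#' @param cfg A [bes_config()].
#' @param init Optional matrix (`pop_size` x `dim`) of starting positions,
#'   e.g. to seed a known candidate into the population.
#' @return A `bes_state` list: `positions` matrix, `fitness` vector,
#'   `best_position`, `best_fitness`, `cfg`.
#' @export
bes_init <- function(fitness, cfg, init = NULL) {
  n <- cfg$pop_size
  d <- cfg$dim
  if (is.null(init)) {
    positions <- matrix(runif(n * d), nrow = n) *
      matrix(cfg$hi - cfg$lo, n, d, byrow = TRUE) +
      matrix(cfg$lo, n, d, byrow = TRUE)
  } else {
    positions <- matrix(as.numeric(init), nrow = n, ncol = d)
    positions <- t(apply(positions, 1L, clip_bounds, lo = cfg$lo, hi = cfg$hi))
    if (d == 1L) positions <- matrix(positions, nrow = n)
  }
  fit <- apply(positions, 1L, function(p) eval_fitness(fitness, p))
  b <- which.min(fit)
  structure(list(positions = positions, fitness = fit,
                 best_position = positions[b, ], best_fitness = fit[b],
                 cfg = cfg),
            class = "bes_state")
}

# greedy accept a candidate for eagle i; returns updated state
accept_if_better <- function(state, i, cand, fitness) {
  cand <- clip_bounds(cand, state$cfg$lo, state$cfg$hi)
  f <- eval_fitness(fitness, cand)
  if (f < state$fitness[i]) {
    state$positions[i, ] <- cand
    state$fitness[i] <- f
    if (f < state$best_fitness) {
      state$best_fitness <- f
      state$best_position <- cand
    }
  }
  state
}

#' BES phase 1: select the search space
#'
#' Each eagle proposes `P_best + alpha * r * (P_mean - P_i)` with a fresh
#' uniform `r` in (0, 1) per eagle; candidates are clipped to the bounds and
#' accepted only when they improve that eagle's fitness.
#'
#' @param state A `bes_state`.
#' @param fitness The fitness function.
#' @return The updated `bes_state`.
#' @export
bes_phase_select <- function(state, fitness) {
  cfg <- state$cfg
  pmean <- colMeans(state$positions)
  r <- runif(cfg$pop_size)
  for (i in seq_len(cfg$pop_size)) {
    cand <- state$best_position + cfg$alpha * r[i] * (pmean - state$positions[i, ])
    state <- accept_if_better(state, i, cand, fitness)
  }
  state
}

#' Spiral coordinates of the search and swoop phases
#'
#' Search variant: polar angle `theta = a * pi * rand`, radius
#' `r = theta + R * rand`, raw coordinates `(r sin theta, r cos theta)`.
#' Swoop variant: `r = theta` and hyperbolic `(r sinh theta, r cosh theta)`.
#' Both coordinate sets are normalized by their population maxima of the
#' absolute value, so `|x|, |y| <= 1` with the maximum attained exactly.
#'
#' @param n Number of eagles (coordinate pairs).
#' @param a_param,R_param Spiral shape parameters.
#' @param swoop If `TRUE`, use the hyperbolic swoop variant.
#' @return A tibble with columns `theta`, `r`, `xr`, `yr`, `x`, `y`.
#' @export
bes_spiral_coords <- function(n, a_param = 10, R_param = 1.5, swoop = FALSE) {
  if (n == 0L) {
    return(tibble(theta = numeric(), r = numeric(), xr = numeric(),
                  yr = numeric(), x = numeric(), y = numeric()))
  }
  theta <- a_param * pi * runif(n)
  if (swoop) {
    r <- theta
    xr <- r * sinh(theta)
    yr <- r * cosh(theta)
  } else {
    r <- theta + R_param * runif(n)
    xr <- r * sin(theta)
    yr <- r * cos(theta)
  }
  tibble(theta = theta, r = r, xr = xr, yr = yr,
         x = xr / max(abs(xr)), y = yr / max(abs(yr)))
}

#' BES phase 2: spiral search for prey
#'
#' Eagle `i` proposes
#' `P_i + x_i * (P_i - P_mean) + y_i * (P_i - P_next)`, where `P_next` is the
#' position of eagle `i + 1` (cyclically wrapped) and `(x_i, y_i)` are the
#' normalized spiral coordinates of [bes_spiral_coords()].
#'
#' @inheritParams bes_phase_select
#' @return The updated `bes_state`.
#' @export
bes_phase_search <- function(state, fitness) {
  cfg <- state$cfg
  pmean <- colMeans(state$positions)
  sc <- bes_spiral_coords(cfg$pop_size, cfg$a_param, cfg$R_param,
                          swoop = FALSE)
  nxt <- c(seq_len(cfg$pop_size)[-1L], 1L)
  for (i in seq_len(cfg$pop_size)) {
    pi_ <- state$positions[i, ]
    cand <- pi_ + sc$x[i] * (pi_ - pmean) +
      sc$y[i] * (pi_ - state$positions[nxt[i], ])
    state <- accept_if_better(state, i, cand, fitness)
  }
  state
}

#' BES phase 3: swoop onto the prey
#'
#' Eagle `i` proposes
#' `rand * P_best + x'_i * (P_i - c1 * P_mean) + y'_i * (P_i - c2 * P_best)`
#' with a fresh uniform `rand` per eagle and `(x'_i, y'_i)` the normalized
#' hyperbolic spiral coordinates.
#'
#' @inheritParams bes_phase_select
#' @return The updated `bes_state`.
#' @export
bes_phase_swoop <- function(state, fitness) {
  cfg <- state$cfg
  pmean <- colMeans(state$positions)
  sc <- bes_spiral_coords(cfg$pop_size, cfg$a_param, cfg$R_param,
                          swoop = TRUE)
  rnd <- runif(cfg$pop_size)
  for (i in seq_len(cfg$pop_size)) {
    pi_ <- state$positions[i, ]
    cand <- rnd[i] * state$best_position +
      sc$x[i] * (pi_ - cfg$c1 * pmean) +
      sc$y[i] * (pi_ - cfg$c2 * state$best_position)
    state <- accept_if_better(state, i, cand, fitness)
  }
  state
}

#' Run the bald eagle search
#'
#' Minimizes `fitness` over the box `[lo, hi]^dim` by running the three BES
#' phases in order for `max_iter` iterations.  Greedy acceptance makes the
#' best-so-far fitness non-increasing; a fixed seed makes the trajectory
#' bit-identical across runs.
#'
#' @param fitness Function mapping a position vector to a single number.
#' @param cfg A [bes_config()].
#' @param init Optional starting positions, see [bes_init()].
#' @return An object of class `bes_result`: `best_position`,
#'   `best_fitness`, and `history`, a tibble with one row per iteration
#'   (`iteration`, `best_fitness`, `best_position` list-column).
#' @examples
#' sphere <- function(p) sum(p^2)
#' res <- bes_optimize(sphere, bes_config(seed = 1))
#' res$best_fitness
#' @export
bes_optimize <- function(fitness, cfg = bes_config(), init = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- bes_init(fitness, cfg, init = init)
  hist <- vector("list", cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    state <- bes_phase_select(state, fitness)
    state <- bes_phase_search(state, fitness)
    state <- bes_phase_swoop(state, fitness)
    hist[[it]] <- tibble(iteration = it,
                         best_fitness = state$best_fitness,
                         best_position = list(state$best_position))
  }
  structure(list(best_position = state$best_position,
                 best_fitness = state$best_fitness,
                 history = list_rbind(hist),
                 cfg = cfg),
            class = "bes_result")
}

#' @export
print.bes_result <- function(x, ...) {
  cat(sprintf("<bes_result> best fitness %.6g at (%s) after %d iterations\n",
              x$best_fitness,
              paste(signif(x$best_position, 5), collapse = ", "),
              nrow(x$history)))
  invisible(x)
}

#' Convergence curve of a BES run
#'
#' @param object A `bes_result`.
#' @param ... Ignored.
#' @return A ggplot of best-so-far fitness against iteration.
#' @export
autoplot.bes_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = "Bald eagle search convergence") +
    ggplot2::theme_minimal()
}

#' Write a BES history to CSV
#'
#' @param result A `bes_result`.
#' @param path Output CSV path.
#' @return The flattened history tibble, invisibly.
#' @export
write_bes_history_csv <- function(result, path) {
  pos <- do.call(rbind, result$history$best_position)
  colnames(pos) <- paste0("best_position_", seq_len(ncol(pos)))
  out <- dplyr::bind_cols(
    result$history |> select("iteration", "best_fitness"),
    as_tibble(pos))
  readr::write_csv(out, path)
  invisible(out)
}
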