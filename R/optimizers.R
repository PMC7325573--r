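#' Bound-constrained search space
#'
#' Axis-aligned box over which the population optimizers search.
#'
#' @param lower,upper numeric vectors of equal length with
#'   `lower[i] < upper[i]` componentwise.
#' @return An object of class `search_space` with fields `dim`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' search_space(c(-10, -10), c(10, 10))
search_space <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L) {
    stop("`lower` and `upper` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("search space bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("`lower[i] < upper[i]` must hold for every coordinate",
         call. = FALSE)
  }
  structure(list(dim = length(lower), lower = lower, upper = upper),
            class = "search_space")
}

#' Population-optimizer settings
#'
#' @param population_size number of search agents (wolves / particles).
#'   GWO needs at least 4 (alpha, beta, delta plus one omega).
#' @param max_iterations iteration budget.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   results.
#' @param inertia_start,inertia_end,c1,c2,v_clamp_frac PSO-only settings:
#'   linearly decayed inertia weight, cognitive/social accelerations, and
#'   the velocity clamp as a fraction of the box width.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 30L, max_iterations = 100L,
                             seed = NULL,
                             inertia_start = 0.9, inertia_end = 0.4,
                             c1 = 2.0, c2 = 2.0, v_clamp_frac = 0.2) {
  population_size <- assert_count(population_size, "population_size", min = 4L)
  max_iterations <- assert_count(max_iterations, "max_iterations", min = 1L)
  structure(list(population_size = population_size,
                 max_iterations = max_iterations,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 c1 = c1, c2 = c2, v_clamp_frac = v_clamp_frac),
            class = "optimizer_config")
}

#' Exploration control parameter of the grey-wolf update
#'
#' Decreases linearly from 2 at the first iteration to 0 at the last, which
#' shifts the pack from exploration (|A| can exceed 1) to exploitation.
#'
#' @param iteration current iteration, `0 <= iteration <= max_iterations`.
#' @param max_iterations total iteration budget.
#' @return `a = 2 * (1 - iteration / max_iterations)`.
#' @export
control_parameter <- function(iteration, max_iterations) {
  assert_scalar_number(iteration, "iteration")
  max_iterations <- assert_count(max_iterations, "max_iterations")
  if (iteration < 0 || iteration > max_iterations) {
    stop("`iteration` must lie in [0, max_iterations]", call. = FALSE)
  }
  2 * (1 - iteration / max_iterations)
}

#' Stochastic coefficient vectors A and C
#'
#' Per component, `A = 2*a*r1 - a` and `C = 2*r2` with `r1, r2 ~ U[0, 1]`,
#' so `A` lies in `[-a, a]` and `C` in `[0, 2]`.  Fresh draws are taken per
#' component; callers draw independently per leader.
#'
#' @param a control parameter in `[0, 2]`.
#' @param dim number of components.
#' @param rng function drawing `n` uniform variates, default [stats::runif].
#' @return List with numeric vectors `A` and `C`.
#' @export
coefficient_vectors <- function(a, dim, rng = stats::runif) {
  assert_scalar_number(a, "a")
  dim <- assert_count(dim, "dim")
  r1 <- rng(dim)
  r2 <- rng(dim)
  list(A = 2 * a * r1 - a, C = 2 * r2)
}

#' One grey-wolf position update
#'
#' Moves a wolf toward the three pack leaders: for each leader L the
#' distance `D_L = |C_L * X_L - X|` and candidate `X_L' = X_L - A_L * D_L`
#' are formed componentwise with independent coefficient draws, and the new
#' position is the average of the three candidates.
#'
#' @param current wolf position.
#' @param alpha_pos,beta_pos,delta_pos leader positions, same length.
#' @param a control parameter (see [control_parameter()]).
#' @param rng uniform generator, default [stats::runif].  Draw order per
#'   leader: the `r1` vector (for `A`), then the `r2` vector (for `C`),
#'   alpha first, then beta, then delta.
#' @return Updated position (not yet clipped to any bounds).
#' @export
update_position <- function(current, alpha_pos, beta_pos, delta_pos, a,
                            rng = stats::runif) {
  d <- length(current)
  if (length(alpha_pos) != d || length(beta_pos) != d ||
      length(delta_pos) != d) {
    stop("position vectors must share one dimension", call. = FALSE)
  }
  ca <- coefficient_vectors(a, d, rng)
  cb <- coefficient_vectors(a, d, rng)
  cd <- coefficient_vectors(a, d, rng)
  x1 <- alpha_pos - ca$A * abs(ca$C * alpha_pos - current)
  x2 <- beta_pos - cb$A * abs(cb$C * beta_pos - current)
  x3 <- delta_pos - cd$A * abs(cd$C * delta_pos - current)
  (x1 + x2 + x3) / 3
}

#' Clamp a position into a search box
#'
#' @param position numeric vector.
#' @param space a [search_space()].
#' @return Componentwise clamp of `position` to `[lower, upper]`.
#' @export
clip_to_bounds <- function(position, space) {
  pmin(pmax(position, space$lower), space$upper)
}

# Non-finite fitness values are routed here so the optimizers stay total:
# a candidate whose objective is NaN/Inf is simply never selected as leader.
WORST_FITNESS <- .Machine$double.xmax

eval_fitness <- function(fitness, positions) {
  f <- vapply(seq_len(nrow(positions)), function(i) {
    v <- fitness(positions[i, ])
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) WORST_FITNESS
    else as.double(v)
  }, numeric(1))
  f
}

init_positions <- function(space, n) {
  d <- space$dim
  u <- matrix(stats::runif(n * d), nrow = n, ncol = d)
  sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
}

new_optimizer_result <- function(best_position, best_fitness, trace,
                                 evaluations, algorithm) {
  structure(list(best_position = as.numeric(best_position),
                 best_fitness = as.double(best_fitness),
                 trace = as.numeric(trace),
                 evaluations = as.integer(evaluations),
                 algorithm = algorithm),
            class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result: %s>\n", x$algorithm))
  cat("  best_fitness:", format(x$best_fitness, digits = 6), "\n")
  cat("  best_position:", paste(format(x$best_position, digits = 6),
                                collapse = ", "), "\n")
  cat("  evaluations:", x$evaluations, "\n")
  invisible(x)
}

#' Grey-Wolf Optimization of a bound-constrained objective
#'
#' Population metaheuristic in which candidate solutions (wolves) move
#' toward the three best solutions seen so far (alpha, beta, delta) with a
#' stochastic step whose amplitude shrinks linearly over the run.  Leaders
#' are elitist best-so-far, so the convergence trace is non-increasing;
#' ties in leader ranking are broken by earlier evaluation order.  Updated
#' positions are clipped into the box.  Candidates with non-finite
#' objective values are treated as worst-possible rather than raising.
#'
#' @param fitness function mapping an in-box numeric vector to a scalar.
#' @param space a [search_space()].
#' @param config an [optimizer_config()].
#' @return An `optimizer_result`: `best_position`, `best_fitness`,
#'   per-iteration best-so-far `trace`, and the `evaluations` count.
#' @export
#' @examples
#' sp <- search_space(c(-10, -10), c(10, 10))
#' res <- gwo_minimize(function(x) sum(x^2), sp,
#'                     optimizer_config(seed = 1))
#' res$best_fitness
gwo_minimize <- function(fitness, space, config = optimizer_config()) {
  stopifnot(inherits(space, "search_space"),
            inherits(config, "optimizer_config"))
  with_local_seed(config$seed, {
    n <- config$population_size
    tmax <- config$max_iterations
    pos <- init_positions(space, n)
    fit <- eval_fitness(fitness, pos)
    evaluations <- n

    # elitist leader archive: three best-so-far, stable in evaluation order
    ord <- order(fit)[1:3]
    leaders_pos <- pos[ord, , drop = FALSE]
    leaders_fit <- fit[ord]

    trace <- numeric(tmax)
    for (t in seq_len(tmax)) {
      a <- control_parameter(t, tmax)
      for (i in seq_len(n)) {
        cand <- update_position(pos[i, ], leaders_pos[1, ], leaders_pos[2, ],
                                leaders_pos[3, ], a)
        pos[i, ] <- clip_to_bounds(cand, space)
      }
      fit <- eval_fitness(fitness, pos)
      evaluations <- evaluations + n
      for (i in seq_len(n)) {
        if (fit[i] < leaders_fit[3]) {
          # strict '<' keeps earlier-evaluated equals ranked ahead
          slot <- if (fit[i] < leaders_fit[1]) 1L
                  else if (fit[i] < leaders_fit[2]) 2L else 3L
          if (slot <= 2L) {
            keep <- seq(slot, 2L)
            leaders_pos[keep + 1L, ] <- leaders_pos[keep, , drop = FALSE]
            leaders_fit[keep + 1L] <- leaders_fit[keep]
          }
          leaders_pos[slot, ] <- pos[i, ]
          leaders_fit[slot] <- fit[i]
        }
      }
      trace[t] <- leaders_fit[1]
    }
    new_optimizer_result(leaders_pos[1, ], leaders_fit[1], trace,
                         evaluations, "gwo")
  })
}

#' Global-best Particle Swarm Optimization (baseline)
#'
#' Canonical global-best PSO used as a comparison baseline: inertia weight
#' decays linearly from `inertia_start` to `inertia_end`, cognitive and
#' social accelerations `c1 = c2 = 2`, velocities clamped to
#' `v_clamp_frac` of the box width, positions clipped into the box.  Same
#' contract as [gwo_minimize()] (best-so-far trace, worst-case sentinel for
#' non-finite objective values, seed determinism).
#'
#' @inheritParams gwo_minimize
#' @return An `optimizer_result`.
#' @export
pso_minimize <- function(fitness, space, config = optimizer_config()) {
  stopifnot(inherits(space, "search_space"),
            inherits(config, "optimizer_config"))
  with_local_seed(config$seed, {
    n <- config$population_size
    tmax <- config$max_iterations
    d <- space$dim
    width <- space$upper - space$lower
    vmax <- config$v_clamp_frac * width

    pos <- init_positions(space, n)
    vel <- matrix(0, nrow = n, ncol = d)
    fit <- eval_fitness(fitness, pos)
    evaluations <- n

    pbest_pos <- pos
    pbest_fit <- fit
    g <- which.min(fit)
    gbest_pos <- pos[g, ]
    gbest_fit <- fit[g]

    trace <- numeric(tmax)
    for (t in seq_len(tmax)) {
      w <- config$inertia_start -
        (config$inertia_start - config$inertia_end) * (t - 1) / max(tmax - 1, 1)
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      vel <- w * vel +
        config$c1 * r1 * (pbest_pos - pos) +
        config$c2 * r2 * sweep(-pos, 2, gbest_pos, `+`)
      vel <- pmin(pmax(vel, matrix(-vmax, n, d, byrow = TRUE)),
                  matrix(vmax, n, d, byrow = TRUE))
      pos <- pos + vel
      for (i in seq_len(n)) pos[i, ] <- clip_to_bounds(pos[i, ], space)
      fit <- eval_fitness(fitness, pos)
      evaluations <- evaluations + n

      improved <- fit < pbest_fit
      pbest_pos[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest_fit <- pbest_fit[g]
        gbest_pos <- pbest_pos[g, ]
      }
      trace[t] <- gbest_fit
    }
    new_optimizer_result(gbest_pos, gbest_fit, trace, evaluations, "pso")
  })
}

#' Dispatch on an optimizer name
#'
#' @param algorithm `"gwo"` or `"pso"`.
#' @return The matching `*_minimize` function.
#' @keywords internal
optimizer_by_name <- function(algorithm) {
  switch(match.arg(algorithm, c("gwo", "pso")),
         gwo = gwo_minimize, pso = pso_minimize)
}
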