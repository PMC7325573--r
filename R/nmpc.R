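#' Input, increment and output constraint boxes
#'
#' Defaults are the operating envelope of the fed-batch lysine process:
#' agitation `u1` in \[316, 345\] rpm, airflow `u2` in \[0.1, 1.65\] vvm,
#' ammonia flow `u3` in \[51, 110\] mL/h; per-step increments bounded by
#' \[-15, 15\], \[-1, 1\], \[-30, 30\]; product concentration constrained
#' to \[0, 45\] g/L.
#'
#' @param u_lower,u_upper length-3 input bounds.
#' @param du_lower,du_upper length-3 increment bounds.
#' @param y_lower,y_upper scalar output bounds.
#' @return Object of class `control_constraints`.
#' @export
control_constraints <- function(u_lower = c(316, 0.1, 51),
                                u_upper = c(345, 1.65, 110),
                                du_lower = c(-15, -1, -30),
                                du_upper = c(15, 1, 30),
                                y_lower = 0, y_upper = 45) {
  stopifnot(length(u_lower) == 3L, length(u_upper) == 3L,
            length(du_lower) == 3L, length(du_upper) == 3L)
  if (any(u_lower >= u_upper) || any(du_lower >= du_upper) ||
      y_lower >= y_upper) {
    stop("constraint lower bounds must be below upper bounds", call. = FALSE)
  }
  if (any(!is.finite(c(u_lower, u_upper, du_lower, du_upper,
                       y_lower, y_upper)))) {
    stop("constraint bounds must be finite", call. = FALSE)
  }
  structure(list(u_lower = as.numeric(u_lower),
                 u_upper = as.numeric(u_upper),
                 du_lower = as.numeric(du_lower),
                 du_upper = as.numeric(du_upper),
                 y_lower = y_lower, y_upper = y_upper),
            class = "control_constraints")
}

#' Receding-horizon controller configuration
#'
#' @param n_pred prediction horizon (default 1).
#' @param n_con control horizon, `<= n_pred` (default 1).
#' @param q_out output-error weight (default 1).
#' @param r_in input-increment penalty (default 0.001).
#' @param constraints a [control_constraints()].
#' @param optimizer an [optimizer_config()] for the per-step solve.
#' @param algorithm `"gwo"` or `"pso"`.
#' @param initial_u starting inputs, inside the input box (default
#'   `c(326, 0.1, 88)`).
#' @return Object of class `controller_config`.
#' @export
controller_config <- function(n_pred = 1L, n_con = 1L, q_out = 1,
                              r_in = 0.001,
                              constraints = control_constraints(),
                              optimizer = optimizer_config(),
                              algorithm = c("gwo", "pso"),
                              initial_u = c(326, 0.1, 88)) {
  n_pred <- assert_count(n_pred, "n_pred")
  n_con <- assert_count(n_con, "n_con")
  if (n_con > n_pred) stop("`n_con` must be <= `n_pred`", call. = FALSE)
  if (q_out < 0 || r_in < 0) {
    stop("`q_out` and `r_in` must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(constraints, "control_constraints"),
            length(initial_u) == 3L)
  if (any(initial_u < constraints$u_lower) ||
      any(initial_u > constraints$u_upper)) {
    stop("`initial_u` must lie inside the input box", call. = FALSE)
  }
  structure(list(n_pred = n_pred, n_con = n_con, q_out = q_out, r_in = r_in,
                 constraints = constraints, optimizer = optimizer,
                 algorithm = match.arg(algorithm),
                 initial_u = as.numeric(initial_u)),
            class = "controller_config")
}

# weight of the quadratic penalty for output/input box violations;
# keeps the objective total over the whole increment box
PENALTY_WEIGHT <- 1e6

# controller-side feature assembly: measured T, pH, DO are held at their
# latest values while candidate u1..u3 vary; sensors trained with the
# lagged-product feature additionally receive the latest product estimate
controller_features <- function(model, aux, u, last_p = NA_real_) {
  feats <- c(aux[1], aux[2], u[1], aux[3], u[2], u[3])
  if ("P_lag" %in% model$feature_names) {
    if (!is.finite(last_p)) {
      stop("sensor uses a lagged-product feature; supply `last_p`",
           call. = FALSE)
    }
    feats <- c(feats, last_p)
  }
  feats
}

#' Output-feedback-corrected soft-sensor prediction
#'
#' Adds the additive output-feedback bias (last measured-minus-predicted
#' error) to the raw soft-sensor prediction, on physical units.
#'
#' @param model a `soft_sensor`.
#' @param aux_features length-6 physical feature vector `(T, pH, u1, DO,
#'   u2, u3)`.
#' @param bias additive correction (g/L).
#' @return Corrected prediction (g/L).
#' @export
predict_corrected <- function(model, aux_features, bias = 0) {
  as.numeric(predict(model, aux_features)) + bias
}

#' Receding-horizon tracking objective
#'
#' Cost of one candidate increment sequence:
#' `J = sum_j q_out * (ypred_j - yref_j)^2 + sum_j r_in * ||du_j||^2`,
#' where predictions come from [predict_corrected()] at the candidate
#' inputs with the measured temperature, pH and dissolved oxygen held at
#' their latest values.  Candidates that push the inputs out of the input
#' box or the corrected prediction out of the output box receive a
#' quadratic penalty instead of an error, so the optimizer's fitness stays
#' finite everywhere on the increment box.
#'
#' @param du_candidate numeric vector of length `3 * n_con` (increments,
#'   time-major: step 1's `(du1, du2, du3)` first).
#' @param state list with `current_u` (length 3) and `bias` (scalar).
#' @param yref_future reference values for steps `1..n_pred` (g/L).
#' @param model a `soft_sensor`.
#' @param aux_now latest measured `(T_C, pH, DO_pct)` named or positional.
#' @param config a [controller_config()].
#' @return Scalar objective value.
#' @export
nmpc_objective <- function(du_candidate, state, yref_future, model, aux_now,
                           config) {
  cn <- config$constraints
  n_con <- config$n_con
  n_pred <- config$n_pred
  stopifnot(length(du_candidate) == 3L * n_con,
            length(yref_future) >= n_pred)
  aux <- as.numeric(aux_now)[1:3]  # T, pH, DO
  u <- state$current_u
  last_p <- if (is.null(state$last_measured_y)) NA_real_
            else state$last_measured_y
  J <- 0
  penalty <- 0
  for (j in seq_len(n_pred)) {
    if (j <= n_con) {
      du <- du_candidate[(3 * (j - 1) + 1):(3 * j)]
      u <- u + du
      J <- J + config$r_in * sum(du^2)
      over <- pmax(u - cn$u_upper, 0) + pmax(cn$u_lower - u, 0)
      penalty <- penalty + sum(over^2)
    }
    u_eval <- pmin(pmax(u, cn$u_lower), cn$u_upper)
    feats <- controller_features(model, aux, u_eval, last_p)
    yp <- predict_corrected(model, feats, state$bias)
    last_p <- yp  # multi-step horizons feed the prediction forward
    J <- J + config$q_out * (yp - yref_future[j])^2
    yover <- max(yp - cn$y_upper, 0) + max(cn$y_lower - yp, 0)
    penalty <- penalty + yover^2
  }
  J + PENALTY_WEIGHT * penalty
}

#' Solve one receding-horizon step
#'
#' Runs the configured population optimizer over the `3 * n_con`
#' dimensional increment box, decodes the best position into increments,
#' applies `u(t+1) = u(t) + du(t+1)` for the first step, and clamps the
#' result into the input box (recording whether clamping occurred).
#'
#' @param state list with `current_u`, `bias`, and optionally
#'   `time_index`.
#' @param yref_future reference over the prediction horizon (g/L).
#' @param model a `soft_sensor`.
#' @param aux_now latest measured `(T_C, pH, DO_pct)`.
#' @param config a [controller_config()].
#' @param seed optional integer seed for this solve.
#' @return List: `du` (applied first increment), `u_new`, `y_pred_raw`
#'   (uncorrected), `y_pred` (bias-corrected), `objective`, `clamped`,
#'   `trace`.
#' @export
solve_step <- function(state, yref_future, model, aux_now, config,
                       seed = NULL) {
  cn <- config$constraints
  n_con <- config$n_con
  space <- search_space(rep(cn$du_lower, n_con), rep(cn$du_upper, n_con))
  opt <- config$optimizer
  opt$seed <- if (is.null(seed)) opt$seed else as.integer(seed)
  minimize <- optimizer_by_name(config$algorithm)
  res <- minimize(function(du) {
    nmpc_objective(du, state, yref_future, model, aux_now, config)
  }, space, opt)
  du <- res$best_position[1:3]
  u_raw <- state$current_u + du
  u_new <- pmin(pmax(u_raw, cn$u_lower), cn$u_upper)
  clamped <- any(abs(u_new - u_raw) > 0)
  du_applied <- u_new - state$current_u
  aux <- as.numeric(aux_now)[1:3]
  last_p <- if (is.null(state$last_measured_y)) NA_real_
            else state$last_measured_y
  feats <- controller_features(model, aux, u_new, last_p)
  y_raw <- as.numeric(predict(model, feats))
  list(du = du_applied, u_new = u_new, y_pred_raw = y_raw,
       y_pred = y_raw + state$bias, objective = res$best_fitness,
       clamped = clamped, trace = res$trace)
}

#' Run a closed control loop against a plant
#'
#' Receding-horizon discipline: at each controller period the latest
#' measurements are read, the output-feedback bias is updated to the last
#' measured-minus-predicted error, one increment problem is solved, only
#' the first increment is applied, and the plant is advanced one period.
#'
#' @param plant stateful stepping function from [make_sim_plant()] (or any
#'   `function(u) -> c(T_C, pH, DO_pct, P_gL)`; a `measure` attribute
#'   providing the pre-step measurement is used when present).
#' @param model a `soft_sensor` used as the controller's process model.
#' @param reference numeric reference trajectory (g/L), one value per
#'   step (values beyond `steps` are used as horizon preview).
#' @param config a [controller_config()].
#' @param steps number of controller periods to run.
#' @param seed optional integer; per-step solver seeds are derived from
#'   it.
#' @param dt_h controller period in hours (log bookkeeping only).
#' @return A `closed_loop_log` data frame: per step `time_h`, `yref`,
#'   applied `u1`-`u3`, `du1`-`du3`, `y_pred_raw`, `y_pred`, `y_meas`,
#'   `objective`, `clamped`.
#' @export
run_closed_loop <- function(plant, model, reference, config, steps,
                            seed = NULL, dt_h = 0.25) {
  stopifnot(is.function(plant), inherits(config, "controller_config"))
  steps <- assert_count(steps, "steps")
  if (length(reference) < steps) {
    stop("`reference` must provide at least `steps` values", call. = FALSE)
  }
  measure <- attr(plant, "measure")
  meas <- if (is.function(measure)) measure() else NULL

  state <- list(current_u = config$initial_u, bias = 0, time_index = 0L,
                last_measured_y = if (!is.null(meas)) meas[["P_gL"]]
                                  else NA_real_)
  prev_raw_pred <- NA_real_
  log <- vector("list", steps)

  for (t in seq_len(steps)) {
    if (!is.null(meas)) {
      if (!is.na(prev_raw_pred)) {
        state$bias <- meas[["P_gL"]] - prev_raw_pred
      }
      aux_now <- c(meas[["T_C"]], meas[["pH"]], meas[["DO_pct"]])
    } else {
      aux_now <- c(32, 7, 60)  # plant exposes no pre-step measurement
    }
    horizon <- reference[pmin(t + seq_len(config$n_pred) - 1L,
                              length(reference))]
    step_seed <- if (is.null(seed)) NULL else derive_seed(seed,
                                                          paste0("step-", t))
    sol <- tryCatch(
      solve_step(state, horizon, model, aux_now, config, seed = step_seed),
      error = function(e) e)
    if (inherits(sol, "error")) {
      warning(sprintf("controller aborted at step %d: %s", t,
                      conditionMessage(sol)))
      log <- log[seq_len(t - 1L)]
      break
    }
    meas_new <- tryCatch(plant(sol$u_new), error = function(e) e)
    if (inherits(meas_new, "error")) {
      warning(sprintf("plant fault at step %d: %s", t,
                      conditionMessage(meas_new)))
      log <- log[seq_len(t - 1L)]
      break
    }
    log[[t]] <- data.frame(
      time_h = t * dt_h, yref = reference[t],
      u1 = sol$u_new[1], u2 = sol$u_new[2], u3 = sol$u_new[3],
      du1 = sol$du[1], du2 = sol$du[2], du3 = sol$du[3],
      y_pred_raw = sol$y_pred_raw, y_pred = sol$y_pred,
      y_meas = meas_new[["P_gL"]], objective = sol$objective,
      clamped = sol$clamped)
    prev_raw_pred <- sol$y_pred_raw
    state$current_u <- sol$u_new
    state$time_index <- t
    state$last_measured_y <- meas_new[["P_gL"]]
    meas <- meas_new
  }
  out <- do.call(rbind, log)
  class(out) <- c("closed_loop_log", "data.frame")
  out
}

#' Built-in reference trajectory generators
#'
#' `reference_step_profile()` emulates a robustness study: a
#' piecewise-constant reference with periodic jumps over the first 44 h of
#' the run, constant afterwards.  `reference_sigmoid_profile()` emulates
#' an optimal batch trajectory: a logistic ramp saturating below the
#' output bound.
#'
#' @param steps number of controller periods.
#' @param dt_h controller period (h).
#' @param levels step levels cycled over the jump phase (g/L).
#' @param jump_every_h hours between jumps.
#' @param active_h duration of the jumping phase (default 44 h).
#' @return Numeric reference of length `steps`.
#' @export
reference_step_profile <- function(steps, dt_h = 0.25,
                                   levels = c(10, 20, 14, 26, 18, 30),
                                   jump_every_h = 8, active_h = 44) {
  t_h <- seq_len(steps) * dt_h
  idx <- pmin(floor(t_h / jump_every_h) + 1, length(levels))
  ref <- levels[idx]
  ref[t_h > active_h] <- levels[min(ceiling(active_h / jump_every_h) + 1,
                                    length(levels))]
  ref
}

#' @rdname reference_step_profile
#' @param y_final plateau concentration (g/L), below the output bound.
#' @param t_mid inflection time (h).
#' @param rate logistic steepness (1/h).
#' @export
reference_sigmoid_profile <- function(steps, dt_h = 0.25, y_final = 38,
                                      t_mid = 30, rate = 0.12) {
  t_h <- seq_len(steps) * dt_h
  y_final / (1 + exp(-rate * (t_h - t_mid)))
}

#' Read/write a reference trajectory CSV
#'
#' Two-column schema `time_h, yref_gL`.
#'
#' @param reference numeric reference values.
#' @param path CSV path.
#' @param dt_h controller period (h).
#' @return `read_reference_csv()` returns the numeric reference vector.
#' @export
write_reference_csv <- function(reference, path, dt_h = 0.25) {
  utils::write.csv(data.frame(time_h = seq_along(reference) * dt_h,
                              yref_gL = reference),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "yref_gL") %in% names(df))) {
    stop("reference CSV must have columns time_h, yref_gL", call. = FALSE)
  }
  df$yref_gL
}
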