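#' Synthetic fed-batch plant parameters
#'
#' Minimal mechanistic stand-in for a 30 L fed-batch l-Lysine fermenter:
#' Monod-limited logistic biomass growth, Luedeking-Piret product
#' formation, a dissolved-oxygen balance driven by agitation (`u1`, rpm)
#' and airflow (`u2`, vvm), and a pH balance driven by ammonia feed (`u3`,
#' mL/h) against acid production.  Defaults are calibrated once so that a
#' 72-h batch under mid-box inputs plateaus at 30-45 g/L product,
#' substrate starts near 150 g/L and temperature is controlled at 32 C.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param K_s Monod substrate half-saturation (g/L).
#' @param X_max logistic biomass ceiling (g/L).
#' @param Y_xs biomass yield on substrate (g/g).
#' @param alpha_lp,beta_lp Luedeking-Piret growth-associated (g/g) and
#'   non-growth-associated (1/h) product coefficients.
#' @param kla0 base oxygen transfer coefficient (1/h) at the low-input
#'   corner; `kla_u1` (per rpm above 316) and `kla_u2` (per vvm) are its
#'   linear actuator gains.
#' @param our_coef growth-associated oxygen uptake (%DO L / g, per unit
#'   `mu * X`); `our_maint` is the maintenance respiration term (%DO /h
#'   per g/L biomass), which dominates once growth slows and makes the
#'   dissolved-oxygen signal track biomass.
#' @param t_heat metabolic heat signature on the controlled temperature
#'   (C per unit oxygen transfer rate / 100): imperfect cooling lets the
#'   broth run slightly warm when respiration is high.
#' @param K_do dissolved-oxygen half-saturation of the growth factor (%).
#' @param g_alk pH rise per unit ammonia flow (1/(mL/h)/h); `g_acid` pH
#'   drop per unit `mu * X` (L/g).
#' @param pH_opt,pH_width optimum and width of the Gaussian pH growth
#'   factor.
#' @param T_set controlled broth temperature (C).
#' @param noise_sd named numeric vector of measurement noise standard
#'   deviations for channels `T_C`, `pH`, `DO_pct`, `P_gL`.
#' @param init named list of initial conditions `X0`, `S0`, `P0`, `DO0`,
#'   `pH0`.
#' @return Object of class `plant_params`.
#' @export
plant_params <- function(mu_max = 0.35, K_s = 1.0, X_max = 30, Y_xs = 0.5,
                         alpha_lp = 1.0, beta_lp = 0.004,
                         kla0 = 2.0, kla_u1 = 0.05, kla_u2 = 2.0,
                         our_coef = 20, our_maint = 8, K_do = 10,
                         g_alk = 1.2e-4, g_acid = 4e-3,
                         pH_opt = 7.0, pH_width = 1.0,
                         T_set = 32, t_heat = 0.25,
                         noise_sd = c(T_C = 0.01, pH = 0.005,
                                      DO_pct = 0.3, P_gL = 0.15),
                         init = list(X0 = 0.2, S0 = 150, P0 = 0.5,
                                     DO0 = 90, pH0 = 6.8)) {
  rates <- c(mu_max = mu_max, K_s = K_s, X_max = X_max, Y_xs = Y_xs,
             alpha_lp = alpha_lp, kla0 = kla0, our_coef = our_coef,
             our_maint = our_maint, K_do = K_do, pH_width = pH_width)
  if (any(rates <= 0)) stop("rate constants must be positive", call. = FALSE)
  if (beta_lp < 0 || g_alk < 0 || g_acid < 0) {
    stop("production/pH coefficients must be non-negative", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise std must be >= 0", call. = FALSE)
  structure(list(mu_max = mu_max, K_s = K_s, X_max = X_max, Y_xs = Y_xs,
                 alpha_lp = alpha_lp, beta_lp = beta_lp,
                 kla0 = kla0, kla_u1 = kla_u1, kla_u2 = kla_u2,
                 our_coef = our_coef, our_maint = our_maint, K_do = K_do,
                 g_alk = g_alk, g_acid = g_acid,
                 pH_opt = pH_opt, pH_width = pH_width, T_set = T_set,
                 t_heat = t_heat,
                 noise_sd = noise_sd, init = init),
            class = "plant_params")
}

# growth modifiers: smooth saturations in [0, 1]
f_do <- function(DO, params) pmax(DO, 0) / (pmax(DO, 0) + params$K_do)
f_ph <- function(pH, params) exp(-((pH - params$pH_opt) / params$pH_width)^2)

plant_deriv <- function(state, u, params) {
  X <- state[["X"]]; S <- state[["S"]]; DO <- state[["DO"]]
  pH <- state[["pH"]]
  mu <- params$mu_max * S / (params$K_s + S) *
    f_do(DO, params) * f_ph(pH, params) * max(1 - X / params$X_max, 0)
  kla <- plant_kla(u, params)
  # maintenance respiration (our_maint * X) scaled by DO availability so
  # uptake vanishes as DO -> 0
  c(X = mu * X,
    S = -mu * X / params$Y_xs,
    P = (params$alpha_lp * mu + params$beta_lp) * X,
    DO = kla * (100 - DO) -
      (params$our_coef * mu * X + params$our_maint * X * f_do(DO, params)),
    pH = params$g_alk * u[3] - params$g_acid * mu * X)
}

plant_kla <- function(u, params) {
  params$kla0 + params$kla_u1 * (u[1] - 316) + params$kla_u2 * u[2]
}

# broth temperature observation: controlled setpoint plus a metabolic
# heat signature proportional to the oxygen transfer rate
plant_temperature <- function(state, u, params) {
  otr <- plant_kla(u, params) * (100 - state[["DO"]]) / 100
  params$T_set + params$t_heat * otr
}

#' Advance the hidden plant state by one integration step
#'
#' One fixed-step RK4 step of the fed-batch kinetics, followed by state
#' sanity clamps (non-negative X/S/P, dissolved oxygen in [0, 100]%) and a
#' noisy observation of the measurable channels.  Observation noise is
#' drawn from the current RNG stream; seed upstream for reproducibility.
#'
#' @param state named numeric vector `c(X, S, P, DO, pH)` (g/L, g/L, g/L,
#'   %, -).
#' @param u applied inputs `c(u1, u2, u3)` (rpm, vvm, mL/h).
#' @param dt step length in hours.
#' @param params a [plant_params()].
#' @param noise logical; add measurement noise to the observation.
#' @return List with `state` (advanced hidden state) and `obs` (named
#'   vector `T_C`, `pH`, `DO_pct`, `P_gL`).
#' @export
plant_step <- function(state, u, dt, params, noise = TRUE) {
  stopifnot(dt > 0, inherits(params, "plant_params"))
  k1 <- plant_deriv(state, u, params)
  k2 <- plant_deriv(state + dt / 2 * k1, u, params)
  k3 <- plant_deriv(state + dt / 2 * k2, u, params)
  k4 <- plant_deriv(state + dt * k3, u, params)
  new_state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(new_state))) {
    stop("plant integration produced a non-finite state", call. = FALSE)
  }
  new_state[c("X", "S", "P")] <- pmax(new_state[c("X", "S", "P")], 0)
  new_state[["DO"]] <- min(max(new_state[["DO"]], 0), 100)
  sd <- if (noise) params$noise_sd else c(T_C = 0, pH = 0, DO_pct = 0,
                                          P_gL = 0)
  obs <- c(T_C = plant_temperature(new_state, u, params) +
             stats::rnorm(1, 0, sd[["T_C"]]),
           pH = new_state[["pH"]] + stats::rnorm(1, 0, sd[["pH"]]),
           DO_pct = new_state[["DO"]] + stats::rnorm(1, 0, sd[["DO_pct"]]),
           P_gL = new_state[["P"]] + stats::rnorm(1, 0, sd[["P_gL"]]))
  list(state = new_state, obs = obs)
}

#' Down-sample a product series to 2-h assays and spline back
#'
#' Emulates the off-line laboratory assay: keep only every-2-h values of
#' the 15-min product series (37 knots over 72 h) and cubic-spline
#' interpolate back onto the 15-min grid.  Output equals input exactly at
#' the knots.  With fewer than 4 knots the spline degenerates and linear
#' interpolation is used instead.
#'
#' @param p_series product values on a uniform 15-min grid.
#' @param sample_every_h assay interval in hours (default 2).
#' @param dt_h grid spacing in hours (default 0.25).
#' @return Interpolated series on the same grid.
#' @export
sparse_sample_and_interpolate <- function(p_series, sample_every_h = 2,
                                          dt_h = 0.25) {
  n <- length(p_series)
  if (n < 2L) stop("series too short to interpolate", call. = FALSE)
  stride <- max(1L, as.integer(round(sample_every_h / dt_h)))
  knots <- seq(1L, n, by = stride)
  if (length(knots) < 2L || knots[length(knots)] != n) {
    knots <- unique(c(knots, n))
  }
  tk <- (knots - 1) * dt_h
  tq <- (seq_len(n) - 1) * dt_h
  if (length(knots) < 4L) {
    stats::approx(tk, p_series[knots], xout = tq, rule = 2)$y
  } else {
    # "fmm" end conditions (cubic through the four end points) reproduce
    # polynomials up to cubic degree exactly, matching spline interp1-style
    # interpolation of slowly varying assay data
    stats::spline(tk, p_series[knots], xout = tq, method = "fmm")$y
  }
}

#' Simulate one 72-h fed-batch fermentation
#'
#' Integrates the plant with internal RK4 sub-stepping (`dt_internal`,
#' default 0.025 h), records noisy observations on the 15-min grid, and
#' replaces the product channel by its 2-h-assay spline reconstruction
#' (the raw 15-min product is kept as attribute `P_raw` for honest error
#' reporting).
#'
#' @param params a [plant_params()].
#' @param input_profiles data frame or matrix with columns `u1_rpm`,
#'   `u2_vvm`, `u3_mlh` on the observation grid (one row per sample,
#'   held constant over each interval), or a length-3 vector of constant
#'   inputs.
#' @param seed integer seed for the observation-noise stream, or `NULL`.
#' @param hours batch duration (default 72).
#' @param dt_obs_h observation period (default 0.25 h = 15 min).
#' @param dt_internal internal integration step (h).
#' @param init optional named list overriding `params$init`.
#' @param batch_id identifier stored in the record's attributes.
#' @return A `batch_record` data frame with the standard schema
#'   (`time_h`, `T_C`, `pH`, `u1_rpm`, `DO_pct`, `u2_vvm`, `u3_mlh`,
#'   `P_gL`) and metadata attributes `batch_id`, `seed`, `init`, `P_raw`.
#' @export
simulate_batch <- function(params = plant_params(), input_profiles,
                           seed = NULL, hours = 72, dt_obs_h = 0.25,
                           dt_internal = 0.025, init = NULL,
                           batch_id = "batch") {
  n_obs <- as.integer(round(hours / dt_obs_h)) + 1L
  if (is.null(dim(input_profiles))) {
    stopifnot(length(input_profiles) == 3L)
    input_profiles <- matrix(rep(as.numeric(input_profiles), each = n_obs),
                             nrow = n_obs,
                             dimnames = list(NULL,
                                             c("u1_rpm", "u2_vvm", "u3_mlh")))
  }
  U <- as.matrix(as.data.frame(input_profiles)[, c("u1_rpm", "u2_vvm",
                                                   "u3_mlh")])
  if (nrow(U) < n_obs) {
    stop("input profiles must cover the full observation grid",
         call. = FALSE)
  }
  ic <- utils::modifyList(params$init, if (is.null(init)) list() else init)
  with_local_seed(seed, {
    state <- c(X = ic$X0, S = ic$S0, P = ic$P0, DO = ic$DO0, pH = ic$pH0)
    n_sub <- max(1L, as.integer(round(dt_obs_h / dt_internal)))
    dt_sub <- dt_obs_h / n_sub
    obs <- matrix(NA_real_, nrow = n_obs, ncol = 4,
                  dimnames = list(NULL, c("T_C", "pH", "DO_pct", "P_gL")))
    nz <- any(params$noise_sd > 0)
    obs[1, ] <- c(plant_temperature(state, U[1L, ], params) +
                    stats::rnorm(1, 0, params$noise_sd[["T_C"]]),
                  state[["pH"]] + stats::rnorm(1, 0, params$noise_sd[["pH"]]),
                  state[["DO"]] +
                    stats::rnorm(1, 0, params$noise_sd[["DO_pct"]]),
                  state[["P"]] +
                    stats::rnorm(1, 0, params$noise_sd[["P_gL"]]))
    for (k in 2:n_obs) {
      u <- U[k - 1L, ]
      for (s in seq_len(n_sub - 1L)) {
        step <- plant_step(state, u, dt_sub, params, noise = FALSE)
        state <- step$state
      }
      step <- plant_step(state, u, dt_sub, params, noise = nz)
      state <- step$state
      obs[k, ] <- step$obs
    }
    p_raw <- obs[, "P_gL"]
    p_assay <- sparse_sample_and_interpolate(p_raw, sample_every_h = 2,
                                             dt_h = dt_obs_h)
    rec <- data.frame(time_h = (seq_len(n_obs) - 1) * dt_obs_h,
                      T_C = obs[, "T_C"], pH = obs[, "pH"],
                      u1_rpm = U[seq_len(n_obs), 1],
                      DO_pct = obs[, "DO_pct"],
                      u2_vvm = U[seq_len(n_obs), 2],
                      u3_mlh = U[seq_len(n_obs), 3],
                      P_gL = p_assay)
    attr(rec, "batch_id") <- batch_id
    attr(rec, "seed") <- seed
    attr(rec, "init") <- ic
    attr(rec, "P_raw") <- p_raw
    class(rec) <- c("batch_record", "data.frame")
    rec
  })
}

# nominal actuator recipe: a campaign runs one base schedule per channel
# (ramping agitation/airflow up as oxygen demand grows, ammonia tracking
# growth), and batches perturb it segment by segment
nominal_schedule <- function(frac) {
  list(u1_rpm = 318 + (342 - 318) * frac,
       u2_vvm = 0.2 + (1.5 - 0.2) * frac,
       u3_mlh = 55 + (105 - 55) * frac)
}

U_BOX <- list(lower = c(u1_rpm = 316, u2_vvm = 0.1, u3_mlh = 51),
              upper = c(u1_rpm = 345, u2_vvm = 1.65, u3_mlh = 110))

#' Draw a piecewise-constant batch feeding strategy
#'
#' Emulates one batch of a recipe-following campaign: every batch runs the
#' same nominal actuator ramps, discretized into `n_segments` constant
#' segments, but the segment switch times are jittered batch to batch
#' (operators advance or delay feed steps, by up to `variability` of the
#' batch length per boundary) and each segment level carries a small
#' execution error (+/- `0.15 * variability` of the actuator box width).
#' Levels are clipped into the actuator box.  Timing jitter moves batches
#' along the shared operating trajectory; level error moves them across
#' it, which is why it is the smaller of the two.
#'
#' @param n_obs number of grid samples.
#' @param n_segments number of constant segments (typically 4-8).
#' @param variability fractional variability dial (0 disables all jitter).
#' @return Data frame with `u1_rpm`, `u2_vvm`, `u3_mlh` columns.
#' @export
draw_input_profile <- function(n_obs, n_segments = 6L, variability = 0.03) {
  bounds_lo <- U_BOX$lower
  bounds_hi <- U_BOX$upper
  # jittered segment boundaries on the sample grid
  bounds_frac <- seq(0, 1, length.out = n_segments + 1L)
  if (variability > 0 && n_segments > 1L) {
    inner <- bounds_frac[2:n_segments] +
      stats::runif(n_segments - 1L, -variability, variability)
    bounds_frac <- c(0, sort(pmin(pmax(inner, 0.01), 0.99)), 1)
  }
  cuts <- pmin(pmax(round(bounds_frac * n_obs), 0), n_obs)
  seg_len <- diff(cuts)
  seg_len[seg_len < 1L] <- 1L
  seg_id <- rep(seq_len(n_segments), seg_len)[seq_len(n_obs)]
  seg_id[is.na(seg_id)] <- n_segments
  frac <- (bounds_frac[-1] + bounds_frac[-length(bounds_frac)]) / 2
  base <- nominal_schedule(frac)
  out <- lapply(names(base), function(ch) {
    width <- bounds_hi[[ch]] - bounds_lo[[ch]]
    seg <- base[[ch]] +
      stats::runif(n_segments, -1, 1) * 0.15 * variability * width
    seg <- pmin(pmax(seg, bounds_lo[[ch]]), bounds_hi[[ch]])
    seg[seg_id]
  })
  names(out) <- names(base)
  as.data.frame(out)
}

#' Generate a reproducible campaign of synthetic batches
#'
#' Emulates a ten-batch identification campaign running one recipe: per
#' batch, initial conditions are jittered around the nominal values and a
#' fresh piecewise-constant feeding strategy (`n_segments` phases per
#' channel, timing and level jittered; see [draw_input_profile()]) is
#' drawn; each batch is then simulated for 72 h.  All randomness flows
#' from `master_seed` via per-batch derived seeds.
#'
#' @param n_batches number of batches (default 10).
#' @param params a [plant_params()].
#' @param variability fractional batch-to-batch variability of initial
#'   conditions and feeding strategy (default 0.03).
#' @param master_seed integer master seed.
#' @param n_segments feed phases per channel in the campaign recipe
#'   (4-8 are sensible; default 6).
#' @param hours,dt_obs_h,dt_internal forwarded to [simulate_batch()].
#' @return List of `batch_record` data frames.
#' @export
generate_batches <- function(n_batches = 10L, params = plant_params(),
                             variability = 0.03, master_seed = 1L,
                             n_segments = 6L, hours = 72, dt_obs_h = 0.25,
                             dt_internal = 0.025) {
  n_batches <- assert_count(n_batches, "n_batches")
  n_obs <- as.integer(round(hours / dt_obs_h)) + 1L
  lapply(seq_len(n_batches), function(k) {
    seed_k <- derive_seed(master_seed, paste0("plant-batch-", k))
    with_local_seed(seed_k, {
      # per-condition jitter scales, all proportional to `variability`:
      # inoculum size varies the most (and only shifts batches along the
      # trajectory manifold); broth make-up (S0) and assay baseline (P0)
      # vary fractionally; inoculation pH is tightly controlled, so its
      # spread is absolute and small
      jit <- function(v, frac, lo = NULL, hi = NULL, absolute = 0) {
        out <- v * (1 + stats::runif(1, -frac, frac)) +
          if (absolute > 0) stats::runif(1, -absolute, absolute) else 0
        if (!is.null(lo)) out <- max(out, lo)
        if (!is.null(hi)) out <- min(out, hi)
        out
      }
      v <- variability
      ic <- list(X0 = jit(params$init$X0, 1.5 * v, lo = 0.01),
                 S0 = jit(params$init$S0, v, lo = 50),
                 P0 = jit(params$init$P0, v, lo = 0.05),
                 DO0 = jit(params$init$DO0, 0.05 * v, lo = 50, hi = 100),
                 pH0 = jit(params$init$pH0, 0, lo = 6, hi = 8,
                           absolute = 0.3 * v))
      profile <- draw_input_profile(n_obs, n_segments, variability)
      sim_seed <- derive_seed(master_seed, paste0("plant-noise-", k))
      simulate_batch(params, profile, seed = sim_seed, hours = hours,
                     dt_obs_h = dt_obs_h, dt_internal = dt_internal,
                     init = ic, batch_id = sprintf("batch%02d", k))
    })
  })
}

#' Wrap the simulator as a closed-loop plant interface
#'
#' Returns a stateful stepping function `function(u)` that advances the
#' hidden plant by one controller period under the applied inputs and
#' returns the measured channels; the controller sees only the
#' measurements.
#'
#' @param params a [plant_params()].
#' @param seed integer seed for the plant's noise stream.
#' @param init optional initial-condition overrides.
#' @param dt_obs_h controller period (h).
#' @param dt_internal integration sub-step (h).
#' @return A function `(u) -> c(T_C, pH, DO_pct, P_gL)` with the current
#'   measurement available before any step via attribute `measure()`.
#' @export
make_sim_plant <- function(params = plant_params(), seed = NULL,
                           init = NULL, dt_obs_h = 0.25,
                           dt_internal = 0.025) {
  ic <- utils::modifyList(params$init, if (is.null(init)) list() else init)
  env <- new.env(parent = emptyenv())
  env$state <- c(X = ic$X0, S = ic$S0, P = ic$P0, DO = ic$DO0, pH = ic$pH0)
  env$rng_seed <- if (is.null(seed)) NULL else as.integer(seed)
  n_sub <- max(1L, as.integer(round(dt_obs_h / dt_internal)))
  dt_sub <- dt_obs_h / n_sub
  env$last_u <- c(326, 0.1, 88)
  step_fun <- function(u) {
    env$last_u <- u
    run <- function() {
      for (s in seq_len(n_sub - 1L)) {
        st <- plant_step(env$state, u, dt_sub, params, noise = FALSE)
        env$state <- st$state
      }
      st <- plant_step(env$state, u, dt_sub, params, noise = TRUE)
      env$state <- st$state
      st$obs
    }
    if (is.null(env$rng_seed)) run()
    else with_local_seed(env$rng_seed + 1L, {
      env$rng_seed <- env$rng_seed + 1L
      run()
    })
  }
  attr(step_fun, "measure") <- function() {
    c(T_C = plant_temperature(env$state, env$last_u, params),
      pH = env$state[["pH"]],
      DO_pct = env$state[["DO"]], P_gL = env$state[["P"]])
  }
  attr(step_fun, "state") <- function() env$state
  step_fun
}
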