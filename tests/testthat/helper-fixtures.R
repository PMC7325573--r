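# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# default synthetic campaign (10 batches, master seed 1)
fixture_campaign <- function() {
  memo("campaign", function() {
    generate_batches(10, master_seed = derive_seed(1, "plant"))
  })
}

# soft sensor tuned on the campaign with a small optimizer budget
fixture_sensor <- function() {
  memo("sensor", function() {
    bs <- fixture_campaign()
    tune_soft_sensor(bs[1:6], bs[7:8],
                     opt_config = optimizer_config(10L, 15L, seed = 99L),
                     subsample = 2L)
  })
}

# a sensor whose prediction responds strongly and smoothly to the three
# actuators, for controller tests; the map is known in closed form
fixture_toy_sensor <- function() {
  memo("toy_sensor", function() {
    set.seed(7)
    n <- 150
    X <- data.frame(T_C = runif(n, 31.9, 32.1), pH = runif(n, 6.9, 7.1),
                    u1_rpm = runif(n, 316, 345), DO_pct = runif(n, 55, 65),
                    u2_vvm = runif(n, 0.1, 1.65), u3_mlh = runif(n, 51, 110))
    y <- 10 + 20 * (X$u1_rpm - 316) / 29 + 8 * X$u2_vvm / 1.65 +
      5 * (X$u3_mlh - 51) / 59
    make_sensor_from_table(X, y, g = 1000, sigma = 1.5)
  })
}

# a sensor that predicts the constant `value` whatever the input
constant_sensor <- function(value) {
  X <- data.frame(T_C = c(31.9, 32.1), pH = c(6.9, 7.1),
                  u1_rpm = c(316, 345), DO_pct = c(55, 65),
                  u2_vvm = c(0.1, 1.65), u3_mlh = c(51, 110))
  sensor <- make_sensor_from_table(X, c(value - 0.5, value + 0.5),
                                   g = 1, sigma = 5)
  # force alpha = 0 so the predictor is exactly the bias
  sensor$model$alpha[] <- 0
  rng <- sensor$stats$max[["P_gL"]] - sensor$stats$min[["P_gL"]]
  sensor$model$b <- 2 * (value - sensor$stats$min[["P_gL"]]) / rng - 1
  sensor
}

# fit a physical-scale soft sensor directly from a feature table
make_sensor_from_table <- function(X, y, g, sigma) {
  full <- cbind(X, P_gL = y)
  st <- fit_normalization(full)
  Xn <- as.matrix(normalize_table(X, st))
  rng <- st$max[["P_gL"]] - st$min[["P_gL"]]
  yn <- 2 * (y - st$min[["P_gL"]]) / rng - 1
  m <- lssvm_fit(Xn, yn, g, sigma)
  fermpc:::new_soft_sensor(m, st, names(X), "P_gL")
}

# wrap a sensor as a memoryless plant: the measured product is exactly the
# sensor's raw prediction at the applied inputs (plus `offset`), with
# T/pH/DO held constant
model_as_plant <- function(sensor, aux = c(T_C = 32, pH = 7, DO_pct = 60),
                           offset = 0, initial_u = c(326, 0.1, 88)) {
  env <- new.env(parent = emptyenv())
  env$p <- as.numeric(predict(sensor, c(aux[[1]], aux[[2]], initial_u[1],
                                        aux[[3]], initial_u[2],
                                        initial_u[3]))) + offset
  plant <- function(u) {
    p <- as.numeric(predict(sensor, c(aux[[1]], aux[[2]], u[1], aux[[3]],
                                      u[2], u[3]))) + offset
    env$p <- p
    c(T_C = aux[[1]], pH = aux[[2]], DO_pct = aux[[3]], P_gL = p)
  }
  attr(plant, "measure") <- function() {
    c(T_C = aux[[1]], pH = aux[[2]], DO_pct = aux[[3]], P_gL = env$p)
  }
  plant
}

# independent dense linear solver (Gauss-Jordan with partial pivoting),
# deliberately not base::solve, for oracle checks of the KKT system
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1L
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    M[k, ] <- M[k, ] / M[k, k]
    for (i in seq_len(n)[-k]) M[i, ] <- M[i, ] - M[i, k] * M[k, ]
  }
  M[, n + 1L]
}

# deterministic "rng" yielding a fixed value, for coefficient-vector tests
const_rng <- function(value) function(n) rep(value, n)

# evaluate under a temporary seed without disturbing the test RNG stream
with_seed_local <- function(seed, expr) fermpc:::with_local_seed(seed, expr)
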