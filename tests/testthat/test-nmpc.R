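test_that("constraint and controller configs validate their inputs", {
  expect_error(control_constraints(u_lower = c(350, 0.1, 51)), "lower")
  expect_error(controller_config(n_pred = 1, n_con = 2), "n_con")
  expect_error(controller_config(initial_u = c(300, 0.1, 88)), "input box")
  cc <- control_constraints()
  expect_equal(cc$u_lower, c(316, 0.1, 51))
  expect_equal(cc$u_upper, c(345, 1.65, 110))
  expect_equal(cc$du_lower, c(-15, -1, -30))
  expect_equal(cc$y_upper, 45)
})

test_that("tracking objective reproduces hand-evaluated costs", {
  sensor <- constant_sensor(10)
  cfg <- controller_config()
  state <- list(current_u = c(326, 0.1, 88), bias = 0)
  aux <- c(32, 7, 60)
  pred <- predict_corrected(sensor, c(32, 7, 326, 60, 0.1, 88), 0)
  expect_equal(pred, 10, tolerance = 1e-9)

  # zero increment, prediction equal to the reference: zero cost
  expect_equal(nmpc_objective(c(0, 0, 0), state, pred, sensor, aux, cfg), 0,
               tolerance = 1e-9)
  # zero increment, error eps: cost eps^2
  expect_equal(nmpc_objective(c(0, 0, 0), state, pred - 0.7, sensor, aux,
                              cfg), 0.49, tolerance = 1e-6)
  # error 2 and du = (10, 0, 0): cost 4 + 0.001 * 100 = 4.1
  expect_equal(nmpc_objective(c(10, 0, 0), state, pred - 2, sensor, aux,
                              cfg), 4.1, tolerance = 1e-6)
})

test_that("infeasible candidates are penalized, not rejected", {
  sensor <- constant_sensor(10)
  cfg <- controller_config()
  state <- list(current_u = c(340, 0.1, 88), bias = 0)
  aux <- c(32, 7, 60)
  # u1 + 10 leaves the input box: cost must be finite but huge
  J <- nmpc_objective(c(10, 0, 0), state, 10, sensor, aux, cfg)
  expect_true(is.finite(J))
  expect_gt(J, 1e4)
})

test_that("output-feedback correction is additive", {
  sensor <- fixture_toy_sensor()
  f <- c(32, 7, 330, 60, 1, 80)
  raw <- predict_corrected(sensor, f, 0)
  expect_equal(predict_corrected(sensor, f, 1.5), raw + 1.5)
  expect_equal(raw, as.numeric(predict(sensor, f)))
})

test_that("solve_step returns feasible, near-zero moves for a flat model", {
  sensor <- constant_sensor(20)
  cfg <- controller_config(optimizer = optimizer_config(20L, 40L))
  state <- list(current_u = c(326, 0.5, 88), bias = 0)
  sol <- solve_step(state, 20, sensor, c(32, 7, 60), cfg, seed = 3L)
  # constant prediction: only the increment penalty matters
  expect_lt(max(abs(sol$du)), 0.5)
  cc <- cfg$constraints
  expect_true(all(sol$u_new >= cc$u_lower & sol$u_new <= cc$u_upper))
  expect_true(all(sol$du >= cc$du_lower - 1e-9 &
                    sol$du <= cc$du_upper + 1e-9))
  expect_true(all(diff(sol$trace) <= 0))
})

test_that("perfect-model loop tracks a constant reachable reference", {
  sensor <- fixture_toy_sensor()
  plant <- model_as_plant(sensor)
  cfg <- controller_config(optimizer = optimizer_config(30L, 60L))
  log <- run_closed_loop(plant, sensor, rep(25, 8), cfg, 8, seed = 11L)
  expect_equal(nrow(log), 8L)
  expect_lt(max(abs(log$y_meas[5:8] - 25)), 1e-2)
})

test_that("bias feedback removes a constant plant-model offset", {
  sensor <- fixture_toy_sensor()
  plant <- model_as_plant(sensor, offset = 1.5)
  cfg <- controller_config(optimizer = optimizer_config(30L, 60L))
  log <- run_closed_loop(plant, sensor, rep(25, 12), cfg, 12, seed = 13L)
  # the bias estimate converges to the offset and tracking error vanishes
  expect_lt(max(abs(log$y_meas[8:12] - 25)), 1e-2)
  expect_equal(log$y_pred[12] - log$y_pred_raw[12], 1.5, tolerance = 0.05)
})

test_that("with q_out = 0 the controller freezes the inputs", {
  sensor <- fixture_toy_sensor()
  plant <- model_as_plant(sensor)
  cfg <- controller_config(q_out = 0,
                           optimizer = optimizer_config(20L, 40L))
  log <- run_closed_loop(plant, sensor, rep(40, 5), cfg, 5, seed = 5L)
  expect_lt(max(abs(as.matrix(log[, c("du1", "du2", "du3")]))), 0.5)
})

test_that("only the first increment of a multi-step solve is applied", {
  sensor <- fixture_toy_sensor()
  plant <- model_as_plant(sensor)
  cfg <- controller_config(n_pred = 2L, n_con = 2L,
                           optimizer = optimizer_config(15L, 25L))
  log <- run_closed_loop(plant, sensor, rep(22, 4), cfg, 4, seed = 2L)
  u_prev <- rbind(cfg$initial_u,
                  as.matrix(log[-nrow(log), c("u1", "u2", "u3")]))
  du <- as.matrix(log[, c("du1", "du2", "du3")])
  expect_equal(unname(as.matrix(log[, c("u1", "u2", "u3")])),
               unname(u_prev + du), tolerance = 1e-10)
  # applied increments respect the per-step box even over the horizon
  cc <- cfg$constraints
  expect_true(all(du >= matrix(cc$du_lower, 4, 3, byrow = TRUE) - 1e-9))
  expect_true(all(du <= matrix(cc$du_upper, 4, 3, byrow = TRUE) + 1e-9))
})

test_that("reference generators and CSV round-trips behave", {
  ref <- reference_step_profile(288)
  expect_length(ref, 288L)
  # piecewise constant with jumps only at the 8-h boundaries
  jumps <- which(diff(ref) != 0)
  expect_true(all((jumps + 1L) %% 32 == 0))
  # constant after the 44-h active window
  expect_equal(length(unique(ref[177:288])), 1L)

  sig <- reference_sigmoid_profile(288)
  expect_true(all(diff(sig) > 0))
  expect_lt(max(sig), 45)

  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(sig, path)
  expect_equal(read_reference_csv(path), sig, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_reference_csv(bad), "time_h")
})

test_that("a lag-augmented sensor plugs into the controller", {
  bs <- fixture_campaign()
  tuned <- tune_soft_sensor(bs[1:2], bs[3],
                            opt_config = optimizer_config(5L, 4L, seed = 6L),
                            include_lag = TRUE, subsample = 8L)
  state <- list(current_u = c(326, 0.5, 88), bias = 0,
                last_measured_y = 5)
  cfg <- controller_config(optimizer = optimizer_config(8L, 10L))
  sol <- solve_step(state, 6, tuned$sensor, c(32, 7, 60), cfg, seed = 1L)
  expect_true(is.finite(sol$objective))
  # without the lagged measurement the features cannot be built
  state$last_measured_y <- NULL
  expect_error(solve_step(state, 6, tuned$sensor, c(32, 7, 60), cfg,
                          seed = 1L), "last_p")
})
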