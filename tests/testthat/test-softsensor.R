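test_that("normalization maps the training range onto [-1, 1] affinely", {
  tab <- data.frame(a = c(2, 4, 6), b = c(-1, 0, 3))
  st <- fit_normalization(tab)
  out <- normalize_table(tab, st)
  expect_equal(out$a, c(-1, 0, 1))
  expect_equal(out$b[1], -1)
  # affine extension outside the fitted range, no clipping
  ext <- normalize_table(data.frame(a = 2 + 1.5 * 4), st)
  expect_equal(ext$a, 2)
  # roundtrip
  expect_equal(denormalize(out$b, st, "b"), tab$b, tolerance = 1e-12)
  expect_error(fit_normalization(data.frame(c = rep(1, 5))), "constant")
  expect_error(normalize_table(data.frame(zz = 1), st), "zz")
})

test_that("regression tables stack batches in order", {
  bs <- fixture_campaign()
  tab <- assemble_regression_table(bs[1])
  expect_equal(dim(tab$X), c(289L, 6L))
  expect_identical(colnames(tab$X),
                   c("T_C", "pH", "u1_rpm", "DO_pct", "u2_vvm", "u3_mlh"))
  tab2 <- assemble_regression_table(bs[1:2])
  expect_equal(nrow(tab2$X), 578L)
  expect_equal(tab2$X[1:289, ], tab$X)
  expect_equal(tab2$y[1:289], tab$y)
  expect_error(assemble_regression_table(list()), "empty")
  broken <- bs[[1]]
  broken$DO_pct <- NULL
  expect_error(assemble_regression_table(list(broken)), "DO_pct")

  lagged <- assemble_regression_table(bs[1], include_lag = TRUE)
  expect_equal(ncol(lagged$X), 7L)
  expect_equal(unname(lagged$X[2, "P_lag"]), lagged$y[1])
  expect_equal(unname(lagged$X[1, "P_lag"]), lagged$y[1])
})

test_that("error metrics match their formulas and inequalities", {
  v <- c(1.2, -0.3, 4)
  expect_equal(rmse(v, v), 0)
  expect_equal(mae(v, v), 0)
  expect_equal(mape(v, v), 0)

  expect_equal(rmse(c(1, 1), c(0, 2)), 1)
  expect_equal(mae(c(1, 1), c(0, 2)), 1)
  expect_equal(mape(c(1, 1), c(0, 2)), 1)

  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(15); p <- rnorm(15)
    expect_gte(rmse(a, p), mae(a, p))
  }
  expect_error(mape(c(0, 1), c(1, 1)), "zero")
  expect_error(rmse(1:3, 1:4), "equal-length")
})

test_that("cv fitness interpolates, saturates on noise, and is total", {
  set.seed(31)
  X <- matrix(runif(60, -1, 1), 30, 2)
  y <- tanh(X[, 1]) + 0.3 * X[, 2]
  tab <- list(X = X, y = y)
  expect_lt(cv_fitness(c(1e8, 0.8), tab, tab), 1e-3)

  # independent target: fitness approaches the cv target sd, not zero
  noise <- list(X = X, y = rnorm(30))
  f <- cv_fitness(c(100, 0.8), tab, noise)
  expect_gt(f, 0.5 * stats::sd(noise$y))

  expect_identical(cv_fitness(c(10, 0.5), tab, tab),
                   cv_fitness(c(10, 0.5), tab, tab))
  # invalid hyperparameters route to the sentinel instead of raising
  expect_identical(cv_fitness(c(-5, 0.5), tab, tab), fermpc:::WORST_FITNESS)
})

test_that("tuning recovers a known RBF-generated hyperparameter regime", {
  # data generated by an LSSVM with known (g*, sigma*) plus small noise:
  # the tuned model must do at least as well as the generator's own cv loss
  set.seed(17)
  l <- 70
  X <- matrix(runif(2 * l, -1, 1), l, 2)
  centres <- X[1:8, ]
  f <- function(M) {
    K <- fermpc:::cross_kernel(M, centres, 0.05)
    as.numeric(K %*% c(2, -1, 1.5, -2, 1, -1.5, 0.8, -0.6))
  }
  noise_sd <- 0.01
  y <- f(X) + rnorm(l, 0, noise_sd)
  mk_batch <- function(X, y) {
    data.frame(T_C = X[, 1], pH = X[, 2], u1_rpm = 0.5 * X[, 1] + 330,
               DO_pct = 60 + 10 * X[, 2], u2_vvm = 1 + 0.2 * X[, 1],
               u3_mlh = 80 + 5 * X[, 2], P_gL = 10 + y)
  }
  Xcv <- matrix(runif(80, -1, 1), 40, 2)
  cvb <- mk_batch(Xcv, f(Xcv) + rnorm(40, 0, noise_sd))
  tuned <- tune_soft_sensor(list(mk_batch(X, y)), list(cvb),
                            opt_config = optimizer_config(10L, 20L,
                                                          seed = 5L))
  expect_gte(tuned$best_g, 1); expect_lte(tuned$best_g, 10000)
  expect_gte(tuned$best_sigma, 0.001); expect_lte(tuned$best_sigma, 0.1)
  # normalized noise floor: the target spans ~[9, 11] -> /(range/2)
  expect_lt(tuned$cv_rmse, 0.1)
  expect_true(all(diff(tuned$optimizer$trace) <= 0))
})

test_that("gwo and pso tuners honour the same contract", {
  bs <- fixture_campaign()
  for (alg in c("gwo", "pso")) {
    tuned <- tune_soft_sensor(bs[1:2], bs[3],
                              opt_config = optimizer_config(6L, 5L,
                                                            seed = 2L),
                              algorithm = alg, subsample = 8L)
    expect_gte(tuned$best_g, 1); expect_lte(tuned$best_g, 10000)
    expect_gte(tuned$best_sigma, 0.001); expect_lte(tuned$best_sigma, 0.1)
    expect_true(all(diff(tuned$optimizer$trace) <= 0))
    expect_s3_class(tuned$sensor, "soft_sensor")
  }
})

test_that("degenerate one-sample cv set still returns a finite fitness", {
  bs <- fixture_campaign()
  one_row <- bs[[3]][1, , drop = FALSE]
  tuned <- tune_soft_sensor(bs[1:2], list(one_row),
                            opt_config = optimizer_config(5L, 3L, seed = 1L),
                            subsample = 8L)
  expect_true(is.finite(tuned$cv_rmse))
})

test_that("normalization statistics come from training batches only", {
  bs <- fixture_campaign()
  tuned <- fixture_sensor()
  train_tab <- assemble_regression_table(bs[1:6])
  keep <- seq(1, nrow(train_tab$X), by = 2)
  full <- cbind(as.data.frame(train_tab$X[keep, ]),
                P_gL = train_tab$y[keep])
  st <- fit_normalization(full)
  expect_equal(tuned$stats$min, st$min)
  expect_equal(tuned$stats$max, st$max)
})

test_that("tuned search beats naive random candidate sampling", {
  # scaled-down version of the invariant: one campaign, 3 seeds
  bs <- fixture_campaign()
  train <- bs[1:6]; cvb <- bs[7:8]
  tab_tr <- assemble_regression_table(train)
  tab_cv <- assemble_regression_table(cvb)
  sub <- function(tab, by) {
    k <- seq(1, nrow(tab$X), by = by)
    list(X = tab$X[k, ], y = tab$y[k])
  }
  tab_tr <- sub(tab_tr, 4); tab_cv <- sub(tab_cv, 4)
  full <- cbind(as.data.frame(tab_tr$X), P_gL = tab_tr$y)
  st <- fit_normalization(full)
  nx <- function(tab) {
    rng <- st$max[["P_gL"]] - st$min[["P_gL"]]
    list(X = as.matrix(normalize_table(as.data.frame(tab$X), st)),
         y = 2 * (tab$y - st$min[["P_gL"]]) / rng - 1)
  }
  trn <- nx(tab_tr); cvn <- nx(tab_cv)
  wins <- 0L
  for (s in 1:3) {
    tuned <- tune_soft_sensor(train, cvb,
                              opt_config = optimizer_config(8L, 10L,
                                                            seed = s),
                              subsample = 4L)
    rand <- with_seed_local(1000 + s, {
      cands <- cbind(runif(25, 1, 10000), runif(25, 0.001, 0.1))
      min(apply(cands, 1, cv_fitness, train_table = trn, cv_table = cvn))
    })
    if (tuned$cv_rmse <= rand + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
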