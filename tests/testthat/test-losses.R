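test_that("data loss is the mean squared misfit", {
  obs <- small_logistic_obs(n = 9)
  m <- tiny_model(seed = 2, zero_output_init = FALSE)
  # brute-force two-loop MSE as the oracle
  pred <- pinn_predict(m, obs$times)
  acc <- 0
  for (i in seq_along(obs$times))
    for (j in seq_len(ncol(obs$values)))
      acc <- acc + (pred[i, j] - obs$values[i, j])^2
  expect_equal(data_loss(m, obs), unname(acc) / length(obs$values),
               tolerance = 1e-12)

  # exact predictions give zero
  m0 <- constant_model(3)
  obs0 <- obs
  obs0$values[] <- 3
  expect_equal(data_loss(m0, obs0), 0)
  # constant offset d over one state gives d^2
  obs_d <- obs
  obs_d$values[] <- 3 - 1.25
  expect_equal(data_loss(m0, obs_d), 1.25^2, tolerance = 1e-12)
})

test_that("IC loss penalizes squared deviation at the initial time", {
  m <- constant_model(3)
  expect_equal(ic_loss(m, 0, 1), 4.0)
  expect_equal(ic_loss(m, 0, 3), 0)
  gene_m <- constant_model(c(17, 25, 0), dim = 3)
  expect_equal(ic_loss(gene_m, 0, c(17.0, 25, 0)), 0)
  expect_error(ic_loss(gene_m, 0, c(1, 2)), "length")
})

test_that("physics loss is the mean squared ODE residual at collocation points", {
  sys <- logistic_system()
  m <- tiny_model(seed = 3, transform = scale_transform(10),
                  zero_output_init = FALSE)
  params <- list(r = 0.5, K = 100)
  m$ode_params <- params

  # single point: equals the squared residual computed from the exported
  # prediction and derivative operators
  t1 <- 4.2
  res1 <- time_derivative(m, t1)[1, 1] -
    logistic_rhs(pinn_predict(m, t1)[1, 1], params)
  expect_equal(physics_loss(m, sys, t1), res1^2, tolerance = 1e-12)

  cs <- sample_collocation(40, 0, 10, seed = 1)
  expect_gte(physics_loss(m, sys, cs), 0)
  # mean over points of the per-point squared residuals
  per_point <- vapply(cs$times, function(t)
    (time_derivative(m, t)[1, 1] -
       logistic_rhs(pinn_predict(m, t)[1, 1], params))^2, numeric(1))
  expect_equal(physics_loss(m, sys, cs), mean(per_point), tolerance = 1e-12)
  expect_error(physics_loss(m, sys, numeric(0)), "empty")
})

test_that("residual of the exact logistic solution vanishes", {
  # the closed form substituted into the ODE: mean squared residual ~ 0
  tt <- sample_collocation(200, 0, 100, seed = 2)$times
  resid <- logistic_analytic_deriv(tt) -
    logistic_rhs(logistic_analytic(tt, logistic_true), logistic_true)
  expect_lt(mean(resid^2), 1e-8)
})

test_that("autodiff and finite-difference residuals agree on a trained model", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 20)
  cfg <- training_config(iterations = 400, log_every = 100, seed = 1)
  h <- train_pinn(pinn_model(case_network_spec(case), case$params, seed = 1),
                  case$system, obs, sample_collocation(60, 0, 100, seed = 1),
                  cfg, ic = 1.0)
  m <- h$model
  tc <- seq(2, 98, length.out = 50)
  step <- 1e-3
  # high-order (5-point) central difference derivative as the oracle
  fd <- (-pinn_predict(m, tc + 2 * step) + 8 * pinn_predict(m, tc + step) -
           8 * pinn_predict(m, tc - step) + pinn_predict(m, tc - 2 * step)) /
    (12 * step)
  f <- logistic_rhs(pinn_predict(m, tc)[, 1], m$ode_params)
  loss_fd <- mean((fd[, 1] - f)^2)
  expect_equal(physics_loss(m, case$system, tc), loss_fd, tolerance = 1e-6)
})

test_that("total loss is the weighted sum of its parts", {
  expect_equal(total_loss(list(data_loss = 1, ic_loss = 2, physics_loss = 3)), 6)
  expect_equal(total_loss(list(data_loss = 0, ic_loss = 0, physics_loss = 7)), 7)
  expect_equal(total_loss(list(data_loss = 1, ic_loss = 5, physics_loss = 4),
                          weights = c(2, 0, 1)), 6)
  expect_error(total_loss(list(data_loss = 1, ic_loss = 1, physics_loss = 1),
                          weights = c(-1, 1, 1)), "nonnegative")
  expect_error(total_loss(list(data_loss = Inf, ic_loss = 0, physics_loss = 0)),
               "finite")

  set.seed(21)
  for (i in 1:10) {
    parts <- loss_breakdown(runif(1), runif(1), runif(1))
    expect_identical(parts$total,
                     parts$data_loss + parts$ic_loss + parts$physics_loss)
  }
})

test_that("the fused objective reproduces the exported loss components", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 15)
  m <- pinn_model(case_network_spec(case), case$params, seed = 5,
                  zero_output_init = FALSE)
  tc <- sample_collocation(30, 0, 100, seed = 5)
  ob <- pinnode:::pinn_objective(m$weights, m$ode_params, m$spec, case$system,
                                 obs$times, t(obs$values), 0, 1.0, tc$times,
                                 need_grad = FALSE)
  expect_equal(ob$parts$data_loss, data_loss(m, obs), tolerance = 1e-12)
  expect_equal(ob$parts$ic_loss, ic_loss(m, 0, 1.0), tolerance = 1e-12)
  expect_equal(ob$parts$physics_loss, physics_loss(m, case$system, tc),
               tolerance = 1e-12)
})

test_that("hand-derived gradients match finite differences of the objective", {
  case <- make_case_study("logistic")
  spec <- network_spec(2, 8, 1, output_transform = scale_transform(100),
                       t_scale = 100)
  m <- pinn_model(spec, list(r = 0.8, K = 60), trainable = c("r", "K"),
                  seed = 3, zero_output_init = FALSE)
  t_obs <- seq(0, 100, length.out = 7)
  y_obs <- t(matrix(logistic_analytic(t_obs, logistic_true), ncol = 1))
  t_col <- seq(1, 99, length.out = 9)
  obj <- pinnode:::pinn_objective(m$weights, m$ode_params, spec, case$system,
                                  t_obs, y_obs, 0, 1.0, t_col,
                                  trainable = c("r", "K"))
  f0 <- function(w, th)
    pinnode:::pinn_objective(w, th, spec, case$system, t_obs, y_obs, 0, 1.0,
                             t_col, need_grad = FALSE)$parts$total
  h <- 1e-6
  set.seed(42)
  for (l in seq_along(m$weights)) {
    for (k in sample(length(m$weights[[l]]$W), 3)) {
      up <- m$weights; up[[l]]$W[k] <- up[[l]]$W[k] + h
      dn <- m$weights; dn[[l]]$W[k] <- dn[[l]]$W[k] - h
      num <- (f0(up, m$ode_params) - f0(dn, m$ode_params)) / (2 * h)
      # central differences on a loss of magnitude ~1e3 carry ~1e-6 absolute
      # cancellation noise; 1e-3 relative still pins the analytic gradient
      expect_equal(obj$grads[[l]]$W[k], num, tolerance = 1e-3)
    }
  }
  for (nm in c("r", "K")) {
    up <- m$ode_params; up[[nm]] <- up[[nm]] + h
    dn <- m$ode_params; dn[[nm]] <- dn[[nm]] - h
    num <- (f0(m$weights, up) - f0(m$weights, dn)) / (2 * h)
    expect_equal(unname(obj$g_theta[[nm]]), num,
                 tolerance = 1e-4 * max(1, abs(num)))
  }
})
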