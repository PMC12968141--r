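test_that("training config validates its fields", {
  expect_error(training_config(iterations = 0), "positive")
  expect_error(training_config(learning_rate = 0), "positive")
  expect_error(training_config(optimizer = "sgd"), "adam")
  expect_error(training_config(loss_weights = c(1, 1)), "three")
})

test_that("a one-iteration run logs exactly one row", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 5)
  cfg <- training_config(iterations = 1, log_every = 100, seed = 1)
  h <- train_pinn(pinn_model(case_network_spec(case), case$params, seed = 1),
                  case$system, obs, sample_collocation(10, 0, 100, seed = 1),
                  cfg, ic = 1.0)
  expect_identical(h$iterations, 1L)
  expect_length(h$total, 1)
  expect_identical(h$best_iteration, 1L)
})

test_that("training is bit-reproducible under a fixed seed", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 10, sigma = 1, seed = 2)
  cfg <- training_config(iterations = 300, log_every = 50, seed = 7)
  run <- function() {
    m <- pinn_model(case_network_spec(case), list(r = 1, K = 50),
                    trainable = c("r", "K"), seed = 7)
    train_pinn(m, case$system, obs, sample_collocation(40, 0, 100, seed = 7),
               cfg, ic = 1.0)
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1$parameter_traces, h2$parameter_traces)
  expect_identical(h1$total, h2$total)
  expect_identical(h1$model$weights, h2$model$weights)
})

test_that("every logged total equals the sum of its logged components", {
  case <- make_case_study("gene")
  obs <- generate_observations(case$system, case$params,
                               case_obs_times(case, 30), ic = case$ic,
                               noise_sigma = 0, seed = 1)
  cfg <- training_config(iterations = 250, log_every = 40, seed = 1)
  m <- pinn_model(case_network_spec(case), list(k_on = 0.05, k_off = 0.05),
                  trainable = c("k_on", "k_off"), seed = 1)
  h <- train_pinn(m, case$system, obs,
                  sample_collocation(30, 0, 100, seed = 1), cfg, ic = case$ic)
  expect_equal(h$total, h$data_loss + h$ic_loss + h$physics_loss,
               tolerance = 1e-12)
  expect_identical(h$iterations[length(h$iterations)], 250L)
})

test_that("the best logged step never exceeds the first, and is retained", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 25)
  cfg <- training_config(iterations = 500, log_every = 50, seed = 1)
  m <- pinn_model(case_network_spec(case), case$params, seed = 1)
  h <- train_pinn(m, case$system, obs,
                  sample_collocation(50, 0, 100, seed = 1), cfg, ic = 1.0)
  expect_lte(h$total[h$best_iteration], h$total[1])
  expect_lte(h$total[h$best_iteration], min(h$total))
  expect_equal(h$total[h$best_iteration], min(h$total))
})

test_that("compiled and reference training loops agree", {
  builtin <- logistic_system()
  clone <- logistic_clone_system()   # same maths, routed through the R loop
  obs <- small_logistic_obs(n = 9, sigma = 0, seed = 2)
  cfg <- training_config(iterations = 50, log_every = 10, seed = 2)
  spec <- network_spec(2, 6, 1, output_transform = scale_transform(100),
                       t_scale = 100)
  m <- pinn_model(spec, list(r = 0.8, K = 70), trainable = c("r", "K"),
                  seed = 5)
  colloc <- sample_collocation(20, 0, 100, seed = 2)
  h_cpp <- train_pinn(m, builtin, obs, colloc, cfg, ic = 1.0)
  h_r <- train_pinn(m, clone, obs, colloc, cfg, ic = 1.0)
  expect_equal(h_cpp$total, h_r$total, tolerance = 1e-8)
  expect_equal(h_cpp$parameter_traces, h_r$parameter_traces,
               tolerance = 1e-8)
  expect_identical(h_cpp$best_iteration, h_r$best_iteration)
})

test_that("convergence diagnosis follows the trailing-window contract", {
  mk <- function(totals) {
    structure(list(iterations = seq_along(totals), total = totals),
              class = "train_history")
  }
  expect_true(has_converged(mk(rep(1, 30)), window = 10, tol = 1e-3))
  expect_false(has_converged(mk(2^-(1:30)), window = 10, tol = 1e-3))
  # relative change exactly equal to tol is not convergence (strict <)
  tot <- rep(1, 20); tot[20] <- 1 - 1e-3
  expect_false(has_converged(mk(tot), window = 10, tol = 1e-3))
  expect_warning(flag <- has_converged(mk(rep(1, 3)), window = 10), "fewer")
  expect_false(flag)
  expect_error(has_converged(mk(numeric(0))), "empty")
})

test_that("checkpoints restore the exact model state", {
  case <- make_case_study("logistic")
  m <- pinn_model(case_network_spec(case), list(r = 0.7, K = 80),
                  trainable = c("r", "K"), seed = 3, zero_output_init = FALSE)
  path <- withr::local_tempfile(fileext = ".ckpt")
  checkpoint_model(m, path)

  blank <- pinn_model(case_network_spec(case), list(r = 1, K = 1),
                      trainable = c("r", "K"), seed = 99)
  back <- restore_model(blank, path)
  tt <- seq(0, 100, length.out = 31)
  expect_identical(pinn_predict(back, tt), pinn_predict(m, tt))
  expect_identical(back$ode_params, m$ode_params)

  other <- pinn_model(network_spec(2, 10, 1), seed = 1)
  expect_error(restore_model(other, path), "neurons|hidden_layers")
})

test_that("training checkpoints are written at the configured cadence", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 6)
  path <- withr::local_tempfile(fileext = ".ckpt")
  cfg <- training_config(iterations = 120, log_every = 30,
                         checkpoint_every = 50, seed = 1)
  m <- pinn_model(case_network_spec(case), case$params, seed = 1)
  h <- train_pinn(m, case$system, obs,
                  sample_collocation(15, 0, 100, seed = 1), cfg, ic = 1.0,
                  checkpoint_path = path)
  expect_true(file.exists(path))
  restored <- restore_model(m, path)
  # the checkpoint is a mid-run snapshot: same architecture, trained weights
  expect_identical(restored$spec$neurons, m$spec$neurons)
  expect_false(identical(restored$weights, m$weights))
})

test_that("histories export to CSV with aligned traces", {
  case <- make_case_study("logistic")
  obs <- small_logistic_obs(n = 8)
  cfg <- training_config(iterations = 90, log_every = 30, seed = 1)
  m <- pinn_model(case_network_spec(case), list(r = 1, K = 50),
                  trainable = c("r", "K"), seed = 1)
  h <- train_pinn(m, case$system, obs,
                  sample_collocation(12, 0, 100, seed = 1), cfg, ic = 1.0)
  stem <- file.path(withr::local_tempdir(), "run")
  files <- write_history(h, stem)
  hist <- utils::read.csv(paste0(stem, "_history.csv"))
  expect_identical(names(hist),
                   c("iteration", "data_loss", "ic_loss", "physics_loss",
                     "total"))
  traces <- utils::read.csv(paste0(stem, "_traces.csv"))
  expect_identical(names(traces), c("iteration", "r", "K"))
  expect_identical(nrow(hist), nrow(traces))
  df <- as.data.frame(h)
  expect_identical(df$iteration, hist$iteration)
})
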