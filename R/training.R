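#' Training configuration
#'
#' @param optimizer Optimizer name; \code{"adam"} is the supported choice
#'   (the robust default for PINN training).
#' @param learning_rate Step size, default 0.001.
#' @param iterations Number of full-batch optimization steps (positive).
#' @param log_every Logging period in iterations; the final iteration is
#'   always logged.
#' @param checkpoint_every Checkpoint period when \code{checkpoint_path} is
#'   given to \code{train_pinn}.
#' @param seed Integer seed fixed at the start of training.
#' @param loss_weights Length-3 nonnegative weights for (data, IC, physics);
#'   equal weighting by default.
#' @return Object of class \code{training_config}.
#' @export
training_config <- function(optimizer = "adam", learning_rate = 1e-3,
                            iterations = 10000L, log_every = 100L,
                            checkpoint_every = 1000L, seed = 1L,
                            loss_weights = c(1, 1, 1)) {
  if (!identical(optimizer, "adam")) stop("only the 'adam' optimizer is supported")
  if (iterations < 1L) stop("iterations must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (length(loss_weights) != 3L || any(loss_weights < 0))
    stop("loss_weights must be three nonnegative numbers")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 log_every = as.integer(log_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed),
                 loss_weights = as.numeric(loss_weights)),
            class = "training_config")
}

#' Train a PINN
#'
#' Runs full-batch Adam on the combined loss, jointly updating the network
#' weights and any ODE parameters flagged trainable in the model. Every
#' \code{log_every} iterations (and at the last one) the loss components and
#' the current ODE parameter values are recorded; the logged step with the
#' lowest total loss is remembered together with its weights.
#'
#' @param model A \code{pinn_model}.
#' @param system The \code{ode_system} whose residual is enforced (may be
#'   \code{NULL} when \code{colloc} is \code{NULL}, i.e. pure regression).
#' @param obs An \code{observation_set} or \code{NULL} (no data term).
#' @param colloc A \code{collocation_set} or \code{NULL} (no physics term).
#' @param config A \code{training_config}.
#' @param ic Initial state vector enforced at \code{t0}, or \code{NULL} for no
#'   IC term.
#' @param t0 Initial time, default 0.
#' @param checkpoint_path Optional file path; the model state is saved there
#'   every \code{checkpoint_every} iterations.
#' @return A \code{train_history}: \code{iterations} (logged step numbers),
#'   \code{data_loss}/\code{ic_loss}/\code{physics_loss}/\code{total}
#'   vectors, \code{parameter_traces} (matrix, one column per trainable
#'   parameter), \code{best_iteration} (index into the logged rows),
#'   \code{best_model}, and \code{model} (final state).
#' @export
train_pinn <- function(model, system, obs = NULL, colloc = NULL,
                       config = training_config(), ic = NULL, t0 = 0,
                       checkpoint_path = NULL) {
  stopifnot(inherits(model, "pinn_model"), inherits(config, "training_config"))
  if (is.null(obs) && is.null(colloc) && is.null(ic))
    stop("nothing to train on: provide observations, collocation points or an IC")
  if (!is.null(colloc) && is.null(system))
    stop("a physics term needs an ode_system")
  set.seed(config$seed)

  t_obs <- if (!is.null(obs)) obs$times else numeric(0)
  y_obs <- if (!is.null(obs)) t(obs$values) else NULL
  t_colloc <- if (!is.null(colloc)) {
    if (inherits(colloc, "collocation_set")) colloc$times else as.numeric(colloc)
  } else numeric(0)
  trainable <- model$trainable

  compiled <- is.null(system) || system$name %in% c("logistic", "gene_binding")
  loop <- if (compiled) train_loop_cpp else train_loop_r
  state <- loop(model, system, t_obs, y_obs, t0, ic, t_colloc, config,
                checkpoint_path)

  final <- model
  final$weights <- state$weights
  final$ode_params <- state$theta
  best <- model
  best$weights <- state$best_weights
  best$ode_params <- state$best_theta
  structure(list(iterations = state$log_it,
                 data_loss = state$log_loss[, 1L],
                 ic_loss = state$log_loss[, 2L],
                 physics_loss = state$log_loss[, 3L],
                 total = state$log_loss[, 4L],
                 parameter_traces = state$log_theta,
                 best_iteration = state$best_row,
                 best_model = best,
                 model = final,
                 config = config),
            class = "train_history")
}

## Compiled full-batch Adam loop for the built-in systems (and pure
## regression). Run in chunks so checkpoints can be written from R.
train_loop_cpp <- function(model, system, t_obs, y_obs, t0, ic, t_colloc,
                           config, checkpoint_path) {
  spec <- model$spec
  trainable <- model$trainable
  if (is.null(system)) {
    schema <- character(0)
    system_id <- "none"
  } else {
    schema <- system$param_schema$name
    system_id <- system$name
    if (!all(schema %in% names(model$ode_params)))
      stop("model is missing ODE parameter(s): ",
           paste(setdiff(schema, names(model$ode_params)), collapse = ", "))
  }
  theta <- as.numeric(unlist(model$ode_params[schema]))
  theta_log <- param_log_flags(system, schema)
  tidx <- match(trainable, schema)
  tr <- spec$output_transform
  ttype <- match(tr$type, c("identity", "scale", "softplus")) - 1L
  out_scale <- if (is.null(tr$scale)) 1 else tr$scale

  m_d <- length(t_obs); m_i <- as.integer(!is.null(ic)); m_c <- length(t_colloc)
  t_all <- c(t_obs, if (m_i) t0, t_colloc)
  y_mat <- if (m_d) y_obs else matrix(0, 1, 0)
  ic_vec <- if (m_i) as.numeric(ic) else numeric(0)

  chunk <- if (!is.null(checkpoint_path))
    min(config$checkpoint_every, config$iterations) else config$iterations
  weights <- model$weights
  adam <- list()
  offset <- 0L
  logs <- list()
  best_total <- Inf
  best_weights <- weights; best_theta <- theta; best_row <- NA_integer_
  rows_so_far <- 0L
  while (offset < config$iterations) {
    n_it <- min(chunk, config$iterations - offset)
    res <- .cpp_train_chunk(weights, theta, as.integer(tidx), system_id,
                            t_all, m_d, m_i, m_c, y_mat, ic_vec,
                            config$loss_weights, spec$t_scale, ttype,
                            out_scale, n_it, offset, config$iterations,
                            config$learning_rate, config$log_every,
                            as.integer(theta_log), adam)
    res$weights <- normalize_weights(res$weights)
    res$best_weights <- normalize_weights(res$best_weights)
    weights <- res$weights
    theta <- as.numeric(res$theta)
    adam <- res$adam
    logs[[length(logs) + 1L]] <- res$log
    if (res$n_logged > 0L && res$best_total < best_total) {
      best_total <- res$best_total
      best_row <- rows_so_far + res$best_row
      best_weights <- res$best_weights
      best_theta <- as.numeric(res$best_theta)
    }
    rows_so_far <- rows_so_far + res$n_logged
    offset <- offset + n_it
    if (!is.null(checkpoint_path) && offset %% config$checkpoint_every == 0L) {
      snap <- model
      snap$weights <- weights
      snap$ode_params <- theta_as_list(model$ode_params, schema, theta)
      checkpoint_model(snap, checkpoint_path)
    }
  }
  log_mat <- do.call(rbind, logs)
  list(weights = weights,
       theta = theta_as_list(model$ode_params, schema, theta),
       log_it = as.integer(log_mat[, 1L]),
       log_loss = log_mat[, 2:5, drop = FALSE],
       log_theta = named_trace(log_mat, trainable, schema),
       best_row = best_row,
       best_weights = best_weights,
       best_theta = theta_as_list(model$ode_params, schema, best_theta))
}

## Positive-flagged parameters are optimized in log space (multiplicative
## Adam steps): scale-free for rate and capacity parameters and positive by
## construction.
param_log_flags <- function(system, schema) {
  if (!length(schema)) return(logical(0))
  system$param_schema$positive[match(schema, system$param_schema$name)]
}

## biases come back from the compiled chunk as n x 1 matrices; flatten them
normalize_weights <- function(weights) {
  lapply(weights, function(l) list(W = l$W, b = as.numeric(l$b)))
}

theta_as_list <- function(ode_params, schema, theta) {
  out <- ode_params
  for (i in seq_along(schema)) out[[schema[i]]] <- theta[i]
  out
}

named_trace <- function(log_mat, trainable, schema) {
  tm <- log_mat[, -(1:5), drop = FALSE]   # logged in `trainable` order
  colnames(tm) <- trainable
  tm
}

## Reference (plain R) loop; used for user-defined systems and as the
## cross-check for the compiled path.
train_loop_r <- function(model, system, t_obs, y_obs, t0, ic, t_colloc,
                         config, checkpoint_path) {
  trainable <- model$trainable
  spec <- model$spec
  weights <- model$weights
  theta <- model$ode_params
  in_log <- if (!is.null(system) && length(trainable)) {
    stats::setNames(param_log_flags(system, trainable), trainable)
  } else stats::setNames(rep(FALSE, length(trainable)), trainable)

  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  vW <- mW
  mT <- vT <- stats::setNames(numeric(length(trainable)), trainable)

  n_log <- config$iterations %/% max(config$log_every, 1L) + 1L
  log_it <- integer(n_log)
  log_loss <- matrix(NA_real_, n_log, 4L)
  log_theta <- matrix(NA_real_, n_log, length(trainable),
                      dimnames = list(NULL, trainable))
  row <- 0L
  best_total <- Inf; best_row <- NA_integer_
  best_weights <- weights; best_theta <- theta

  for (it in seq_len(config$iterations)) {
    ob <- pinn_objective(weights, theta, spec, system,
                         t_obs, y_obs, t0, ic, t_colloc,
                         loss_weights = config$loss_weights,
                         trainable = trainable, need_grad = TRUE)
    parts <- ob$parts
    if (!is.finite(parts$total)) {
      bad <- c("data", "ic", "physics")[!is.finite(c(parts$data_loss,
                                                     parts$ic_loss,
                                                     parts$physics_loss))]
      stop("non-finite loss at iteration ", it, " (component: ",
           paste(if (length(bad)) bad else "total", collapse = ", "), ")")
    }
    ## Adam update (bias-corrected)
    bc1 <- 1 - beta1^it; bc2 <- 1 - beta2^it
    for (l in seq_along(weights)) {
      g <- ob$grads[[l]]
      mW[[l]]$W <- beta1 * mW[[l]]$W + (1 - beta1) * g$W
      mW[[l]]$b <- beta1 * mW[[l]]$b + (1 - beta1) * g$b
      vW[[l]]$W <- beta2 * vW[[l]]$W + (1 - beta2) * g$W^2
      vW[[l]]$b <- beta2 * vW[[l]]$b + (1 - beta2) * g$b^2
      weights[[l]]$W <- weights[[l]]$W -
        lr * (mW[[l]]$W / bc1) / (sqrt(vW[[l]]$W / bc2) + eps)
      weights[[l]]$b <- weights[[l]]$b -
        lr * (mW[[l]]$b / bc1) / (sqrt(vW[[l]]$b / bc2) + eps)
    }
    if (length(trainable)) {
      g <- ob$g_theta[trainable]
      g[in_log] <- g[in_log] * unlist(theta[trainable])[in_log]  # d/d(log theta)
      mT <- beta1 * mT + (1 - beta1) * g
      vT <- beta2 * vT + (1 - beta2) * g^2
      step <- lr * (mT / bc1) / (sqrt(vT / bc2) + eps)
      for (nm in trainable) {
        theta[[nm]] <- if (in_log[[nm]]) theta[[nm]] * exp(-step[[nm]])
                       else theta[[nm]] - step[[nm]]
      }
    }

    if (it %% config$log_every == 0L || it == config$iterations) {
      row <- row + 1L
      log_it[row] <- it
      log_loss[row, ] <- c(parts$data_loss, parts$ic_loss,
                           parts$physics_loss, parts$total)
      if (length(trainable)) log_theta[row, ] <- unlist(theta[trainable])
      if (parts$total < best_total) {
        best_total <- parts$total
        best_row <- row
        best_weights <- weights
        best_theta <- theta
      }
    }
    if (!is.null(checkpoint_path) && it %% config$checkpoint_every == 0L) {
      snap <- model; snap$weights <- weights; snap$ode_params <- theta
      checkpoint_model(snap, checkpoint_path)
    }
  }
  list(weights = weights, theta = theta,
       log_it = log_it[seq_len(row)],
       log_loss = log_loss[seq_len(row), , drop = FALSE],
       log_theta = log_theta[seq_len(row), , drop = FALSE],
       best_row = best_row,
       best_weights = best_weights, best_theta = best_theta)
}

#' @export
print.train_history <- function(x, ...) {
  n <- length(x$iterations)
  cat("<train_history> ", n, " logged steps up to iteration ",
      x$iterations[n], "; final total loss ",
      format(x$total[n], digits = 6), "\n", sep = "")
  if (ncol(x$parameter_traces))
    cat("  final parameter estimates: ",
        paste(sprintf("%s=%.6g", colnames(x$parameter_traces),
                      x$parameter_traces[n, ]), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
as.data.frame.train_history <- function(x, ...) {
  df <- data.frame(iteration = x$iterations, data_loss = x$data_loss,
                   ic_loss = x$ic_loss, physics_loss = x$physics_loss,
                   total = x$total)
  if (ncol(x$parameter_traces)) df <- cbind(df, x$parameter_traces)
  df
}

#' Diagnose convergence of a training run
#'
#' Smooths the logged total loss with a short moving average and reports
#' whether its relative change across the trailing \code{window} logged steps
#' is strictly below \code{tol}. This mirrors monitoring for a monotone,
#' flattening loss; it is diagnostic only and never stops training.
#'
#' @param history A \code{train_history}.
#' @param window Number of trailing logged steps to examine.
#' @param tol Relative-change tolerance (strict inequality).
#' @return Logical flag; \code{FALSE} with a warning when the history is
#'   shorter than \code{window}.
#' @export
has_converged <- function(history, window = 10L, tol = 1e-3) {
  stopifnot(inherits(history, "train_history"))
  tot <- history$total
  if (length(tot) == 0L) stop("empty training history")
  if (window > length(tot)) {
    warning("history has ", length(tot), " logged steps, fewer than window = ",
            window)
    return(FALSE)
  }
  sm <- as.numeric(stats::filter(tot, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- tot[is.na(sm)]   # keep raw values at the ends
  tail_sm <- sm[(length(sm) - window + 1L):length(sm)]
  rel <- abs(tail_sm[1L] - tail_sm[window]) /
    max(abs(tail_sm[1L]), .Machine$double.eps)
  rel < tol
}

#' Checkpoint and restore a model
#'
#' \code{checkpoint_model} saves the full model state (architecture spec,
#' weights, ODE parameter values and trainable flags) in a versioned
#' container; \code{restore_model} loads it back into a model with an
#' identical architecture, erroring on any spec mismatch.
#'
#' @param model A \code{pinn_model} (for \code{restore_model}: the model whose
#'   architecture the checkpoint must match).
#' @param path File path.
#' @return \code{checkpoint_model}: \code{path}, invisibly.
#'   \code{restore_model}: the restored \code{pinn_model}.
#' @export
checkpoint_model <- function(model, path) {
  stopifnot(inherits(model, "pinn_model"))
  payload <- list(format = "pinnode-checkpoint", version = 1L,
                  spec = checkpoint_spec(model$spec),
                  weights = model$weights,
                  ode_params = model$ode_params,
                  trainable = model$trainable,
                  seed = model$seed)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname checkpoint_model
#' @export
restore_model <- function(model, path) {
  stopifnot(inherits(model, "pinn_model"))
  payload <- readRDS(path)
  if (!identical(payload$format, "pinnode-checkpoint"))
    stop("not a pinnode checkpoint: ", path)
  want <- checkpoint_spec(model$spec)
  have <- payload$spec
  for (fld in names(want)) {
    if (!identical(want[[fld]], have[[fld]]))
      stop("checkpoint spec mismatch in field '", fld, "': model has ",
           deparse(want[[fld]]), ", checkpoint has ", deparse(have[[fld]]))
  }
  model$weights <- payload$weights
  model$ode_params <- payload$ode_params
  model$trainable <- payload$trainable
  model
}

## comparable summary of a network_spec (functions stripped)
checkpoint_spec <- function(spec) {
  list(hidden_layers = spec$hidden_layers, neurons = spec$neurons,
       output_dim = spec$output_dim, activation = spec$activation,
       transform = spec$output_transform$type,
       transform_scale = spec$output_transform$scale,
       t_scale = spec$t_scale)
}

#' Write a training history to CSV files
#'
#' Loss history goes to \code{<stem>_history.csv}
#' (\code{iteration,data_loss,ic_loss,physics_loss,total}); parameter traces,
#' when present, to \code{<stem>_traces.csv} (\code{iteration,<param>...}).
#'
#' @param history A \code{train_history}.
#' @param stem Path stem (without extension).
#' @return Character vector of files written, invisibly.
#' @export
write_history <- function(history, stem) {
  files <- paste0(stem, "_history.csv")
  utils::write.csv(data.frame(iteration = history$iterations,
                              data_loss = history$data_loss,
                              ic_loss = history$ic_loss,
                              physics_loss = history$physics_loss,
                              total = history$total),
                   files, row.names = FALSE)
  if (ncol(history$parameter_traces)) {
    f2 <- paste0(stem, "_traces.csv")
    utils::write.csv(data.frame(iteration = history$iterations,
                                history$parameter_traces),
                     f2, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}
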