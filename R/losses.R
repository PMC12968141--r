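#' Loss components of PINN training
#'
#' The training objective combines three mean-squared terms with equal
#' weights by default: the data loss (predictions vs observations), the
#' initial-condition loss (prediction at \code{t0} vs the prescribed initial
#' state), and the physics loss (squared residual of the governing ODE at the
#' collocation points, using the network's exact time derivative).
#'
#' @param model A \code{pinn_model}.
#' @param obs An \code{observation_set}.
#' @return Nonnegative scalar.
#' @export
data_loss <- function(model, obs) {
  stopifnot(inherits(obs, "observation_set"))
  if (length(obs$times) == 0L) stop("observation set is empty")
  pred <- pinn_predict(model, obs$times)
  if (!all(dim(pred) == dim(obs$values)))
    stop("prediction dimension ", paste(dim(pred), collapse = "x"),
         " does not match observations ",
         paste(dim(obs$values), collapse = "x"))
  mean((pred - obs$values)^2)
}

#' @rdname data_loss
#' @param t0 Initial time.
#' @param ic Initial state vector, length \code{output_dim}.
#' @export
ic_loss <- function(model, t0, ic) {
  pred <- as.numeric(pinn_predict(model, t0))
  if (length(pred) != length(ic))
    stop("initial condition has length ", length(ic),
         " but the model outputs ", length(pred), " states")
  mean((pred - ic)^2)
}

#' @rdname data_loss
#' @param system An \code{ode_system}.
#' @param params Named list of ODE parameter values; defaults to the model's
#'   own (possibly trainable) parameters.
#' @param colloc A \code{collocation_set} (non-empty).
#' @export
physics_loss <- function(model, system, colloc, params = model$ode_params) {
  stopifnot(inherits(system, "ode_system"))
  tc <- if (inherits(colloc, "collocation_set")) colloc$times else as.numeric(colloc)
  if (length(tc) == 0L)
    stop("collocation set is empty: the physics residual cannot be enforced")
  fw <- mlp_forward(model$weights, model$spec, tc, tangent = TRUE)
  f <- eval_rhs(system, fw$U, tc, as.list(params))
  mean((fw$Udot - f)^2)
}

#' @rdname data_loss
#' @param parts A \code{loss_breakdown} (or list with \code{data_loss},
#'   \code{ic_loss}, \code{physics_loss}).
#' @param weights Nonnegative length-3 weights \code{(data, ic, physics)};
#'   all ones by default.
#' @export
total_loss <- function(parts, weights = c(1, 1, 1)) {
  if (length(weights) != 3L || any(weights < 0))
    stop("weights must be three nonnegative numbers (data, ic, physics)")
  comp <- c(parts$data_loss, parts$ic_loss, parts$physics_loss)
  if (any(!is.finite(comp))) stop("loss components must be finite")
  sum(weights * comp)
}

#' Loss breakdown container
#'
#' @param data_loss,ic_loss,physics_loss Component values (nonnegative).
#' @param weights Length-3 weights used to combine them.
#' @return Object of class \code{loss_breakdown} with the components and
#'   their weighted \code{total}.
#' @export
loss_breakdown <- function(data_loss, ic_loss, physics_loss,
                           weights = c(1, 1, 1)) {
  parts <- list(data_loss = data_loss, ic_loss = ic_loss,
                physics_loss = physics_loss)
  parts$total <- total_loss(parts, weights)
  parts$weights <- weights
  structure(parts, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.6g = data %.6g + ic %.6g + physics %.6g (weights %s)\n",
              x$total, x$data_loss, x$ic_loss, x$physics_loss,
              paste(x$weights, collapse = "/")))
  invisible(x)
}

## ---- internal: vectorized rhs and its adjoints -----------------------------

## rhs on a dim x m state matrix; falls back to column-wise application when
## the system's rhs is not vectorized.
eval_rhs <- function(system, states, t, params) {
  if (system$vectorized) {
    out <- system$rhs(states, t, params)
    matrix(out, nrow = nrow(states))
  } else {
    vapply(seq_along(t),
           function(j) as.numeric(system$rhs(states[, j], t[j], params)),
           numeric(nrow(states)))
  }
}

## J^T R columnwise (J = state Jacobian of rhs); central differences when the
## system provides no analytic vjp.
eval_vjp <- function(system, states, t, params, R) {
  if (!is.null(system$vjp)) return(system$vjp(states, t, params, R))
  D <- nrow(states)
  out <- matrix(0, D, ncol(states))
  h <- 1e-6 * pmax(abs(states), 1)   # first arg keeps the matrix shape
  for (j in seq_len(D)) {
    up <- states; up[j, ] <- up[j, ] + h[j, ]
    dn <- states; dn[j, ] <- dn[j, ] - h[j, ]
    Jcol <- (eval_rhs(system, up, t, params) -
               eval_rhs(system, dn, t, params)) / (2 * h[rep(j, D), , drop = FALSE])
    out[j, ] <- colSums(R * Jcol)
  }
  out
}

## sum over collocation entries of R * df/dtheta_j for each requested name.
eval_param_grad <- function(system, states, t, params, R, names) {
  if (!is.null(system$param_grad))
    return(system$param_grad(states, t, params, R, names))
  g <- numeric(length(names)); names(g) <- names
  for (nm in names) {
    h <- 1e-6 * max(1, abs(params[[nm]]))
    up <- params; up[[nm]] <- up[[nm]] + h
    dn <- params; dn[[nm]] <- dn[[nm]] - h
    df <- (eval_rhs(system, states, t, up) -
             eval_rhs(system, states, t, dn)) / (2 * h)
    g[nm] <- sum(R * df)
  }
  g
}

## ---- internal: fused objective + gradient ----------------------------------

## One pass computing all loss components and (optionally) the gradient with
## respect to every network weight and the trainable ODE parameters. The
## batch is the concatenation [obs times | t0 | collocation times]; the
## tangent pass runs only when a physics term is present.
pinn_objective <- function(weights, ode_params, spec, system,
                           t_obs, y_obs, t0, ic, t_colloc,
                           loss_weights = c(1, 1, 1), trainable = character(),
                           need_grad = TRUE) {
  m_d <- length(t_obs)
  m_i <- as.integer(!is.null(ic))
  m_c <- length(t_colloc)
  D <- spec$output_dim
  t_all <- c(t_obs, if (m_i) t0, t_colloc)
  tangent <- m_c > 0L
  fw <- mlp_forward(weights, spec, t_all, tangent = tangent)
  U <- fw$U

  L_data <- L_ic <- L_phys <- 0
  Ubar <- if (need_grad) matrix(0, D, length(t_all))
  Udotbar <- if (need_grad && tangent) matrix(0, D, length(t_all))

  if (m_d > 0L) {
    idx <- seq_len(m_d)
    Rd <- U[, idx, drop = FALSE] - y_obs
    L_data <- mean(Rd^2)
    if (need_grad)
      Ubar[, idx] <- loss_weights[1L] * 2 * Rd / (m_d * D)
  }
  if (m_i) {
    j <- m_d + 1L
    Ri <- U[, j] - ic
    L_ic <- mean(Ri^2)
    if (need_grad)
      Ubar[, j] <- Ubar[, j] + loss_weights[2L] * 2 * Ri / D
  }
  g_theta <- NULL
  if (m_c > 0L) {
    cidx <- (m_d + m_i + 1L):length(t_all)
    Uc <- U[, cidx, drop = FALSE]
    f <- eval_rhs(system, Uc, t_colloc, ode_params)
    Rc <- fw$Udot[, cidx, drop = FALSE] - f
    L_phys <- mean(Rc^2)
    if (need_grad) {
      scale <- loss_weights[3L] * 2 / (m_c * D)
      Udotbar[, cidx] <- scale * Rc
      Ubar[, cidx] <- Ubar[, cidx] -
        scale * eval_vjp(system, Uc, t_colloc, ode_params, Rc)
      if (length(trainable))
        g_theta <- -scale *
          eval_param_grad(system, Uc, t_colloc, ode_params, Rc, trainable)
    }
  }

  parts <- loss_breakdown(L_data, L_ic, L_phys, loss_weights)
  if (!need_grad) return(list(parts = parts))
  grads <- mlp_backward(weights, spec, fw, Ubar, Udotbar)
  if (length(trainable) && is.null(g_theta)) {
    g_theta <- numeric(length(trainable)); names(g_theta) <- trainable
  }
  list(parts = parts, grads = grads, g_theta = g_theta)
}
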