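#' Fully connected network architecture for a PINN
#'
#' Describes a feedforward network with a single time input, tanh hidden
#' layers and a linear output layer, optionally followed by an output
#' transform. Only smooth activations are admissible because the physics loss
#' differentiates the network with respect to its input; tanh is the one
#' supported here (it is also the standard choice for PINNs).
#'
#' @param hidden_layers Number of hidden layers (positive).
#' @param neurons Neurons per hidden layer (positive).
#' @param output_dim State dimension of the ODE system being approximated.
#' @param activation Activation name; only \code{"tanh"} is supported.
#' @param output_transform An \code{output_transform()} object; identity by
#'   default.
#' @param t_scale Input scaling constant: the network sees \code{t / t_scale}.
#'   Set it to the domain length (e.g. 100) so the tanh layers operate in
#'   their responsive range; all derivatives account for it via the chain
#'   rule.
#' @return Object of class \code{network_spec}.
#' @export
network_spec <- function(hidden_layers = 3L, neurons = 50L, output_dim = 1L,
                         activation = "tanh",
                         output_transform = identity_transform(),
                         t_scale = 1) {
  if (hidden_layers < 1L || neurons < 1L || output_dim < 1L)
    stop("hidden_layers, neurons and output_dim must be positive")
  if (!identical(activation, "tanh"))
    stop("only the smooth 'tanh' activation is supported; got '",
         activation, "'")
  if (!inherits(output_transform, "output_transform"))
    stop("output_transform must be created with identity_transform(), ",
         "scale_transform() or softplus_transform()")
  if (!is.finite(t_scale) || t_scale <= 0) stop("t_scale must be positive")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 neurons = as.integer(neurons),
                 output_dim = as.integer(output_dim),
                 activation = activation,
                 output_transform = output_transform,
                 t_scale = t_scale),
            class = "network_spec")
}

#' Output transforms
#'
#' Smooth elementwise maps applied to the raw network output: the identity, a
#' constant rescaling (useful to put the output on the natural scale of the
#' state, e.g. the carrying capacity for logistic growth), and softplus for
#' strictly nonnegative outputs such as concentrations. Each transform
#' carries its first two derivatives, which the physics loss and its
#' gradient need.
#'
#' @param scale Positive multiplier for \code{scale_transform}.
#' @return Object of class \code{output_transform} with fields \code{value},
#'   \code{d1}, \code{d2} (elementwise functions) and \code{type}.
#' @export
identity_transform <- function() {
  structure(list(type = "identity",
                 value = function(y) y,
                 d1 = function(y) array(1, dim = dim(y)),
                 d2 = function(y) array(0, dim = dim(y))),
            class = "output_transform")
}

#' @rdname identity_transform
#' @export
scale_transform <- function(scale) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  force(scale)
  structure(list(type = "scale", scale = scale,
                 value = function(y) scale * y,
                 d1 = function(y) array(scale, dim = dim(y)),
                 d2 = function(y) array(0, dim = dim(y))),
            class = "output_transform")
}

#' @rdname identity_transform
#' @export
softplus_transform <- function(scale = 1) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  force(scale)
  sp <- function(y) ifelse(y > 30, y, log1p(exp(pmin(y, 30))))
  sig <- function(y) 1 / (1 + exp(-y))
  structure(list(type = "softplus", scale = scale,
                 value = function(y) scale * sp(y),
                 d1 = function(y) scale * sig(y),
                 d2 = function(y) { s <- sig(y); scale * s * (1 - s) }),
            class = "output_transform")
}

#' Construct a PINN model
#'
#' Initializes network weights (Glorot-uniform, reproducible via \code{seed})
#' and binds the trainable ODE parameters. Parameters flagged trainable are
#' optimized jointly with the network weights; the rest stay fixed.
#'
#' @param spec A \code{network_spec}.
#' @param ode_params Named list/vector of initial ODE parameter values (may be
#'   empty for a pure forward surrogate).
#' @param trainable Character vector naming which of \code{ode_params} are
#'   trainable; default none.
#' @param seed Integer seed for the weight initialization.
#' @param zero_output_init Initialize the linear output layer at zero
#'   (default). The surrogate then starts at \code{transform(0)}, so the
#'   physics residual is inert at the start of training and the data and
#'   initial-condition terms shape the trajectory before the ODE term
#'   engages; hidden layers keep their Glorot draws.
#' @return Object of class \code{pinn_model} with fields \code{spec},
#'   \code{weights} (list of \code{W}, \code{b} per layer), \code{ode_params},
#'   \code{trainable}, \code{seed}.
#' @export
pinn_model <- function(spec, ode_params = list(), trainable = character(),
                       seed = 1L, zero_output_init = TRUE) {
  stopifnot(inherits(spec, "network_spec"))
  ode_params <- as.list(ode_params)
  if (length(trainable) && !all(trainable %in% names(ode_params)))
    stop("trainable names not among ode_params: ",
         paste(setdiff(trainable, names(ode_params)), collapse = ", "))
  sizes <- c(1L, rep(spec$neurons, spec$hidden_layers), spec$output_dim)
  weights <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_out * fan_in, -lim, lim),
                      nrow = fan_out),
           b = numeric(fan_out))
    })
  })
  if (zero_output_init) {
    L <- length(weights)
    weights[[L]]$W[] <- 0
    weights[[L]]$b[] <- 0
  }
  structure(list(spec = spec, weights = weights,
                 ode_params = ode_params,
                 trainable = as.character(trainable),
                 seed = as.integer(seed)),
            class = "pinn_model")
}

#' @export
print.pinn_model <- function(x, ...) {
  s <- x$spec
  cat("<pinn_model> 1 -> ", paste(rep(s$neurons, s$hidden_layers),
                                  collapse = " -> "),
      " -> ", s$output_dim, " (tanh, ", s$output_transform$type,
      " transform)\n", sep = "")
  if (length(x$ode_params))
    cat("  ODE parameters: ",
        paste(sprintf("%s=%.6g%s", names(x$ode_params),
                      unlist(x$ode_params),
                      ifelse(names(x$ode_params) %in% x$trainable, "*", "")),
              collapse = ", "), "  (* trainable)\n", sep = "")
  invisible(x)
}

## ---- forward / tangent pass ------------------------------------------------

## Runs the network on a time batch. Columns are batch entries. When
## `tangent` is TRUE the exact derivative with respect to t is propagated
## alongside the values (forward-mode differentiation seeded with
## dx0/dt = 1/t_scale). Returns all intermediates needed for backprop.
mlp_forward <- function(weights, spec, t, tangent = TRUE) {
  m <- length(t)
  L <- length(weights)           # hidden layers + output layer
  X <- vector("list", L + 1L)    # X[[1]] is the (scaled) input
  Xdot <- if (tangent) vector("list", L + 1L) else NULL
  X[[1L]] <- matrix(t / spec$t_scale, nrow = 1L)
  if (tangent) Xdot[[1L]] <- matrix(1 / spec$t_scale, nrow = 1L, ncol = m)
  for (l in seq_len(L - 1L)) {
    Z <- weights[[l]]$W %*% X[[l]] + weights[[l]]$b
    A <- tanh(Z)
    X[[l + 1L]] <- A
    if (tangent) Xdot[[l + 1L]] <- (1 - A * A) * (weights[[l]]$W %*% Xdot[[l]])
  }
  Y <- weights[[L]]$W %*% X[[L]] + weights[[L]]$b
  Ydot <- if (tangent) weights[[L]]$W %*% Xdot[[L]] else NULL
  tr <- spec$output_transform
  U <- tr$value(Y)
  Udot <- if (tangent) tr$d1(Y) * Ydot else NULL
  list(X = X, Xdot = Xdot, Y = Y, Ydot = Ydot, U = U, Udot = Udot)
}

## Reverse pass through the joint (value, tangent) computation. Ubar/Udotbar
## are the loss adjoints of U and Udot (dim x m, Udotbar may be NULL).
## Returns per-layer weight gradients.
mlp_backward <- function(weights, spec, fw, Ubar, Udotbar = NULL) {
  L <- length(weights)
  tr <- spec$output_transform
  tangent <- !is.null(Udotbar)
  d1 <- tr$d1(fw$Y)
  if (tangent) {
    Ybar <- d1 * Ubar + tr$d2(fw$Y) * fw$Ydot * Udotbar
    Ydotbar <- d1 * Udotbar
  } else {
    Ybar <- d1 * Ubar
    Ydotbar <- NULL
  }
  grads <- vector("list", L)
  ## output (linear) layer
  gW <- Ybar %*% t(fw$X[[L]])
  if (tangent) gW <- gW + Ydotbar %*% t(fw$Xdot[[L]])
  grads[[L]] <- list(W = gW, b = rowSums(Ybar))
  Abar <- crossprod(weights[[L]]$W, Ybar)
  Adotbar <- if (tangent) crossprod(weights[[L]]$W, Ydotbar) else NULL
  ## hidden layers, deepest first
  for (l in rev(seq_len(L - 1L))) {
    A <- fw$X[[l + 1L]]
    s <- 1 - A * A                      # tanh'
    if (tangent) {
      Zdot <- weights[[l]]$W %*% fw$Xdot[[l]]
      Zbar <- s * Abar + (-2 * A * s) * Zdot * Adotbar
      Zdotbar <- s * Adotbar
    } else {
      Zbar <- s * Abar
      Zdotbar <- NULL
    }
    gW <- Zbar %*% t(fw$X[[l]])
    if (tangent) gW <- gW + Zdotbar %*% t(fw$Xdot[[l]])
    grads[[l]] <- list(W = gW, b = rowSums(Zbar))
    if (l > 1L) {
      Abar <- crossprod(weights[[l]]$W, Zbar)
      Adotbar <- if (tangent) crossprod(weights[[l]]$W, Zdotbar) else NULL
    }
  }
  grads
}

#' Evaluate a PINN model
#'
#' @param model A \code{pinn_model}.
#' @param t Time vector.
#' @return \code{length(t) x output_dim} matrix of (transformed) predictions.
#' @export
pinn_predict <- function(model, t) {
  stopifnot(inherits(model, "pinn_model"))
  if (length(t) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = model$spec$output_dim))
  fw <- mlp_forward(model$weights, model$spec, as.numeric(t), tangent = FALSE)
  t(fw$U)
}

#' @export
predict.pinn_model <- function(object, t, ...) pinn_predict(object, t)

#' Exact time derivative of a PINN model
#'
#' Propagates the derivative with respect to the input through every layer
#' (forward-mode differentiation), so the result is exact up to floating
#' point, not a finite-difference estimate.
#'
#' @param model A \code{pinn_model}.
#' @param t Time vector.
#' @return \code{length(t) x output_dim} matrix of d(prediction)/dt.
#' @export
time_derivative <- function(model, t) {
  stopifnot(inherits(model, "pinn_model"))
  if (length(t) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = model$spec$output_dim))
  fw <- mlp_forward(model$weights, model$spec, as.numeric(t), tangent = TRUE)
  t(fw$Udot)
}
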