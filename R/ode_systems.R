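#' First-order ODE system definition
#'
#' Bundles everything the solver and the physics loss need to know about a
#' system \eqn{dx_i/dt = f_i(x_1, \ldots, x_n, t)}: the state labels, the
#' right-hand side, and (optionally) analytic derivative information used to
#' speed up gradient-based training.
#'
#' @param name Identifier for the system.
#' @param state_names Character vector of state labels; its length fixes the
#'   state dimension.
#' @param rhs Function \code{(state, t, params)} returning the derivative
#'   vector. When \code{vectorized = TRUE} it must also accept a
#'   \code{dim x m} matrix of states with a length-\code{m} time vector and
#'   return a matrix of the same shape.
#' @param param_schema Data frame with columns \code{name} (character) and
#'   \code{positive} (logical): the parameters the system depends on and
#'   whether each must be nonnegative.
#' @param vjp Optional function \code{(state_matrix, t, params, R)} returning
#'   \eqn{J^T R} columnwise, where \eqn{J} is the state Jacobian of \code{rhs}.
#'   Used by the physics-loss gradient; a finite-difference fallback is used
#'   when absent.
#' @param param_grad Optional function
#'   \code{(state_matrix, t, params, R, names)} returning the named vector
#'   \eqn{\sum R \odot \partial f / \partial \theta_j} for the requested
#'   parameter names; finite differences are used when absent.
#' @param vectorized Logical; whether \code{rhs} handles matrix batches.
#' @param reference Optional closed-form solution
#'   \code{(t, params, ic) -> matrix}; used instead of numerical integration
#'   when generating clean observations.
#'
#' @return An object of class \code{ode_system}.
#' @export
ode_system <- function(name, state_names, rhs, param_schema,
                       vjp = NULL, param_grad = NULL, vectorized = FALSE,
                       reference = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(state_names), length(state_names) >= 1L,
            is.function(rhs), is.data.frame(param_schema))
  if (!all(c("name", "positive") %in% names(param_schema)))
    stop("param_schema needs columns 'name' and 'positive'")
  structure(list(name = name,
                 state_names = state_names,
                 dim = length(state_names),
                 rhs = rhs,
                 param_schema = param_schema,
                 vjp = vjp,
                 param_grad = param_grad,
                 vectorized = isTRUE(vectorized),
                 reference = reference),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> ", x$name, ": ", x$dim, " state(s) [",
      paste(x$state_names, collapse = ", "), "], parameters: ",
      paste(x$param_schema$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## ---- logistic growth -------------------------------------------------------

#' Logistic growth rate
#'
#' Right-hand side of the logistic equation \eqn{dP/dt = r P (1 - P/K)}.
#'
#' @param P Population size (scalar, vector or matrix).
#' @param params List or named vector with intrinsic growth rate \code{r} and
#'   carrying capacity \code{K} (\code{K > 0}).
#' @return Growth rate, same shape as \code{P}.
#' @export
logistic_rhs <- function(P, params) {
  params <- validate_logistic_params(params, need_P0 = FALSE)
  if (any(!is.finite(P))) stop("non-finite population passed to logistic_rhs")
  params$r * P * (1 - P / params$K)
}

#' Closed-form logistic trajectory
#'
#' Analytic solution \eqn{P(t) = K / (1 + (K/P_0 - 1) e^{-rt})} of the
#' logistic equation with initial population \code{P0}.
#'
#' @param t Time point or vector, \code{t >= 0}.
#' @param params List or named vector with \code{r}, \code{K} and \code{P0}
#'   (\code{K > 0}, \code{P0 > 0}).
#' @return Population at each \code{t}.
#' @export
logistic_analytic <- function(t, params) {
  params <- validate_logistic_params(params, need_P0 = TRUE)
  if (any(t < 0)) stop("logistic_analytic requires t >= 0")
  params$K / (1 + (params$K / params$P0 - 1) * exp(-params$r * t))
}

validate_logistic_params <- function(params, need_P0 = FALSE) {
  params <- as.list(params)
  if (is.null(params$r) || !is.finite(params$r)) stop("growth rate 'r' must be finite")
  if (is.null(params$K) || !is.finite(params$K) || params$K <= 0)
    stop("carrying capacity 'K' must be positive")
  if (need_P0) {
    if (is.null(params$P0) || !is.finite(params$P0) || params$P0 <= 0)
      stop("initial population 'P0' must be positive")
  }
  params
}

#' Logistic growth system
#'
#' @return An \code{ode_system} for the one-state logistic model with
#'   parameters \code{r} (growth rate) and \code{K} (carrying capacity),
#'   including analytic gradient information and the closed-form reference
#'   solution.
#' @export
logistic_system <- function() {
  ode_system(
    name = "logistic",
    state_names = "P",
    rhs = function(state, t, params) {
      params$r * state * (1 - state / params$K)
    },
    param_schema = data.frame(name = c("r", "K"),
                              positive = c(TRUE, TRUE),
                              stringsAsFactors = FALSE),
    vjp = function(state, t, params, R) {
      R * (params$r * (1 - 2 * state / params$K))
    },
    param_grad = function(state, t, params, R, names) {
      g <- c(r = sum(R * state * (1 - state / params$K)),
             K = sum(R * params$r * state^2 / params$K^2))
      g[names]
    },
    vectorized = TRUE,
    reference = function(t, params, ic) {
      p <- as.list(params)
      p$P0 <- ic[1L]
      matrix(logistic_analytic(t, p), ncol = 1L,
             dimnames = list(NULL, "P"))
    }
  )
}

## ---- promoter / transcription-factor binding -------------------------------

#' Mass-action binding kinetics rate vector
#'
#' Right-hand side of the promoter (\code{prom}) / transcription-factor
#' (\code{tf}) binding system: binding at rate \code{k_on * prom * tf} and
#' unbinding of the complex (\code{promtf}) at rate \code{k_off * promtf}.
#' The derivatives of \code{prom} and \code{tf} are equal; the derivative of
#' the complex is their negation, so \code{prom + promtf} and
#' \code{tf + promtf} are conserved.
#'
#' @param state Numeric vector \code{(prom, tf, promtf)} (or a 3 x m matrix of
#'   such columns).
#' @param params List or named vector with rates \code{k_on} and \code{k_off}
#'   (both nonnegative).
#' @return Rate vector (or matrix), same shape as \code{state}.
#' @export
gene_rhs <- function(state, params) {
  params <- validate_gene_params(params)
  if (is.matrix(state)) {
    if (nrow(state) != 3L) stop("gene_rhs expects 3 states (prom, tf, promtf)")
    flux <- params$k_on * state[1L, ] * state[2L, ] - params$k_off * state[3L, ]
    rbind(-flux, -flux, flux, deparse.level = 0)
  } else {
    if (length(state) != 3L) stop("gene_rhs expects 3 states (prom, tf, promtf)")
    flux <- params$k_on * state[1L] * state[2L] - params$k_off * state[3L]
    c(-flux, -flux, flux)
  }
}

validate_gene_params <- function(params) {
  params <- as.list(params)
  for (nm in c("k_on", "k_off")) {
    if (is.null(params[[nm]]) || !is.finite(params[[nm]]) || params[[nm]] < 0)
      stop("rate '", nm, "' must be finite and nonnegative")
  }
  params
}

#' Promoter/transcription-factor binding system
#'
#' @return An \code{ode_system} with states \code{(prom, tf, promtf)} and
#'   mass-action parameters \code{k_on}, \code{k_off}, including analytic
#'   gradient information.
#' @export
gene_binding_system <- function() {
  ode_system(
    name = "gene_binding",
    state_names = c("prom", "tf", "promtf"),
    rhs = function(state, t, params) {
      if (is.matrix(state)) {
        flux <- params$k_on * state[1L, ] * state[2L, ] - params$k_off * state[3L, ]
        rbind(-flux, -flux, flux, deparse.level = 0)
      } else {
        flux <- params$k_on * state[1L] * state[2L] - params$k_off * state[3L]
        c(-flux, -flux, flux)
      }
    },
    param_schema = data.frame(name = c("k_on", "k_off"),
                              positive = c(TRUE, TRUE),
                              stringsAsFactors = FALSE),
    vjp = function(state, t, params, R) {
      ## f = (-g, -g, g) with g = k_on*prom*tf - k_off*promtf, so
      ## J^T R depends only on s = -R1 - R2 + R3 through dg/dstate.
      s <- -R[1L, ] - R[2L, ] + R[3L, ]
      rbind(params$k_on * state[2L, ] * s,
            params$k_on * state[1L, ] * s,
            -params$k_off * s, deparse.level = 0)
    },
    param_grad = function(state, t, params, R, names) {
      s <- -R[1L, ] - R[2L, ] + R[3L, ]
      g <- c(k_on = sum(state[1L, ] * state[2L, ] * s),
             k_off = -sum(state[3L, ] * s))
      g[names]
    },
    vectorized = TRUE
  )
}

## ---- numerical integration -------------------------------------------------

#' Integrate an ODE system on a time grid
#'
#' Solves the initial-value problem with an adaptive Dormand-Prince
#' Runge-Kutta scheme (\code{deSolve::ode}, method \code{"ode45"}) at tight
#' tolerances (\code{rtol = 1e-8}, \code{atol = 1e-10}); these systems are
#' non-stiff at the parameter values used here.
#'
#' @param system An \code{ode_system}.
#' @param params Named list/vector of parameter values matching the system's
#'   schema.
#' @param ic Initial state vector, length \code{system$dim}.
#' @param t_grid Strictly increasing time vector; the solution is reported at
#'   exactly these times and the first row equals \code{ic}.
#' @param rtol,atol Solver tolerances.
#' @return A \code{pinn_trajectory}: list with \code{times} and a
#'   \code{length(t_grid) x dim} \code{states} matrix (columns named after the
#'   states).
#' @export
integrate_ode <- function(system, params, ic, t_grid,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "ode_system"))
  if (length(ic) != system$dim)
    stop("initial condition has length ", length(ic),
         " but the system has dimension ", system$dim)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  params <- as.list(params)
  deriv <- function(t, y, p) list(as.numeric(system$rhs(y, t, p)))
  sol <- deSolve::ode(y = as.numeric(ic), times = t_grid, func = deriv,
                      parms = params, method = "ode45",
                      rtol = rtol, atol = atol)
  attrs <- attributes(sol)
  if (!is.null(attrs$istate) && attrs$istate[1L] < 0)
    stop("ODE solver failed (istate = ", attrs$istate[1L],
         "); try loosening rtol/atol or shortening the grid")
  states <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  if (nrow(states) != length(t_grid) || any(!is.finite(states)))
    stop("ODE solver returned an incomplete or non-finite trajectory")
  states[1L, ] <- as.numeric(ic)  # guard against representation round-off
  colnames(states) <- system$state_names
  trajectory(t_grid, states)
}

#' Trajectory container
#'
#' @param times Strictly increasing time vector.
#' @param states Numeric matrix, one row per time point.
#' @return Object of class \code{pinn_trajectory}.
#' @export
trajectory <- function(times, states) {
  states <- as.matrix(states)
  if (nrow(states) != length(times))
    stop("states must have one row per time point")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(states))) stop("trajectory contains non-finite states")
  structure(list(times = as.numeric(times), states = states),
            class = "pinn_trajectory")
}

#' @export
as.data.frame.pinn_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
print.pinn_trajectory <- function(x, ...) {
  cat("<pinn_trajectory> ", length(x$times), " time points x ",
      ncol(x$states), " state(s) over [", format(min(x$times)), ", ",
      format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' CSV layout is \code{t,<state names...>}.
#' @param x A \code{pinn_trajectory}.
#' @param path File path.
#' @return \code{write_trajectory} returns \code{path} invisibly;
#'   \code{read_trajectory} returns a \code{pinn_trajectory}.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "t") stop("expected first CSV column to be 't'")
  trajectory(df$t, as.matrix(df[, -1L, drop = FALSE]))
}
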