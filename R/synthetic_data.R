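#' Uniform collocation points
#'
#' Draws the time locations at which the ODE residual is penalized: \code{n}
#' i.i.d. uniform samples on \code{[t_min, t_max]}, sorted ascending. Sorting
#' makes logs reproducible to read; training itself is order-insensitive.
#'
#' @param n Number of points (\code{n >= 0}).
#' @param t_min,t_max Domain bounds, \code{t_max > t_min}.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Object of class \code{collocation_set} with fields \code{times},
#'   \code{t_min}, \code{t_max}, \code{seed}.
#' @export
sample_collocation <- function(n, t_min, t_max, seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be a nonnegative count")
  if (t_max <= t_min) stop("t_max must exceed t_min")
  times <- withr::with_seed(as.integer(seed), stats::runif(n, t_min, t_max))
  structure(list(times = sort(times), t_min = t_min, t_max = t_max,
                 seed = as.integer(seed)),
            class = "collocation_set")
}

#' @export
print.collocation_set <- function(x, ...) {
  cat("<collocation_set> ", length(x$times), " points on [", x$t_min, ", ",
      x$t_max, "] (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Synthetic observations from an ODE system
#'
#' Evaluates the clean solution (the closed form when the system carries one,
#' otherwise numerical integration) at the requested times and adds i.i.d.
#' Gaussian noise of standard deviation \code{noise_sigma} per state.
#' \code{noise_sigma = 0} returns the clean values exactly.
#'
#' @param system An \code{ode_system}.
#' @param params Named parameter list/vector.
#' @param times Observation times (ascending).
#' @param ic Initial state (needed when the trajectory must be computed).
#' @param noise_sigma Noise standard deviation, scalar or one value per state;
#'   in the units of the state variables.
#' @param seed Integer seed for the noise draw.
#' @param t0 Time at which \code{ic} holds; defaults to the first observation
#'   time. Must not exceed \code{times[1]}.
#' @return Object of class \code{observation_set}: \code{times},
#'   \code{values} (n x dim matrix), \code{clean} (noise-free matrix),
#'   \code{noise_sigma}, \code{seed}.
#' @export
generate_observations <- function(system, params, times, ic,
                                  noise_sigma = 0, seed = 1L, t0 = times[1L]) {
  stopifnot(inherits(system, "ode_system"))
  if (any(noise_sigma < 0)) stop("noise_sigma must be nonnegative")
  if (length(noise_sigma) == 1L) noise_sigma <- rep(noise_sigma, system$dim)
  if (length(noise_sigma) != system$dim)
    stop("noise_sigma must be scalar or one value per state")
  times <- as.numeric(times)
  if (t0 > times[1L]) stop("t0 must not exceed the first observation time")

  clean <- if (!is.null(system$reference)) {
    system$reference(times, params, ic)
  } else {
    grid <- if (t0 < times[1L]) c(t0, times) else times
    if (length(grid) < 2L) grid <- c(grid, grid + 1)
    traj <- integrate_ode(system, params, ic, grid)
    keep <- match(times, grid)
    traj$states[keep, , drop = FALSE]
  }
  colnames(clean) <- system$state_names

  noise <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(length(times) * system$dim), nrow = length(times)) %*%
      diag(noise_sigma, nrow = system$dim)
  })
  values <- clean + noise
  structure(list(times = times, values = values, clean = clean,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> ", length(x$times), " observations x ",
      ncol(x$values), " state(s), noise sd ",
      paste(format(x$noise_sigma), collapse = "/"),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read observations as CSV
#'
#' Layout \code{t,<state names...>}; only the noisy values are stored.
#' @param x An \code{observation_set}.
#' @param path File path.
#' @export
write_observations <- function(x, path) {
  df <- data.frame(t = x$times, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "t") stop("expected first CSV column to be 't'")
  values <- as.matrix(df[, -1L, drop = FALSE])
  structure(list(times = df$t, values = values, clean = NULL,
                 noise_sigma = NA_real_, seed = NA_integer_),
            class = "observation_set")
}

#' Preconfigured case studies
#'
#' Returns the two study systems with their true parameters, initial
#' conditions and time domain: logistic growth (\code{r = 0.5},
#' \code{K = 100}, \code{P0 = 1}) and promoter/transcription-factor binding
#' (\code{k_on = 1/60}, \code{k_off = 0.5/60}, initial concentrations
#' \code{(17, 25, 0)}), both on \code{t} in \code{[0, 100]}.
#'
#' @param name \code{"logistic"} or \code{"gene"}.
#' @return List with \code{system} (\code{ode_system}), \code{params} (true
#'   values), \code{ic}, \code{domain} (length-2 vector), and defaults used by
#'   the experiment runners: \code{n_colloc}, \code{n_obs},
#'   \code{noise_sigma}, \code{hidden_layers}, \code{neurons},
#'   \code{output_scale}, \code{iterations}.
#' @export
make_case_study <- function(name = c("logistic", "gene")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("logistic", "gene"))
    stop("unknown case study '", paste(name, collapse = ","),
         "'; choices are \"logistic\", \"gene\"")
  if (name == "logistic") {
    list(name = "logistic",
         system = logistic_system(),
         params = list(r = 0.5, K = 100),
         ic = 1.0,
         domain = c(0, 100),
         n_colloc = 500L,
         n_obs = 50L,
         noise_sigma = 1.0,
         hidden_layers = 3L,
         neurons = 50L,
         output_scale = 100,
         iterations = 200000L)
  } else {
    list(name = "gene",
         system = gene_binding_system(),
         params = list(k_on = 1 / 60, k_off = 0.5 / 60),
         ic = c(17.0, 25, 0),
         domain = c(0, 100),
         n_colloc = 350L,
         n_obs = 300L,
         noise_sigma = 0,
         hidden_layers = 4L,
         neurons = 50L,
         output_scale = 25,
         iterations = 10000L)
  }
}

#' Default equally spaced observation times for a case study
#'
#' @param case A case-study list from \code{make_case_study}.
#' @param n Number of observation points.
#' @return Numeric vector of times spanning the case domain.
#' @export
case_obs_times <- function(case, n = case$n_obs) {
  seq(case$domain[1L], case$domain[2L], length.out = n)
}
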