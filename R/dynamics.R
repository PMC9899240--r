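#' Specify a metastable potential and its simulation parameters
#'
#' Defines the energy landscape and integration settings for the overdamped
#' Langevin dynamics \eqn{dX_t = -\nabla V(X_t)\,dt + \sqrt{2\beta^{-1}}\,dW_t}.
#' Two landscapes are available: a ring potential with `s` angular wells,
#' \eqn{V(x) = \cos(s\,\mathrm{atan2}(x_2, x_1)) + 10(\sqrt{x_1^2+x_2^2}-1)^2},
#' and the scalar double-well \eqn{V(x) = x^4/4 - x^2/2}.
#'
#' @param kind `"s_well"` (two-dimensional ring potential) or `"double_well"`
#'   (one-dimensional).
#' @param s Number of wells (s_well only, integer >= 2).
#' @param beta Inverse temperature; larger values make transitions between
#'   wells rarer.
#' @param dt Integration time step of the Euler-Maruyama scheme.
#' @param n_steps Number of retained time steps `T`.
#' @param thin Integration steps per retained step: the SDE is integrated at
#'   `dt` but only every `thin`-th point is kept, so `T` snapshots span
#'   `n_steps * thin * dt` time units. Decouples integrator stability (small
#'   `dt`) from the physical time span needed to observe well transitions.
#' @param seed Integer seed; simulation is bit-reproducible for a fixed seed.
#' @param x0 Initial point: a scalar for `double_well`, a 2-vector for
#'   `s_well`. Defaults to a well minimum (`1` resp. the minimum at angle
#'   `pi/s`).
#' @return An object of class `potential_spec`.
#' @seealso [simulate_trajectory()], [potential_value()]
#' @export
potential_spec <- function(kind = c("double_well", "s_well"), s = 2L,
                           beta = 6, dt = 0.01, n_steps = 10000L,
                           thin = 6L, seed = 1L, x0 = NULL) {
  kind <- match.arg(kind)
  stopifnot(dt > 0, beta > 0, n_steps >= 1, thin >= 1)
  s <- as.integer(s)
  if (kind == "s_well" && s < 2L)
    stop("s_well potential requires s >= 2 wells")
  if (kind == "double_well") s <- 2L
  if (is.null(x0)) {
    x0 <- if (kind == "double_well") 1 else
      c(cos(pi / s), sin(pi / s))  # minimum of cos(s*theta) at theta = pi/s
  }
  dim_needed <- if (kind == "double_well") 1L else 2L
  if (length(x0) != dim_needed)
    stop("x0 must have length ", dim_needed, " for kind '", kind, "'")
  structure(
    list(kind = kind, s = s, beta = beta, dt = dt,
         n_steps = as.integer(n_steps), thin = as.integer(thin),
         seed = as.integer(seed), x0 = as.numeric(x0)),
    class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("potential_spec: %s (s = %d), beta = %g, dt = %g, T = %d\n",
              x$kind, x$s, x$beta, x$dt, x$n_steps))
  invisible(x)
}

#' Evaluate the potential energy at a point
#'
#' @param x A point: scalar for the double-well, 2-vector for the s-well.
#' @param spec A [potential_spec()].
#' @return The potential value \eqn{V(x)}.
#' @export
potential_value <- function(x, spec) {
  check_point_dim(x, spec)
  if (spec$kind == "double_well") {
    x[1]^4 / 4 - x[1]^2 / 2
  } else {
    r <- sqrt(x[1]^2 + x[2]^2)
    cos(spec$s * atan2(x[2], x[1])) + 10 * (r - 1)^2
  }
}

#' Analytic gradient of the potential
#'
#' @inheritParams potential_value
#' @return `dV/dx`: scalar for the double-well; for the s-well the 2-vector
#'   gradient, using `datan2(x2,x1)/dx = (-x2, x1)/r^2`.
#' @export
potential_gradient <- function(x, spec) {
  check_point_dim(x, spec)
  if (spec$kind == "double_well") return(x[1]^3 - x[1])
  r2 <- x[1]^2 + x[2]^2
  r <- sqrt(r2)
  if (r2 == 0) return(c(0, 0))  # atan2 convention at the origin
  theta <- atan2(x[2], x[1])
  dcos <- -spec$s * sin(spec$s * theta)
  dtheta <- c(-x[2], x[1]) / r2
  dradial <- 20 * (r - 1) / r * c(x[1], x[2])
  dcos * dtheta + dradial
}

check_point_dim <- function(x, spec) {
  dim_needed <- if (spec$kind == "double_well") 1L else 2L
  if (length(x) != dim_needed)
    stop("point has length ", length(x), ", expected ", dim_needed,
         " for kind '", spec$kind, "'")
  invisible(TRUE)
}

#' Assign the ground-truth metastable state of a point
#'
#' For the double-well, state 0 for `x < 0` and state 1 otherwise. For the
#' s-well, the index of the angular sector of width `2*pi/s` centred on the
#' well minimum at angle `(2k+1)*pi/s`; sector boundaries (angles `2k*pi/s`)
#' belong to the sector they open, i.e. ties break toward the lower-index
#' sector.
#'
#' @inheritParams potential_value
#' @return Integer state label in `0:(s-1)`.
#' @export
assign_state <- function(x, spec) {
  check_point_dim(x, spec)
  if (spec$kind == "double_well") {
    return(if (x[1] < 0) 0L else 1L)
  }
  theta <- atan2(x[2], x[1]) %% (2 * pi)
  as.integer(floor(theta * spec$s / (2 * pi))) %% spec$s
}

#' Simulate a metastable trajectory by Euler-Maruyama integration
#'
#' Iterates \eqn{X_{k+1} = X_k - \nabla V(X_k)\,dt + \sqrt{2\,dt/\beta}\,\xi_k}
#' with i.i.d. standard normal \eqn{\xi_k} and labels every step with its
#' metastable state.
#'
#' @param spec A [potential_spec()].
#' @return An object of class `trajectory` with fields `points` (a
#'   `n_steps x dim` matrix), `states` (integer labels), and `spec`.
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "potential_spec"))
  d <- if (spec$kind == "double_well") 1L else 2L
  T_ <- spec$n_steps
  n_int <- T_ * spec$thin
  pts <- matrix(NA_real_, T_, d)
  sigma <- sqrt(2 * spec$dt / spec$beta)
  x <- spec$x0
  withr::with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n_int * d), n_int, d)
    for (k in seq_len(n_int)) {
      x <- x - potential_gradient(x, spec) * spec$dt + sigma * noise[k, ]
      if (any(abs(x) > 1e6))
        stop("trajectory diverged (|X| > 1e6) at step ", k,
             "; use a smaller dt")
      if (k %% spec$thin == 0) pts[k / spec$thin, ] <- x
    }
  })
  states <- vapply(seq_len(T_), function(k) assign_state(pts[k, ], spec),
                   integer(1))
  structure(list(points = pts, states = states, spec = spec),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d steps, dim %d, %d states visited (%s)\n",
              nrow(x$points), ncol(x$points),
              length(unique(x$states)), x$spec$kind))
  invisible(x)
}

#' Write / read a trajectory as a tab-separated file
#'
#' Columns: `time_index`, `x1` (and `x2` for two-dimensional trajectories),
#' `state`; one header line. The potential specification is not stored.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a list with `points` and `states` (no `spec`).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  d <- ncol(traj$points)
  df <- data.frame(time_index = seq_len(nrow(traj$points)) - 1L)
  df$x1 <- traj$points[, 1]
  if (d == 2L) df$x2 <- traj$points[, 2]
  df$state <- traj$states
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param path Path of a file written by `write_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  cols <- intersect(c("x1", "x2"), names(df))
  list(points = as.matrix(df[, cols, drop = FALSE]),
       states = as.integer(df$state))
}

#' Mean dwell time of a label sequence
#'
#' Average run length of consecutive identical state labels, a summary of how
#' metastable a trajectory is.
#'
#' @param states Integer vector of state labels in time order.
#' @return Mean number of consecutive steps spent in a state before leaving.
#' @export
mean_dwell_time <- function(states) {
  r <- rle(states)
  mean(r$lengths)
}
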