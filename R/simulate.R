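#' Simulate the diffusion process by Euler-Maruyama discretization
#'
#' Each step updates `X <- X + mu(X) * dt + sqrt(2 * sigma^2 * dt) * Z`
#' with Z i.i.d. standard normal per cell and coordinate; `mu` is the
#' model drift (negative potential gradient). `dt` and `sigma` default to
#' the model's process constants.
#'
#' @param model a potential model.
#' @param init n x k matrix of initial states.
#' @param n_steps number of steps (>= 0).
#' @param seed RNG seed for the noise stream.
#' @param dt,sigma process constants; default from the model.
#' @param keep_path if TRUE return the whole path, else only the final
#'   states.
#' @return object of class `Trajectory`: list with `states` (an
#'   (n_steps+1) x n x k array when `keep_path`, else the final n x k
#'   matrix in `final`), `t0`, `dt`, `sigma`, `seed`.
#' @export
simulate_diffusion <- function(model, init, n_steps, seed = 1,
                               dt = model$dt, sigma = model$sigma,
                               keep_path = TRUE, t0 = 0) {
  init <- as_state_matrix(init, model$k)
  if (n_steps < 0) stop("n_steps must be >= 0")
  n <- nrow(init); k <- ncol(init)
  noise_sd <- sqrt(2 * sigma^2 * dt)
  path <- if (keep_path) array(NA_real_, c(n_steps + 1, n, k)) else NULL
  if (keep_path) path[1, , ] <- init
  X <- init
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      X <- X + drift(model, X) * dt +
        noise_sd * matrix(stats::rnorm(n * k), n, k)
      if (any(!is.finite(X)))
        stop("non-finite states at simulation step ", s)
      if (keep_path) path[s + 1, , ] <- X
    }
  })
  structure(list(states = path, final = X, t0 = t0, dt = dt,
                 sigma = sigma, seed = seed, n_steps = n_steps),
            class = "Trajectory")
}

#' Final states of a trajectory
#' @param traj Trajectory.
#' @return n x k matrix.
#' @export
final_states <- function(traj) traj$final

#' Sample initial cells with replacement, weighted by mass
#'
#' Used to initialize simulations from an observed snapshot with sampling
#' probability proportional to each cell's expected number of descendants,
#' biasing toward proliferative cells.
#'
#' @param population n x k matrix of states.
#' @param weights nonnegative per-cell masses (not all zero); default
#'   uniform.
#' @param n_cells number of draws.
#' @param seed RNG seed.
#' @return list with `states` (n_cells x k) and `index` of the drawn rows.
#' @export
sample_initial <- function(population, weights = NULL, n_cells, seed = 1) {
  population <- as.matrix(population)
  n <- nrow(population)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("weights must not all be zero")
  idx <- with_seed(seed,
                   sample.int(n, n_cells, replace = TRUE, prob = weights))
  list(states = population[idx, , drop = FALSE], index = idx)
}

#' Convert a real-time interval to simulation steps
#'
#' @param t_from,t_to real times (`t_to > t_from`).
#' @param dt step size (> 0).
#' @return integer `round((t_to - t_from) / dt)`; warns when the interval
#'   is not an integral number of steps.
#' @export
real_time_to_steps <- function(t_from, t_to, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (t_to <= t_from) stop("t_to must be greater than t_from")
  ratio <- (t_to - t_from) / dt
  n <- round(ratio)
  if (abs(ratio - n) > 1e-8)
    warning(sprintf("interval %g is not an integral number of steps of %g; using %d",
                    t_to - t_from, dt, n))
  as.integer(n)
}

#' Evaluate potential and drift on a uniform grid
#'
#' Produces the landscape visualization data: potential heights on a
#' regular 2-D grid plus unit-normalized drift arrows at the grid points.
#' When the model lives in a higher-dimensional state space, `embed`
#' maps a grid point (length-2) to a full state vector (e.g. fixing the
#' remaining coordinates at their data means).
#'
#' @param model potential model.
#' @param bounds list with `x = c(min, max)` and `y = c(min, max)`.
#' @param resolution grid points per axis (>= 2).
#' @param embed optional function(matrix n x 2) -> matrix n x k.
#' @return data.frame with columns x, y, psi, dx, dy (unit arrows),
#'   drift_norm.
#' @export
grid_landscape <- function(model, bounds, resolution = 25, embed = NULL) {
  if (resolution < 2) stop("resolution must be >= 2")
  if (any(!is.finite(unlist(bounds)))) stop("bounds must be finite")
  gx <- seq(bounds$x[1], bounds$x[2], length.out = resolution)
  gy <- seq(bounds$y[1], bounds$y[2], length.out = resolution)
  pts2 <- as.matrix(expand.grid(x = gx, y = gy))
  pts <- if (is.null(embed)) pts2 else embed(pts2)
  psi <- potential(model, pts)
  mu <- drift(model, pts)
  nrm <- sqrt(rowSums(mu[, 1:2, drop = FALSE]^2))
  u <- ifelse(nrm > 0, mu[, 1] / nrm, 0)
  v <- ifelse(nrm > 0, mu[, 2] / nrm, 0)
  data.frame(x = pts2[, 1], y = pts2[, 2], psi = psi,
             dx = u, dy = v, drift_norm = nrm)
}
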