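## Entropy-regularized optimal transport between weighted point clouds.
##
## Training compares simulated and observed cell populations with the
## debiased Sinkhorn divergence under squared-Euclidean ground cost, with
## source masses carrying expected descendant counts. A hand-written
## transportation simplex provides the exact small-instance oracle.

#' Weighted point cloud
#' @param points m x k matrix of states.
#' @param masses nonnegative per-point weights (default uniform). They are
#'   normalized to sum 1 when a transport problem is solved.
#' @return object of class `WeightedCloud`.
#' @export
weighted_cloud <- function(points, masses = NULL) {
  points <- as.matrix(points)
  if (is.null(masses)) masses <- rep(1, nrow(points))
  if (length(masses) != nrow(points)) stop("masses length mismatch")
  if (any(masses < 0)) stop("masses must be nonnegative")
  if (sum(masses) <= 0) stop("total mass must be positive")
  structure(list(points = points, masses = masses), class = "WeightedCloud")
}

#' Squared-Euclidean cost matrix
#' @param X m x k matrix.
#' @param Y M x k matrix.
#' @return m x M matrix with `C[i, j] = ||x_i - y_j||^2`.
#' @export
cost_matrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  C <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  pmax(C, 0)
}

#' Source masses from expected descendant counts
#'
#' Normalizes per-cell expected descendant counts into transport source
#' marginals; target marginals stay uniform.
#'
#' @param n positive per-cell expected descendant counts.
#' @return masses summing to 1, proportional to `n`.
#' @export
weighted_marginals_from_growth <- function(n) {
  if (any(!is.finite(n) | n <= 0)) stop("descendant counts must be positive")
  n / sum(n)
}

## ---- exact solver (transportation simplex, small-instance oracle) ----

#' Exact optimal transport on small instances
#'
#' Solves the balanced transportation problem exactly with the
#' transportation simplex (northwest-corner start + MODI pivoting). Meant
#' as an oracle on small instances (m, M <= 64) for validating the
#' entropic solver, and for exact midpoint interpolation baselines.
#'
#' @param source,target WeightedCloud objects.
#' @param normalize if TRUE (default) each cloud's masses are normalized
#'   to total 1 before solving; with `normalize = FALSE` the raw totals
#'   must agree within 1e-6 (relative) or the problem is infeasible.
#' @return object of class `TransportPlan`: `plan` (m x M), `cost_matrix`,
#'   `cost` (total transport cost), `alpha`, `beta`.
#' @export
exact_ot <- function(source, target, normalize = TRUE) {
  stopifnot(inherits(source, "WeightedCloud"), inherits(target, "WeightedCloud"))
  a <- source$masses; b <- target$masses
  if (!normalize && abs(sum(a) - sum(b)) > 1e-6 * max(sum(a), sum(b)))
    stop("infeasible masses: totals differ beyond tolerance")
  a <- a / sum(a); b <- b / sum(b)
  C <- cost_matrix(source$points, target$points)
  sol <- transport_simplex(a, b, C)
  structure(list(plan = sol$plan, cost_matrix = C,
                 cost = sum(sol$plan * C), alpha = a, beta = b),
            class = "TransportPlan")
}

transport_simplex <- function(a, b, C, max_iter = 100000L) {
  m <- length(a); M <- length(b)
  # perturbation to avoid degenerate pivots
  eps <- 1e-9 / max(m, M)
  a <- a + eps; b <- b + eps * m / M
  a <- a * (sum(b) / sum(a))
  # northwest corner start
  plan <- matrix(0, m, M)
  basis <- matrix(FALSE, m, M)
  i <- 1L; j <- 1L; ra <- a; rb <- b
  while (i <= m && j <= M) {
    q <- min(ra[i], rb[j])
    plan[i, j] <- q; basis[i, j] <- TRUE
    ra[i] <- ra[i] - q; rb[j] <- rb[j] - q
    if (i == m && j == M) break
    if (ra[i] <= rb[j] && i < m) i <- i + 1L else j <- j + 1L
  }
  for (iter in seq_len(max_iter)) {
    uv <- simplex_duals(basis, C)
    red <- C - outer(uv$u, uv$v, "+")
    red[basis] <- 0
    ent <- which.min(red)
    if (red[ent] >= -1e-10 * (1 + max(abs(C)))) break
    ei <- (ent - 1L) %% m + 1L; ej <- (ent - 1L) %/% m + 1L
    cyc <- simplex_cycle(basis, ei, ej)
    minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
    th <- plan[minus]
    theta <- min(th)
    leave <- minus[which.min(th), , drop = FALSE]
    sgn <- rep_len(c(1, -1), nrow(cyc))
    plan[cyc] <- plan[cyc] + sgn * theta
    basis[ei, ej] <- TRUE
    basis[leave] <- FALSE
    plan[leave] <- 0
  }
  # the O(1e-9) anti-degeneracy perturbation leaves marginals off by eps;
  # renormalize total mass (error far below oracle tolerances)
  plan <- plan / sum(plan)
  list(plan = plan)
}

# duals via the basis spanning tree: u_1 = 0, propagate c_ij = u_i + v_j
simplex_duals <- function(basis, C) {
  m <- nrow(basis); M <- ncol(basis)
  u <- rep(NA_real_, m); v <- rep(NA_real_, M)
  u[1] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) {
      if (is.na(u[i])) next
      js <- which(basis[i, ] & is.na(v))
      if (length(js)) { v[js] <- C[i, js] - u[i]; changed <- TRUE }
    }
    for (j in seq_len(M)) {
      if (is.na(v[j])) next
      is_ <- which(basis[, j] & is.na(u))
      if (length(is_)) { u[is_] <- C[is_, j] - v[j]; changed <- TRUE }
    }
    if (!anyNA(u) && !anyNA(v)) break
    if (!changed) { # disconnected (degenerate): anchor one missing node
      if (anyNA(u)) u[which(is.na(u))[1]] <- 0 else
        v[which(is.na(v))[1]] <- 0
    }
  }
  list(u = u, v = v)
}

# unique alternating cycle created by adding cell (ei, ej) to the basis
# tree; returns a 2-column index matrix starting at (ei, ej), alternating
# +, -, +, - ...
simplex_cycle <- function(basis, ei, ej) {
  m <- nrow(basis); M <- ncol(basis)
  # nodes: rows 1..m, cols m+1..m+M; find path col (m+ej) -> row ei
  adj <- function(node) {
    if (node <= m) m + which(basis[node, ]) else which(basis[, node - m])
  }
  prev <- rep(NA_integer_, m + M)
  seen <- rep(FALSE, m + M)
  queue <- m + ej; seen[m + ej] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == ei) break
    for (nb in adj(cur)) if (!seen[nb]) {
      seen[nb] <- TRUE; prev[nb] <- cur; queue <- c(queue, nb)
    }
  }
  if (!seen[ei]) stop("basis tree disconnected; cannot form cycle")
  path <- ei
  while (!is.na(prev[path[length(path)]]))
    path <- c(path, prev[path[length(path)]])
  # path: ei, ..., m+ej (alternating row/col nodes)
  cells <- matrix(c(ei, ej), 1, 2)
  for (s in seq_len(length(path) - 1)) {
    n1 <- path[s]; n2 <- path[s + 1]
    cell <- if (n1 <= m) c(n1, n2 - m) else c(n2, n1 - m)
    cells <- rbind(cells, cell)
  }
  unname(cells)
}

## ---- entropic solver ----

#' Entropy-regularized OT cost (raw, non-debiased)
#'
#' Stabilized Sinkhorn with geometric epsilon annealing from the squared
#' cloud diameter down to `blur^2` (each level multiplies the blur by
#' `scaling`). Iterates each level until the worst marginal violation is
#' below `tol` or `max_iter` is reached.
#'
#' @param source,target WeightedCloud objects.
#' @param blur entropic blur; the regularizer is `epsilon = blur^2`
#'   (squared-Euclidean cost, so blur is a length scale).
#' @param scaling annealing rate in (0, 1).
#' @param tol marginal residual tolerance.
#' @param max_iter maximum Sinkhorn iterations per epsilon level.
#' @return list with `value` (dual objective), `plan`, `f`, `g`
#'   (potentials), `residual`.
#' @export
sinkhorn_ot <- function(source, target, blur = 0.1, scaling = 0.7,
                        tol = 1e-6, max_iter = 500L) {
  a <- source$masses / sum(source$masses)
  b <- target$masses / sum(target$masses)
  C <- cost_matrix(source$points, target$points)
  res <- sinkhorn_core(a, b, C, blur, scaling, tol, max_iter)
  if (res$residual > 1e-3)
    stop("Sinkhorn did not converge; marginal residual ", res$residual)
  res
}

eps_ladder <- function(d2, eps_final, scaling) {
  if (d2 <= eps_final || scaling <= 0 || scaling >= 1) return(eps_final)
  e <- d2; ladder <- c()
  while (e > eps_final) { ladder <- c(ladder, e); e <- e * scaling^2 }
  c(ladder, eps_final)
}

# asymmetric Sinkhorn with eps annealing: stabilized kernel scaling.
# Per eps level the Gibbs kernel (with current potentials absorbed) is
# exponentiated once; iterations are then plain BLAS matrix-vector
# scalings u = 1/(M bv), v = 1/(M' au), equivalent to the log-domain
# updates but far cheaper. Potentials are re-absorbed into the kernel
# whenever a scaling factor drifts too far from 1.
sinkhorn_core <- function(a, b, C, blur, scaling, tol, max_iter) {
  m <- length(a); M <- length(b)
  eps_list <- eps_ladder(max(C), blur^2, scaling)
  f <- rep(0, m); g <- rep(0, M)
  plan <- NULL
  for (eps in eps_list) {
    K <- exp((outer(f, g, "+") - C) / eps)
    u <- rep(1, m); v <- rep(1, M)
    for (it in seq_len(max_iter)) {
      u <- 1 / as.numeric(K %*% (b * v))
      v <- 1 / as.numeric(crossprod(K, a * u))
      if (max(abs(log(u))) > 30 || max(abs(log(v))) > 30) {
        f <- f + eps * log(u); g <- g + eps * log(v)
        K <- exp((outer(f, g, "+") - C) / eps)
        u <- rep(1, m); v <- rep(1, M)
      }
      if (it %% 5 == 0 || it == max_iter) {
        # after the v-update columns are exact; check the row residual
        rowres <- max(abs(a * u * as.numeric(K %*% (b * v)) - a))
        if (rowres < tol) break
      }
    }
    f <- f + eps * log(u); g <- g + eps * log(v)
    if (eps == eps_list[length(eps_list)])
      plan <- (a * u) * K * rep(b * v, each = m)
  }
  eps <- eps_list[length(eps_list)]
  list(value = sum(a * f) + sum(b * g), plan = plan, f = f, g = g,
       eps = eps,
       residual = max(max(abs(rowSums(plan) - a)),
                      max(abs(colSums(plan) - b))))
}

# symmetric problem OT_eps(alpha, alpha): averaged fixed-point updates
# (u <- sqrt(u / (K a u)) is the kernel-scaling form of averaging the
# dual potentials, preserving symmetry)
sinkhorn_symmetric <- function(a, X, blur, scaling, tol, max_iter) {
  C <- cost_matrix(X, X)
  m <- length(a)
  eps_list <- eps_ladder(max(C), blur^2, scaling)
  p <- rep(0, m)
  plan <- NULL
  for (eps in eps_list) {
    K <- exp((outer(p, p, "+") - C) / eps)
    u <- rep(1, m)
    for (it in seq_len(max_iter)) {
      w <- 1 / as.numeric(K %*% (a * u))
      delta <- max(abs(eps * (log(w) - log(u))))
      u <- sqrt(u * w)
      if (max(abs(log(u))) > 30) {
        p <- p + eps * log(u)
        K <- exp((outer(p, p, "+") - C) / eps)
        u <- rep(1, m)
      }
      if (delta < tol * eps) break
    }
    p <- p + eps * log(u)
    if (eps == eps_list[length(eps_list)]) {
      K <- exp((outer(p, p, "+") - C) / eps)
      plan <- a * K * rep(a, each = m)
    }
  }
  list(value = 2 * sum(a * p), plan = plan, p = p,
       eps = eps_list[length(eps_list)])
}

#' Debiased Sinkhorn divergence between weighted clouds
#'
#' `S(a, b) = OT_eps(a, b) - OT_eps(a, a)/2 - OT_eps(b, b)/2`, the
#' debiased entropic divergence: nonnegative, zero iff the clouds
#' coincide, and differentiable in the source points. With `grad = TRUE`
#' the envelope-theorem gradient with respect to the source points is
#' returned (the quantity training backpropagates through the simulated
#' trajectories).
#'
#' @inheritParams sinkhorn_ot
#' @param grad if TRUE also return `grad_source` (m x k matrix).
#' @return list with `value` and optionally `grad_source`.
#' @export
sinkhorn_divergence <- function(source, target, blur = 0.1, scaling = 0.7,
                                tol = 1e-6, max_iter = 500L, grad = FALSE) {
  a <- source$masses / sum(source$masses)
  b <- target$masses / sum(target$masses)
  X <- source$points; Y <- target$points
  ab <- sinkhorn_core(a, b, cost_matrix(X, Y), blur, scaling, tol, max_iter)
  aa <- sinkhorn_symmetric(a, X, blur, scaling, tol, max_iter)
  bb <- sinkhorn_symmetric(b, Y, blur, scaling, tol, max_iter)
  value <- ab$value - 0.5 * aa$value - 0.5 * bb$value
  out <- list(value = value, residual = ab$residual)
  if (grad) {
    # d/dx_i OT(a,b) = sum_j pi_ij * 2 (x_i - y_j)
    g_ab <- 2 * (rowSums(ab$plan) * X - ab$plan %*% Y)
    # x appears in both slots of OT(a,a); plan is symmetric
    g_aa <- 4 * (rowSums(aa$plan) * X - aa$plan %*% X)
    out$grad_source <- g_ab - 0.5 * g_aa
  }
  out
}

#' Midpoint interpolation under a transport plan
#'
#' Samples pairs (i, j) with probability proportional to the plan mass
#' `pi_ij` and emits the midpoints `(x_i + y_j) / 2`. This is the
#' linear-interpolation baseline for held-out time-point recovery.
#'
#' @param source,target WeightedCloud objects.
#' @param plan m x M transport plan (e.g. from [exact_ot()] or
#'   [sinkhorn_ot()]).
#' @param n_points number of interpolated points (default m).
#' @param seed RNG seed.
#' @return n_points x k matrix of interpolated states.
#' @export
interpolate_midpoint <- function(source, target, plan,
                                 n_points = nrow(source$points), seed = 1) {
  plan <- as.matrix(plan)
  tot <- sum(plan)
  if (tot <= 0) stop("degenerate plan: all mass zero")
  pr <- as.numeric(plan) / tot
  idx <- with_seed(seed,
                   sample.int(length(pr), n_points, replace = TRUE, prob = pr))
  i <- (idx - 1L) %% nrow(plan) + 1L
  j <- (idx - 1L) %/% nrow(plan) + 1L
  (source$points[i, , drop = FALSE] + target$points[j, , drop = FALSE]) / 2
}

#' Write a transport plan as a delimited matrix
#' @param plan TransportPlan or plain matrix.
#' @param file output path.
#' @export
write_plan <- function(plan, file) {
  m <- if (inherits(plan, "TransportPlan")) plan$plan else as.matrix(plan)
  utils::write.table(m, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
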