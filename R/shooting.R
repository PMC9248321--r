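#' Landmark correspondence with matching covariance
#'
#' Paired moving/fixed point sets with a per-pair symmetric
#' positive-definite covariance (mm^2) quantifying how softly each pair is
#' matched: the data term of the registration objective is the Mahalanobis
#' distance `(y_n - phi(x_n, 1))' Sigma_n^{-1} (y_n - phi(x_n, 1))`.
#'
#' @param moving,fixed `N x d` matrices of corresponding points (mm).
#' @param covariance a single positive scalar (isotropic, shared by all
#'   pairs, default 0.25 mm^2) or a list of `N` SPD `d x d` matrices.
#' @return An object of class `lg_corr`.
#' @export
landmark_correspondence <- function(moving, fixed, covariance = 0.25) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  d <- ncol(moving)
  if (!all(dim(moving) == dim(fixed)))
    stop("moving and fixed landmark sets must have equal count and dimension")
  if (nrow(moving) < 1L) stop("need at least one landmark pair")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("landmark coordinates must be finite")
  if (is.numeric(covariance) && length(covariance) == 1L) {
    if (covariance <= 0) stop("isotropic covariance must be positive")
  } else if (is.list(covariance)) {
    if (length(covariance) != nrow(moving))
      stop("need one covariance per landmark pair")
    ok <- vapply(covariance, function(S) {
      is.matrix(S) && all(dim(S) == d) && all(abs(S - t(S)) < 1e-12) &&
        all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0)
    }, logical(1))
    if (!all(ok)) stop("every covariance matrix must be symmetric positive-definite")
  } else stop("covariance must be a positive scalar or a list of SPD matrices")
  structure(list(moving = moving, fixed = fixed, covariance = covariance),
            class = "lg_corr")
}

#' @export
print.lg_corr <- function(x, ...) {
  cat("<lg_corr> ", nrow(x$moving), " landmark pairs in ", ncol(x$moving),
      "D; mean |y - x| = ",
      format(mean(sqrt(rowSums((x$fixed - x$moving)^2))), digits = 4),
      " mm\n", sep = "")
  invisible(x)
}

#' Gaussian reproducing-kernel matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / (2 sigma^2))`, the kernel that turns
#' landmark momenta into a smooth velocity field. Symmetric with unit
#' diagonal when both point sets coincide.
#'
#' @param points_a,points_b point matrices (`n x d`, `m x d`).
#' @param sigma kernel width in mm (> 0).
#' @return `n x m` kernel matrix.
#' @export
kernel_matrix <- function(points_a, points_b, sigma) {
  stopifnot(sigma > 0)
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Landmark Hamiltonian
#'
#' `H(q, p) = 1/2 sum_ij p_i . p_j K(q_i, q_j)`; conserved along geodesics,
#' used to monitor integration accuracy.
#'
#' @param q,p `N x d` positions and momenta.
#' @param sigma kernel width (mm).
#' @return Scalar energy.
#' @export
hamiltonian <- function(q, p, sigma) {
  K <- kernel_matrix(q, q, sigma)
  0.5 * sum(p * (K %*% p))
}

# right-hand side of the canonical landmark system:
#   dq_i/dt =  sum_j K(q_i, q_j) p_j
#   dp_i/dt = -sum_j (p_i . p_j) grad_{q_i} K(q_i, q_j)
shooting_rhs <- function(q, p, sigma) {
  K <- kernel_matrix(q, q, sigma)
  dq <- K %*% p
  P2K <- tcrossprod(p) * K
  d <- ncol(q)
  dp <- matrix(0, nrow(q), d)
  for (k in seq_len(d)) {
    Dk <- outer(q[, k], q[, k], "-")
    dp[, k] <- rowSums(P2K * Dk) / sigma^2
  }
  list(dq = dq, dp = dp)
}

# vector-Jacobian product of the rhs: given adjoint weights (a on dq rows,
# b on dp rows) return gradients of sum(a * dq) + sum(b * dp) wrt (q, p)
shooting_vjp <- function(q, p, a, b, sigma) {
  N <- nrow(q); d <- ncol(q)
  s2 <- sigma^2
  K <- kernel_matrix(q, q, sigma)
  P2 <- tcrossprod(p)
  AP <- tcrossprod(a, p)             # a_i . p_j
  P2K <- P2 * K
  B <- matrix(0, N, N)               # b_i . (q_i - q_j)
  Dk <- vector("list", d)
  for (k in seq_len(d)) {
    Dk[[k]] <- outer(q[, k], q[, k], "-")
    B <- B + b[, k] * Dk[[k]]
  }
  APs <- AP + t(AP)
  Bs <- B + t(B)
  KB <- K * B
  gq <- matrix(0, N, d)
  gp <- K %*% a + ((KB + K * t(B)) %*% p) / s2
  rsP2K <- rowSums(P2K)
  for (k in seq_len(d)) {
    gq[, k] <- -rowSums(K * APs * Dk[[k]]) / s2 -
      rowSums(P2K * Bs * Dk[[k]]) / s2^2 +
      (b[, k] * rsP2K - P2K %*% b[, k]) / s2
  }
  list(gq = gq, gp = gp)
}

# one RK4 step; returns the new state and (optionally) the stage inputs
# needed by the discrete adjoint
rk4_step <- function(q, p, h, sigma, keep_stages = FALSE) {
  k1 <- shooting_rhs(q, p, sigma)
  q2 <- q + h / 2 * k1$dq; p2 <- p + h / 2 * k1$dp
  k2 <- shooting_rhs(q2, p2, sigma)
  q3 <- q + h / 2 * k2$dq; p3 <- p + h / 2 * k2$dp
  k3 <- shooting_rhs(q3, p3, sigma)
  q4 <- q + h * k3$dq; p4 <- p + h * k3$dp
  k4 <- shooting_rhs(q4, p4, sigma)
  qn <- q + h / 6 * (k1$dq + 2 * k2$dq + 2 * k3$dq + k4$dq)
  pn <- p + h / 6 * (k1$dp + 2 * k2$dp + 2 * k3$dp + k4$dp)
  out <- list(q = qn, p = pn)
  if (keep_stages)
    out$stages <- list(u1 = list(q = q, p = p), u2 = list(q = q2, p = p2),
                       u3 = list(q = q3, p = p3), u4 = list(q = q4, p = p4))
  out
}

#' Integrate the landmark geodesic from an initial momentum
#'
#' Runs the canonical Hamiltonian system forward from `t = 0` to `t = 1`
#' with a classical Runge-Kutta (RK4) scheme on a uniform time grid. The
#' Hamiltonian is conserved along the exact flow, so its drift measures
#' integration error.
#'
#' @param q0 `N x d` initial landmark positions (mm).
#' @param p0 `N x d` initial momenta.
#' @param sigma Gaussian kernel width (mm).
#' @param steps number of RK4 steps (>= 1; default 20).
#' @return An object of class `lg_shooting` with fields `times`
#'   (`steps + 1` instants), `q`, `p` (arrays `steps+1 x N x d`) and
#'   `sigma`.
#' @export
shoot <- function(q0, p0, sigma, steps = 20L) {
  q0 <- as.matrix(q0); p0 <- as.matrix(p0)
  stopifnot(steps >= 1, all(dim(q0) == dim(p0)))
  if (!all(is.finite(q0)) || !all(is.finite(p0)))
    stop("non-finite shooting inputs")
  N <- nrow(q0); d <- ncol(q0)
  h <- 1 / steps
  qs <- array(0, c(steps + 1, N, d))
  ps <- array(0, c(steps + 1, N, d))
  qs[1, , ] <- q0; ps[1, , ] <- p0
  q <- q0; p <- p0
  for (s in seq_len(steps)) {
    st <- rk4_step(q, p, h, sigma)
    q <- st$q; p <- st$p
    qs[s + 1, , ] <- q; ps[s + 1, , ] <- p
  }
  structure(list(times = seq(0, 1, length.out = steps + 1),
                 q = qs, p = ps, sigma = sigma),
            class = "lg_shooting")
}

#' @export
print.lg_shooting <- function(x, ...) {
  N <- dim(x$q)[2]
  h0 <- hamiltonian(knot_state(x, 1)$q, knot_state(x, 1)$p, x$sigma)
  h1 <- hamiltonian(knot_state(x, length(x$times))$q,
                    knot_state(x, length(x$times))$p, x$sigma)
  cat("<lg_shooting> ", N, " landmarks, ", length(x$times) - 1,
      " RK4 steps, sigma = ", x$sigma, " mm; H(0) = ",
      format(h0, digits = 6), ", H(1) = ", format(h1, digits = 6), "\n",
      sep = "")
  invisible(x)
}

knot_state <- function(state, i) {
  d <- dim(state$q)[3]
  list(q = matrix(state$q[i, , ], ncol = d),
       p = matrix(state$p[i, , ], ncol = d))
}

# (q, p) linearly interpolated at an arbitrary time in [0, 1]
state_at_time <- function(state, t) {
  Tn <- length(state$times) - 1
  s <- max(0, min(1, t)) * Tn
  i0 <- floor(s)
  if (i0 >= Tn) return(knot_state(state, Tn + 1))
  f <- s - i0
  a <- knot_state(state, i0 + 1)
  b <- knot_state(state, i0 + 2)
  list(q = (1 - f) * a$q + f * b$q, p = (1 - f) * a$p + f * b$p)
}

# objective and its gradient wrt p0 under shooting:
#   J(p0) = 1/2 p0' K(q0) p0 + sum_n (y_n - q_n(1))' Sigma_n^{-1} (y_n - q_n(1))
shooting_objective <- function(p0, corr, sigma, steps, want_grad = TRUE) {
  q0 <- corr$moving; y <- corr$fixed
  N <- nrow(q0); d <- ncol(q0)
  h <- 1 / steps
  K0 <- kernel_matrix(q0, q0, sigma)
  reg <- 0.5 * sum(p0 * (K0 %*% p0))
  q <- q0; p <- p0
  stages <- if (want_grad) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    st <- rk4_step(q, p, h, sigma, keep_stages = want_grad)
    if (want_grad) stages[[s]] <- st$stages
    q <- st$q; p <- st$p
  }
  e <- y - q
  if (is.list(corr$covariance)) {
    Sie <- t(vapply(seq_len(N),
                    function(n) solve(corr$covariance[[n]], e[n, ]),
                    numeric(d)))
    if (d == 1L) Sie <- t(Sie)
    match_term <- sum(e * Sie)
  } else {
    Sie <- e / corr$covariance
    match_term <- sum(e * Sie)
  }
  J <- reg + match_term
  if (!want_grad)
    return(list(value = J, q1 = q, match = match_term))
  # discrete adjoint back through the RK4 steps
  aq <- -2 * Sie                      # dJ/dq(1)
  ap <- matrix(0, N, d)
  for (s in rev(seq_len(steps))) {
    u <- stages[[s]]
    gk4 <- list(q = h / 6 * aq, p = h / 6 * ap)
    v4 <- shooting_vjp(u$u4$q, u$u4$p, gk4$q, gk4$p, sigma)
    gk3 <- list(q = 2 * h / 6 * aq + h * v4$gq,
                p = 2 * h / 6 * ap + h * v4$gp)
    v3 <- shooting_vjp(u$u3$q, u$u3$p, gk3$q, gk3$p, sigma)
    gk2 <- list(q = 2 * h / 6 * aq + h / 2 * v3$gq,
                p = 2 * h / 6 * ap + h / 2 * v3$gp)
    v2 <- shooting_vjp(u$u2$q, u$u2$p, gk2$q, gk2$p, sigma)
    gk1 <- list(q = h / 6 * aq + h / 2 * v2$gq,
                p = h / 6 * ap + h / 2 * v2$gp)
    v1 <- shooting_vjp(u$u1$q, u$u1$p, gk1$q, gk1$p, sigma)
    aq <- aq + v1$gq + v2$gq + v3$gq + v4$gq
    ap <- ap + v1$gp + v2$gp + v3$gp + v4$gp
  }
  grad <- K0 %*% p0 + ap
  list(value = J, grad = grad, q1 = q, match = match_term)
}

#' Estimate the initial momentum matching a landmark correspondence
#'
#' Gradient-based minimization of the geodesic-shooting objective
#' `J(p0) = 1/2 p0' K(q0) p0 + sum_n Mahalanobis(y_n, q_n(1))`, with
#' gradients obtained by the discrete adjoint of the RK4 integrator.
#' The default optimizer is gradient descent with a backtracking
#' (Armijo) line search; `method = "lbfgs"` hands the same objective and
#' gradient to [stats::optim()].
#'
#' @param corr an [landmark_correspondence()], already in the initially
#'   aligned frame.
#' @param sigma Gaussian kernel width (mm).
#' @param steps RK4 steps for each shoot (default 20).
#' @param max_iter iteration budget (default 200).
#' @param step_size initial line-search step (default 1).
#' @param tol stop when the relative objective decrease falls below this
#'   (default 1e-6).
#' @param method `"gd"` (default) or `"lbfgs"`.
#' @return An object of class `lg_match`: `state` (the [shoot()] result at
#'   the optimum), `p0`, `objective_trace`, `matching_error` (per-landmark
#'   Mahalanobis distance at `t = 1`) and `converged`.
#' @export
optimize_momentum <- function(corr, sigma, steps = 20L, max_iter = 200L,
                              step_size = 1, tol = 1e-6,
                              method = c("gd", "lbfgs")) {
  stopifnot(inherits(corr, "lg_corr"), sigma > 0, steps >= 1,
            max_iter >= 1, step_size > 0)
  method <- match.arg(method)
  N <- nrow(corr$moving); d <- ncol(corr$moving)
  p0 <- matrix(0, N, d)
  if (method == "lbfgs") {
    fn <- function(v) shooting_objective(matrix(v, N, d), corr, sigma, steps,
                                         want_grad = FALSE)$value
    gr <- function(v) as.vector(shooting_objective(matrix(v, N, d), corr,
                                                   sigma, steps)$grad)
    J0 <- fn(as.vector(p0))
    opt <- stats::optim(as.vector(p0), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1e4))
    p0 <- matrix(opt$par, N, d)
    trace <- c(J0, min(J0, opt$value))
    converged <- opt$convergence == 0
  } else {
    ob <- shooting_objective(p0, corr, sigma, steps)
    if (!is.finite(ob$value))
      stop("objective diverged; try a smaller step_size or a larger covariance")
    trace <- ob$value
    t_ls <- step_size
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      g <- ob$grad
      gnorm2 <- sum(g^2)
      if (gnorm2 < 1e-20) { converged <- TRUE; break }
      accepted <- FALSE
      for (bt in 1:40) {
        cand <- p0 - t_ls * g
        obc <- shooting_objective(cand, corr, sigma, steps)
        if (is.finite(obc$value) &&
            obc$value <= ob$value - 1e-4 * t_ls * gnorm2) {
          accepted <- TRUE
          break
        }
        t_ls <- t_ls / 2
      }
      if (!accepted) { converged <- TRUE; break }
      rel <- (ob$value - obc$value) / max(abs(ob$value), 1e-12)
      p0 <- cand
      ob <- obc
      trace <- c(trace, ob$value)
      t_ls <- t_ls * 2
      if (rel < tol) { converged <- TRUE; break }
    }
    if (!is.finite(ob$value))
      stop("objective diverged; try a smaller step_size or a larger covariance")
  }
  state <- shoot(corr$moving, p0, sigma, steps)
  e <- corr$fixed - knot_state(state, steps + 1)$q
  if (is.list(corr$covariance)) {
    merr <- sqrt(vapply(seq_len(N), function(n)
      sum(e[n, ] * solve(corr$covariance[[n]], e[n, ])), numeric(1)))
  } else {
    merr <- sqrt(rowSums(e^2) / corr$covariance)
  }
  structure(list(state = state, p0 = p0, objective_trace = trace,
                 matching_error = merr, converged = converged,
                 corr = corr),
            class = "lg_match")
}

#' @export
print.lg_match <- function(x, ...) {
  cat("<lg_match> ", nrow(x$p0), " landmarks; objective ",
      format(x$objective_trace[1], digits = 6), " -> ",
      format(x$objective_trace[length(x$objective_trace)], digits = 6),
      " in ", length(x$objective_trace) - 1, " accepted steps; mean endpoint",
      " error ", format(mean(x$matching_error), digits = 4),
      " (Mahalanobis)\n", sep = "")
  invisible(x)
}

# velocity field induced by the (interpolated) landmark trajectory at time t
velocity_at <- function(state, pts, t) {
  st <- state_at_time(state, t)
  K <- kernel_matrix(pts, st$q, state$sigma)
  K %*% st$p
}

# advect arbitrary points through the flow; direction "forward" integrates
# v from t=0 to 1, "reverse" integrates -v along the time-reversed path
flow_points <- function(state, pts, direction = c("forward", "reverse"),
                        chunk = 4096L) {
  direction <- match.arg(direction)
  steps <- length(state$times) - 1
  h <- 1 / steps
  n <- nrow(pts)
  out <- matrix(0, n, ncol(pts))
  vel <- function(x, s) {
    if (direction == "forward") velocity_at(state, x, s)
    else -velocity_at(state, x, 1 - s)
  }
  starts <- seq(1, n, by = chunk)
  for (b in starts) {
    ix <- b:min(b + chunk - 1, n)
    x <- pts[ix, , drop = FALSE]
    for (s in seq_len(steps)) {
      t0 <- (s - 1) * h
      k1 <- vel(x, t0)
      k2 <- vel(x + h / 2 * k1, t0 + h / 2)
      k3 <- vel(x + h / 2 * k2, t0 + h / 2)
      k4 <- vel(x + h * k3, t0 + h)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[ix, ] <- x
  }
  out
}

#' Rasterize a shooting solution into a dense displacement field
#'
#' Advects every grid point through the kernel-interpolated velocity field
#' of the optimal landmark trajectory. `direction = "forward"` integrates
#' from `t = 0` to `1` giving `D(x) = phi(x, 1) - x`; `direction =
#' "reverse"` advects along the sign-flipped, time-reversed velocity,
#' giving the matching reverse field `D^{-1}` (an independently
#' integrated reversed flow, not a numerical inversion of the forward
#' field).
#'
#' @param state an [shoot()] / [optimize_momentum()] trajectory.
#' @param grid target [lg_grid()].
#' @param direction `"forward"` or `"reverse"`.
#' @param domain domain tag for the resulting field (defaults to
#'   `"subject"` for forward, `"template"` for reverse).
#' @return An [displacement_field()].
#' @export
rasterize_field <- function(state, grid, direction = c("forward", "reverse"),
                            domain = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(state, "lg_shooting"), inherits(grid, "lg_grid"))
  if (is.null(domain))
    domain <- if (direction == "forward") "subject" else "template"
  pts <- grid_points(grid)
  ends <- flow_points(state, pts, direction)
  displacement_field(grid, matrix_to_field_values(grid, ends - pts),
                     domain = domain, direction = direction)
}

#' Register one region's landmarks and rasterize both dense fields
#'
#' Convenience composition of [optimize_momentum()] and
#' [rasterize_field()] in both directions for a single region whose
#' correspondence is already in the initially aligned frame.
#'
#' @param corr an [landmark_correspondence()].
#' @param sigma kernel width (mm).
#' @param grid_subject grid for the forward field.
#' @param grid_template grid for the reverse field.
#' @param steps,max_iter,step_size,tol,method passed to
#'   [optimize_momentum()].
#' @param max_landmarks cap on landmark pairs; larger sets are thinned
#'   uniformly before optimization (default 2000).
#' @return List with elements `forward`, `reverse` (displacement fields)
#'   and `match` (the `lg_match`).
#' @export
register_region <- function(corr, sigma, grid_subject, grid_template,
                            steps = 20L, max_iter = 200L, step_size = 1,
                            tol = 1e-6, method = "gd", max_landmarks = 2000L) {
  N <- nrow(corr$moving)
  if (N > max_landmarks) {
    keep <- unique(round(seq(1, N, length.out = max_landmarks)))
    cv <- if (is.list(corr$covariance)) corr$covariance[keep] else corr$covariance
    corr <- landmark_correspondence(corr$moving[keep, , drop = FALSE],
                                    corr$fixed[keep, , drop = FALSE], cv)
  }
  match <- optimize_momentum(corr, sigma, steps = steps, max_iter = max_iter,
                             step_size = step_size, tol = tol, method = method)
  list(forward = rasterize_field(match$state, grid_subject, "forward"),
       reverse = rasterize_field(match$state, grid_template, "reverse"),
       match = match)
}
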