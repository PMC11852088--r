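library(reacharm)

# Independent numerical oracles used across the test files. These are
# deliberately written from first principles (finite differences, textbook
# recursions, exhaustive enumeration) and share no code with the package
# implementations they check.

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# central finite-difference Jacobian of a vector function
fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# textbook finite-horizon discrete LQR backward Riccati recursion,
# returning gains in the u = L x convention (negative feedback included)
lqr_gains <- function(A, B, Qlist, R) {
  N <- length(Qlist)
  S <- Qlist[[N]]
  L <- vector("list", N - 1)
  for (k in (N - 1):1) {
    G <- R + t(B) %*% S %*% B
    Lk <- solve(G, t(B) %*% S %*% A)
    S <- Qlist[[k]] + t(A) %*% S %*% (A - B %*% Lk)
    L[[k]] <- -Lk
  }
  L
}

# discrete algebraic Riccati equation for the filter, solved by fixed-point
# iteration; returns the stationary predictive Kalman gain K = A P H'(HPH'+W)^-1
dare_kalman <- function(A, H, V, W, iters = 10000, tol = 1e-14) {
  P <- V
  for (i in seq_len(iters)) {
    K <- A %*% P %*% t(H) %*% solve(H %*% P %*% t(H) + W)
    Pn <- A %*% P %*% t(A) - K %*% H %*% P %*% t(A) + V
    if (max(abs(Pn - P)) < tol) { P <- Pn; break }
    P <- Pn
  }
  A %*% P %*% t(H) %*% solve(H %*% P %*% t(H) + W)
}

# two-link joint accelerations from the Lagrangian, evaluated numerically:
# M from the kinetic-energy quadratic form (exact for unit velocities),
# Coriolis from Christoffel symbols of finite-differenced dM/dq.
# Independent path: kinetic energy is built from link COM velocities.
lagrangian_accel <- function(p, q, qd, tau = c(0, 0), endpoint_force = c(0, 0),
                             hand_mass = 0) {
  T_of <- function(q, qd) {
    # COM positions differentiated by hand (chain rule)
    v1 <- p$d1 * qd[1] * c(-sin(q[1]), cos(q[1]))
    w1 <- qd[1]
    ve <- p$l1 * qd[1] * c(-sin(q[1]), cos(q[1]))
    v2 <- ve + p$d2 * (qd[1] + qd[2]) * c(-sin(q[1] + q[2]), cos(q[1] + q[2]))
    w2 <- qd[1] + qd[2]
    vh <- ve + p$l2 * (qd[1] + qd[2]) * c(-sin(q[1] + q[2]), cos(q[1] + q[2]))
    0.5 * (p$m1 * sum(v1^2) + p$I1 * w1^2 + p$m2 * sum(v2^2) + p$I2 * w2^2 +
             hand_mass * sum(vh^2))
  }
  # mass matrix from the quadratic form
  M <- matrix(0, 2, 2)
  e <- diag(2)
  for (i in 1:2) M[i, i] <- 2 * T_of(q, e[i, ])
  M[1, 2] <- M[2, 1] <- T_of(q, c(1, 1)) - 0.5 * (M[1, 1] + M[2, 2])
  # Christoffel symbols from dM/dq (finite differences)
  h <- 1e-6
  dM <- lapply(1:2, function(k) {
    qp <- q; qp[k] <- qp[k] + h
    qm <- q; qm[k] <- qm[k] - h
    Mp <- matrix(0, 2, 2); Mm <- matrix(0, 2, 2)
    for (i in 1:2) { Mp[i, i] <- 2 * T_of(qp, e[i, ]); Mm[i, i] <- 2 * T_of(qm, e[i, ]) }
    Mp[1, 2] <- Mp[2, 1] <- T_of(qp, c(1, 1)) - 0.5 * (Mp[1, 1] + Mp[2, 2])
    Mm[1, 2] <- Mm[2, 1] <- T_of(qm, c(1, 1)) - 0.5 * (Mm[1, 1] + Mm[2, 2])
    (Mp - Mm) / (2 * h)
  })
  cvec <- numeric(2)
  for (i in 1:2) {
    for (j in 1:2) {
      for (k in 1:2) {
        cvec[i] <- cvec[i] +
          0.5 * (dM[[k]][i, j] + dM[[j]][i, k] - dM[[i]][j, k]) * qd[j] * qd[k]
      }
    }
  }
  # endpoint force enters through the hand Jacobian (finite-differenced FK)
  fk <- function(q) {
    p$base + p$l1 * c(cos(q[1]), sin(q[1])) +
      p$l2 * c(cos(q[1] + q[2]), sin(q[1] + q[2]))
  }
  J <- fd_jacobian(fk, q, h = 1e-7)
  as.numeric(solve(M, tau + as.numeric(t(J) %*% endpoint_force) - cvec))
}

# exhaustive active-set oracle for small non-negative least squares:
# enumerates all support sets and returns the best feasible objective
nnls_oracle <- function(B, f) {
  n <- ncol(B)
  best <- list(value = sum(f^2), x = rep(0, n))
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    sol <- tryCatch(qr.solve(B[, idx, drop = FALSE], f), error = function(e) NULL)
    if (is.null(sol) || any(sol < -1e-10)) next
    x <- rep(0, n)
    x[idx] <- sol
    v <- sum((B %*% x - f)^2)
    if (v < best$value) best <- list(value = v, x = x)
  }
  best
}

# minimum-jerk point-to-point trajectory (closed form)
min_jerk <- function(from, to, Tmove, n) {
  s <- seq(0, 1, length.out = n)
  shape <- 10 * s^3 - 15 * s^4 + 6 * s^5
  dshape <- (30 * s^2 - 60 * s^3 + 30 * s^4) / Tmove
  list(pos = outer(shape, to - from) + matrix(from, n, 2, byrow = TRUE),
       vel = outer(dshape, to - from))
}

# small internal-model parameter set for fast unit tests
fast_params <- function(...) {
  internal_model_params(N = 61, D = 11, ...)
}

# shared fixtures (built once per test run)
test_arm <- arm_model_default()
test_syn <- learn_synergies(test_arm, seed = 1)
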