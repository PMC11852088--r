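# Mid-level dimension expansion: muscle synergies.
#
# A synergy is a fixed non-negative co-activation pattern across the six
# muscles; its action in task space is the hand-force vector produced by
# activating the pattern isometrically. Four synergies are learned offline
# (optimal static load sharing over sampled force directions, reduced by
# non-negative matrix factorization) and stored together with their
# task-space basis vectors. Online, the high-level 2-D command is decomposed
# onto the basis by non-negative least squares and expanded to six
# non-negative neural excitations.

#' Minimum-effort static muscle activations for a desired hand force
#'
#' Solves the isometric muscle load-sharing problem
#' \eqn{\min \|a\|^2} subject to the statics map producing `force` at the
#' posture, \eqn{0 \le a \le 1}, with the force-velocity factor at 1
#' (isometric). The equality constraint is enforced through a heavily
#' weighted non-negative least-squares formulation; the achieved force is
#' verified to 1e-6 N.
#'
#' @param model `arm_model`
#' @param q posture (rad)
#' @param force desired static hand force (N, length 2)
#' @return 6-vector of activations in [0, 1]
#' @export
optimal_static_activations <- function(model, q, force) {
  stop_if(length(force) != 2 || any(!is.finite(force)), "force must be a finite 2-vector")
  Phi <- arm_statics_map(q, model, return_matrix = TRUE)
  if (sqrt(sum(force^2)) < 1e-15) return(rep(0, 6))
  w <- 1e4
  Cmat <- rbind(w * Phi, diag(6))
  dvec <- c(w * force, rep(0, 6))
  a <- nnls_solve(Cmat, dvec)$x
  if (any(a > 1 + 1e-9)) {
    # the unbounded-above minimum-norm solution leaves the box; retry with
    # the upper bound active (penalized box-constrained least squares)
    obj <- function(a) sum((w * (as.numeric(Phi %*% a) - force))^2) + sum(a^2)
    gr <- function(a) as.numeric(2 * w^2 * t(Phi) %*% (as.numeric(Phi %*% a) - force)) + 2 * a
    fit <- stats::optim(pmin(a, 1), obj, gr, method = "L-BFGS-B",
                        lower = 0, upper = 1,
                        control = list(maxit = 500, factr = 10))
    a <- fit$par
  }
  achieved <- as.numeric(Phi %*% a)
  if (max(abs(achieved - force)) > 1e-6 || any(a > 1 + 1e-9)) {
    dir <- force / sqrt(sum(force^2))
    fmax_dir <- .max_feasible_force(Phi, dir)
    stop(sprintf(paste0("requested hand force (%.2f, %.2f) N is infeasible at this posture; ",
                        "maximum achievable magnitude along that direction is %.2f N"),
                 force[1], force[2], fmax_dir), call. = FALSE)
  }
  pmin(a, 1)
}

# Lawson-Hanson active-set non-negative least squares:
# min ||C x - d||^2 subject to x >= 0. Standard algorithm with a generous
# iteration cap; returns the solution and the squared residual norm.
nnls_solve <- function(C, d, itmax = NULL) {
  n <- ncol(C)
  if (is.null(itmax)) itmax <- max(100L, 30L * n)
  nC <- norm(C, "2")
  tol <- 10 * .Machine$double.eps * nC * (max(dim(C)) + 1)
  # dual (gradient) tolerance must scale with the data magnitude, otherwise
  # round-off-level gradients at the optimum trigger degenerate cycling
  tol_w <- tol * max(1, sqrt(sum(d^2))) * max(1, nC)
  x <- numeric(n)
  P <- logical(n)
  w <- as.numeric(t(C) %*% (d - C %*% x))
  it <- 0
  blocked <- logical(n)   # indices that produced a zero-progress step
  while (any(!P & !blocked) && any(w[!P & !blocked] > tol_w)) {
    cand <- which(!P & !blocked)
    new_i <- cand[which.max(w[cand])]
    P[new_i] <- TRUE
    progressed <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.solve(C[, P, drop = FALSE], d)
      if (all(z[P] > tol)) break
      it <- it + 1
      if (it > itmax) stop("NNLS iteration count exceeded", call. = FALSE)
      Q <- P & (z <= tol)
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      if (!is.finite(alpha)) alpha <- 0
      if (alpha <= 0 && Q[new_i]) progressed <- FALSE
      x <- x + alpha * (z - x)
      P <- P & (x > tol)
      if (!progressed) break
    }
    if (!progressed) { blocked[new_i] <- TRUE; next }
    x <- z
    blocked[] <- FALSE
    w <- as.numeric(t(C) %*% (d - C %*% x))
    it <- it + 1
    if (it > itmax) stop("NNLS iteration count exceeded", call. = FALSE)
  }
  resid <- d - as.numeric(C %*% x)
  list(x = x, resid_norm2 = sum(resid^2))
}

# Largest force magnitude achievable along unit direction `dir` with
# activations in [0,1]: bisection on the magnitude, feasibility tested by
# box-constrained least squares on the statics map.
.max_feasible_force <- function(Phi, dir, tol = 1e-3) {
  feasible <- function(s) {
    target <- s * dir
    obj <- function(a) sum((as.numeric(Phi %*% a) - target)^2)
    gr <- function(a) as.numeric(2 * t(Phi) %*% (as.numeric(Phi %*% a) - target))
    fit <- stats::optim(rep(0.5, ncol(Phi)), obj, gr, method = "L-BFGS-B",
                        lower = 0, upper = 1, control = list(maxit = 200))
    fit$value < 1e-10
  }
  lo <- 0; hi <- 1
  while (feasible(hi) && hi < 1e5) { lo <- hi; hi <- hi * 2 }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Multiplicative-update non-negative matrix factorization (Frobenius loss).
# V (n x m, non-negative) ~ W (n x r) %*% H (r x m). Deterministic given the
# supplied seed. Small problems only (here 6 x n_directions).
.nmf <- function(V, r, seed = 1, max_iter = 2000, tol = 1e-10) {
  stopifnot(all(V >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  sc <- sqrt(mean(V) / r)
  W <- matrix(stats::runif(n * r, 0.1, 1), n, r) * sc
  H <- matrix(stats::runif(r * m, 0.1, 1), r, m) * sc
  eps <- 1e-12
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    if (it %% 25 == 0) {
      err <- sum((V - W %*% H)^2)
      if (err_old - err < tol * max(1, err)) break
      err_old <- err
    }
  }
  list(W = W, H = H, sse = sum((V - W %*% H)^2))
}

#' Learn a muscle synergy set offline
#'
#' Samples minimum-effort static activation patterns for `n_directions` unit
#' hand forces equally spaced on the circle at the reference posture, reduces
#' them to `n_synergies` non-negative components by NMF, normalizes each
#' synergy to unit maximum element, and computes each synergy's task-space
#' hand-force basis vector through the isometric statics map.
#'
#' @param model `arm_model`
#' @param reference_q reference posture (rad); defaults to the model's
#' @param n_directions number of sampled force directions (>= `n_synergies`)
#' @param n_synergies number of synergies (4 by default)
#' @param seed integer seed for the NMF initialization (deterministic result)
#' @return an object of class `synergy_set`: `S` (6 x n_synergies,
#'   non-negative, unit max element per column), `B` (2 x n_synergies basis
#'   of synergy-produced hand forces at the reference posture, N per unit
#'   synergy activation), `reference_q`, `recon_r2` (reconstruction R^2 of
#'   the sampled activations)
#' @export
learn_synergies <- function(model, reference_q = NULL, n_directions = 16,
                            n_synergies = 4, seed = 1) {
  if (is.null(reference_q)) reference_q <- model$reference_q
  stop_if(n_directions < n_synergies, "need at least as many directions as synergies")
  ang <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  Amat <- vapply(ang, function(th) {
    optimal_static_activations(model, reference_q, c(cos(th), sin(th)))
  }, numeric(6))
  fit <- .nmf(Amat, n_synergies, seed = seed)
  if (!all(is.finite(fit$W))) stop("synergy factorization did not converge", call. = FALSE)
  S <- fit$W
  scl <- apply(S, 2, max)
  stop_if(any(scl <= 0), "degenerate (all-zero) synergy produced")
  S <- sweep(S, 2, scl, "/")
  # order synergies by their task-space force direction for reproducibility
  Bref <- vapply(seq_len(n_synergies), function(i) {
    arm_statics_map(reference_q, model, S[, i])
  }, numeric(2))
  ord <- order(atan2(Bref[2, ], Bref[1, ]))
  S <- S[, ord, drop = FALSE]
  Bref <- Bref[, ord, drop = FALSE]
  recon <- fit$W %*% fit$H
  r2 <- 1 - sum((Amat - recon)^2) / sum((Amat - mean(Amat))^2)
  structure(list(S = S, B = Bref, reference_q = reference_q,
                 n_synergies = n_synergies, recon_r2 = r2),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("Muscle synergy set: %d synergies over %d muscles (reconstruction R^2 = %.3f)\n",
              x$n_synergies, nrow(x$S), x$recon_r2))
  invisible(x)
}

#' Task-space basis of a synergy set at a posture
#'
#' Recomputes each synergy's hand-force vector through the muscle geometry at
#' the current posture. At the reference posture this returns the stored
#' basis.
#'
#' @param synergies `synergy_set`
#' @param model `arm_model`
#' @param q posture (rad)
#' @return 2 x n_synergies basis matrix (N per unit synergy activation)
#' @export
task_basis <- function(synergies, model, q) {
  vapply(seq_len(ncol(synergies$S)), function(i) {
    arm_statics_map(q, model, synergies$S[, i])
  }, numeric(2))
}

#' Velocity-compensated task-force command
#'
#' Converts the abstract command into a desired hand force,
#' \eqn{F = u F_{max}}, and adds the task-space equivalent of the arm's
#' velocity-product (Coriolis/centrifugal) joint torques so that the
#' multi-link arm's velocity-dependent accelerations do not distort the
#' point-mass motion the high-level controller planned. The compensation is
#' exactly zero at zero joint velocity.
#'
#' @param u abstract command (2-vector)
#' @param state `arm_state`
#' @param model `arm_model`
#' @param fmax_abstract abstract force scale (N; the internal model's Fmax)
#' @return desired task-space force (N, length 2)
#' @export
compensate_velocity <- function(u, state, model, fmax_abstract = 1000) {
  base <- as.numeric(u) * fmax_abstract
  J <- hand_jacobian(state$q, model)
  if (abs(det(J)) < 1e-8) {
    warning("singular hand Jacobian; skipping velocity compensation", call. = FALSE)
    return(base)
  }
  cv <- arm_velocity_torques(model, state$q, state$qd)
  base + as.numeric(solve(t(J), cv))
}

#' Decompose a task force onto the synergy basis
#'
#' Non-negative least squares \eqn{\min_{C \ge 0} \|B C - u\|^2} via the
#' Lawson-Hanson active-set algorithm. Commands outside the positive cone of
#' the basis are projected onto the nearest achievable force (non-zero
#' residual, reported in the attribute).
#'
#' @param force task-space force command (N, length 2)
#' @param basis 2 x n basis matrix of synergy-produced forces
#' @return non-negative coefficient vector with attribute `residual`
#' @export
decompose_command <- function(force, basis) {
  stop_if(qr(basis)$rank < 2, "synergy basis does not span the task space")
  if (max(abs(force)) < 1e-300) {
    out <- rep(0, ncol(basis))
    attr(out, "residual") <- 0
    return(out)
  }
  fit <- nnls_solve(basis, as.numeric(force))
  out <- fit$x
  attr(out, "residual") <- sqrt(max(fit$resid_norm2, 0))
  out
}

#' Expand synergy coefficients to muscle excitations
#'
#' \eqn{e = S C}, clipped to [0, 1] before entering the muscle activation
#' dynamics; the pre-clip values are kept as an attribute for diagnostics.
#'
#' @param synergies `synergy_set`
#' @param coef non-negative coefficient vector
#' @return 6-vector of neural excitations in [0, 1]
#' @export
expand_to_excitations <- function(synergies, coef) {
  stop_if(any(coef < -1e-12), "synergy coefficients must be non-negative")
  raw <- as.numeric(synergies$S %*% pmax(coef, 0))
  e <- clip01(raw)
  attr(e, "pre_clip") <- raw
  e
}

#' Write a synergy set to a plain-text file
#'
#' Serializes the synergy matrix (rows = muscles, columns = synergies), the
#' reference-posture basis, and the reference posture as a commented
#' whitespace-delimited text file that [read_synergies()] can reload.
#'
#' @param synergies `synergy_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_synergies <- function(synergies, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# reacharm synergy set",
    sprintf("# n_synergies %d", synergies$n_synergies),
    sprintf("# reference_q %s", paste(format(synergies$reference_q, digits = 17), collapse = " ")),
    sprintf("# recon_r2 %s", format(synergies$recon_r2, digits = 17)),
    "# S: rows = muscles, columns = synergies"), con)
  utils::write.table(format(synergies$S, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("# B: rows = task dimensions (x, y), columns = synergies", con)
  utils::write.table(format(synergies$B, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a synergy set written by [write_synergies()]
#'
#' @param path file path
#' @return a `synergy_set`
#' @export
read_synergies <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getmeta <- function(key) {
    ln <- meta[grepl(paste0("^# ", key, " "), meta)]
    stop_if(length(ln) != 1, sprintf("missing '%s' in synergy file", key))
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln), "\\s+")[[1]])
  }
  n_syn <- as.integer(getmeta("n_synergies"))
  ref_q <- getmeta("reference_q")
  r2 <- getmeta("recon_r2")
  vals <- lapply(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+"), as.numeric)
  stop_if(length(vals) != 8, "synergy file must contain 6 muscle rows and 2 basis rows")
  S <- do.call(rbind, vals[1:6])
  B <- do.call(rbind, vals[7:8])
  structure(list(S = S, B = B, reference_q = ref_q,
                 n_synergies = n_syn, recon_r2 = r2),
            class = "synergy_set")
}
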