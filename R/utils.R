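#' @keywords internal
#' @useDynLib reacharm, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Small numerical helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite <- function(x, what = "value") {
  if (!all(is.finite(x))) stop(sprintf("non-finite %s", what), call. = FALSE)
  invisible(x)
}

is_psd <- function(M, tol = 1e-10) {
  if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

# Classical fixed-step RK4 for autonomous first-order ODEs written as
# deriv(state) -> d(state)/dt, both plain numeric vectors.
rk4_step <- function(state, deriv, dt) {
  k1 <- deriv(state)
  k2 <- deriv(state + 0.5 * dt * k1)
  k3 <- deriv(state + 0.5 * dt * k2)
  k4 <- deriv(state + dt * k3)
  state + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
}
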