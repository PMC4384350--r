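# Internal numeric helpers shared across the package. All angles are in
# radians internally; degrees appear only at user-facing interfaces.

v_norm <- function(v) sqrt(sum(v * v))

v_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

v_unit <- function(v) {
  n <- v_norm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angle into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi + 1e-15] <- pi
  y
}

# clamp to [-1, 1], erroring if farther than tol outside
clamp_cos <- function(x, tol = 1e-9, what = "cosine") {
  if (any(abs(x) > 1 + tol)) {
    stop(sprintf("infeasible geometry: |%s| = %.6g exceeds 1", what,
                 max(abs(x))), call. = FALSE)
  }
  pmin(1, pmax(-1, x))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
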