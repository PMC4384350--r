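#' Angular domains: unions of closed intervals and singletons
#'
#' Torsion-angle constraints are expressed as a domain formed by the union
#' of disjoint closed intervals and singleton values on the circle,
#' represented in radians within `(-pi, pi]`. Intervals given with
#' `lower > upper` are interpreted as wrapping through the +/- pi cut and
#' are split into two pieces. Singletons are stored as zero-width
#' intervals.
#'
#' @param intervals two-column matrix (or vector of length 2) of interval
#'   bounds, one interval per row; `NULL` for none.
#' @param singletons numeric vector of singleton angles; `NULL` for none.
#' @param degrees logical; if `TRUE`, inputs are in degrees.
#' @return An object of class `angle_domain`: a list with numeric vectors
#'   `lower` and `upper` (radians, sorted, pairwise disjoint).
#' @examples
#' angle_domain(c(-90, -30), degrees = TRUE)            # helical phi window
#' angle_domain(rbind(c(50, 180), c(-180, -170)), degrees = TRUE)
#' @export
angle_domain <- function(intervals = NULL, singletons = NULL, degrees = FALSE) {
  lo <- numeric(0)
  hi <- numeric(0)
  if (!is.null(intervals)) {
    if (is.vector(intervals)) intervals <- matrix(intervals, ncol = 2, byrow = TRUE)
    if (ncol(intervals) != 2L) stop("'intervals' must have two columns")
    if (degrees) intervals <- deg2rad(intervals)
    for (r in seq_len(nrow(intervals))) {
      a <- intervals[r, 1L]; b <- intervals[r, 2L]
      if (b - a >= 2 * pi - 1e-12) { a <- -pi; b <- pi }
      aw <- wrap_angle(a); bw <- wrap_angle(b)
      # keep an endpoint sitting exactly on the cut on its natural side
      if (abs(a - (-pi)) < 1e-12) aw <- -pi
      if (aw <= bw + 1e-15) {
        lo <- c(lo, aw); hi <- c(hi, bw)
      } else { # wraps through the +/- pi cut
        lo <- c(lo, aw, -pi); hi <- c(hi, pi, bw)
      }
    }
  }
  if (!is.null(singletons)) {
    if (degrees) singletons <- deg2rad(singletons)
    s <- wrap_angle(singletons)
    lo <- c(lo, s); hi <- c(hi, s)
  }
  if (length(lo) == 0L) stop("empty angle domain")
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  # merge touching/overlapping pieces so members are pairwise disjoint
  mlo <- lo[1L]; mhi <- hi[1L]
  if (length(lo) > 1L) {
    for (r in 2L:length(lo)) {
      nlast <- length(mhi)
      if (lo[r] <= mhi[nlast] + 1e-12) {
        mhi[nlast] <- max(mhi[nlast], hi[r])
      } else {
        mlo <- c(mlo, lo[r]); mhi <- c(mhi, hi[r])
      }
    }
  }
  structure(list(lower = mlo, upper = mhi), class = "angle_domain")
}

#' @export
print.angle_domain <- function(x, ...) {
  parts <- ifelse(
    x$upper - x$lower < 1e-12,
    sprintf("{%.2f}", rad2deg(x$lower)),
    sprintf("[%.2f, %.2f]", rad2deg(x$lower), rad2deg(x$upper))
  )
  cat("angle domain (deg):", paste(parts, collapse = " U "), "\n")
  invisible(x)
}

#' Test whether an angle lies in a domain
#'
#' Containment is checked with an additive angular tolerance, inclusively,
#' and with proper handling of the circular cut at +/- pi. The sign of the
#' angle is respected: no folding of `x` onto `|x|` is performed.
#'
#' @param dom an [angle_domain()].
#' @param x angle in radians.
#' @param tol inclusive additive tolerance in radians (default 0).
#' @return logical.
#' @export
domain_contains <- function(dom, x, tol = 0) {
  stopifnot(inherits(dom, "angle_domain"))
  xw <- wrap_angle(x)
  for (cand in c(xw, xw - 2 * pi, xw + 2 * pi)) {
    if (any(dom$lower - tol <= cand & cand <= dom$upper + tol)) return(TRUE)
  }
  FALSE
}

#' Shift an angle domain by a constant offset
#'
#' Used to transport backbone phi/psi windows onto the torsions actually
#' branched over in the atom order (which differ from phi/psi by constant
#' covalent-geometry offsets).
#'
#' @param dom an [angle_domain()].
#' @param delta offset in radians.
#' @return a new [angle_domain()].
#' @export
domain_shift <- function(dom, delta) {
  stopifnot(inherits(dom, "angle_domain"))
  n <- length(dom$lower)
  iv <- cbind(dom$lower + delta, dom$upper + delta)
  sing <- dom$upper - dom$lower < 1e-12
  angle_domain(intervals = if (any(!sing)) iv[!sing, , drop = FALSE],
               singletons = if (any(sing)) iv[sing, 1L])
}

#' Mirror an angle domain through zero
#'
#' Returns the domain of `-x` for `x` in `dom` (reflection symmetry of a
#' torsion under a mirror image of the coordinates).
#'
#' @param dom an [angle_domain()].
#' @return a new [angle_domain()].
#' @export
domain_negate <- function(dom) {
  stopifnot(inherits(dom, "angle_domain"))
  iv <- cbind(-dom$upper, -dom$lower)
  sing <- dom$upper - dom$lower < 1e-12
  angle_domain(intervals = if (any(!sing)) iv[!sing, , drop = FALSE],
               singletons = if (any(sing)) iv[sing, 1L])
}

# range of cos(x) over the domain: used for the torsion->distance envelope
domain_cos_range <- function(dom) {
  cmin <- Inf; cmax <- -Inf
  for (r in seq_along(dom$lower)) {
    a <- dom$lower[r]; b <- dom$upper[r]
    vals <- cos(c(a, b))
    if (a <= 0 && 0 <= b) vals <- c(vals, 1)           # cos max at 0
    if (a <= -pi + 1e-15 || b >= pi - 1e-15) vals <- c(vals, -1)
    cmin <- min(cmin, vals); cmax <- max(cmax, vals)
  }
  c(cmin, cmax)
}

# which signs the domain admits (zero counts for both)
domain_signs <- function(dom) {
  c(neg = any(dom$lower < -1e-12),
    pos = any(dom$upper > 1e-12) ||
      any(abs(dom$lower - pi) < 1e-12 | abs(dom$upper - pi) < 1e-12),
    zero = any(dom$lower <= 1e-12 & dom$upper >= -1e-12))
}
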