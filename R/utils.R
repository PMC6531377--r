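# Internal numerical helpers shared across modules.

# Map angles (degrees) into [-180, 180).
wrap_deg <- function(x) ((x + 180) %% 360) - 180

# Map angles (radians) into [-pi, pi).
wrap_rad <- function(x) ((x + pi) %% (2 * pi)) - pi

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Draw von Mises variates
#'
#' Best-Fisher rejection sampler, vectorised over elements so that `mu` and
#' `kappa` may differ per draw (needed for conditional sampling in coupled
#' angular models). Concentrations numerically indistinguishable from zero
#' fall back to the circular uniform distribution.
#'
#' @param n number of draws.
#' @param mu mean direction(s), radians; recycled to length `n`.
#' @param kappa concentration(s) >= 0; recycled to length `n`.
#' @return numeric vector of angles in radians, wrapped to `[-pi, pi)`.
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-8
  if (any(unif)) out[unif] <- runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo)) {
    k <- kappa[todo]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    f <- numeric(length(todo))
    remaining <- seq_along(todo)
    while (length(remaining)) {
      m <- length(remaining)
      u1 <- runif(m); u2 <- runif(m)
      z <- cos(pi * u1)
      fr <- (1 + r[remaining] * z) / (r[remaining] + z)
      cc <- k[remaining] * (r[remaining] - fr)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      f[remaining[ok]] <- fr[ok]
      remaining <- remaining[!ok]
    }
    u3 <- runif(length(todo))
    out[todo] <- mu[todo] + sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
  }
  wrap_rad(out)
}

# Kabsch optimal rotation: returns the 3x3 rotation R minimising
# || (P - centroid_P) R - (Q - centroid_Q) ||^2 for row-wise coordinates.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

# Superpose coordinate matrix `mob` (atoms x 3) onto `ref` using the fit
# atoms in `fit_idx`; the transform is applied to all atoms.
superpose_frame <- function(mob, ref, fit_idx) {
  cm <- colMeans(mob[fit_idx, , drop = FALSE])
  cr <- colMeans(ref[fit_idx, , drop = FALSE])
  R <- kabsch_rotation(sweep(mob[fit_idx, , drop = FALSE], 2, cm),
                       sweep(ref[fit_idx, , drop = FALSE], 2, cr))
  sweep(sweep(mob, 2, cm) %*% R, 2, cr, `+`)
}

#' Signed dihedral angle from four points
#'
#' Standard atan2 formulation; vectorised over frames when the inputs are
#' `n x 3` matrices. Returns angles in degrees in `[-180, 180)`; frames whose
#' first or last atom triplet is collinear yield `NA` (the torsion is
#' undefined there).
#'
#' @param p1,p2,p3,p4 coordinate matrices (`n x 3`) or length-3 vectors.
#' @return numeric vector of dihedrals in degrees.
#' @export
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)) # 0: cis
dihedral_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- wrap_deg(rad2deg(atan2(y, x)))
  bad <- rowSums(n1^2) < 1e-14 | rowSums(n2^2) < 1e-14
  ang[bad] <- NA_real_
  ang
}

# Pairwise Euclidean distances between two coordinate matrices (rows).
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
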