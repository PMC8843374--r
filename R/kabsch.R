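# Kabsch superposition: least-squares rigid-body fit over proper rotations.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1; reflections forbidden) and
#' translation `t` minimizing the RMSD of `R %*% b + t` against `a` over all
#' paired points. Uses the SVD of the cross-covariance of the centered sets.
#'
#' @param a,b n x 3 coordinate matrices of paired points (n >= 3,
#'   non-collinear).
#' @return list with `R` (3 x 3), `t` (length-3), `rmsd`.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop_data("paired n x 3 coordinate sets required")
  if (nrow(a) < 3) stop_data("at least 3 point pairs required")
  if (anyNA(a) || anyNA(b)) stop_data("coordinates contain NA")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  H <- crossprod(bc, ac)           # maps b-frame onto a-frame
  sv <- svd(H)
  # collinear/degenerate: rotation about the point axis is unconstrained
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop_data("degenerate (collinear) geometry: rotation not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ca - as.vector(R %*% cb)
  fitted <- sweep(bc %*% t(R), 2, ca, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - a)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# apply a superposition to an n x 3 matrix
apply_transform <- function(x, R, t) {
  sweep(as.matrix(x) %*% t(R), 2, t, `+`)
}

# rotation angle (degrees) between two rotation matrices
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# RMSD of paired sets under a fixed (given) transform
rmsd_under <- function(a, b, R, t) {
  sqrt(mean(rowSums((apply_transform(b, R, t) - a)^2)))
}
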