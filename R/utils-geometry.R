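# Rigid-body geometry helpers shared by conformer dedup, pharmacophore
# alignment and the synthetic generator.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation (no scaling) mapping \code{X} onto
#' \code{Y} via singular value decomposition of the cross-covariance matrix,
#' with the usual reflection correction.
#'
#' @param X n x 3 moving coordinates.
#' @param Y n x 3 target coordinates.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3),
#'   \code{rmsd}; transformed points are \code{X \%*\% rotation + translation}
#'   (row-vector convention).
#' @export
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # row-vector convention: Xc %*% R
  fit <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((fit - Yc)^2)))
  list(rotation = R, translation = cy - as.numeric(cx %*% R), rmsd = rmsd)
}

#' Best-fit RMSD between two conformers of the same molecule
#'
#' Identity atom correspondence; heavy atoms only (the stored atoms).
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom after optimal superposition.
#' @export
bestFitRmsd <- function(a, b) kabsch(a, b)$rmsd

# Apply a rigid transform (row-vector convention).
applyTransform <- function(X, rotation, translation) {
  sweep(X %*% rotation, 2, translation, `+`)
}

# Random rotation matrix (uniform via QR of Gaussian), uses current RNG.
randomRotation <- function() {
  repeat {
    M <- matrix(stats::rnorm(9), 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-8) return(Q)
  }
}

# Rotate points about an axis through `origin` with direction `axis` by
# `angle` radians (Rodrigues).
rotateAboutAxis <- function(X, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  P <- sweep(X, 2, origin)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(P %*% R, 2, origin, `+`)
}

# Evaluate an expression under a temporary, seeded RNG state; restores the
# caller's RNG afterwards so package internals never disturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Unit vector (zero vector returned as-is).
unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) v else v / n
}
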