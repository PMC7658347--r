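## Small geometric and bookkeeping helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix from axis and angle
#'
#' Builds a proper rotation matrix (Rodrigues formula) about an arbitrary
#' axis through the origin.
#'
#' @param axis Numeric length-3 axis; it is normalised internally.
#' @param angle Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' rotationMatrix(c(0, 0, 1), 90)
rotationMatrix <- function(axis, angle) {
  stopifnot(length(axis) == 3, is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R A 3x3 proper rotation matrix.
#' @return The rotation angle in degrees, in [0, 180].
#' @export
rotationAngle <- function(R) {
  tr <- sum(diag(R))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

## angular difference between two rotations, degrees
rotationDifference <- function(R1, R2) rotationAngle(crossprod(R2, R1))

## residue key used everywhere a residue must be uniquely identified
.resKey <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == " ", "", insert),
        sep = "|")
}

.assertFiniteMatrix <- function(x, what) {
  if (!is.matrix(x) || ncol(x) != 3 || !all(is.finite(x)))
    stop(what, " must be a finite n x 3 coordinate matrix")
  invisible(x)
}

## evaluate expr with a locally-set RNG seed, restoring global state
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
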