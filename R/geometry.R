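# Rigid-body geometry: Kabsch superposition, RMSD, rotation parametrizations.

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation R and translation t minimizing
#' ||(X R + t) - Y||^2 over matched rows, via SVD of the cross-covariance.
#'
#' @param X,Y n x 3 coordinate matrices (X is moved onto Y)
#' @return list with \code{R} (3x3, det +1), \code{t} (length 3) and
#'   \code{rmsd} of the fit; apply as \code{X \%*\% R + t}
#' @export
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- unname(cy - as.vector(cx %*% R))
  fit <- sweep(Xc %*% R, 2, cy, "+")
  list(R = unname(R), t = t, rmsd = sqrt(mean(rowSums((fit - Y)^2))))
}

#' Root-mean-square deviation between matched coordinate sets
#' @param X,Y n x 3 matrices, rows matched
#' @param fit superpose X onto Y first (Kabsch) before measuring
#' @export
coordRmsd <- function(X, Y, fit = FALSE) {
  stopifnot(nrow(X) == nrow(Y))
  if (fit) return(kabsch(X, Y)$rmsd)
  sqrt(mean(rowSums((X - Y)^2)))
}

# axis-angle (rotation vector) to rotation matrix
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# deterministic uniform random rotation from 3 unit-uniform draws (Shoemake)
random_rotation <- function(u) {
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# principal axes (eigenvectors of the centered covariance), proper-rotation set:
# the 4 sign assignments with det +1
principal_frames <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lapply(flips, function(f) ev %*% diag(f))
}
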