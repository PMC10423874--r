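# Theoretical hydrophobicity field: orient the residue point cloud, fit the
# encapsulating 3D Gaussian, evaluate the normalized T profile.

#' Orient a point cloud for encapsulation
#'
#' Rotates the points so the principal axes of the cloud (covariance
#' eigenvectors about the centroid) align with x, y, z in decreasing order
#' of spread, then translates them so the per-axis bounding-box midpoint of
#' the oriented cloud sits at the origin. Working in the intrinsic frame
#' makes the result invariant to any rigid-body transform of the input.
#' Axis signs are fixed deterministically: the largest-magnitude component
#' of each eigenvector is made positive, and the third axis is flipped if
#' needed so the rotation is proper (det = +1). The downstream Gaussian is
#' even in every coordinate, so these sign choices never affect T.
#'
#' @param points numeric matrix, one row per residue, columns x, y, z.
#' @return List with `points` (oriented copy), `rotation` (3x3 matrix whose
#'   columns are the new axes) and `center` (bounding-box midpoint of the
#'   cloud, original frame).
#' @export
orient_unit <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1)
  centroid <- colMeans(points)
  centered <- sweep(points, 2, centroid)
  if (nrow(points) == 1 || all(abs(centered) < 1e-12)) {
    return(list(points = centered, rotation = diag(3), center = centroid))
  }
  cv <- stats::cov(centered)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors # columns ordered by decreasing eigenvalue
  for (k in 1:3) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  rotated <- centered %*% v
  mid <- (apply(rotated, 2, max) + apply(rotated, 2, min)) / 2
  list(points = sweep(rotated, 2, mid), rotation = v,
       center = centroid + as.vector(v %*% mid))
}

#' Fit the encapsulating 3D Gaussian
#'
#' Per axis, `sigma = max(extent/2 + pad, floor) / 3` where `extent` is the
#' max-min spread of the oriented effective atoms. Placing the half-extent
#' at three standard deviations puts the molecular surface where the
#' Gaussian is close to zero.
#'
#' @param points oriented point matrix (see [orient_unit]).
#' @param pad padding added to each half-extent, Angstrom (default 0).
#' @param floor smallest allowed half-extent, Angstrom (default 1).
#' @param rotation,center orientation bookkeeping stored in the result.
#' @return An object of class `encapsulation`: list with `center`,
#'   `rotation` and `sigma` (3-vector, Angstrom).
#' @export
encapsulate <- function(points, pad = 0, floor = 1, rotation = diag(3),
                        center = c(0, 0, 0)) {
  points <- as.matrix(points)
  ext <- apply(points, 2, max) - apply(points, 2, min)
  sigma <- pmax(ext / 2 + pad, floor) / 3
  structure(list(center = center, rotation = rotation, sigma = sigma),
            class = "encapsulation")
}

#' @export
print.encapsulation <- function(x, ...) {
  cat(sprintf("3D Gaussian encapsulation: sigma = (%.2f, %.2f, %.2f) A\n",
              x$sigma[1], x$sigma[2], x$sigma[3]))
  invisible(x)
}

#' Theoretical hydrophobicity profile T
#'
#' Evaluates the encapsulating Gaussian at each oriented effective-atom
#' position and normalises to sum 1:
#' `T_i = g(p_i) / sum_j g(p_j)` with
#' `g(p) = exp(-x^2/2sx^2 - y^2/2sy^2 - z^2/2sz^2)`.
#' Values are floored at 1e-12 before normalisation to guard the Gaussian
#' tails against floating-point underflow.
#'
#' @param points oriented point matrix.
#' @param enc an `encapsulation` (or any list with a `sigma` 3-vector).
#' @return Numeric vector summing to 1, all entries positive.
#' @export
t_profile <- function(points, enc) {
  points <- as.matrix(points)
  s <- enc$sigma
  stopifnot(all(s > 0))
  g <- exp(-(points[, 1]^2 / (2 * s[1]^2) +
               points[, 2]^2 / (2 * s[2]^2) +
               points[, 3]^2 / (2 * s[3]^2)))
  g <- pmax(g, 1e-12)
  g / sum(g)
}

# Orient + encapsulate + T in one step, from a structure unit.
unit_t_profile <- function(unit, pad = 0, floor = 1) {
  pts <- as.matrix(unit$residues[, c("x", "y", "z")])
  ori <- orient_unit(pts)
  enc <- encapsulate(ori$points, pad = pad, floor = floor,
                     rotation = ori$rotation, center = ori$center)
  list(T = t_profile(ori$points, enc), enc = enc, oriented = ori$points)
}
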