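## Planar homography between the beam plane (mm) and the sensor (px).
## The oblique camera view foreshortens the scintillator into a trapezoid;
## a single projective map relates the two coordinate systems. The clinical
## plan is transformed once into sensor coordinates at load time, so per-frame
## analysis never transforms an image.

#' Apply a homography to points
#'
#' @param H a \code{\linkS4class{Homography}} (or 3x3 matrix).
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) positions.
#' @return n x 2 matrix of mapped positions.
#' @export
applyHomography <- function(H, pts) {
  h <- if (is(H, "Homography")) H@h else H
  pts <- listOrMat(pts)
  w <- h[3, 1] * pts[, 1] + h[3, 2] * pts[, 2] + h[3, 3]
  cbind((h[1, 1] * pts[, 1] + h[1, 2] * pts[, 2] + h[1, 3]) / w,
        (h[2, 1] * pts[, 1] + h[2, 2] * pts[, 2] + h[2, 3]) / w)
}

# accept a vector c(x, y) or an n x 2 matrix
listOrMat <- function(pts) {
  if (is.matrix(pts)) return(pts)
  if (length(pts) == 2) return(matrix(pts, ncol = 2))
  stop("pts must be c(x, y) or an n x 2 matrix")
}

#' Invert a homography
#' @param H a \code{\linkS4class{Homography}}.
#' @export
invertHomography <- function(H) Homography(solve(H@h), rmsPx = H@rmsPx)

#' Estimate a homography by the normalized direct linear transform
#'
#' Hartley point normalization (translate centroids to the origin, scale the
#' mean distance to sqrt(2)) on both point sets, then the standard DLT via
#' SVD of the 2n x 9 design matrix. Noise-free correspondences are recovered
#' to numerical precision; the reprojection RMS is stored on the result.
#'
#' @param src n x 2 source points (beam plane, mm), n >= 4.
#' @param dst n x 2 destination points (sensor, px).
#' @return a \code{\linkS4class{Homography}}.
#' @export
estimateHomography <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n)
    stop("need >= 4 correspondences with matching counts")

  norm2d <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    Tm <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = Tm, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  ns <- norm2d(src); nd <- norm2d(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  zero <- rep(0, n); one <- rep(1, n)
  A <- rbind(
    cbind(-x, -y, -one, zero, zero, zero, u * x, u * y, u),
    cbind(zero, zero, zero, -x, -y, -one, v * x, v * y, v))
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-12)
    stop("degenerate correspondence configuration (rank deficiency)")
  hvec <- sv$v[, 9]
  Hn <- matrix(hvec, 3, 3, byrow = TRUE)
  h <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(h[3, 3]) < 1e-12 * max(abs(h)))
    stop("estimated homography has vanishing normalization element")
  h <- h / h[3, 3]
  proj <- applyHomography(h, src)
  rms <- sqrt(mean(rowSums((proj - dst)^2)))
  Homography(h, rmsPx = rms)
}

#' Read / write a homography as JSON (9 numbers, row-major)
#' @param H a \code{Homography}.
#' @param path JSON file path.
#' @export
writeHomographyJson <- function(H, path) {
  jsonlite::write_json(list(h = as.vector(t(H@h)), rms_px = H@rmsPx),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHomographyJson
#' @export
readHomographyJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Homography(matrix(obj$h, 3, 3, byrow = TRUE),
             rmsPx = if (!is.null(obj$rms_px)) obj$rms_px else 0)
}
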