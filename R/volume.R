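## Volume3D: a 3-D intensity array with a voxel-to-world affine (RAS mm,
## 0-based voxel indices), the container used by the whole MRI pipeline.

#' Construct a 3-D volume
#'
#' @param voxels numeric 3-D array (X x Y x Z).
#' @param affine 4x4 voxel-to-world matrix mapping 0-based voxel indices to
#'   world mm (RAS). If `NULL`, built from `voxel_mm` with the field of view
#'   centered on the world origin.
#' @param voxel_mm length-3 voxel size in mm; if `NULL`, derived from the
#'   affine column norms.
#' @return An object of class `volume3d` with fields `voxels`, `affine`,
#'   `voxel_mm`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 2)), voxel_mm = c(1, 0.9, 5))
#' dim(v$voxels)
#' @export
volume3d <- function(voxels, affine = NULL, voxel_mm = NULL) {
  stopifnot_msg(is.array(voxels) && length(dim(voxels)) == 3L,
                "voxels must be a 3-D array")
  if (is.null(affine)) {
    if (is.null(voxel_mm)) voxel_mm <- c(1, 1, 1)
    affine <- centered_affine(dim(voxels), voxel_mm)
  }
  stopifnot_msg(is.matrix(affine) && all(dim(affine) == c(4L, 4L)),
                "affine must be a 4x4 matrix")
  stopifnot_msg(abs(det(affine[1:3, 1:3])) > 1e-12, "affine must be invertible")
  vm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (!is.null(voxel_mm)) {
    stopifnot_msg(all(voxel_mm > 0), "voxel_mm must be positive")
    stopifnot_msg(all(abs(vm - voxel_mm) < 1e-6 * (1 + voxel_mm)),
                  "voxel_mm inconsistent with affine column norms")
  }
  structure(list(voxels = voxels, affine = affine, voxel_mm = vm),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel-to-world affine with the grid centered at the world origin
#' @param dim integer length-3 grid shape
#' @param voxel_mm length-3 voxel size (mm)
#' @return 4x4 matrix
#' @export
centered_affine <- function(dim, voxel_mm) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel_mm, 3, 3)
  A[1:3, 4] <- -voxel_mm * (dim - 1) / 2
  A
}

## World coordinates (3 x N) of every voxel center, in grid order.
vox_world_coords <- function(vol) {
  d <- dim(vol$voxels)
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  A <- vol$affine
  out <- matrix(0, 3, length(i))
  out[1, ] <- A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4]
  out[2, ] <- A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4]
  out[3, ] <- A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4]
  out
}

## Apply a 4x4 to 3 x N points.
apply_affine_pts <- function(A, pts) {
  A[1:3, 1:3] %*% pts + A[1:3, 4]
}

#' Trilinear interpolation at continuous 0-based voxel coordinates
#'
#' @param vol `volume3d`
#' @param pts 3 x N matrix of continuous voxel coordinates (0-based)
#' @param outside value used for points outside the grid
#' @return numeric vector length N
#' @export
trilinear_sample <- function(vol, pts, outside = 0) {
  v <- vol$voxels
  d <- dim(v)
  x <- pts[1, ]; y <- pts[2, ]; z <- pts[3, ]
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  inside <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    i0 <= d[1] - 1 & j0 <= d[2] - 1 & k0 <= d[3] - 1 &
    (i0 + 1) * (fx > 0) <= d[1] - 1 &
    (j0 + 1) * (fy > 0) <= d[2] - 1 &
    (k0 + 1) * (fz > 0) <= d[3] - 1
  ## clamp so linear indices stay valid; masked afterwards
  i0c <- pmin(pmax(i0, 0), d[1] - 1); i1 <- pmin(i0c + 1, d[1] - 1)
  j0c <- pmin(pmax(j0, 0), d[2] - 1); j1 <- pmin(j0c + 1, d[2] - 1)
  k0c <- pmin(pmax(k0, 0), d[3] - 1); k1 <- pmin(k0c + 1, d[3] - 1)
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  lin <- function(i, j, k) v[1 + i + d[1] * (j + d[2] * k)]
  c000 <- lin(i0c, j0c, k0c); c100 <- lin(i1, j0c, k0c)
  c010 <- lin(i0c, j1, k0c);  c110 <- lin(i1, j1, k0c)
  c001 <- lin(i0c, j0c, k1);  c101 <- lin(i1, j0c, k1)
  c011 <- lin(i0c, j1, k1);   c111 <- lin(i1, j1, k1)
  out <- (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
         (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
         (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
         (c011 * (1 - fx) + c111 * fx) * fy * fz
  out[!inside] <- outside
  out
}

#' Nearest-neighbor interpolation at continuous voxel coordinates
#' @inheritParams trilinear_sample
#' @export
nearest_sample <- function(vol, pts, outside = 0) {
  v <- vol$voxels
  d <- dim(v)
  i <- round(pts[1, ]); j <- round(pts[2, ]); k <- round(pts[3, ])
  inside <- i >= 0 & j >= 0 & k >= 0 & i <= d[1] - 1 & j <= d[2] - 1 & k <= d[3] - 1
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  out <- v[1 + i + d[1] * (j + d[2] * k)]
  out[!inside] <- outside
  out
}

#' Resample a volume onto a target grid
#'
#' Maps each target voxel center to world, optionally through `world_map`
#' (a 4x4 taking target-world to source-world, e.g. a rigid coregistration),
#' then into source voxel coordinates, and interpolates.
#'
#' @param src `volume3d` to sample from
#' @param dim_out target grid shape
#' @param affine_out target voxel-to-world affine
#' @param world_map 4x4 world-to-world transform (default identity)
#' @param method "trilinear" or "nearest"
#' @param outside fill value outside the source grid
#' @return `volume3d` on the target grid
#' @export
resample_volume <- function(src, dim_out, affine_out, world_map = diag(4),
                            method = c("trilinear", "nearest"), outside = 0) {
  method <- match.arg(method)
  tgt <- volume3d(array(0, dim_out), affine = affine_out)
  w <- vox_world_coords(tgt)
  w <- apply_affine_pts(world_map, w)
  pv <- apply_affine_pts(solve(src$affine), w)
  vals <- if (method == "trilinear") trilinear_sample(src, pv, outside)
          else nearest_sample(src, pv, outside)
  volume3d(array(vals, dim_out), affine = affine_out)
}

#' Build a 4x4 rigid transform from 6 parameters
#'
#' Rotations are applied about the world origin in the order x, then y, then
#' z (i.e. `Rz %*% Ry %*% Rx`), followed by the translation.
#'
#' @param params numeric length 6: rotations (degrees) about x, y, z then
#'   translations (mm) along x, y, z
#' @return 4x4 matrix of class `rigid_transform`
#' @export
rigid_matrix <- function(params) {
  stopifnot_msg(length(params) == 6, "rigid transform needs 6 parameters")
  a <- params[1:3] * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  M <- diag(4)
  M[1:3, 1:3] <- Rz %*% Ry %*% Rx
  M[1:3, 4] <- params[4:6]
  structure(M, class = c("rigid_transform", "matrix", "array"), params = params)
}

#' Build a 4x4 affine from 12 parameters (row-major top 3 rows)
#' @param params numeric length 12, the first three rows of the matrix
#' @return 4x4 matrix
#' @export
affine_matrix <- function(params) {
  stopifnot_msg(length(params) == 12, "affine transform needs 12 parameters")
  M <- diag(4)
  M[1:3, ] <- matrix(params, 3, 4, byrow = TRUE)
  stopifnot_msg(abs(det(M[1:3, 1:3])) > 1e-12, "affine not invertible")
  M
}
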