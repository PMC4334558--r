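## Intensity-based registration: rigid T1-to-FLAIR coregistration and
## 12-dof affine spatial normalization to the package template, both by
## mutual-information maximization (Nelder-Mead over a coarse-to-fine
## pyramid of deterministic voxel subsamples). Everything is deterministic
## given the input volumes.

## mutual information of two paired intensity vectors via a joint histogram
mutual_information <- function(a, b, nbins = 32) {
  ra <- range(a); rb <- range(b)
  if (ra[2] <= ra[1] || rb[2] <= rb[1]) return(0)
  ia <- pmin(pmax(ceiling((a - ra[1]) / (ra[2] - ra[1]) * nbins), 1L), nbins)
  ib <- pmin(pmax(ceiling((b - rb[1]) / (rb[2] - rb[1]) * nbins), 1L), nbins)
  joint <- tabulate(ia + nbins * (ib - 1L), nbins * nbins) / length(a)
  pa <- tabulate(ia, nbins) / length(a)
  pb <- tabulate(ib, nbins) / length(b)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz])) - sum(pa[pa > 0] * log(pa[pa > 0])) -
    sum(pb[pb > 0] * log(pb[pb > 0]))
}

## deterministic subsample of informative fixed-image voxels: world coords
## (3 x n) and intensities, taken at a stride so at most n_max survive
reg_samples <- function(fixed, decimate = 1, n_max = 30000) {
  d <- dim(fixed$voxels)
  keep_ijk <- lapply(d, function(nn) seq(1, nn, by = decimate))
  vals <- fixed$voxels[keep_ijk[[1]], keep_ijk[[2]], keep_ijk[[3]], drop = FALSE]
  i <- rep.int(keep_ijk[[1]] - 1, length(keep_ijk[[2]]) * length(keep_ijk[[3]]))
  j <- rep.int(rep(keep_ijk[[2]] - 1, each = length(keep_ijk[[1]])), length(keep_ijk[[3]]))
  k <- rep(keep_ijk[[3]] - 1, each = length(keep_ijk[[1]]) * length(keep_ijk[[2]]))
  v <- as.vector(vals)
  ## head voxels only: pure background noise carries no alignment signal
  ## and corrupts the overlap fraction, but CSF and skull classes hold most
  ## of the rotational leverage, so cut below them (two-stage Otsu: first
  ## isolates the parenchyma, the second splits background from the
  ## remaining low-intensity head classes)
  th <- otsu_threshold(v)
  low <- v[v <= th]
  th2 <- if (length(unique(low)) > 2) otsu_threshold(low) else th
  sel <- which(v > th2)
  if (length(sel) > n_max) sel <- sel[seq(1, length(sel), length.out = n_max)]
  A <- fixed$affine
  pts <- rbind(A[1, 1] * i[sel] + A[1, 2] * j[sel] + A[1, 3] * k[sel] + A[1, 4],
               A[2, 1] * i[sel] + A[2, 2] * j[sel] + A[2, 3] * k[sel] + A[2, 4],
               A[3, 1] * i[sel] + A[3, 2] * j[sel] + A[3, 3] * k[sel] + A[3, 4])
  list(pts = pts, vals = v[sel])
}

## negative MI of moving resampled at mapped fixed samples; world_map 4x4.
## MI is weighted by the overlap fraction: otherwise the optimizer can
## inflate MI by pushing hard-to-match samples off the moving grid.
neg_mi_cost <- function(world_map, samples, moving, moving_inv) {
  pv <- apply_affine_pts(moving_inv %*% world_map, samples$pts)
  mv <- trilinear_sample(moving, pv, outside = NA_real_)
  ok <- !is.na(mv)
  frac <- sum(ok) / length(mv)
  if (frac < 0.25) return(1e3)  # mostly outside: reject
  -mutual_information(samples$vals[ok], mv[ok]) * min(1, frac / 0.95)
}

## cyclic coordinate-wise parabolic refinement: walks along each parameter
## in turn fitting a local quadratic; climbs the narrow ridges on which a
## collapsed Nelder-Mead simplex stalls
coord_refine <- function(par, cost, step, sweeps = 4) {
  f0 <- cost(par)
  for (sw in seq_len(sweeps)) {
    for (i in seq_along(par)) {
      d <- step[i] / sw
      pm <- par; pm[i] <- par[i] - d
      pp <- par; pp[i] <- par[i] + d
      fm <- cost(pm); fp <- cost(pp)
      denom <- fm - 2 * f0 + fp
      cand <- if (is.finite(denom) && denom > 0) {
        par[i] + d * (fm - fp) / (2 * denom)  # parabola vertex
      } else if (fm < f0) pm[i] else if (fp < f0) pp[i] else par[i]
      cand <- min(max(cand, par[i] - 2 * d), par[i] + 2 * d)
      pc <- par; pc[i] <- cand
      fc <- cost(pc)
      best <- which.min(c(f0, fm, fp, fc))
      par[i] <- c(par[i], pm[i], pp[i], cand)[best]
      f0 <- c(f0, fm, fp, fc)[best]
    }
  }
  list(par = par, value = f0)
}

## intensity-weighted centroid (world mm)
com_world <- function(vol) {
  w <- as.vector(vol$voxels) - min(vol$voxels)
  pts <- vox_world_coords(vol)
  as.vector(pts %*% w) / sum(w)
}

#' Rigid coregistration of two volumes by mutual information
#'
#' Estimates the 6-parameter rigid transform taking fixed-image world
#' coordinates to moving-image world coordinates (the pull-back used to
#' resample `moving` onto the `fixed` grid), maximizing mutual information
#' over a 3-level coarse-to-fine pyramid. Initialization translates the
#' intensity centroids onto each other. Deterministic given the inputs.
#'
#' @param moving,fixed `volume3d` (may be different modalities)
#' @param n_max voxel samples per pyramid level
#' @param maxit Nelder-Mead iteration cap per level
#' @return `rigid_transform` (4x4 with a `params` attribute of 3 rotations
#'   in degrees and 3 translations in mm); attribute `mi` holds the final
#'   mutual information
#' @export
register_rigid <- function(moving, fixed, n_max = 25000, maxit = 500) {
  for (v in list(moving, fixed)) {
    stopifnot_msg(inherits(v, "volume3d"), "inputs must be volume3d")
    stopifnot_msg(max(v$voxels) > min(v$voxels),
                  "degenerate intensity histogram: constant volume")
  }
  moving_inv <- solve(moving$affine)
  init <- c(0, 0, 0, com_world(moving) - com_world(fixed))
  par <- init
  res <- NULL
  for (decim in c(4L, 2L, 1L)) {
    samples <- reg_samples(fixed, decimate = decim, n_max = n_max)
    cost <- function(p) neg_mi_cost(rigid_matrix(p), samples, moving, moving_inv)
    res <- stats::optim(par, cost, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(1, 1, 1, 1, 1, 1),
                                       reltol = 1e-10))
    par <- res$par
    ## coordinate refinement at the two finest levels
    if (decim <= 2L) {
      ref <- coord_refine(par, cost, step = rep(0.5, 6), sweeps = 4)
      par <- ref$par
      res$par <- ref$par; res$value <- ref$value; res$convergence <- 0L
    }
  }
  if (res$convergence != 0) {
    abort("rigid registration did not converge (last MI = %.4f)", -res$value)
  }
  out <- rigid_matrix(par)
  attr(out, "mi") <- -res$value
  out
}

#' Affine spatial normalization to a template
#'
#' Estimates a 12-parameter affine taking native (subject) world coordinates
#' to template world coordinates: initialized by moment matching (centroid
#' plus per-axis second-moment scaling), then refined by monotone
#' coordinate-wise mutual-information maximization. The refinement can only
#' improve on the moment fit, so it stays in the initialization's basin -
#' full 12-D simplex search proved prone to distant local optima of the MI
#' surface. The exact inverse accompanies the forward map, so
#' template-space atlas masks can be pulled into native space.
#'
#' @param t1 subject `volume3d`
#' @param template template `volume3d` (see [canonical_template()])
#' @param n_max voxel samples for the MI refinement
#' @param sweeps coordinate-refinement sweeps
#' @return list of class `affine_result`: `forward` and `inverse` 4x4
#'   matrices, and `mi`
#' @export
register_affine_to_template <- function(t1, template, n_max = 25000, sweeps = 5) {
  stopifnot_msg(inherits(t1, "volume3d") && inherits(template, "volume3d"),
                "inputs must be volume3d")
  ## moment init: per-axis centroid + sd matching, native -> template
  mom <- function(vol) {
    v <- as.vector(vol$voxels)
    w <- pmax(v - otsu_threshold(v), 0)   # foreground-weighted moments
    pts <- vox_world_coords(vol)
    ctr <- as.vector(pts %*% w) / sum(w)
    sds <- sqrt(colSums(t((pts - ctr)^2) * w) / sum(w))
    list(ctr = ctr, sds = sds)
  }
  ms <- mom(t1); mt <- mom(template)
  S <- diag(mt$sds / ms$sds, 3, 3)
  M0 <- diag(4)
  M0[1:3, 1:3] <- S
  M0[1:3, 4] <- mt$ctr - S %*% ms$ctr
  par <- as.vector(t(M0[1:3, ]))

  ## refinement: fixed = t1 (native samples), mapped into the template
  tmpl_inv <- solve(template$affine)
  samples <- reg_samples(t1, decimate = 2L, n_max = n_max)
  cost <- function(p) {
    M <- diag(4); M[1:3, ] <- matrix(p, 3, 4, byrow = TRUE)
    if (abs(det(M[1:3, 1:3])) < 1e-6) return(1e3)
    neg_mi_cost(M, samples, template, tmpl_inv)
  }
  ref <- coord_refine(par, cost, step = rep(c(0.02, 0.02, 0.02, 2), 3),
                      sweeps = sweeps)
  M <- diag(4); M[1:3, ] <- matrix(ref$par, 3, 4, byrow = TRUE)
  if (abs(det(M[1:3, 1:3])) < 1e-8) abort("affine normalization fit is not invertible")
  structure(list(forward = M, inverse = solve(M), mi = -ref$value),
            class = "affine_result")
}
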