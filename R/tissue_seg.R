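## T1 tissue segmentation: univariate 3-class Gaussian mixture fitted by EM
## on in-brain intensities, components labeled CSF < GM < WM by ascending
## mean (the T1 contrast convention). Posterior probabilities are returned
## per voxel; volumes integrate posteriors (soft counting).

#' Segment brain tissues on a T1 volume
#'
#' @param t1 `volume3d`
#' @param brain_mask `volume3d` 0/1 mask on the T1 grid (from
#'   [extract_brain()]) or a logical array
#' @param tol relative log-likelihood tolerance for EM convergence
#' @param max_iter EM iteration cap
#' @return list of class `tissue_maps`: `prob_csf`, `prob_gm`, `prob_wm`
#'   (`volume3d` posteriors, zero outside the brain), `brain_mask`, and the
#'   fitted `model` (means, sds, weights, iterations, loglik)
#' @export
segment_tissues <- function(t1, brain_mask, tol = 1e-6, max_iter = 500) {
  stopifnot_msg(inherits(t1, "volume3d"), "t1 must be a volume3d")
  mask <- if (inherits(brain_mask, "volume3d")) brain_mask$voxels != 0 else brain_mask != 0
  stopifnot_msg(any(mask), "brain_mask is empty")
  x <- as.vector(t1$voxels)[as.vector(mask)]
  ux <- unique(x)
  if (length(ux) < 3) abort("degenerate input: fewer than 3 distinct in-brain intensities")

  ## deterministic k-means init from intensity quantiles
  centers <- stats::quantile(x, c(0.15, 0.5, 0.85), names = FALSE, type = 7)
  if (anyDuplicated(centers)) centers <- centers + c(-1e-6, 0, 1e-6) * max(abs(centers), 1)
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers, 3, 1),
                                       iter.max = 50))
  mu <- as.vector(km$centers)
  sd3 <- vapply(1:3, function(kk) {
    s <- stats::sd(x[km$cluster == kk])
    if (!is.finite(s) || s == 0) diff(range(x)) / 100 else s
  }, numeric(1))
  w <- as.vector(table(factor(km$cluster, levels = 1:3))) / length(x)
  var_floor <- max(stats::var(x) * 1e-6, .Machine$double.eps)

  ll_old <- -Inf
  iter <- 0
  dens <- matrix(0, length(x), 3)
  repeat {
    iter <- iter + 1
    for (kk in 1:3) dens[, kk] <- w[kk] * stats::dnorm(x, mu[kk], sd3[kk])
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1)) {
      abort("degenerate mixture component (effective weight ~ 0) in tissue segmentation")
    }
    mu <- colSums(resp * x) / nk
    v <- colSums(resp * (outer(x, mu, "-")^2)) / nk
    v <- pmax(v, var_floor)
    sd3 <- sqrt(v)
    w <- nk / length(x)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) break
    if (iter >= max_iter) break
    ll_old <- ll
  }

  ord <- order(mu)  # CSF < GM < WM on T1
  mu <- mu[ord]; sd3 <- sd3[ord]; w <- w[ord]
  for (kk in 1:3) dens[, kk] <- w[kk] * stats::dnorm(x, mu[kk], sd3[kk])
  resp <- dens / pmax(rowSums(dens), .Machine$double.xmin)

  mk <- function(kk) {
    a <- array(0, dim(t1$voxels))
    a[mask] <- resp[, kk]
    volume3d(a, affine = t1$affine)
  }
  structure(list(
    prob_csf = mk(1), prob_gm = mk(2), prob_wm = mk(3),
    brain_mask = volume3d(array(as.double(mask), dim(t1$voxels)), affine = t1$affine),
    model = list(means = mu, sds = sd3, weights = w, iterations = iter, loglik = ll)
  ), class = "tissue_maps")
}

#' Hard tissue assignment from posterior maps
#' @param tissues `tissue_maps`
#' @return integer array: 0 outside brain, 1 CSF, 2 GM, 3 WM
#' @export
hard_assignment <- function(tissues) {
  p <- cbind(as.vector(tissues$prob_csf$voxels),
             as.vector(tissues$prob_gm$voxels),
             as.vector(tissues$prob_wm$voxels))
  lab <- max.col(p, ties.method = "first")
  lab[rowSums(p) == 0] <- 0L
  array(lab, dim(tissues$prob_csf$voxels))
}

#' Tissue volumes in cm3 from posterior probability maps
#'
#' Each tissue volume integrates that tissue's posterior probability over
#' the voxel grid (soft counting); total brain volume is GM + WM, with CSF
#' reported separately. Computed in the subject's own anatomical space.
#'
#' @param tissues `tissue_maps`
#' @param voxel_mm voxel size override (defaults to the maps' own)
#' @return named list: `gm_cm3`, `wm_cm3`, `csf_cm3`, `total_brain_cm3`
#' @export
tissue_volumes_cm3 <- function(tissues, voxel_mm = NULL) {
  if (is.null(voxel_mm)) voxel_mm <- tissues$prob_gm$voxel_mm
  vox_cm3 <- prod(voxel_mm) / 1000
  gm <- sum(tissues$prob_gm$voxels) * vox_cm3
  wm <- sum(tissues$prob_wm$voxels) * vox_cm3
  csf <- sum(tissues$prob_csf$voxels) * vox_cm3
  list(gm_cm3 = gm, wm_cm3 = wm, csf_cm3 = csf, total_brain_cm3 = gm + wm)
}
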