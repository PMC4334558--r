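## Brain extraction: Otsu thresholding, 3-D morphology, connected
## components (via igraph on the voxel adjacency), hole filling.

#' Otsu threshold of a numeric vector
#' @param x intensities
#' @param nbins histogram bins
#' @return scalar threshold maximizing between-class variance
#' @export
otsu_threshold <- function(x, nbins = 256) {
  r <- range(x)
  stopifnot_msg(r[2] > r[1], "cannot threshold a constant image")
  breaks <- seq(r[1], r[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(findInterval(x, breaks, all.inside = TRUE), nbins))
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w <- cumsum(h); mu <- cumsum(h * mids)
  n <- w[nbins]; mu_t <- mu[nbins]
  w1 <- w[-nbins]; mu1 <- mu[-nbins]
  between <- (mu_t * w1 - mu1 * n)^2 / (w1 * (n - w1) + .Machine$double.eps)
  between[w1 == 0 | w1 == n] <- 0
  ## well-separated classes leave a plateau of equally optimal thresholds
  ## across the empty gap: take its midpoint
  cand <- which(between >= max(between) * (1 - 1e-12))
  breaks[cand[ceiling(length(cand) / 2)] + 1]
}

## shift a 3-D array by (dx,dy,dz), zero-padded
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

#' 3-D morphological dilation / erosion with a box structuring element
#'
#' Implemented separably (1-D max filter along each axis in turn), which is
#' equivalent to a `(2r+1)^3` box structuring element.
#'
#' @param mask logical or 0/1 3-D array
#' @param op "dilate" or "erode"
#' @param r structuring element radius in voxels
#' @return logical array
#' @export
morph3d <- function(mask, op = c("dilate", "erode"), r = 1) {
  op <- match.arg(op)
  m <- array(mask != 0, dim(mask))
  if (op == "erode") m <- !m
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (axis in 1:3) {
    for (rr in seq_len(r)) {
      s1 <- shifts[[2 * axis - 1]]; s2 <- shifts[[2 * axis]]
      m <- m | (shift3d(m, s1[1], s1[2], s1[3]) > 0) |
        (shift3d(m, s2[1], s2[2], s2[3]) > 0)
    }
  }
  if (op == "erode") m <- !m
  array(m, dim(mask))
}

#' Connected-component labels of a 3-D mask (6-connectivity)
#' @param mask logical 3-D array
#' @return integer array, 0 = background, components numbered by decreasing size
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (step in c(1L, d[1], d[1] * d[2])) {
    ## neighbor along +x / +y / +z; guard axis wrap-around
    nb <- idx + step
    ok <- nb <= prod(d) & pos[pmin(nb, prod(d))] > 0
    if (step == 1L) ok <- ok & ((idx - 1) %% d[1]) < d[1] - 1
    if (step == d[1]) ok <- ok & ((idx - 1) %/% d[1]) %% d[2] < d[2] - 1
    if (any(ok)) edges <- c(edges, rbind(pos[idx[ok]], pos[nb[ok]]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  remap <- integer(comp$no); remap[ord] <- seq_len(comp$no)
  lab[idx] <- remap[comp$membership]
  lab
}

#' Fill interior holes of a 3-D mask
#'
#' Background components not connected to the array border become foreground.
#' @param mask logical 3-D array
#' @return logical array
#' @export
fill_holes3d <- function(mask) {
  bg <- label_components(!mask)
  d <- dim(mask)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Extract the brain from a T1 head volume
#'
#' Otsu thresholding (brain parenchyma is the brightest intensity class on
#' T1, so the threshold separates GM/WM from CSF, skull and background),
#' morphological closing, largest connected component, and hole filling (so
#' ventricles are included). The result is a single connected binary
#' component.
#'
#' @param t1 `volume3d`
#' @return `volume3d` with a 0/1 brain mask on the T1 grid
#' @export
extract_brain <- function(t1) {
  stopifnot_msg(inherits(t1, "volume3d"), "t1 must be a volume3d")
  x <- as.vector(t1$voxels)
  if (max(x) - min(x) <= 0) abort("cannot extract a brain from a constant volume")
  th <- otsu_threshold(x)
  if (!any(x > th)) abort("brain extraction found no foreground")
  fg <- array(x > th, dim(t1$voxels))
  fg <- morph3d(morph3d(fg, "dilate", 1), "erode", 1)   # closing
  ## work inside the foreground bounding box (+1) - components and holes
  ## are unchanged there, and the arrays shrink considerably
  d <- dim(fg)
  idx <- which(fg, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  sub <- fg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab <- label_components(sub)
  if (max(lab) == 0) abort("brain extraction found no connected component")
  filled <- fill_holes3d(lab == 1L)
  brain <- array(FALSE, d)
  brain[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- filled
  volume3d(array(as.double(brain), d), affine = t1$affine)
}
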