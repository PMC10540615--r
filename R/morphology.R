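## Internal 3D array utilities for the phantom simulator: integer shifts,
## binary morphology with a spherical structuring element, and separable
## Gaussian smoothing. All operate on plain R arrays; morphology crops to the
## foreground bounding box (plus the structuring radius) so cost scales with
## the structure, not the grid.

# voxel offsets of the digital ball of radius r (dx^2+dy^2+dz^2 <= r^2)
.ballOffsets <- function(r) {
  r <- as.integer(r)
  if (r <= 0L) return(matrix(0L, 1L, 3L))
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

# shift a 3D array by integer offsets, filling exposed planes
.shiftArray <- function(a, shift, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) {
      src[[ax]] <- seq_len(d[ax] - s)
      dst[[ax]] <- seq.int(s + 1L, d[ax])
    } else {
      src[[ax]] <- seq.int(-s + 1L, d[ax])
      dst[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# bounding box of TRUE voxels, expanded by margin and clamped to the grid
.bbox <- function(mask, margin = 0L) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  coord <- arrayInd(idx, d)
  lo <- pmax(apply(coord, 2L, min) - margin, 1L)
  hi <- pmin(apply(coord, 2L, max) + margin, d)
  list(lo = lo, hi = hi)
}

.applyBinaryMorph <- function(mask, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  r <- as.integer(r)
  if (r <= 0L) return(mask)
  bb <- .bbox(mask, margin = r)
  if (is.null(bb)) return(mask)  # empty mask: both operations are no-ops
  ix <- bb$lo[1L]:bb$hi[1L]; iy <- bb$lo[2L]:bb$hi[2L]; iz <- bb$lo[3L]:bb$hi[3L]
  crop <- mask[ix, iy, iz, drop = FALSE]
  dim(crop) <- c(length(ix), length(iy), length(iz))
  offs <- .ballOffsets(r)
  acc <- NULL
  for (o in seq_len(nrow(offs))) {
    sh <- .shiftArray(crop, offs[o, ], fill = FALSE)
    acc <- if (is.null(acc)) sh
    else if (op == "dilate") acc | sh else acc & sh
  }
  out <- mask
  if (op == "erode") out[] <- FALSE  # survivors are confined to the bbox
  out[ix, iy, iz] <- acc
  out
}

.binaryDilate <- function(mask, r) .applyBinaryMorph(mask, r, "dilate")
.binaryErode  <- function(mask, r) .applyBinaryMorph(mask, r, "erode")

# separable Gaussian smoothing; sigmaMm is isotropic in mm, converted to a
# per-axis voxel sigma through the spacing. Kernels are truncated at 3 sigma
# and renormalized, so total mass is preserved.
.gaussianSmooth <- function(a, sigmaMm, spacing) {
  if (sigmaMm <= 0) return(a)
  out <- a
  for (ax in 1:3) {
    sv <- sigmaMm / spacing[ax]
    h <- max(1L, as.integer(ceiling(3 * sv)))
    w <- stats::dnorm(-h:h, sd = sv)
    w <- w / sum(w)
    acc <- array(0, dim(out))
    for (t in -h:h) {
      sh <- integer(3L); sh[ax] <- t
      # replicate edge planes so mass is not lost at the boundary
      acc <- acc + w[t + h + 1L] * .shiftArrayReplicate(out, sh)
    }
    out <- acc
  }
  out
}

# shift with edge replication (used by the smoother only)
.shiftArrayReplicate <- function(a, shift) {
  d <- dim(a)
  idx <- vector("list", 3L)
  for (ax in 1:3) {
    i <- seq_len(d[ax]) - shift[ax]
    idx[[ax]] <- pmin(pmax(i, 1L), d[ax])
  }
  a[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}
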