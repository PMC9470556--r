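# 8-connected component labelling of a logical matrix by iterative
# minimum-label propagation (skeletons are tiny, so convergence is cheap).
.label8 <- function(mask) {
  ids <- matrix(0L, nrow(mask), ncol(mask))
  ids[mask] <- seq_len(sum(mask))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  nr <- nrow(mask); nc <- ncol(mask)
  repeat {
    old <- ids
    for (s in shifts) {
      sh <- matrix(Inf, nr, nc)
      rs <- max(1, 1 + s[1]):min(nr, nr + s[1])
      cs <- max(1, 1 + s[2]):min(nc, nc + s[2])
      sh[rs, cs] <- ids[rs - s[1], cs - s[2]]
      sh[sh == 0] <- Inf
      upd <- mask & sh < ids
      ids[upd] <- sh[upd]
    }
    if (identical(ids, old)) break
  }
  # compact labels
  u <- sort(unique(ids[ids > 0]))
  ids[ids > 0] <- match(ids[ids > 0], u)
  ids
}

# Thinning erodes segment ends by a few pixels; walk every skeleton
# endpoint outward along its local direction until the mask boundary so
# that measured lengths match the vessel extent.
.extendEndpoints <- function(sk, mask, maxSteps = 50L) {
  nr <- nrow(sk); nc <- ncol(sk)
  cnt <- .neighborCount8(sk)
  ends <- which(sk & cnt == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(ends))) {
    p <- ends[k, ]
    nb <- NULL
    for (dz in -1:1) for (dx in -1:1) {
      if (dz == 0 && dx == 0) next
      r <- p[1] + dz; c <- p[2] + dx
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && sk[r, c]) {
        nb <- c(dz, dx)
      }
    }
    if (is.null(nb)) next
    d <- -nb                      # away from the segment
    cur <- p
    for (s in seq_len(maxSteps)) {
      cur <- cur + d
      if (cur[1] < 1 || cur[1] > nr || cur[2] < 1 || cur[2] > nc) break
      if (!mask[cur[1], cur[2]] || sk[cur[1], cur[2]]) break
      sk[cur[1], cur[2]] <- TRUE
    }
  }
  sk
}

# Count of 8-connected neighbors for every pixel of a logical matrix.
.neighborCount8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  cnt <- matrix(0L, nr, nc)
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    cnt <- cnt + p[(2:(nr + 1L)) + dz, (2:(nc + 1L)) + dx]
  }
  cnt
}

#' Skeletonize a binary image
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels in two
#' sub-iterations until only a one-pixel-wide, 8-connected skeleton
#' remains. Used by [vesselMetrics()] to measure vessel center lines.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size containing the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- matrix(FALSE, nr + 2L, nc + 2L)
      p[2:(nr + 1L), 2:(nc + 1L)] <- m
      ctr <- 2:(nr + 1L); cct <- 2:(nc + 1L)
      # neighbors clockwise from north (P2..P9); rows are z (down = +1)
      p2 <- p[ctr - 1L, cct]; p3 <- p[ctr - 1L, cct + 1L]
      p4 <- p[ctr, cct + 1L]; p5 <- p[ctr + 1L, cct + 1L]
      p6 <- p[ctr + 1L, cct]; p7 <- p[ctr + 1L, cct - 1L]
      p8 <- p[ctr, cct - 1L]; p9 <- p[ctr - 1L, cct - 1L]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq1 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (!seq1[[i]] & seq1[[i + 1L]])
      if (step == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' En-face OCTA projection
#'
#' Post-processes an OCTA decorrelation volume into the en-face image on
#' which vessels are quantified: the volume is masked with the intensity
#' validity mask (separating tissue from background), smoothed with a 3-d
#' Gaussian filter (sigma 1.1 px in all directions), maximum-projected
#' over a depth window (default 30 pixels, 0.2 mm at the default depth
#' pitch), and cropped to a lateral region of interest (default
#' 200 x 150 pixels when the volume is large enough).
#'
#' @param octa decorrelation array `(z, x, y)` or a [ContrastSet-class]
#'   (whose `octa`, `valid` and geometry are then used).
#' @param valid logical validity array (ignored for a `ContrastSet`).
#' @param geometry an [AcquisitionGeometry-class] (ignored for a
#'   `ContrastSet`).
#' @param depthStart first depth pixel of the projection window.
#' @param depthPixels depth window length, pixels (default 30).
#' @param sigma Gaussian smoothing sigma, pixels.
#' @param roi region of interest `c(x0, y0, width, height)` in pixels, or
#'   `NULL` for the full lateral extent.
#' @return matrix `(x, y)` with attributes `depth_extent_mm`,
#'   `roi_extent_mm` (fast/slow physical size) and `pixel_pitch_um`.
#' @export
octaEnface <- function(octa, valid = NULL, geometry = NULL,
                       depthStart = 1L, depthPixels = 30L, sigma = 1.1,
                       roi = NULL) {
  if (is(octa, "ContrastSet")) {
    valid <- validMask(octa)
    geometry <- acqGeometry(octa)
    octa <- octaMap(octa)
  }
  stopifnot(length(dim(octa)) == 3L, is(geometry, "AcquisitionGeometry"))
  d <- dim(octa)
  depthStart <- as.integer(depthStart)
  depthPixels <- as.integer(depthPixels)
  if (depthStart < 1L || depthStart + depthPixels - 1L > d[1L]) {
    stop("depth window outside the volume")
  }
  masked <- octa
  if (!is.null(valid)) masked[!valid] <- 0
  sm <- gaussianFilter3d(masked, sigma)

  zWin <- depthStart:(depthStart + depthPixels - 1L)
  proj <- sm[zWin[1L], , ]
  for (z in zWin[-1L]) proj <- pmax(proj, sm[z, , ])

  if (is.null(roi)) {
    roi <- c(1L, 1L, d[2L], d[3L])
  }
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[2] < 1L || roi[1] + roi[3] - 1L > d[2L] ||
      roi[2] + roi[4] - 1L > d[3L]) {
    stop("ROI outside the lateral extent")
  }
  proj <- proj[roi[1]:(roi[1] + roi[3] - 1L),
               roi[2]:(roi[2] + roi[4] - 1L), drop = FALSE]

  pf <- lateralPixelPitch(geometry@fovFast, geometry@nFast)
  ps <- lateralPixelPitch(geometry@fovSlow, geometry@nSlow)
  attr(proj, "depth_extent_mm") <-
    physicalExtent(depthPixels, geometry@depthPitch, display = TRUE)
  attr(proj, "roi_extent_mm") <- c(fast = physicalExtent(roi[3], pf),
                                   slow = physicalExtent(roi[4], ps))
  attr(proj, "pixel_pitch_um") <- c(fast = pf, slow = ps)
  proj
}

#' Binarize a vessel projection
#'
#' Thresholds an en-face projection into a binary vessel mask (global
#' Otsu threshold by default, or a fixed value) and removes connected
#' components below a minimum area. A flat (degenerate) image yields an
#' empty mask with a warning.
#'
#' @param projection numeric matrix, e.g. from [octaEnface()].
#' @param threshold `NULL` for Otsu on the normalized image, or a fixed
#'   threshold on the original scale.
#' @param minArea minimum component area in pixels.
#' @return logical matrix.
#' @export
binarizeVessels <- function(projection, threshold = NULL, minArea = 10L) {
  stopifnot(is.matrix(projection), length(projection) > 0)
  lo <- min(projection); hi <- max(projection)
  if (hi - lo < 1e-12) {
    warning("flat projection: no vessels detected")
    return(matrix(FALSE, nrow(projection), ncol(projection)))
  }
  if (is.null(threshold)) {
    x01 <- (projection - lo) / (hi - lo)
    th <- EBImage::otsu(x01, range = c(0, 1))
    mask <- x01 > th
  } else {
    mask <- projection > threshold
  }
  lbl <- EBImage::bwlabel(mask)
  if (max(lbl) > 0) {
    sizes <- tabulate(lbl[lbl > 0])
    keep <- which(sizes >= minArea)
    mask <- matrix(lbl %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Vessel metrics of a binary en-face mask
#'
#' The two vasculature statistics reported from en-face angiograms:
#' vessel density, `100 * mask area / ROI area` (percent), and mean
#' vessel length, the total skeleton path length divided by the number of
#' skeleton segments between branch points. The skeleton is computed by
#' [skeletonize()]; path length sums 8-connected steps using the
#' anisotropic per-axis pixel pitches (diagonal steps count their
#' Euclidean length); branch points (skeleton pixels with three or more
#' skeleton neighbors) split the skeleton into segments.
#'
#' @param mask logical matrix `(x, y)` (rows along the fast axis).
#' @param pitchFast,pitchSlow pixel pitches along rows/columns, um.
#' @return list with `mean_vessel_length_mm`, `vessel_density_pct`,
#'   `n_segments`, `total_length_mm`.
#' @export
vesselMetrics <- function(mask, pitchFast, pitchSlow) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  density <- 100 * sum(m) / length(m)
  if (!any(m)) {
    return(list(mean_vessel_length_mm = 0, vessel_density_pct = 0,
                n_segments = 0L, total_length_mm = 0))
  }
  sk <- skeletonize(m)
  if (!any(sk)) {
    return(list(mean_vessel_length_mm = 0, vessel_density_pct = density,
                n_segments = 0L, total_length_mm = 0))
  }
  sk <- .extendEndpoints(sk, m)

  # Total path length: each unique adjacent skeleton pixel pair counted
  # once, with anisotropic step lengths (um -> mm).
  nr <- nrow(sk); nc <- ncol(sk)
  stepLen <- function(dr, dc) sqrt((dr * pitchFast)^2 + (dc * pitchSlow)^2)
  pairs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  total <- 0
  for (k in seq_len(nrow(pairs))) {
    dr <- pairs[k, 1]; dc <- pairs[k, 2]
    r1 <- 1:(nr - abs(dr)); c1 <- if (dc >= 0) 1:(nc - dc) else
      (1 - dc):nc
    r2 <- r1 + abs(dr); c2 <- c1 + dc
    both <- sk[r1, c1, drop = FALSE] & sk[r2, c2, drop = FALSE]
    total <- total + sum(both) * stepLen(dr, dc)
  }
  totalMm <- total / 1000

  branch <- sk & .neighborCount8(sk) >= 3L
  segMask <- sk & !branch
  nSeg <- if (any(segMask)) max(.label8(segMask)) else 1L
  nSeg <- max(nSeg, 1L)

  list(mean_vessel_length_mm = totalMm / nSeg,
       vessel_density_pct = density,
       n_segments = as.integer(nSeg),
       total_length_mm = totalMm)
}
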