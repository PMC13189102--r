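#' Hessian ridge filter for curvilinear structures
#'
#' Single-scale tubeness measure: after Gaussian smoothing at `sigma_px`,
#' the response is the magnitude of the negative principal curvature
#' (-lambda2 of the Hessian, clamped at 0), which is large on bright ridges
#' such as neurites and small on blobs and flat background.
#'
#' @param m intensity matrix.
#' @param sigma_px smoothing scale in pixels.
#' @return ridge-response matrix (same shape, >= 0).
#' @export
ridge_filter <- function(m, sigma_px = 1.5) {
  sm <- from_ebimage(EBImage::gblur(as_ebimage(m), sigma = sigma_px))
  # finite-difference Hessian
  shift <- function(a, dy, dx) {
    nr <- nrow(a); nc <- ncol(a)
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    a[ys, xs, drop = FALSE]
  }
  hyy <- shift(sm, 1, 0) + shift(sm, -1, 0) - 2 * sm
  hxx <- shift(sm, 0, 1) + shift(sm, 0, -1) - 2 * sm
  hxy <- (shift(sm, 1, 1) + shift(sm, -1, -1) -
            shift(sm, 1, -1) - shift(sm, -1, 1)) / 4
  tr <- hxx + hyy
  disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
  lambda2 <- (tr - disc) / 2   # most negative eigenvalue on bright ridges
  pmax(-lambda2, 0)
}

#' Morphological skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels while preserving 8-connectivity until no
#' change, yielding a one-pixel-wide skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask
  if (!any(m)) return(m)
  # pad to avoid boundary bookkeeping
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  nbr <- function(a, dy, dx) {
    a[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx), drop = FALSE]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      ctr <- p[2:(nr + 1), 2:(nc + 1), drop = FALSE]
      p2 <- nbr(p, -1, 0); p3 <- nbr(p, -1, 1); p4 <- nbr(p, 0, 1)
      p5 <- nbr(p, 1, 1);  p6 <- nbr(p, 1, 0);  p7 <- nbr(p, 1, -1)
      p8 <- nbr(p, 0, -1); p9 <- nbr(p, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- ctr & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- ctr & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        ctr[cond] <- FALSE
        p[2:(nr + 1), 2:(nc + 1)] <- ctr
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1), 2:(nc + 1), drop = FALSE]
}

# 8-neighbour count for every pixel of a logical matrix.
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  s <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- s + p[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx), drop = FALSE]
  }
  s
}

# Calibrated length of a one-pixel skeleton: orthogonal neighbour pairs
# contribute pixel_size, diagonal pairs sqrt(2) * pixel_size; diagonal pairs
# whose corner is short-circuited by an orthogonal pixel are not counted.
skeleton_length_um <- function(skel, pixel_size_um) {
  if (!any(skel)) return(0)
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- skel
  at <- function(dy, dx) p[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx),
                           drop = FALSE]
  ctr <- at(0, 0)
  n_orth <- sum(ctr & at(0, 1)) + sum(ctr & at(1, 0))
  # count each diagonal direction once; skip corner-cutting diagonals
  d1 <- ctr & at(1, 1) & !(at(0, 1) & at(1, 0))
  d2 <- ctr & at(1, -1) & !(at(0, -1) & at(1, 0))
  n_diag <- sum(d1) + sum(d2)
  (n_orth + sqrt(2) * n_diag) * pixel_size_um
}

#' Trace neurites and measure their morphology
#'
#' The neurite mask is the ridge-enhanced (optional), thresholded MAP2
#' signal minus the soma mask; it is skeletonized and summarized as a
#' calibrated total length (orthogonal steps = pixel size, diagonal steps =
#' sqrt(2) x pixel size) and the number of endpoint tips (skeleton pixels of
#' degree 1 outside somata). Empty input yields a zero-length skeleton.
#'
#' @param map2_channel a [channel_image()].
#' @param somata soma `roi_label_map` (same shape); may be NULL.
#' @param threshold absolute MAP2 threshold; default Otsu.
#' @param use_ridge apply [ridge_filter()] before thresholding (helps on
#'   noisy images; default FALSE, plain intensity thresholding).
#' @param min_component_px remove mask components smaller than this (speckle
#'   suppression, default 10).
#' @return list of class `neurite_skeleton`: `skeleton` (logical matrix),
#'   `mask`, `total_length_um`, `endpoint_count`, `pixel_size_um`.
#' @export
trace_neurites <- function(map2_channel, somata = NULL, threshold = NULL,
                           use_ridge = FALSE, min_component_px = 10) {
  stopifnot(inherits(map2_channel, "channel_image"))
  m <- map2_channel$intensity
  px <- map2_channel$pixel_size_um
  empty <- structure(list(skeleton = matrix(FALSE, nrow(m), ncol(m)),
                          mask = matrix(FALSE, nrow(m), ncol(m)),
                          total_length_um = 0, endpoint_count = 0L,
                          pixel_size_um = px), class = "neurite_skeleton")
  if (all(m == m[1])) return(empty)
  src <- if (use_ridge) ridge_filter(m) else m
  thr <- threshold %||% otsu_threshold(src)
  mask <- src > thr
  if (!is.null(somata)) {
    if (!all(dim(somata$labels) == dim(m))) stop("image/label shape mismatch")
    mask <- mask & somata$labels == 0L
  }
  if (min_component_px > 0 && any(mask)) {
    lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask)))
    sizes <- tabulate(lab[lab > 0])
    mask[sizes[pmax(lab, 1)] < min_component_px & lab > 0] <- FALSE
  }
  if (!any(mask)) return(empty)
  skel <- skeletonize(mask)
  deg <- neighbor_count(skel)
  endpoints <- skel & deg == 1
  if (!is.null(somata)) endpoints <- endpoints & somata$labels == 0L
  structure(list(skeleton = skel, mask = mask,
                 total_length_um = skeleton_length_um(skel, px),
                 endpoint_count = sum(endpoints),
                 pixel_size_um = px), class = "neurite_skeleton")
}
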