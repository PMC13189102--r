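#' Calibrated single-channel image
#'
#' Thin wrapper coupling an intensity matrix (rows = y, columns = x) with
#' its pixel size so that downstream areas and lengths are reported in
#' micrometres.
#'
#' @param intensity numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return object of class `channel_image`.
#' @export
channel_image <- function(intensity, pixel_size_um) {
  stopifnot(is.matrix(intensity), pixel_size_um > 0,
            all(is.finite(intensity)))
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um),
            class = "channel_image")
}

as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

# Otsu threshold (256-bin between-class variance maximization) on an
# arbitrary-range matrix.
otsu_threshold <- function(m, n_bins = 256L) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(m, breaks, rightmost.closed = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(w)
  mu1 <- cumsum(w * mids)
  mu_t <- mu1[n_bins]
  bcv <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Segment nuclei from the DAPI channel
#'
#' Threshold (Otsu unless given), fill holes, split touching nuclei by
#' distance-transform watershed, and filter by area in square micrometres.
#' An all-zero or empty-foreground image yields an empty label map.
#'
#' @param nucleus_channel a [channel_image()].
#' @param min_area_um2,max_area_um2 area gate.
#' @param threshold absolute intensity threshold; default Otsu.
#' @return list of class `roi_label_map`: `labels` (integer matrix, 0 =
#'   background), `kind` = "nucleus", `n`, `pixel_size_um`.
#' @export
segment_nuclei <- function(nucleus_channel, min_area_um2 = 12,
                           max_area_um2 = 500, threshold = NULL) {
  stopifnot(inherits(nucleus_channel, "channel_image"))
  m <- nucleus_channel$intensity
  px <- nucleus_channel$pixel_size_um
  if (all(m == m[1])) return(roi_label_map(matrix(0L, nrow(m), ncol(m)),
                                           "nucleus", px))
  thr <- threshold %||% otsu_threshold(m)
  mask <- m > thr
  if (!any(mask)) return(roi_label_map(matrix(0L, nrow(m), ncol(m)),
                                       "nucleus", px))
  emask <- EBImage::fillHull(as_ebimage(mask))
  dm <- EBImage::distmap(emask)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- from_ebimage(lab)
  # area gate in um^2, then relabel contiguously
  areas <- tabulate(labm[labm > 0])
  keep <- which(areas * px^2 >= min_area_um2 & areas * px^2 <= max_area_um2)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labm), ncol(labm))
  sel <- labm > 0
  out[sel] <- relab[labm[sel]]
  roi_label_map(out, "nucleus", px)
}

roi_label_map <- function(labels, kind, pixel_size_um) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind, n = max(labels),
                 pixel_size_um = pixel_size_um),
            class = "roi_label_map")
}

#' Segment somata around seed nuclei
#'
#' Each soma is the nucleus-seeded region of the thresholded MAP2 mask,
#' obtained by seeded propagation (geodesic nearest-seed assignment, so one
#' MAP2 blob containing two nuclei is partitioned between them), capped at a
#' configurable radius around the nucleus. Soma labels equal their seed
#' nucleus labels; a nucleus without surrounding MAP2 signal keeps its own
#' footprint as the soma.
#'
#' @param map2_channel a [channel_image()].
#' @param nuclei nucleus `roi_label_map` computed on the same-shape image.
#' @param radius_cap_um maximum soma radius from the nucleus (um);
#'   default 15. Prevents somata from swallowing proximal neurites.
#' @param threshold absolute MAP2 threshold. The default is a two-stage Otsu:
#'   a second Otsu split among above-(global-)Otsu pixels, which separates
#'   the bright, thick somatic MAP2 signal from the dimmer neurites so that
#'   the soma region does not leak down proximal neurites.
#' @return soma `roi_label_map` (labels match nuclei 1-to-1).
#' @export
segment_soma <- function(map2_channel, nuclei, radius_cap_um = 15,
                         threshold = NULL) {
  stopifnot(inherits(map2_channel, "channel_image"),
            inherits(nuclei, "roi_label_map"))
  m <- map2_channel$intensity
  if (!all(dim(m) == dim(nuclei$labels))) stop("image/label shape mismatch")
  px <- map2_channel$pixel_size_um
  if (nuclei$n == 0) return(roi_label_map(matrix(0L, nrow(m), ncol(m)),
                                          "soma", px))
  if (is.null(threshold)) {
    t1 <- otsu_threshold(m)
    above <- m[m > t1]
    threshold <- if (length(unique(above)) > 1) otsu_threshold(above) else t1
  }
  mask <- m > threshold | nuclei$labels > 0
  seeds <- as_ebimage(nuclei$labels)
  prop <- EBImage::propagate(as_ebimage(m), seeds, mask = as_ebimage(mask))
  labm <- from_ebimage(prop)
  storage.mode(labm) <- "integer"
  # radius cap: keep pixels within the cap of the nearest nucleus pixel
  dnuc <- from_ebimage(EBImage::distmap(as_ebimage(nuclei$labels == 0)))
  labm[dnuc * px > radius_cap_um] <- 0L
  labm[nuclei$labels > 0] <- nuclei$labels[nuclei$labels > 0]
  roi_label_map(labm, "soma", px)
}

#' Whole-cell mask and MAP2+ cell count
#'
#' Connected components of the thresholded MAP2 signal. A component counts as
#' a MAP2+ cell only when it contains at least one segmented nucleus; the
#' reported `n_cells` excludes nucleus-free components (all components remain
#' in the label map for compartment assignment).
#'
#' @param map2_channel a [channel_image()].
#' @param nuclei optional nucleus `roi_label_map` for the cell count.
#' @param threshold absolute threshold; default Otsu.
#' @return list of class `roi_label_map` with additional `n_cells` field.
#' @export
whole_cell_mask <- function(map2_channel, nuclei = NULL, threshold = NULL) {
  stopifnot(inherits(map2_channel, "channel_image"))
  m <- map2_channel$intensity
  px <- map2_channel$pixel_size_um
  if (all(m == m[1])) {
    out <- roi_label_map(matrix(0L, nrow(m), ncol(m)), "whole_cell", px)
    out$n_cells <- 0L
    return(out)
  }
  thr <- threshold %||% otsu_threshold(m)
  mask <- m > thr
  if (!is.null(nuclei)) mask <- mask | nuclei$labels > 0
  labm <- from_ebimage(EBImage::bwlabel(as_ebimage(mask)))
  storage.mode(labm) <- "integer"
  out <- roi_label_map(labm, "whole_cell", px)
  if (is.null(nuclei)) {
    out$n_cells <- out$n
  } else {
    with_nuc <- unique(labm[nuclei$labels > 0 & labm > 0])
    out$n_cells <- length(with_nuc)
  }
  out
}
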