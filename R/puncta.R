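#' Background intensity threshold from negative-control wells
#'
#' Pools all pixels of the channel across the negative-control wells and
#' returns mean + k * SD of the background staining. The default k = 0 uses
#' the plain background mean.
#'
#' @param negative_control_images list of [channel_image()] (or plain
#'   matrices) from negative-control wells; at least one required.
#' @param channel channel name recorded on the threshold.
#' @param k SD multiplier (default 0).
#' @return list of class `intensity_threshold`: `channel`, `value`, `k`,
#'   `n_wells`.
#' @export
background_threshold <- function(negative_control_images, channel, k = 0) {
  if (length(negative_control_images) == 0)
    stop("at least one negative-control well is required")
  vals <- unlist(lapply(negative_control_images, function(im) {
    if (inherits(im, "channel_image")) as.numeric(im$intensity)
    else as.numeric(im)
  }))
  s <- stats::sd(vals)
  if (is.na(s)) s <- 0
  structure(list(channel = channel, value = mean(vals) + k * s, k = k,
                 n_wells = length(negative_control_images)),
            class = "intensity_threshold")
}

#' Detect puncta in a channel and assign them to compartments
#'
#' Candidate spot pixels are those exceeding the negative-control threshold
#' by `mask_n_sd` background SDs (spot segmentation level); touching spots
#' are split by intensity watershed. Each footprint is summarized by its
#' centroid, equivalent-circular diameter and mean intensity. Footprints
#' whose mean intensity does not exceed the threshold value are discarded,
#' as are footprints with diameter outside the size gate (default
#' 0.4-4 um). Retained puncta are assigned to soma / neurite / whole-cell
#' compartments by centroid membership in the supplied ROI maps.
#'
#' @param channel_image a [channel_image()].
#' @param roi_maps optional named list with any of `soma` (roi_label_map),
#'   `neurite` (logical mask or neurite_skeleton) and `whole_cell`
#'   (roi_label_map) for compartment assignment.
#' @param threshold an `intensity_threshold` from [background_threshold()].
#' @param size_gate_um retained equivalent-circular diameter range (um).
#' @param background_sd background SD used for the segmentation level;
#'   defaults to (threshold value) * 0 + SD estimated from the image border
#'   when NULL — pass the known value for calibrated data.
#' @param mask_n_sd segmentation level above the threshold, in background
#'   SDs (default 4).
#' @param split_tolerance watershed tolerance for splitting touching spots;
#'   default 4 background SDs.
#' @param channel channel name; must match the threshold's channel.
#' @return data.frame of class `puncta_set`: id, channel, x, y (centroid,
#'   px), area_px, diameter_um, mean_intensity, compartment; the logical
#'   footprint label matrix is attached as attribute `footprints`.
#' @export
detect_puncta <- function(channel_image, roi_maps = NULL, threshold,
                          size_gate_um = c(0.4, 4), background_sd = NULL,
                          mask_n_sd = PUNCTA_MASK_N_SD,
                          split_tolerance = NULL, channel = threshold$channel) {
  stopifnot(inherits(channel_image, "channel_image"),
            inherits(threshold, "intensity_threshold"))
  if (!identical(channel, threshold$channel))
    stop("threshold channel ('", threshold$channel,
         "') does not match requested channel ('", channel, "')")
  m <- channel_image$intensity
  px <- channel_image$pixel_size_um
  if (is.null(background_sd)) {
    border <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
    background_sd <- stats::sd(border)
  }
  level <- threshold$value + mask_n_sd * background_sd
  mask <- m > level
  empty <- empty_puncta_set(channel)
  if (!any(mask)) return(empty)
  tol <- split_tolerance %||% (4 * background_sd)
  topo <- (m - level) * mask
  lab <- from_ebimage(EBImage::watershed(as_ebimage(topo), tolerance = tol,
                                         ext = 1))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  idx <- which(lab > 0)
  labs <- lab[idx]
  nr <- nrow(m)
  ys <- ((idx - 1) %% nr) + 1
  xs <- ((idx - 1) %/% nr) + 1
  area <- tabulate(labs, nlab)
  cx <- tapply(xs, labs, mean)
  cy <- tapply(ys, labs, mean)
  mi <- tapply(m[idx], labs, mean)
  diam <- 2 * sqrt(area * px^2 / pi)
  keep <- mi > threshold$value & diam >= size_gate_um[1] &
    diam <= size_gate_um[2]
  out <- data.frame(id = seq_len(sum(keep)), channel = channel,
                    x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
                    area_px = area[keep], diameter_um = diam[keep],
                    mean_intensity = as.numeric(mi[keep]),
                    compartment = "none", stringsAsFactors = FALSE)
  # relabel footprints to retained ids
  relab <- integer(nlab)
  relab[which(keep)] <- seq_len(sum(keep))
  foot <- matrix(0L, nrow(m), ncol(m))
  foot[idx] <- relab[labs]
  if (!is.null(roi_maps) && nrow(out) > 0) {
    out$compartment <- assign_compartment(out, roi_maps)
  }
  attr(out, "footprints") <- foot
  attr(out, "pixel_size_um") <- px
  class(out) <- c("puncta_set", "data.frame")
  out
}

empty_puncta_set <- function(channel) {
  out <- data.frame(id = integer(0), channel = character(0), x = numeric(0),
                    y = numeric(0), area_px = integer(0),
                    diameter_um = numeric(0), mean_intensity = numeric(0),
                    compartment = character(0), stringsAsFactors = FALSE)
  class(out) <- c("puncta_set", "data.frame")
  out
}

# Centroid-membership compartment call: soma wins over neurite, neurite over
# plain whole-cell membership.
assign_compartment <- function(puncta, roi_maps) {
  iy <- pmax(1, round(puncta$y)); ix <- pmax(1, round(puncta$x))
  get_at <- function(obj) {
    mm <- if (inherits(obj, "roi_label_map")) obj$labels > 0
    else if (inherits(obj, "neurite_skeleton")) obj$mask
    else obj
    mm[cbind(iy, ix)]
  }
  comp <- rep("none", nrow(puncta))
  if (!is.null(roi_maps$whole_cell)) comp[get_at(roi_maps$whole_cell)] <- "whole_cell"
  if (!is.null(roi_maps$neurite)) comp[get_at(roi_maps$neurite)] <- "neurite"
  if (!is.null(roi_maps$soma)) comp[get_at(roi_maps$soma)] <- "soma"
  comp
}

#' Overlap-based colocalization of two puncta channels
#'
#' For every punctum of channel A (the overlaid channel), the overlap
#' fraction is the share of its footprint pixels covered by any channel-B
#' footprint; the punctum is colocalized when the fraction reaches
#' `min_overlap` (ties at exactly the cutoff count, "at least" semantics).
#' An A punctum overlapping several B puncta is counted once.
#'
#' @param puncta_a,puncta_b `puncta_set` objects from [detect_puncta()] on
#'   the same well/field geometry.
#' @param min_overlap minimum overlap fraction (default 0.5).
#' @return list of class `colocalization_result`: `pairs` (data.frame:
#'   punctum_a, overlap_fraction, colocalized), `colocalized_count`,
#'   `n_a`, `n_b`.
#' @export
colocalize <- function(puncta_a, puncta_b, min_overlap = 0.5) {
  fa <- attr(puncta_a, "footprints")
  fb <- attr(puncta_b, "footprints")
  n_a <- nrow(puncta_a); n_b <- nrow(puncta_b)
  if (n_a == 0) {
    return(structure(list(pairs = data.frame(punctum_a = integer(0),
                                             overlap_fraction = numeric(0),
                                             colocalized = logical(0)),
                          colocalized_count = 0L, n_a = 0L, n_b = n_b),
                     class = "colocalization_result"))
  }
  if (!all(dim(fa) == dim(fb))) stop("footprint geometries differ")
  bcov <- fb > 0
  idx <- which(fa > 0)
  labs <- fa[idx]
  area <- tabulate(labs, n_a)
  inter <- tapply(bcov[idx], labs, sum)
  frac <- rep(0, n_a)
  frac[as.integer(names(inter))] <- as.numeric(inter) / area[as.integer(names(inter))]
  pairs <- data.frame(punctum_a = seq_len(n_a), overlap_fraction = frac,
                      colocalized = frac >= min_overlap)
  structure(list(pairs = pairs, colocalized_count = sum(pairs$colocalized),
                 n_a = n_a, n_b = n_b),
            class = "colocalization_result")
}
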