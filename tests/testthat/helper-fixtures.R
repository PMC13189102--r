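# Shared fixtures built in code.

# Small noise-controlled plate: bright well-separated spots, no matched
# channel-B partners; used by detection and colocalization tests.
clean_plate <- function(seed = 11, ...) {
  generate_plate_images(image_sim_config(
    rng_seed = seed, n_wells_per_group = 1,
    min_separation_um = 3, coloc_fraction = 0,
    punctum_intensity = c(500, 50), ...))
}

# Synthetic blank channel (pure Gaussian background).
blank_channel <- function(nr = 64, nc = 64, mean = 100, sd = 10, seed = 1,
                          pixel_size_um = 0.3) {
  set.seed(seed)
  channel_image(matrix(rnorm(nr * nc, mean, sd), nr, nc), pixel_size_um)
}

# Matrix with rendered disks (for nucleus/soma fixtures).
disk_image <- function(centers, r, nr = 96, nc = 96, value = 200, bg = 0,
                       pixel_size_um = 0.5) {
  m <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    for (x in seq_len(nc)) {
      dy2 <- r^2 - (x - centers[i, 1])^2
      if (dy2 < 0) next
      ys <- max(1, ceiling(centers[i, 2] - sqrt(dy2))):
        min(nr, floor(centers[i, 2] + sqrt(dy2)))
      m[ys, x] <- value
    }
  }
  channel_image(m, pixel_size_um)
}

# Greedy centroid matching of detected puncta against ground truth.
match_puncta <- function(det, truth, max_dist_px = 2) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2)
    j <- which(!used & d < max_dist_px)
    if (length(j) > 0) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp,
       precision = if (nrow(det)) tp / nrow(det) else NA_real_,
       recall = if (nrow(truth)) tp / nrow(truth) else NA_real_)
}

# Minimal synthetic puncta_set with given footprints (list of pixel index
# matrices rbind(y, x)) on an nr x nc grid, for colocalization oracles.
manual_puncta_set <- function(footprints, nr, nc, channel = "a") {
  foot <- matrix(0L, nr, nc)
  rows <- lapply(seq_along(footprints), function(i) {
    pix <- footprints[[i]]
    foot[pix] <<- i
    data.frame(id = i, channel = channel,
               x = mean(pix[, 2]), y = mean(pix[, 1]),
               area_px = nrow(pix),
               diameter_um = 2 * sqrt(nrow(pix) * 0.09 / pi),
               mean_intensity = 1000, compartment = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "footprints") <- foot
  class(out) <- c("puncta_set", "data.frame")
  out
}
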