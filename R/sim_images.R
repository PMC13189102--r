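#' Configuration for the synthetic fluorescence plate simulator
#'
#' Describes one plate of a high-content imaging experiment: four channels
#' per well (nucleus, MAP2-like cytoskeletal, puncta channel A, puncta
#' channel B), wells grouped by genotype with per-compartment puncta-density
#' multipliers, one wild-type reference group and one negative-control well
#' (structure channels plus background only, no puncta-channel signal).
#'
#' @param image_size_px integer pair (rows, cols).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param n_wells_per_group technical wells per genotype.
#' @param genotype_effects named list: genotype -> named numeric multipliers
#'   for `neurite`, `soma`, `whole_cell` densities. Must contain a
#'   `wildtype` entry (the plate reference).
#' @param base_densities named numeric: `neurite` = puncta per 100 um of
#'   neurite, `soma` = puncta per soma, `whole_cell` = puncta per cell.
#' @param punctum_diameter_um length-2 bounds (um) of the sampled
#'   above-threshold footprint diameter.
#' @param punctum_intensity length-2 mean and SD of the spot peak amplitude
#'   above background (a.u.).
#' @param background_mean,background_sd Gaussian background statistics (a.u.).
#' @param n_fields_per_well fields of view imaged per well; counts and
#'   lengths are aggregated across fields at quantification.
#' @param n_cells cells placed per field.
#' @param neurites_per_cell primary neurites per cell.
#' @param mean_neurite_length_um mean primary-neurite length (um).
#' @param branch_probability per-step probability that a growing neurite
#'   spawns a branch.
#' @param coloc_fraction fraction of channel-A puncta that receive a matched
#'   channel-B punctum at the same centre (putative synapses).
#' @param min_separation_um when > 0, placed puncta closer than this to an
#'   already-placed punctum of the same channel are dropped (noise-controlled
#'   plates for detector validation); 0 (default) keeps the pure Poisson
#'   placement.
#' @param nucleus_radius_um,soma_radius_um rendered structure radii (um).
#' @param rng_seed integer seed.
#' @return object of class `image_sim_config`.
#' @export
image_sim_config <- function(image_size_px = c(256, 256), pixel_size_um = 0.3,
                             n_wells_per_group = 3, n_fields_per_well = 1,
                             genotype_effects = list(
                               wildtype = c(neurite = 1, soma = 1, whole_cell = 1),
                               hom = c(neurite = 2, soma = 1, whole_cell = 1)),
                             base_densities = c(neurite = 3, soma = 4,
                                                whole_cell = 6),
                             punctum_diameter_um = c(0.8, 1.6),
                             punctum_intensity = c(500, 50),
                             background_mean = 100, background_sd = 15,
                             n_cells = 8, neurites_per_cell = 3,
                             mean_neurite_length_um = 40,
                             branch_probability = 0.25,
                             coloc_fraction = 0.3, min_separation_um = 0,
                             nucleus_radius_um = 3.5, soma_radius_um = 6,
                             rng_seed = 1) {
  if (any(image_size_px <= 0) || pixel_size_um <= 0)
    stop("image size and pixel size must be positive")
  if (!"wildtype" %in% names(genotype_effects))
    stop("genotype_effects must include a 'wildtype' reference group")
  stopifnot(all(base_densities >= 0),
            all(unlist(genotype_effects) >= 0),
            all(c("neurite", "soma", "whole_cell") %in% names(base_densities)))
  structure(as.list(environment()), class = "image_sim_config")
}

# Detection defaults shared between the renderer and detect_puncta(): the
# punctum footprint is the set of pixels exceeding the background threshold
# by `mask_n_sd` background SDs.
PUNCTA_MASK_N_SD <- 4

# sample() that never falls into the 1:x scalar trap
sample_vec <- function(x, k, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), k, replace = replace, prob = prob)]
}

#' Generate a simulated plate with full ground truth
#'
#' Places nuclei, somata and random-walk neurite trees per well, renders the
#' four channels, and scatters puncta in each compartment at the configured
#' genotype-scaled densities (counts are Poisson: neurite counts with mean
#' density x length / 100, soma and whole-cell counts with the per-unit
#' means). Spots are 2D isotropic Gaussians whose sigma is chosen so that the
#' above-threshold footprint (background mean + 4 background SD) has the
#' sampled equivalent-circular diameter; that diameter is recorded in the
#' ground truth. Deterministic under the config seed.
#'
#' @param config an [image_sim_config()].
#' @return list of class `plate_sim` with `wells` (named list; each well is a
#'   list of fields, each field holding `channels` —
#'   nucleus/map2/puncta_a/puncta_b matrices — and `truth`), `plate_map`
#'   (well, clone, genotype, role) and `config`. Each field truth carries
#'   nuclei centres, soma parameters, neurite polylines with lengths, the
#'   placed puncta table and the ground-truth compartment masks.
#' @export
generate_plate_images <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed(config$rng_seed, {
    wells <- list()
    rows <- list()
    idx <- 0L
    sim_fields <- function(effects, puncta) {
      lapply(seq_len(config$n_fields_per_well), function(f)
        simulate_well(config, effects, puncta = puncta))
    }
    for (g in names(config$genotype_effects)) {
      for (w in seq_len(config$n_wells_per_group)) {
        idx <- idx + 1L
        id <- sprintf("W%02d", idx)
        wells[[id]] <- sim_fields(config$genotype_effects[[g]], TRUE)
        rows[[idx]] <- data.frame(
          well = id, clone = paste0(g, "_c1"), genotype = g,
          role = if (g == "wildtype") "wildtype_reference" else "sample",
          stringsAsFactors = FALSE)
      }
    }
    idx <- idx + 1L
    id <- sprintf("W%02d", idx)
    wells[[id]] <- sim_fields(config$genotype_effects[["wildtype"]], FALSE)
    rows[[idx]] <- data.frame(well = id, clone = "none", genotype = "none",
                              role = "negative_control",
                              stringsAsFactors = FALSE)
    structure(list(wells = wells, plate_map = do.call(rbind, rows),
                   config = config),
              class = "plate_sim")
  })
}

#' Aggregate the ground truth of one well across its fields
#'
#' @param well one element of `plate_sim$wells`.
#' @return list with summed `total_neurite_length_um`, `n_endpoints`,
#'   `n_cells`, and the row-bound `puncta` table (with a `field` column).
#' @export
well_truth <- function(well) {
  pl <- lapply(seq_along(well), function(f) {
    p <- well[[f]]$truth$puncta
    if (nrow(p) > 0) p$field <- f
    p
  })
  pl <- pl[vapply(pl, nrow, 1L) > 0]
  list(
    total_neurite_length_um = sum(vapply(well, function(fd)
      fd$truth$total_neurite_length_um, 1)),
    n_endpoints = sum(vapply(well, function(fd) fd$truth$n_endpoints, 1)),
    n_cells = sum(vapply(well, function(fd)
      nrow(fd$truth$nuclei_centers), 1L)),
    puncta = if (length(pl)) do.call(rbind, pl) else empty_puncta_truth()
  )
}

# One well: structure geometry, channel rendering, puncta placement.
simulate_well <- function(config, effects, puncta = TRUE) {
  px <- config$pixel_size_um
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  r_nuc <- config$nucleus_radius_um / px
  r_soma <- config$soma_radius_um / px
  margin <- r_soma + 2

  centers <- place_centers(config$n_cells, nr, nc, margin,
                           min_sep = 2.4 * r_soma)
  n_cells <- nrow(centers)

  trees <- lapply(seq_len(n_cells), function(i) {
    grow_neurites(centers[i, ], r_soma, config, nr, nc)
  })

  # masks: label maps for nuclei/soma/cells, logical mask for neurites
  nuc_lab <- matrix(0L, nr, nc)
  soma_lab <- matrix(0L, nr, nc)
  for (i in seq_len(n_cells)) {
    nuc_lab <- stamp_disk_label(nuc_lab, centers[i, ], r_nuc, i)
    soma_lab <- stamp_disk_label(soma_lab, centers[i, ], r_soma, i)
  }
  neur_mask <- matrix(FALSE, nr, nc)
  width_px <- max(3, round(1.2 / px))
  for (tr in trees) for (pl in tr$polylines)
    neur_mask <- rasterize_polyline(neur_mask, pl, width_px / 2)
  neur_mask <- neur_mask & soma_lab == 0L
  cell_lab <- soma_lab
  # whole cell = soma plus this well's neurite pixels, labelled by nearest soma
  if (any(neur_mask)) {
    near <- nearest_center(which(neur_mask), nr, centers)
    cell_lab[which(neur_mask)] <- near
  }

  # channels
  bgm <- config$background_mean; bgs <- config$background_sd
  ch_nuc <- matrix(stats::rnorm(nr * nc, bgm, bgs), nr, nc)
  ch_map2 <- matrix(stats::rnorm(nr * nc, bgm, bgs), nr, nc)
  # somata render bright and thick, neurites dimmer, as in MAP2 stains
  ch_nuc[nuc_lab > 0L] <- ch_nuc[nuc_lab > 0L] + 8 * bgs + bgm
  ch_map2[neur_mask] <- ch_map2[neur_mask] + 5 * bgs + bgm
  ch_map2[soma_lab > 0L] <- ch_map2[soma_lab > 0L] + 12 * bgs + bgm
  ch_a <- matrix(stats::rnorm(nr * nc, bgm, bgs), nr, nc)
  ch_b <- matrix(stats::rnorm(nr * nc, bgm, bgs), nr, nc)

  truth_puncta <- empty_puncta_truth()
  if (puncta) {
    dens <- config$base_densities * effects[names(config$base_densities)]
    masks <- list(soma = soma_lab > 0L, neurite = neur_mask,
                  whole_cell = cell_lab > 0L)
    pa <- place_puncta(config, trees, centers, dens, masks, nr, nc)
    pb <- place_puncta(config, trees, centers, dens, masks, nr, nc)
    # matched channel-B partners for a fraction of A puncta
    if (nrow(pa) > 0 && config$coloc_fraction > 0) {
      n_match <- stats::rbinom(1, nrow(pa), config$coloc_fraction)
      if (n_match > 0) {
        sel <- sample(nrow(pa), n_match)
        pb <- rbind(pb, pa[sel, , drop = FALSE])
      }
    }
    if (nrow(pa) > 0) pa$channel <- "puncta_a"
    if (nrow(pb) > 0) pb$channel <- "puncta_b"
    ch_a <- add_spots(ch_a, pa)
    ch_b <- add_spots(ch_b, pb)
    truth_puncta <- rbind(pa, pb)
  }

  total_len <- sum(vapply(trees, function(tr) tr$total_length_um, 1))
  n_tips <- sum(vapply(trees, function(tr) tr$n_tips, 1L))
  list(
    channels = list(nucleus = ch_nuc, map2 = ch_map2,
                    puncta_a = ch_a, puncta_b = ch_b),
    truth = list(
      nuclei_centers = centers,
      soma_radius_px = r_soma, nucleus_radius_px = r_nuc,
      polylines = unlist(lapply(trees, `[[`, "polylines"), recursive = FALSE),
      polyline_lengths_um = unlist(lapply(trees, `[[`, "lengths_um")),
      total_neurite_length_um = total_len,
      n_endpoints = n_tips,
      puncta = truth_puncta,
      masks = list(nucleus = nuc_lab, soma = soma_lab,
                   neurite = neur_mask, whole_cell = cell_lab),
      densities = if (puncta)
        config$base_densities * effects[names(config$base_densities)]
      else config$base_densities * 0
    )
  )
}

empty_puncta_truth <- function() {
  data.frame(x = numeric(0), y = numeric(0), diameter_um = numeric(0),
             amplitude = numeric(0), sigma_px = numeric(0),
             compartment = character(0), channel = character(0),
             stringsAsFactors = FALSE)
}

# Rejection-sample cell centres with a minimum separation; may return fewer
# than requested when the field is crowded.
place_centers <- function(n, nr, nc, margin, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 400 * n) {
    tries <- tries + 1
    cand <- c(stats::runif(1, margin, nc - margin),
              stats::runif(1, margin, nr - margin))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep)
      pts <- rbind(pts, cand)
  }
  colnames(pts) <- c("x", "y")
  pts
}

# Persistent-direction random-walk neurite tree rooted at the soma edge.
grow_neurites <- function(center, r_soma, config, nr, nc) {
  px <- config$pixel_size_um
  step_um <- 2
  polylines <- list(); lengths <- numeric(0); n_tips <- 0L
  grow_one <- function(start, theta, length_um) {
    pts <- matrix(start, 1, 2)
    len <- 0
    branches <- list()
    while (len < length_um) {
      theta <- theta + stats::rnorm(1, 0, 0.25)
      nxt <- pts[nrow(pts), ] + step_um / px * c(cos(theta), sin(theta))
      if (nxt[1] < 3 || nxt[1] > nc - 2 || nxt[2] < 3 || nxt[2] > nr - 2) break
      pts <- rbind(pts, nxt)
      len <- len + step_um
      if (stats::runif(1) < config$branch_probability && len > 6) {
        branches[[length(branches) + 1L]] <-
          list(start = nxt, theta = theta + sample(c(-1, 1), 1) * 0.7,
               length_um = max(4, (length_um - len) * stats::runif(1, 0.4, 1)))
      }
    }
    list(pts = pts, len = len, branches = branches)
  }
  queue <- lapply(seq_len(config$neurites_per_cell), function(i) {
    theta <- stats::runif(1, 0, 2 * pi)
    list(start = center + (r_soma - 0.5) * c(cos(theta), sin(theta)),
         theta = theta,
         length_um = max(8, stats::rnorm(1, config$mean_neurite_length_um,
                                         config$mean_neurite_length_um / 4)))
  })
  while (length(queue) > 0) {
    job <- queue[[1]]; queue <- queue[-1]
    res <- grow_one(job$start, job$theta, job$length_um)
    if (nrow(res$pts) >= 2) {
      polylines[[length(polylines) + 1L]] <- res$pts
      lengths <- c(lengths, res$len)
      n_tips <- n_tips + 1L
    }
    queue <- c(queue, res$branches)
  }
  list(polylines = polylines, lengths_um = lengths,
       total_length_um = sum(lengths), n_tips = n_tips)
}

stamp_disk_label <- function(lab, center, r, value) {
  nr <- nrow(lab); nc <- ncol(lab)
  xs <- max(1, floor(center[1] - r)):min(nc, ceiling(center[1] + r))
  ys <- max(1, floor(center[2] - r)):min(nr, ceiling(center[2] + r))
  for (x in xs) {
    dy <- sqrt(pmax(0, r^2 - (x - center[1])^2))
    yy <- ys[ys >= center[2] - dy & ys <= center[2] + dy]
    lab[yy, x] <- value
  }
  lab
}

# Mark all pixels within `radius` px (square stencil) of the polyline.
rasterize_polyline <- function(mask, pts, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    n <- max(2, ceiling(sqrt(sum((b - a)^2)) * 1.5))
    ts <- seq(0, 1, length.out = n)
    xs <- c(xs, a[1] + ts * (b[1] - a[1]))
    ys <- c(ys, a[2] + ts * (b[2] - a[2]))
  }
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  py <- pmin(pmax(round(rep(ys, each = nrow(off)) + off$dy), 1), nr)
  px <- pmin(pmax(round(rep(xs, each = nrow(off)) + off$dx), 1), nc)
  mask[cbind(py, px)] <- TRUE
  mask
}

nearest_center <- function(lin_idx, nr, centers) {
  y <- ((lin_idx - 1) %% nr) + 1
  x <- ((lin_idx - 1) %/% nr) + 1
  d2 <- outer(x, centers[, 1], function(a, b) (a - b)^2) +
    outer(y, centers[, 2], function(a, b) (a - b)^2)
  max.col(-d2)
}

# Scatter puncta in each compartment and return the ground-truth table.
place_puncta <- function(config, trees, centers, dens, masks, nr, nc) {
  px <- config$pixel_size_um
  out <- list()
  # neurite puncta: Poisson along total arc length
  total_len <- sum(vapply(trees, function(tr) tr$total_length_um, 1))
  n_neu <- stats::rpois(1, dens[["neurite"]] * total_len / 100)
  if (n_neu > 0 && total_len > 0) {
    pos <- sample_on_polylines(trees, n_neu, masks, nr)
    out[[length(out) + 1L]] <- cbind(pos, compartment = "neurite")
  }
  # soma puncta: per-soma Poisson, uniform in the disk
  for (i in seq_len(nrow(centers))) {
    k <- stats::rpois(1, dens[["soma"]])
    if (k == 0) next
    r <- (config$soma_radius_um / px - 1) * sqrt(stats::runif(k))
    th <- stats::runif(k, 0, 2 * pi)
    out[[length(out) + 1L]] <- data.frame(
      x = centers[i, 1] + r * cos(th), y = centers[i, 2] + r * sin(th),
      compartment = "soma", stringsAsFactors = FALSE)
  }
  # whole-cell puncta: per-cell Poisson, uniform over the cell mask
  cell_idx <- which(masks$whole_cell)
  if (length(cell_idx) > 0) {
    for (i in seq_len(nrow(centers))) {
      k <- stats::rpois(1, dens[["whole_cell"]])
      if (k == 0) next
      pick <- sample_vec(cell_idx, k, replace = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        x = ((pick - 1) %/% nr) + 1, y = ((pick - 1) %% nr) + 1,
        compartment = "whole_cell", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_puncta_truth())
  pts <- do.call(rbind, out)
  if (config$min_separation_um > 0 && nrow(pts) > 1) {
    keep <- logical(nrow(pts))
    keep[1] <- TRUE
    sep_px <- config$min_separation_um / px
    for (i in 2:nrow(pts)) {
      d <- sqrt((pts$x[keep] - pts$x[i])^2 + (pts$y[keep] - pts$y[i])^2)
      keep[i] <- all(d >= sep_px)
    }
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  d <- stats::runif(n, config$punctum_diameter_um[1],
                    config$punctum_diameter_um[2])
  amp <- pmax(stats::rnorm(n, config$punctum_intensity[1],
                           config$punctum_intensity[2]),
              config$punctum_intensity[1] / 2)
  level <- PUNCTA_MASK_N_SD * config$background_sd
  sigma_px <- (d / px / 2) / sqrt(2 * log(amp / level))
  data.frame(x = pts$x, y = pts$y, diameter_um = d, amplitude = amp,
             sigma_px = sigma_px, compartment = pts$compartment,
             channel = NA_character_, stringsAsFactors = FALSE)
}

# Arc-length-uniform positions on the neurite trees, nudged onto the
# recorded neurite mask (outside somata).
sample_on_polylines <- function(trees, n, masks, nr) {
  polys <- unlist(lapply(trees, `[[`, "polylines"), recursive = FALSE)
  lens <- unlist(lapply(trees, `[[`, "lengths_um"))
  pick <- sample(seq_along(polys), n, replace = TRUE, prob = lens)
  pts <- t(vapply(pick, function(i) {
    pl <- polys[[i]]
    seg <- sample(nrow(pl) - 1, 1)
    t0 <- stats::runif(1)
    pl[seg, ] + t0 * (pl[seg + 1, ] - pl[seg, ])
  }, numeric(2)))
  df <- data.frame(x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
  # keep only positions whose pixel lies in the neurite mask (polyline points
  # close to a soma fall in the soma mask and are resampled from the rest)
  px_ok <- masks$neurite[cbind(round(df$y), round(df$x))]
  bad <- which(!px_ok)
  good <- which(px_ok)
  for (b in bad) {
    if (length(good) > 0) df[b, ] <- df[sample_vec(good, 1), ]
    else {
      idx <- which(masks$neurite)
      if (length(idx) == 0) next
      j <- sample_vec(idx, 1)
      df[b, ] <- c(((j - 1) %/% nr) + 1, ((j - 1) %% nr) + 1)
    }
  }
  df
}

# Stamp Gaussian spots into a channel matrix.
add_spots <- function(mat, p) {
  if (nrow(p) == 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  x <- p$x; y <- p$y; s <- p$sigma_px; amp <- p$amplitude
  for (i in seq_len(nrow(p))) {
    ext <- ceiling(4 * s[i])
    xs <- max(1, round(x[i]) - ext):min(nc, round(x[i]) + ext)
    ys <- max(1, round(y[i]) - ext):min(nr, round(y[i]) + ext)
    gx <- exp(-(xs - x[i])^2 / (2 * s[i]^2))
    gy <- exp(-(ys - y[i])^2 / (2 * s[i]^2))
    mat[ys, xs] <- mat[ys, xs] + amp[i] * outer(gy, gx)
  }
  mat
}

#' Write a simulated plate to disk
#'
#' One multi-page TIFF per field (pages: nucleus, map2, puncta_a, puncta_b;
#' 16-bit), the plate map as CSV, and the per-well ground truth as JSON.
#'
#' @param plate a `plate_sim` from [generate_plate_images()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_plate_images <- function(plate, dir) {
  stopifnot(inherits(plate, "plate_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(plate$wells)) {
    for (f in seq_along(plate$wells[[id]])) {
      chs <- plate$wells[[id]][[f]]$channels
      imgs <- lapply(chs, function(m) {
        EBImage::Image(t(pmax(pmin(m / 4096, 1), 0)))
      })
      EBImage::writeImage(EBImage::combine(imgs),
                          file.path(dir, sprintf("%s_F%02d.tiff", id, f)),
                          type = "tiff", bits.per.sample = 16L)
    }
  }
  utils::write.csv(plate$plate_map, file.path(dir, "plate_map.csv"),
                   row.names = FALSE)
  truth <- lapply(plate$wells, function(w) {
    tr <- well_truth(w)
    list(total_neurite_length_um = tr$total_neurite_length_um,
         n_endpoints = tr$n_endpoints,
         n_cells = tr$n_cells,
         puncta = tr$puncta)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
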