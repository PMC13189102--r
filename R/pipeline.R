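#' Segment and count one simulated (or loaded) well
#'
#' Runs the full compartment workflow on a well's four channels: nucleus
#' segmentation, nucleus-seeded soma segmentation, neurite tracing and
#' whole-cell labelling, then puncta detection per puncta channel with
#' compartment assignment.
#'
#' @param channels named list of intensity matrices (`nucleus`, `map2`, and
#'   the puncta channels).
#' @param pixel_size_um pixel calibration.
#' @param thresholds named list of `intensity_threshold` objects, one per
#'   puncta channel.
#' @param size_gate_um punctum diameter gate (um).
#' @param background_sd known background SD (passed to [detect_puncta()]).
#' @return list with `rois` (nuclei, somata, neurites, cells), `puncta`
#'   (named list of `puncta_set`) and `quant` (one-row data.frame of well
#'   summary counts).
#' @export
analyze_well <- function(channels, pixel_size_um, thresholds,
                         size_gate_um = c(0.4, 4), background_sd = NULL) {
  nuc <- segment_nuclei(channel_image(channels$nucleus, pixel_size_um))
  map2 <- channel_image(channels$map2, pixel_size_um)
  soma <- segment_soma(map2, nuc)
  neur <- trace_neurites(map2, soma)
  cells <- whole_cell_mask(map2, nuc)
  rois <- list(soma = soma, neurite = neur, whole_cell = cells)
  puncta <- list()
  for (ch in names(thresholds)) {
    puncta[[ch]] <- detect_puncta(channel_image(channels[[ch]], pixel_size_um),
                                  roi_maps = rois, threshold = thresholds[[ch]],
                                  size_gate_um = size_gate_um,
                                  background_sd = background_sd)
  }
  quant <- data.frame(n_nuclei = nuc$n, n_somata = soma$n,
                      n_cells = cells$n_cells,
                      total_neurite_length_um = neur$total_length_um,
                      n_endpoints = neur$endpoint_count)
  list(rois = rois, puncta = puncta, quant = quant)
}

#' Quantify a simulated plate end to end
#'
#' Derives the per-channel background thresholds from the plate's
#' negative-control wells, analyzes every sample well, and returns a tidy
#' per-(well, channel, compartment) table of puncta counts (PC), denominators
#' and normalized densities (delta-PC), plus plate-matched fold changes
#' (delta-delta-PC) against the mean wild-type-reference density.
#'
#' @param plate a `plate_sim` from [generate_plate_images()], or an
#'   equivalent list with `wells`, `plate_map` and `config`.
#' @param channels puncta channels to quantify.
#' @param k SD multiplier for the background threshold (default 0).
#' @param size_gate_um punctum diameter gate.
#' @param colocalization if TRUE, also compute channel-A-onto-B
#'   colocalization per well (count normalized to neurite length).
#' @return list with `wells` (well-level summary), `puncta` (tidy per-well
#'   PC/dPC/ddPC table), `replicates` (technical wells averaged per clone,
#'   with the fold change recomputed on the averaged densities — the grain
#'   the group statistics consume) and optionally `coloc`.
#' @export
quantify_plate <- function(plate, channels = c("puncta_a", "puncta_b"),
                           k = 0, size_gate_um = c(0.4, 4),
                           colocalization = FALSE) {
  pm <- plate$plate_map
  px <- plate$config$pixel_size_um
  bg_sd <- plate$config$background_sd
  neg <- pm$well[pm$role == "negative_control"]
  if (length(neg) == 0) stop("plate has no negative-control well")
  thresholds <- lapply(stats::setNames(channels, channels), function(ch) {
    imgs <- unlist(lapply(neg, function(w)
      lapply(plate$wells[[w]], function(fd) fd$channels[[ch]])),
      recursive = FALSE)
    background_threshold(imgs, channel = ch, k = k)
  })
  sample_wells <- pm$well[pm$role != "negative_control"]
  # analyze each field, then aggregate counts and lengths per well
  res <- lapply(stats::setNames(sample_wells, sample_wells), function(w) {
    fields <- lapply(plate$wells[[w]], function(fd) {
      analyze_well(fd$channels, px, thresholds,
                   size_gate_um = size_gate_um, background_sd = bg_sd)
    })
    quant <- Reduce(`+`, lapply(fields, `[[`, "quant"))
    pc <- list()
    for (ch in channels) {
      pc[[ch]] <- c(soma = 0, neurite = 0, whole_cell = 0)
      for (fd in fields) {
        p <- fd$puncta[[ch]]
        pc[[ch]] <- pc[[ch]] + c(
          soma = sum(p$compartment == "soma"),
          neurite = sum(p$compartment == "neurite"),
          whole_cell = sum(p$compartment != "none"))
      }
    }
    coloc_n <- if (colocalization && length(channels) >= 2) {
      sum(vapply(fields, function(fd)
        colocalize(fd$puncta[[channels[1]]],
                   fd$puncta[[channels[2]]])$colocalized_count, 1L))
    } else NA_integer_
    list(quant = quant, pc = pc, coloc_n = coloc_n)
  })
  wells <- do.call(rbind, lapply(sample_wells, function(w) {
    cbind(pm[pm$well == w, , drop = FALSE], res[[w]]$quant)
  }))
  rownames(wells) <- NULL
  rows <- list()
  for (w in sample_wells) {
    q <- res[[w]]$quant
    for (ch in channels) {
      for (comp in c("soma", "neurite", "whole_cell")) {
        pc <- res[[w]]$pc[[ch]][[comp]]
        dpc <- normalize_puncta(
          pc, comp,
          somata_count = q$n_somata, cell_count = q$n_cells,
          neurite_length_um = q$total_neurite_length_um)
        rows[[length(rows) + 1L]] <- data.frame(
          well = w, clone = pm$clone[pm$well == w],
          genotype = pm$genotype[pm$well == w],
          role = pm$role[pm$well == w], channel = ch, compartment = comp,
          pc = pc, dpc = dpc, stringsAsFactors = FALSE)
      }
    }
  }
  tidy <- do.call(rbind, rows)
  # plate-matched fold change against the mean wild-type reference density
  tidy$ddpc <- NA_real_
  for (ch in channels) for (comp in c("soma", "neurite", "whole_cell")) {
    sel <- tidy$channel == ch & tidy$compartment == comp
    ref <- tidy$dpc[sel & tidy$role == "wildtype_reference"]
    tidy$ddpc[sel] <- vapply(tidy$dpc[sel], fold_change_vs_reference,
                             numeric(1), dpc_reference = ref)
  }
  # technical wells averaged per (clone, genotype): one fold change per
  # clone and plate, the grain the group statistics consume
  reps <- list()
  for (ch in channels) for (comp in c("soma", "neurite", "whole_cell")) {
    sel <- tidy$channel == ch & tidy$compartment == comp
    sub <- tidy[sel, , drop = FALSE]
    ref <- mean(sub$dpc[sub$role == "wildtype_reference"], na.rm = TRUE)
    avg <- average_technical_replicates(sub$dpc, sub$clone, 1L,
                                        genotype = sub$genotype)
    avg$channel <- ch; avg$compartment <- comp
    avg$ddpc <- vapply(avg$value, fold_change_vs_reference, numeric(1),
                       dpc_reference = ref)
    reps[[length(reps) + 1L]] <- avg
  }
  replicates <- do.call(rbind, reps)
  names(replicates)[names(replicates) == "value"] <- "dpc"
  out <- list(wells = wells, puncta = tidy, replicates = replicates,
              thresholds = thresholds)
  if (colocalization) {
    out$coloc <- do.call(rbind, lapply(sample_wells, function(w) {
      data.frame(well = w, genotype = pm$genotype[pm$well == w],
                 colocalized_count = res[[w]]$coloc_n,
                 per_um = res[[w]]$coloc_n /
                   res[[w]]$quant$total_neurite_length_um,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Genotype density-multiplier recovery experiment
#'
#' Simulates plates whose mutant wells carry a configured per-compartment
#' puncta-density multiplier, runs the full segmentation/detection/
#' normalization pipeline, and reports the recovered mean neurite
#' delta-delta-PC per multiplier. Plate design: 2 wild-type-reference and 2
#' mutant wells of 2 fields each plus one negative control; densities are
#' kept low enough (1.25 neurite puncta per 100 um at multiplier 1, spot
#' diameters 0.6-1 um) that spot overlap stays negligible relative to the
#' detector's ~1 um two-point resolution at the largest multiplier.
#'
#' @param multipliers numeric vector of density multipliers to plant.
#' @param n_plates simulated plates per multiplier.
#' @param seed base seed; plate p of multiplier m uses a seed derived from
#'   (seed, m, p).
#' @return data.frame: multiplier, plate, recovered ddpc; with a summary
#'   attribute `means` (named mean recovered ddpc per multiplier).
#' @export
ddpc_recovery_experiment <- function(multipliers = c(0.5, 2, 4),
                                     n_plates = 20, seed = 1) {
  rows <- list()
  for (mi in seq_along(multipliers)) {
    m <- multipliers[mi]
    for (p in seq_len(n_plates)) {
      cfg <- image_sim_config(
        rng_seed = (seed * 131071L + mi * 8191L + p) %% 2147483629L,
        n_wells_per_group = 2, n_fields_per_well = 2,
        genotype_effects = list(
          wildtype = c(neurite = 1, soma = 1, whole_cell = 1),
          mutant = c(neurite = m, soma = m, whole_cell = m)),
        base_densities = c(neurite = 1.25, soma = 1, whole_cell = 1.5),
        punctum_diameter_um = c(0.6, 1.0), coloc_fraction = 0)
      q <- quantify_plate(generate_plate_images(cfg), channels = "puncta_a")
      r <- q$replicates
      rows[[length(rows) + 1L]] <- data.frame(
        multiplier = m, plate = p,
        ddpc = r$ddpc[r$compartment == "neurite" & r$genotype == "mutant"])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- tapply(out$ddpc, out$multiplier, mean)
  out
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = "compartquant_run",
    stages = list(simulate = TRUE, quantify = TRUE, stats = TRUE),
    image = list(),                 # overrides for image_sim_config()
    thresholds = list(k = 0, size_gate_um = c(0.4, 4), min_overlap = 0.5),
    stats = list(alpha = 0.05)
  )
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) run configuration, fills defaults, and checks
#' value ranges; unknown keys and out-of-range thresholds are reported
#' together in one itemized error. An empty file yields all defaults.
#'
#' @param path YAML/JSON file path, or NULL for pure defaults.
#' @return validated configuration list of class `run_config`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                             simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    errs <- character(0)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
    for (nm in intersect(names(user), names(cfg))) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      else cfg[[nm]] <- user[[nm]]
    }
    th <- cfg$thresholds
    if (!is.null(th$min_overlap) &&
        (th$min_overlap < 0 || th$min_overlap > 1))
      errs <- c(errs, "thresholds$min_overlap must lie in [0, 1]")
    if (!is.null(th$k) && th$k < 0)
      errs <- c(errs, "thresholds$k must be >= 0")
    if (!is.null(th$size_gate_um) &&
        (length(th$size_gate_um) != 2 || any(th$size_gate_um <= 0) ||
         diff(th$size_gate_um) <= 0))
      errs <- c(errs, "thresholds$size_gate_um must be an increasing positive pair")
    if (!is.null(cfg$stats$alpha) &&
        (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1))
      errs <- c(errs, "stats$alpha must lie in (0, 1)")
    if (length(errs) > 0)
      stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the simulate-segment-detect-quantify-statistics pipeline
#'
#' Executes the enabled stages in dependency order on a simulated plate,
#' writes tidy CSV results under the output directory, and returns a run
#' manifest with per-file checksums. Re-running with an unchanged
#' configuration reproduces identical checksums.
#'
#' @param config a `run_config` from [validate_config()] (or NULL for
#'   defaults).
#' @param out_dir overrides the configured output directory.
#' @return list of class `run_manifest`: `config`, `files` (named md5
#'   checksums), `results` (the in-memory tables), `warnings`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) validate_config(NULL) else config
  stopifnot(inherits(cfg, "run_config"))
  dir <- out_dir %||% cfg$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  warns <- character(0)
  results <- list()

  icfg <- do.call(image_sim_config,
                  c(cfg$image, list(rng_seed = cfg$seed)))
  plate <- generate_plate_images(icfg)
  utils::write.csv(plate$plate_map, file.path(dir, "plate_map.csv"),
                   row.names = FALSE)
  results$plate_map <- plate$plate_map

  if (isTRUE(cfg$stages$quantify)) {
    q <- withCallingHandlers(
      quantify_plate(plate, k = cfg$thresholds$k,
                     size_gate_um = cfg$thresholds$size_gate_um,
                     colocalization = TRUE),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    utils::write.csv(q$wells, file.path(dir, "well_morphology.csv"),
                     row.names = FALSE)
    utils::write.csv(q$puncta, file.path(dir, "puncta_quant.csv"),
                     row.names = FALSE)
    utils::write.csv(q$coloc, file.path(dir, "colocalization.csv"),
                     row.names = FALSE)
    results$quant <- q
  }

  if (isTRUE(cfg$stages$stats) && !is.null(results$quant)) {
    tidy <- results$quant$puncta
    sel <- tidy$channel == "puncta_a" & tidy$compartment == "neurite" &
      is.finite(tidy$ddpc)
    groups <- split(tidy$ddpc[sel], tidy$genotype[sel])
    stat <- if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
      gate <- tryCatch(normality_gate(groups, alpha = cfg$stats$alpha),
                       warning = function(w) list(branch = "nonparametric"))
      if (gate$branch == "parametric") {
        s <- oneway_anova(groups)
        list(branch = "parametric", test = s, posthoc = tukey_hsd(groups))
      } else {
        s <- kruskal_wallis(groups)
        list(branch = "nonparametric", test = s, posthoc = dunn_holm(groups))
      }
    } else NULL
    results$stats <- stat
    if (!is.null(stat)) {
      jsonlite::write_json(
        list(branch = stat$branch,
             statistic = stat$test$statistic, df = stat$test$df,
             p = stat$test$p, eta2 = stat$test$eta2,
             posthoc = stat$posthoc),
        file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  files <- list.files(dir, full.names = TRUE)
  structure(list(config = cfg,
                 files = tools::md5sum(files),
                 results = results,
                 warnings = warns),
            class = "run_manifest")
}
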